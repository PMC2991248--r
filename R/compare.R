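#' Rank BP candidates by Hamming distance to a strict consensus
#'
#' Consensus-complementarity baseline: every 9-mer window whose putative
#' branch adenosine (window position 6) lies within `window` nucleotides of
#' the 3SS is compared to the consensus, and candidates within `max_dist`
#' mismatches are ranked by ascending distance (ties towards the 3SS). With
#' `proximal_preference` the *prediction* is the candidate closest to the
#' 3SS among those passing `max_dist`, regardless of rank — top-ranked
#' candidates further upstream are discarded.
#'
#' @param introns Intron tibble or character vector.
#' @param consensus 9-nt consensus (default TACTAACAC, the U2-complementary
#'   sequence).
#' @param window Search region length upstream of the 3SS (e.g. 100 or 200).
#' @param max_dist Maximum Hamming distance a candidate may have.
#' @param proximal_preference Select the 3'-most passing candidate as the
#'   prediction instead of the best-ranked one.
#' @return Tibble `intron_id`, `bp_pos`, `ninemer`, `distance`, `rank`,
#'   `predicted` (at most one `TRUE` per intron).
#' @export
hamming_rank <- function(introns, consensus = "TACTAACAC", window = 100L,
                         max_dist = 2L, proximal_preference = TRUE) {
  stopifnot(nchar(consensus) == 9L)
  introns <- as_intron_tbl(introns)
  cons_chars <- seq_to_chars(toupper(consensus))
  rows <- purrr::map2(introns$intron_id, introns$sequence, function(id, seq) {
    L <- nchar(seq)
    from <- max(-L + 5L, -as.integer(window))
    a_pos <- seq(from, -4L) # adenosine slot of each window
    a_pos <- a_pos[a_pos + L - 5L >= 0L & a_pos + L + 3L <= L - 1L]
    if (length(a_pos) == 0L) {
      return(NULL)
    }
    o <- a_pos + L
    nm <- substring(seq, o - 4L, o + 4L)
    dist <- vapply(
      nm,
      function(x) sum(seq_to_chars(x) != cons_chars),
      integer(1), USE.NAMES = FALSE
    )
    keep <- dist <= max_dist & !grepl("N", nm, fixed = TRUE)
    if (!any(keep)) {
      return(NULL)
    }
    out <- tibble::tibble(
      intron_id = id, bp_pos = a_pos[keep],
      ninemer = nm[keep], distance = dist[keep]
    )
    out <- dplyr::arrange(out, .data$distance, dplyr::desc(.data$bp_pos))
    out$rank <- seq_len(nrow(out))
    out$predicted <- FALSE
    if (proximal_preference) {
      out$predicted[which.max(out$bp_pos)] <- TRUE
    } else {
      out$predicted[1L] <- TRUE
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      intron_id = character(), bp_pos = integer(), ninemer = character(),
      distance = integer(), rank = integer(), predicted = logical()
    )
  }
  out
}

#' Evaluate ranked BP predictions against mapped branch points
#'
#' A prediction is a hit when any mapped BP position of the intron equals
#' one of its top-k predicted positions (introns with several mapped BPs
#' count as correct if any one is found). Sensitivity is TP over the number
#' of introns in the truth set; positive predictive value is TP over the
#' number of introns for which the method emitted at least one top-k
#' prediction. The standard error of each proportion is
#' `sqrt(p * (1 - p) / n)`.
#'
#' @param predictions Tibble with `intron_id`, `bp_pos`, `rank` (1 = best),
#'   e.g. from [hamming_rank()] or the `candidates` table of
#'   [predict_branch_points()].
#' @param truth Tibble with `intron_id`, `bp_pos` (one row per mapped BP).
#' @param top_k Number of top-ranked candidates counted (default 1).
#' @return An object of class `bp_benchmark`: list with `per_intron`
#'   (intron_id, hit, n_predictions) and `summary` (n_introns, n_predicted,
#'   tp, sensitivity, ppv, se_sensitivity, se_ppv).
#' @export
evaluate_predictions <- function(predictions, truth, top_k = 1L) {
  stray <- setdiff(unique(predictions$intron_id), unique(truth$intron_id))
  if (length(stray) > 0L) {
    stop(
      "predictions for intron(s) absent from the truth set: ",
      paste(utils::head(stray, 5), collapse = ", ")
    )
  }
  preds <- dplyr::filter(predictions, .data$rank <= top_k)
  truth_by <- split(truth$bp_pos, truth$intron_id)
  pred_by <- split(preds$bp_pos, preds$intron_id)
  ids <- unique(truth$intron_id)
  per_intron <- tibble::tibble(
    intron_id = ids,
    n_predictions = lengths(pred_by[ids]),
    hit = purrr::map_lgl(ids, function(id) {
      p <- pred_by[[id]]
      !is.null(p) && any(truth_by[[id]] %in% p)
    })
  )
  n <- length(ids)
  n_pred <- sum(per_intron$n_predictions > 0L)
  tp <- sum(per_intron$hit)
  sens <- tp / n
  ppv <- if (n_pred > 0L) tp / n_pred else NA_real_
  summary <- tibble::tibble(
    n_introns = n, n_predicted = n_pred, tp = tp,
    sensitivity = sens,
    ppv = ppv,
    se_sensitivity = sqrt(sens * (1 - sens) / n),
    se_ppv = if (n_pred > 0L) sqrt(ppv * (1 - ppv) / n_pred) else NA_real_
  )
  structure(
    list(per_intron = per_intron, summary = summary, top_k = top_k),
    class = "bp_benchmark"
  )
}

#' @export
print.bp_benchmark <- function(x, ...) {
  cat("Branch-point benchmark (top-", x$top_k, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.bp_benchmark <- function(x, ...) x$per_intron

#' @export
glance.bp_benchmark <- function(x, ...) x$summary

#' Benchmark the SVM against baseline BP prediction methods
#'
#' Runs four methods on the same introns and evaluates each against the
#' truth table: the SVM model (top AGEZ candidate), a PWM-over-AGEZ
#' baseline (ranks the same AGEZ candidates by PWM log-odds), and two
#' consensus Hamming-distance baselines searching fixed windows of 100 and
#' 200 nt with proximal preference.
#'
#' @param introns Intron tibble.
#' @param truth Truth tibble (`intron_id`, `bp_pos`).
#' @param bundle Trained `bp_model_bundle`.
#' @param top_k Top-k criterion for the evaluation (default 1).
#' @param max_dist Hamming cutoff of the consensus baselines.
#' @return Tibble with one row per method: the [evaluate_predictions()]
#'   summary plus a `method` column.
#' @export
benchmark_bp_methods <- function(introns, truth, bundle, top_k = 1L,
                                 max_dist = 2L) {
  introns <- as_intron_tbl(introns)
  pred <- predict_branch_points(introns, bundle)
  svm_cand <- dplyr::filter(pred$candidates, !is.na(.data$rank))
  pwm_cand <- dplyr::mutate(
    svm_cand,
    pwm = pwm_score(bundle$pos_pwm, bundle$neg_pwm, .data$ninemer)
  )
  pwm_cand <- dplyr::arrange(
    dplyr::group_by(pwm_cand, .data$intron_id),
    dplyr::desc(.data$pwm), dplyr::desc(.data$bp_pos),
    .by_group = TRUE
  )
  pwm_cand <- dplyr::ungroup(
    dplyr::mutate(pwm_cand, rank = dplyr::row_number())
  )
  ham <- function(w) {
    h <- hamming_rank(
      introns,
      window = w, max_dist = max_dist, proximal_preference = TRUE
    )
    # with proximal preference the prediction, not the rank, is what counts
    h$rank <- ifelse(h$predicted, 1L, h$rank + 1L)
    h
  }
  methods <- list(
    svm_agez = svm_cand,
    pwm_agez = pwm_cand,
    hamming_100 = ham(100L),
    hamming_200 = ham(200L)
  )
  purrr::imap_dfr(methods, function(p, nm) {
    res <- evaluate_predictions(p, truth, top_k = top_k)
    dplyr::bind_cols(tibble::tibble(method = nm), res$summary)
  })
}

#' EST inclusion level of an exon
#'
#' `100 * I / (I + S)` where I ESTs include the exon and S ESTs skip it.
#' Exons with fewer than `min_total` informative ESTs are flagged as
#' filtered rather than dropped or erroring.
#'
#' @param n_incl,n_skip Integer vectors of inclusion / skipping EST counts.
#' @param min_total Minimum informative EST count (default 10).
#' @return Tibble `n_incl`, `n_skip`, `inclusion` (percentage),
#'   `pass_filter`.
#' @export
est_inclusion <- function(n_incl, n_skip, min_total = 10L) {
  stopifnot(length(n_incl) == length(n_skip), all(n_incl >= 0), all(n_skip >= 0))
  total <- n_incl + n_skip
  tibble::tibble(
    n_incl = as.integer(n_incl),
    n_skip = as.integer(n_skip),
    inclusion = ifelse(total > 0, 100 * n_incl / total, NA_real_),
    pass_filter = total >= min_total
  )
}
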