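FEATURE_NAMES <- c("motif_score", "py_content", "ppt_distance", "ppt_score")

#' Extract the four SVM features of BP candidates
#'
#' For each candidate 9-mer: the MM1 log-odds motif score, the pyrimidine
#' content of the interval strictly between the branch adenosine and the
#' acceptor AG (positions `bp_pos + 1 .. -3`), and the distance and score of
#' the closest downstream polypyrimidine tract.
#'
#' @param candidates Tibble with `intron_id`, `bp_pos`, `ninemer`.
#' @param introns Intron tibble with `intron_id`, `sequence`.
#' @param tracts Tract tibble from [find_ppts()]; computed here when `NULL`.
#' @param pos_mm1,neg_mm1 `bp_mm1_model`s for the log-odds motif score.
#' @param sentinel Distance reported when no downstream tract exists.
#' @return `candidates` with columns `motif_score`, `py_content`,
#'   `ppt_distance`, `ppt_score` added.
#' @export
extract_features <- function(candidates, introns, tracts = NULL,
                             pos_mm1, neg_mm1, sentinel = 500L) {
  introns <- as_intron_tbl(introns)
  if (is.null(tracts)) tracts <- find_ppts(introns)
  if (nrow(candidates) == 0L) {
    for (f in FEATURE_NAMES) candidates[[f]] <- numeric()
    return(candidates)
  }
  candidates$motif_score <- mm1_score(pos_mm1, neg_mm1, candidates$ninemer)
  seqs <- introns$sequence[match(candidates$intron_id, introns$intron_id)]
  candidates$py_content <- purrr::map2_dbl(
    seqs, candidates$bp_pos,
    function(seq, bp) {
      L <- nchar(seq)
      gap <- substring(seq, bp + 1L + L + 1L, -3L + L + 1L)
      mean(seq_to_chars(gap) %in% c("C", "T"))
    }
  )
  closest_downstream_ppt(candidates, tracts, sentinel = sentinel)
}

#' Sample negative training 9-mers
#'
#' Draws `n` canonical candidate positions uniformly without replacement from
#' the scan regions of a set of introns, excluding positive (intron,
#' position) pairs. Reproducible for a fixed seed.
#'
#' @param introns Intron tibble.
#' @param n Number of negatives to draw.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param exclude Tibble with `intron_id`, `bp_pos` of positions that may not
#'   be sampled (typically the positives).
#' @param region,min_dist Candidate scan region and minimum 3SS distance
#'   passed to [enumerate_candidates()].
#' @return Tibble `intron_id`, `bp_pos`, `ninemer` with `n` rows.
#' @export
sample_negatives <- function(introns, n, seed, exclude = NULL,
                             region = c(-500L, -3L), min_dist = 15L) {
  pool <- enumerate_candidates(introns, region = region, min_dist = min_dist)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    pool <- dplyr::anti_join(
      pool, exclude[c("intron_id", "bp_pos")],
      by = c("intron_id", "bp_pos")
    )
  }
  if (nrow(pool) < n) {
    stop("candidate pool (", nrow(pool), ") smaller than requested n = ", n)
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  pool[sort(idx), ]
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  code
}

#' Train the branch-point SVM on extracted features
#'
#' Balanced training: the larger class is downsampled (seeded) to the size of
#' the smaller one; features are standardized to mean 0 / sd 1 on the
#' training set and the statistics stored in the model. The decision
#' threshold is 0: candidates with positive decision values are labeled
#' branch points.
#'
#' @param features_pos,features_neg Tibbles with the four feature columns
#'   (see [extract_features()]).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost Soft-margin cost C (default 1).
#' @param seed Integer seed controlling the balancing subsample.
#' @return An object of class `bp_svm`.
#' @export
train_bp_svm <- function(features_pos, features_neg,
                         kernel = c("linear", "radial"), cost = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  xp <- as.matrix(features_pos[FEATURE_NAMES])
  xn <- as.matrix(features_neg[FEATURE_NAMES])
  if (nrow(xp) == 0L || nrow(xn) == 0L) {
    stop("both classes must be nonempty")
  }
  if (!all(is.finite(xp)) || !all(is.finite(xn))) {
    stop("non-finite feature values")
  }
  m <- min(nrow(xp), nrow(xn))
  with_seed(seed, {
    if (nrow(xp) > m) xp <- xp[sample.int(nrow(xp), m), , drop = FALSE]
    if (nrow(xn) > m) xn <- xn[sample.int(nrow(xn), m), , drop = FALSE]
  })
  x <- rbind(xp, xn)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  y <- factor(rep(c("bp", "bg"), c(nrow(xp), nrow(xn))), levels = c("bp", "bg"))
  fit <- e1071::svm(
    x = xs, y = y,
    kernel = kernel, cost = cost, scale = FALSE, probability = FALSE
  )
  structure(
    list(
      svm = fit, kernel = kernel, cost = cost, center = center, scale = scale,
      features = FEATURE_NAMES, seed = seed,
      n_pos = nrow(xp), n_neg = nrow(xn)
    ),
    class = "bp_svm"
  )
}

#' SVM decision values for candidate features
#'
#' Signed distance to the decision boundary in standardized feature space;
#' positive values mean predicted branch point.
#'
#' @param model A `bp_svm`.
#' @param features Tibble with the four feature columns.
#' @return Numeric vector of decision values.
#' @export
svm_decision <- function(model, features) {
  stopifnot(inherits(model, "bp_svm"))
  if (nrow(features) == 0L) {
    return(numeric())
  }
  x <- as.matrix(features[model$features])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  pred <- stats::predict(model$svm, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value by the order classes were seen; flip so
  # that positive always means the "bp" class
  if (colnames(dv)[1] == "bg/bp") dv <- -dv
  as.numeric(dv)
}

#' @export
print.bp_svm <- function(x, ...) {
  cat(
    "Branch-point SVM (", x$kernel, " kernel, C = ", x$cost, "), trained on ",
    x$n_pos, " positives / ", x$n_neg, " negatives\n",
    sep = ""
  )
  invisible(x)
}

#' Train a full branch-point model bundle
#'
#' Convenience wrapper that fits everything [predict_branch_points()] needs:
#' positive and negative MM1 models and PWMs from the 9-mers, then the SVM on
#' the extracted features. Negatives are drawn with [sample_negatives()]
#' (balanced: as many as there are positives).
#'
#' @param introns Intron tibble.
#' @param positives Tibble with `intron_id`, `bp_pos` of known/planted branch
#'   adenosines (3SS-anchored).
#' @param seed Integer seed (negative sampling and SVM balancing).
#' @param kernel,cost Passed to [train_bp_svm()].
#' @param pseudocount Passed to the motif model fits.
#' @param config Named list overriding scan defaults: `grace`, `min_dist`,
#'   `scan_window`, `sentinel`, `dbp_threshold`.
#' @param tracts Precomputed [find_ppts()] table for these introns
#'   (computed here when `NULL`).
#' @return An object of class `bp_model_bundle` with elements `pos_mm1`,
#'   `neg_mm1`, `pos_pwm`, `neg_pwm`, `svm`, `config`, and the training
#'   feature tables (`features_pos`, `features_neg`).
#' @export
train_bp_model <- function(introns, positives, seed = 1L,
                           kernel = "linear", cost = 1, pseudocount = 1,
                           config = list(), tracts = NULL) {
  introns <- as_intron_tbl(introns)
  cfg <- utils::modifyList(default_bp_config(), config)
  scan_region <- c(-cfg$scan_window, -3L)
  cand_all <- enumerate_candidates(
    introns,
    region = scan_region, min_dist = cfg$min_dist
  )
  pos <- dplyr::inner_join(
    cand_all, positives[c("intron_id", "bp_pos")],
    by = c("intron_id", "bp_pos")
  )
  if (nrow(pos) == 0L) {
    stop("no positive position coincides with a canonical candidate")
  }
  neg <- sample_negatives(
    introns, nrow(pos), seed,
    exclude = pos, region = scan_region, min_dist = cfg$min_dist
  )
  pos_mm1 <- fit_mm1(pos$ninemer, pseudocount)
  neg_mm1 <- fit_mm1(neg$ninemer, pseudocount)
  if (is.null(tracts)) tracts <- find_ppts(introns)
  fpos <- extract_features(
    pos, introns, tracts, pos_mm1, neg_mm1,
    sentinel = cfg$sentinel
  )
  fneg <- extract_features(
    neg, introns, tracts, pos_mm1, neg_mm1,
    sentinel = cfg$sentinel
  )
  svm <- train_bp_svm(fpos, fneg, kernel = kernel, cost = cost, seed = seed)
  structure(
    list(
      pos_mm1 = pos_mm1, neg_mm1 = neg_mm1,
      pos_pwm = fit_frequency_model(pos$ninemer, pseudocount),
      neg_pwm = fit_frequency_model(neg$ninemer, pseudocount),
      svm = svm, config = cfg,
      features_pos = fpos, features_neg = fneg
    ),
    class = "bp_model_bundle"
  )
}

#' Default prediction configuration
#'
#' @return Named list: `grace` (12 nt), `min_dist` (15 nt), `scan_window`
#'   (500 nt), `sentinel` (500 nt, no-downstream-PPT distance),
#'   `dbp_threshold` (100 nt, distant-BP cutoff), `max_extent` (500 nt, AGEZ
#'   truncation).
#' @export
default_bp_config <- function() {
  list(
    grace = 12L, min_dist = 15L, scan_window = 500L,
    sentinel = 500L, dbp_threshold = 100L, max_extent = 500L
  )
}

#' @export
print.bp_model_bundle <- function(x, ...) {
  cat("Branch-point model bundle\n")
  print(x$svm)
  cat(
    " MM1 models:", x$pos_mm1$n_seqs, "positive /",
    x$neg_mm1$n_seqs, "negative 9-mers\n"
  )
  invisible(x)
}

#' Score all BP candidates in the last n nucleotides of each intron
#'
#' Scores every canonical candidate in the 3'-terminal scan window, with no
#' AGEZ restriction (introns shorter than the window are scanned entirely).
#'
#' @param introns Intron tibble.
#' @param bundle A `bp_model_bundle` from [train_bp_model()].
#' @param n Scan window length (default from the bundle config, 500 nt).
#' @param tracts Precomputed [find_ppts()] table for these introns
#'   (computed here when `NULL`).
#' @return Candidate tibble with features and `svm_score`.
#' @export
scan_last_n <- function(introns, bundle, n = bundle$config$scan_window,
                        tracts = NULL) {
  introns <- as_intron_tbl(introns)
  cfg <- bundle$config
  cand <- enumerate_candidates(
    introns,
    region = c(-as.integer(n), -3L), min_dist = cfg$min_dist
  )
  cand <- extract_features(
    cand, introns, tracts, bundle$pos_mm1, bundle$neg_mm1,
    sentinel = cfg$sentinel
  )
  cand$svm_score <- svm_decision(bundle$svm, cand)
  cand
}

#' Predict branch points for a set of introns
#'
#' Scans the last `scan_window` nucleotides of each intron for canonical
#' candidates, delimits the first AGEZ, ranks the AGEZ candidates by SVM
#' score (ties broken towards the 3SS), and assigns each intron to one of
#' four categories: `no_candidates` (no canonical 9-mer in the scan region),
#' `none_in_agez` (candidates exist but none inside the first AGEZ),
#' `negative_scoring` (top AGEZ candidate below the zero decision threshold)
#' or `positive_scoring`. The best candidate is reported whenever the AGEZ
#' holds at least one, and flagged `is_distant` when its adenosine lies more
#' than `dbp_threshold` (default 100) nucleotides from the 3SS.
#'
#' @param introns Intron tibble.
#' @param bundle A `bp_model_bundle`.
#' @param tracts Precomputed [find_ppts()] table for these introns
#'   (computed here when `NULL`).
#' @return An object of class `bp_predictions`: a list with `predictions`
#'   (one row per intron) and `candidates` (all scored candidates, with
#'   `in_agez` and `rank`; rank 1 is the best AGEZ candidate). [tidy()]
#'   returns the candidate table, [glance()] the category counts.
#' @export
predict_branch_points <- function(introns, bundle, tracts = NULL) {
  introns <- as_intron_tbl(introns)
  cfg <- bundle$config
  cand <- scan_last_n(introns, bundle, tracts = tracts)
  agez <- find_agez(
    introns,
    grace = cfg$grace, rank = 0L, max_extent = cfg$max_extent
  )
  cand <- dplyr::left_join(
    cand,
    agez[c("intron_id", "agez_start", "agez_end")],
    by = "intron_id"
  )
  cand$in_agez <- cand$bp_pos >= cand$agez_start & cand$bp_pos <= cand$agez_end
  cand <- dplyr::arrange(
    cand, .data$intron_id,
    dplyr::desc(.data$in_agez), dplyr::desc(.data$svm_score),
    dplyr::desc(.data$bp_pos)
  )
  cand <- dplyr::mutate(
    dplyr::group_by(cand, .data$intron_id),
    rank = ifelse(.data$in_agez, cumsum(.data$in_agez), NA_integer_)
  )
  cand <- dplyr::ungroup(cand)
  best <- dplyr::filter(cand, !is.na(.data$rank) & .data$rank == 1L)
  n_cand <- dplyr::count(cand, .data$intron_id, name = "n_candidates")
  preds <- dplyr::left_join(agez, n_cand, by = "intron_id")
  preds$n_candidates[is.na(preds$n_candidates)] <- 0L
  preds <- dplyr::left_join(
    preds,
    dplyr::select(
      best, "intron_id",
      bp_pos = "bp_pos", ninemer = "ninemer",
      motif_score = "motif_score", py_content = "py_content",
      ppt_distance = "ppt_distance", ppt_score = "ppt_score",
      svm_score = "svm_score"
    ),
    by = "intron_id"
  )
  preds$category <- dplyr::case_when(
    preds$n_candidates == 0L ~ "no_candidates",
    is.na(preds$svm_score) ~ "none_in_agez",
    preds$svm_score > 0 ~ "positive_scoring",
    TRUE ~ "negative_scoring"
  )
  preds$is_distant <- !is.na(preds$bp_pos) &
    preds$bp_pos < -cfg$dbp_threshold
  structure(
    list(
      predictions = preds,
      candidates = dplyr::select(cand, -"agez_start", -"agez_end"),
      config = cfg
    ),
    class = "bp_predictions"
  )
}

#' @export
print.bp_predictions <- function(x, ...) {
  cat("Branch-point predictions for", nrow(x$predictions), "introns\n")
  print(table(x$predictions$category))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bp_predictions <- function(x, ...) {
  x$candidates
}

#' @export
glance.bp_predictions <- function(x, ...) {
  cats <- c(
    "no_candidates", "none_in_agez", "negative_scoring", "positive_scoring"
  )
  counts <- table(factor(x$predictions$category, levels = cats))
  out <- tibble::as_tibble(as.list(counts))
  out$n_introns <- nrow(x$predictions)
  out$n_distant <- sum(x$predictions$is_distant)
  out
}

#' @export
tidy.bp_svm <- function(x, ...) {
  if (x$kernel != "linear") {
    stop("coefficients are only available for the linear kernel")
  }
  w <- crossprod(x$svm$coefs, x$svm$SV)
  sgn <- if (x$svm$levels[1] == "bp") 1 else -1
  tibble::tibble(
    term = c("(intercept)", colnames(w)),
    estimate = c(-x$svm$rho, as.numeric(w)) * sgn
  )
}

#' @export
glance.bp_svm <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel, cost = x$cost,
    n_pos = x$n_pos, n_neg = x$n_neg,
    n_support_vectors = nrow(x$svm$SV)
  )
}

#' Histogram of predicted BP positions
#'
#' Tallies the best-candidate adenosine positions either relative to the 3SS
#' or re-anchored on the AGEZ-defining AG (position of the best candidate
#' minus position of the defining AG, so negative values are upstream of that
#' AG). Switching the anchor is a pure re-indexing: totals are preserved.
#'
#' @param predictions A `bp_predictions` object or its `predictions` tibble.
#' @param anchor `"3ss"` (default) or `"defining_ag"`.
#' @return Tibble `position`, `n`, sorted by position; total `n` equals the
#'   number of introns with a best candidate (for `"defining_ag"`, those that
#'   also have a defining AG).
#' @export
position_histogram <- function(predictions, anchor = c("3ss", "defining_ag")) {
  anchor <- match.arg(anchor)
  preds <- if (inherits(predictions, "bp_predictions")) {
    predictions$predictions
  } else {
    predictions
  }
  preds <- dplyr::filter(preds, !is.na(.data$bp_pos))
  pos <- if (anchor == "3ss") {
    preds$bp_pos
  } else {
    preds <- dplyr::filter(preds, !is.na(.data$defining_ag))
    preds$bp_pos - preds$defining_ag
  }
  out <- dplyr::count(tibble::tibble(position = pos), .data$position)
  dplyr::arrange(out, .data$position)
}

#' k-fold cross-validation of the SVM, MM1 and PWM scores
#'
#' Splits the labeled candidates into k folds; in each fold the MM1 and PWM
#' models are refit on the training part, features recomputed, the SVM
#' retrained, and the held-out part scored. Reports per-fold accuracy at the
#' zero decision threshold and the ROC AUC of the SVM decision value, the
#' MM1 log-odds alone, and the PWM log-odds alone.
#'
#' @param features_pos,features_neg Labeled candidate tibbles with `ninemer`
#'   plus the PPT feature columns (`py_content`, `ppt_distance`, `ppt_score`),
#'   e.g. the `features_pos` / `features_neg` elements of a trained bundle.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param kernel,cost,pseudocount Model settings, as in [train_bp_model()].
#' @return Tibble with one row per fold: `fold`, `accuracy`, `auc_svm`,
#'   `auc_mm1`, `auc_pwm`.
#' @export
cv_bp_models <- function(features_pos, features_neg, folds = 10L, seed = 1L,
                         kernel = "linear", cost = 1, pseudocount = 1) {
  np <- nrow(features_pos)
  nn <- nrow(features_neg)
  fold_p <- with_seed(seed, sample(rep_len(seq_len(folds), np)))
  fold_n <- with_seed(seed + 1L, sample(rep_len(seq_len(folds), nn)))
  purrr::map_dfr(seq_len(folds), function(k) {
    trn_p <- features_pos[fold_p != k, ]
    trn_n <- features_neg[fold_n != k, ]
    tst_p <- features_pos[fold_p == k, ]
    tst_n <- features_neg[fold_n == k, ]
    pos_mm1 <- fit_mm1(trn_p$ninemer, pseudocount)
    neg_mm1 <- fit_mm1(trn_n$ninemer, pseudocount)
    pos_pwm <- fit_frequency_model(trn_p$ninemer, pseudocount)
    neg_pwm <- fit_frequency_model(trn_n$ninemer, pseudocount)
    rescore <- function(tbl) {
      tbl$motif_score <- mm1_score(pos_mm1, neg_mm1, tbl$ninemer)
      tbl
    }
    trn_p <- rescore(trn_p)
    trn_n <- rescore(trn_n)
    tst_p <- rescore(tst_p)
    tst_n <- rescore(tst_n)
    fit <- train_bp_svm(trn_p, trn_n, kernel = kernel, cost = cost, seed = seed)
    tst <- dplyr::bind_rows(tst_p, tst_n)
    labels <- rep(c(TRUE, FALSE), c(nrow(tst_p), nrow(tst_n)))
    dv <- svm_decision(fit, tst)
    tibble::tibble(
      fold = k,
      accuracy = mean((dv > 0) == labels),
      auc_svm = rank_auc(dv, labels),
      auc_mm1 = rank_auc(tst$motif_score, labels),
      auc_pwm = rank_auc(
        pwm_score(pos_pwm, neg_pwm, tst$ninemer), labels
      )
    )
  })
}

# Mann-Whitney AUC: probability that a random positive outscores a random
# negative (ties counted half)
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load a model bundle
#'
#' The bundle directory holds the four motif models and the SVM as plain
#' files (JSON and an RDS for the libsvm fit) together with a config echo,
#' so trained bundles are portable across sessions.
#'
#' @param bundle A `bp_model_bundle`.
#' @param dir Directory path (created if needed).
#' @return `write_model_bundle()` returns `dir` invisibly;
#'   `read_model_bundle()` returns the bundle.
#' @export
write_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bp_model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_motif_model(bundle$pos_mm1, file.path(dir, "pos_mm1.json"))
  write_motif_model(bundle$neg_mm1, file.path(dir, "neg_mm1.json"))
  write_motif_model(bundle$pos_pwm, file.path(dir, "pos_pwm.json"))
  write_motif_model(bundle$neg_pwm, file.path(dir, "neg_pwm.json"))
  saveRDS(bundle$svm, file.path(dir, "svm.rds"))
  jsonlite::write_json(
    c(list(format = "lariatr-bundle", version = 1L), bundle$config),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
    simplifyVector = TRUE
  )
  if (!identical(cfg$format, "lariatr-bundle")) {
    stop("'", dir, "' is not a lariatr model bundle")
  }
  cfg$format <- NULL
  cfg$version <- NULL
  structure(
    list(
      pos_mm1 = read_motif_model(file.path(dir, "pos_mm1.json")),
      neg_mm1 = read_motif_model(file.path(dir, "neg_mm1.json")),
      pos_pwm = read_motif_model(file.path(dir, "pos_pwm.json")),
      neg_pwm = read_motif_model(file.path(dir, "neg_pwm.json")),
      svm = readRDS(file.path(dir, "svm.rds")),
      config = lapply(cfg, function(v) if (is.numeric(v)) as.integer(v) else v)
    ),
    class = "bp_model_bundle"
  )
}
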