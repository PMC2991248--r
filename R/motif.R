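NTS <- c("A", "C", "G", "T")
# MM1 chain over the free positions; 4 and 6 are fixed as T and A. Position 5
# conditions on 3 and position 7 on 5 (second-order skips over the fixed
# positions).
MM1_CHAIN <- c(1L, 2L, 3L, 5L, 7L, 8L, 9L)

check_ninemers <- function(seqs, canonical = TRUE) {
  if (length(seqs) == 0L) stop("empty 9-mer set")
  if (any(nchar(seqs) != 9L)) stop("all sequences must be 9-mers")
  if (any(grepl("[^ACGT]", seqs))) stop("9-mers must be over A/C/G/T")
  if (canonical &&
      (any(substring(seqs, 4, 4) != "T") || any(substring(seqs, 6, 6) != "A"))) {
    stop("non-canonical 9-mer: need T at position 4 and A at position 6")
  }
  invisible(seqs)
}

ninemer_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
    nrow = length(seqs), ncol = 9L, byrow = TRUE
  )
}

#' Fit a per-position nucleotide frequency model of the BP 9-mer
#'
#' Position-independent model used for information content, sequence logos and
#' the PWM score. Probabilities are Laplace-smoothed:
#' `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param seqs Character vector of 9-mers over A/C/G/T.
#' @param pseudocount Added to every cell before normalization (default 1).
#' @return An object of class `bp_freq_model` with elements `counts` and
#'   `probs` (9 x 4 matrices, columns A/C/G/T), `n_seqs`, `pseudocount`.
#' @export
fit_frequency_model <- function(seqs, pseudocount = 1) {
  check_ninemers(seqs, canonical = FALSE)
  m <- ninemer_matrix(seqs)
  counts <- t(vapply(
    1:9,
    function(i) table(factor(m[, i], levels = NTS)),
    numeric(4)
  ))
  dimnames(counts) <- list(position = 1:9, nucleotide = NTS)
  probs <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  structure(
    list(
      counts = counts, probs = probs,
      n_seqs = length(seqs), pseudocount = pseudocount
    ),
    class = "bp_freq_model"
  )
}

#' @export
print.bp_freq_model <- function(x, ...) {
  cat("Per-position frequency model of a 9-mer,", x$n_seqs, "sequences\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Information content of a frequency model
#'
#' Per-position conservation in bits, `IC_i = 2 + sum_n p * log2(p)` with
#' `0 * log2(0) = 0`, so a uniform position carries 0 bits and an invariant
#' one 2 bits. The total is the sum over the 9 positions.
#'
#' @param model A `bp_freq_model`.
#' @return A list with `per_position` (numeric length 9) and `total`.
#' @export
information_content <- function(model) {
  stopifnot(inherits(model, "bp_freq_model"))
  p <- model$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  per_pos <- 2 + rowSums(plogp)
  list(per_position = unname(per_pos), total = sum(per_pos))
}

#' Mutual information between 9-mer positions
#'
#' `MI(i, j) = sum p(n_i, m_j) log2( p(n_i, m_j) / (p(n_i) p(m_j)) )` over
#' empirical (unsmoothed) frequencies. The invariant positions 4 and 6 are
#' reported as `NA`.
#'
#' @param seqs Character vector of canonical 9-mers (n >= 2).
#' @return A symmetric 9 x 9 matrix; diagonal and rows/columns 4 and 6 `NA`.
#' @export
mutual_information <- function(seqs) {
  check_ninemers(seqs, canonical = FALSE)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- ninemer_matrix(seqs)
  n <- nrow(m)
  marg <- lapply(1:9, function(i) table(factor(m[, i], levels = NTS)) / n)
  mi <- matrix(NA_real_, 9, 9)
  for (i in 1:8) {
    for (j in (i + 1):9) {
      if (i %in% c(4L, 6L) || j %in% c(4L, 6L)) next
      joint <- table(
        factor(m[, i], levels = NTS),
        factor(m[, j], levels = NTS)
      ) / n
      expct <- outer(as.numeric(marg[[i]]), as.numeric(marg[[j]]))
      term <- ifelse(joint > 0, joint * log2(joint / expct), 0)
      mi[i, j] <- mi[j, i] <- sum(term)
    }
  }
  mi
}

#' Fit the position-dependent first-order Markov model (MM1) of the BP signal
#'
#' Models the canonical 9-mer with positions 4 and 6 fixed as T and A. The
#' remaining positions form the chain 1 -> 2 -> 3 -> 5 -> 7 -> 8 -> 9: the
#' probability of a 9-mer is the initial probability of position 1 times the
#' conditional probabilities along the chain. Conditioning position 5 on 3 and
#' position 7 on 5 realizes second-order dependencies across the fixed
#' positions. Estimates are Laplace-smoothed per conditional distribution.
#'
#' @param seqs Character vector of canonical 9-mers.
#' @param pseudocount Added to every transition cell (default 1).
#' @return An object of class `bp_mm1_model`: `initial` (length-4 probability
#'   vector), `transitions` (list of 4 x 4 matrices, one per chain step,
#'   rows = conditioning nucleotide), `chain`, `n_seqs`, `pseudocount`.
#' @export
fit_mm1 <- function(seqs, pseudocount = 1) {
  check_ninemers(seqs, canonical = TRUE)
  m <- ninemer_matrix(seqs)
  init_counts <- table(factor(m[, 1], levels = NTS))
  initial <- (as.numeric(init_counts) + pseudocount) /
    (length(seqs) + 4 * pseudocount)
  names(initial) <- NTS
  steps <- cbind(MM1_CHAIN[-length(MM1_CHAIN)], MM1_CHAIN[-1])
  transitions <- lapply(seq_len(nrow(steps)), function(s) {
    from <- factor(m[, steps[s, 1]], levels = NTS)
    to <- factor(m[, steps[s, 2]], levels = NTS)
    counts <- table(from, to)
    probs <- (counts + pseudocount) /
      (rowSums(counts) + 4 * pseudocount)
    mat <- matrix(as.numeric(probs), 4, 4, dimnames = list(NTS, NTS))
    mat
  })
  names(transitions) <- paste0(steps[, 1], "->", steps[, 2])
  structure(
    list(
      initial = initial, transitions = transitions, chain = MM1_CHAIN,
      n_seqs = length(seqs), pseudocount = pseudocount
    ),
    class = "bp_mm1_model"
  )
}

#' @export
print.bp_mm1_model <- function(x, ...) {
  cat(
    "Position-dependent order-1 Markov model of the BP 9-mer,",
    x$n_seqs, "sequences; chain", paste(x$chain, collapse = "-"), "\n"
  )
  invisible(x)
}

# log2 probability of canonical 9-mers under an MM1 model (vectorized)
mm1_log2prob <- function(model, ninemers) {
  m <- ninemer_matrix(ninemers)
  idx <- function(chars) match(chars, NTS)
  lp <- log2(model$initial)[idx(m[, 1])]
  chain <- model$chain
  for (s in seq_along(model$transitions)) {
    from <- idx(m[, chain[s]])
    to <- idx(m[, chain[s + 1]])
    lp <- lp + log2(model$transitions[[s]])[cbind(from, to)]
  }
  unname(lp)
}

# log2 probability under a per-position frequency model, restricted to the
# free positions of the canonical 9-mer (so that PWM and MM1 log-odds are on
# the same 7-position support)
pwm_log2prob <- function(model, ninemers) {
  m <- ninemer_matrix(ninemers)
  free <- MM1_CHAIN
  lp <- rep(0, length(ninemers))
  for (i in free) {
    lp <- lp + log2(model$probs)[cbind(rep(i, nrow(m)), match(m[, i], NTS))]
  }
  unname(lp)
}

#' Motif log-odds scores for candidate 9-mers
#'
#' `mm1_score()` scores canonical 9-mers as `log2(P_pos / P_neg)` under a pair
#' of MM1 models; `pwm_score()` does the same under position-independent
#' frequency models (over the 7 free positions, so the two scores are
#' comparable). Positive scores mean the 9-mer looks more like the positive
#' (branch point) set than the negative (background) set.
#'
#' @param pos,neg Models of matching class (`bp_mm1_model` for [mm1_score()],
#'   `bp_freq_model` for [pwm_score()]).
#' @param ninemer Character vector of canonical 9-mers.
#' @return Numeric vector of log2 odds scores.
#' @export
mm1_score <- function(pos, neg, ninemer) {
  stopifnot(inherits(pos, "bp_mm1_model"), inherits(neg, "bp_mm1_model"))
  check_ninemers(ninemer, canonical = TRUE)
  mm1_log2prob(pos, ninemer) - mm1_log2prob(neg, ninemer)
}

#' @rdname mm1_score
#' @export
pwm_score <- function(pos, neg, ninemer) {
  stopifnot(inherits(pos, "bp_freq_model"), inherits(neg, "bp_freq_model"))
  check_ninemers(ninemer, canonical = TRUE)
  pwm_log2prob(pos, ninemer) - pwm_log2prob(neg, ninemer)
}

#' All canonical 9-mers
#'
#' The 4^7 = 16384 9-mers with T at position 4 and A at position 6.
#'
#' @return Character vector of length 16384.
#' @export
all_canonical_ninemers <- function() {
  g <- expand.grid(rep(list(NTS), 7), stringsAsFactors = FALSE)[7:1]
  paste0(g[[1]], g[[2]], g[[3]], "T", g[[4]], "A", g[[5]], g[[6]], g[[7]])
}

#' U2 snRNA duplex energy of a branch-point 9-mer
#'
#' Folds each 9-mer against the U2 branch-site recognition sequence with the
#' ViennaRNA `RNAcofold` program, forcing every nucleotide to pair except the
#' branch adenosine (position 6), which is forced to stay unpaired (it bulges
#' out of the U2 helix). Lower (more negative) energies mean a more stable
#' duplex. The U2 strand used is GUGUUAGUA, the reverse complement of the
#' consensus-complementary sequence TACTAACAC; the constraint string is
#' `(((((x(((` for the 9-mer and `(((x(((((` for the U2 strand.
#'
#' @param ninemer Character vector of canonical 9-mers (DNA; T is transcribed
#'   to U internally).
#' @param backend Path to the `RNAcofold` executable; the default looks it up
#'   on `PATH`. If it cannot be found the function stops with an explicit
#'   error rather than silently falling back.
#' @return Numeric vector of duplex free energies in kcal/mol.
#' @export
u2_duplex_energy <- function(ninemer, backend = Sys.which("RNAcofold")) {
  check_ninemers(ninemer, canonical = TRUE)
  if (is.null(backend) || !nzchar(backend) || !file.exists(backend)) {
    stop(
      "U2 duplex energy is disabled: RNAcofold backend not available. ",
      "Install ViennaRNA or pass its path via `backend`."
    )
  }
  u2 <- "GUGUUAGUA"
  rna <- chartr("T", "U", ninemer)
  input <- as.vector(rbind(
    paste0(rna, "&", u2),
    rep("(((((x(((&(((x(((((", length(rna))
  ))
  out <- system2(backend, c("-C", "--noPS"), stdout = TRUE, input = input)
  energy_lines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(energy_lines) != length(rna)) {
    stop("RNAcofold returned an unexpected number of structures")
  }
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", energy_lines))
}

#' Serialize / restore motif models
#'
#' Writes a frequency or MM1 model to a small versioned JSON file so trained
#' models are portable and diffable, and reads it back.
#'
#' @param model A `bp_freq_model` or `bp_mm1_model`.
#' @param path File path.
#' @return `write_motif_model()` returns `path` invisibly;
#'   `read_motif_model()` returns the model object.
#' @export
write_motif_model <- function(model, path) {
  if (inherits(model, "bp_freq_model")) {
    payload <- list(
      format = "lariatr-motif-model", version = 1L, type = "freq",
      counts = model$counts, n_seqs = model$n_seqs,
      pseudocount = model$pseudocount
    )
  } else if (inherits(model, "bp_mm1_model")) {
    payload <- list(
      format = "lariatr-motif-model", version = 1L, type = "mm1",
      initial = model$initial, transitions = model$transitions,
      chain = model$chain, n_seqs = model$n_seqs,
      pseudocount = model$pseudocount
    )
  } else {
    stop("not a motif model")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_motif_model
#' @export
read_motif_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "lariatr-motif-model")) {
    stop("'", path, "' is not a lariatr motif model file")
  }
  if (x$type == "freq") {
    counts <- matrix(unlist(x$counts), 9, 4,
      dimnames = list(position = 1:9, nucleotide = NTS)
    )
    probs <- (counts + x$pseudocount) / (x$n_seqs + 4 * x$pseudocount)
    structure(
      list(
        counts = counts, probs = probs,
        n_seqs = x$n_seqs, pseudocount = x$pseudocount
      ),
      class = "bp_freq_model"
    )
  } else {
    transitions <- lapply(x$transitions, function(m) {
      matrix(unlist(m), 4, 4, dimnames = list(NTS, NTS))
    })
    initial <- unlist(x$initial)
    names(initial) <- NTS
    structure(
      list(
        initial = initial, transitions = transitions,
        chain = as.integer(x$chain), n_seqs = x$n_seqs,
        pseudocount = x$pseudocount
      ),
      class = "bp_mm1_model"
    )
  }
}
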