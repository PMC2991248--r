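#' Configuration for the synthetic intron generator
#'
#' The generator emulates the 3'-end architecture of mammalian introns: a
#' planted canonical branch-point 9-mer whose adenosine position peaks at
#' -24 with 96% of the mass between -55 and -15 and a small distal tail, a
#' downstream polypyrimidine tract, an acceptor AG, and (by default) no
#' competing AG between the planted adenosine and the 3SS grace region, so
#' the planted BP lies inside the first AGEZ. The planted 9-mer is sampled
#' from per-position marginals consistent with the degenerate YTNAY branch
#' consensus, with a marginal-preserving first-order dependency between
#' adjacent free positions (pyrimidine/purine-class coupling of strength
#' `motif_dependency`) so that a Markov model genuinely captures more signal
#' than a PWM.
#'
#' @param n_introns Number of introns.
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @param length_meanlog,length_sdlog,length_range Log-normal intron length
#'   distribution, clipped to `length_range`.
#' @param bg_probs Background nucleotide probabilities (A, C, G, T).
#' @param bp_pos_weights Mixture weights of the planted-position components:
#'   proximal truncated-normal peak, mid tail, deep tail.
#' @param bp_peak,bp_sd Center and sd of the proximal peak (default -24, 7).
#' @param proximal_window,mid_range,deep_range Supports of the three
#'   position components.
#' @param motif_marginals 7 x 4 matrix of marginals for the free 9-mer
#'   positions (rows 1,2,3,5,7,8,9; columns A,C,G,T).
#' @param motif_dependency Strength (0 to 0.5) of the marginal-preserving
#'   pyrimidine/purine-class coupling between adjacent free positions
#'   (default 0.35; 0 = independent positions).
#' @param planted_cores Optional character vector of central pentamers
#'   (pattern N T N A N); when given, the sampled 9-mer's positions 3-7 are
#'   overwritten by a uniformly drawn member, giving a small explicit
#'   planted pentamer family (used for trainset recovery experiments).
#' @param ppt_gap_max Maximum gap between the 9-mer end and the tract start.
#' @param ppt_len_range Planted tract length range.
#' @param ppt_t_prob T probability within tract pyrimidines (rest C).
#' @param ppt_purine_rate Rate of isolated purine interruptions.
#' @param ag_free Scrub AG dinucleotides between the planted adenosine and
#'   the grace region so the planted BP falls inside the first AGEZ.
#' @param grace Grace region used for scrubbing (default 12).
#' @param species Species names for alignment blocks (reference first).
#' @param cons_background Per-site, per-species probability that a
#'   background column is conserved.
#' @param cons_bp Probability that the planted central pentamer survives
#'   intact in a given species.
#' @param gap_rate Per-species probability of one random deletion (gap)
#'   outside the planted pentamer.
#' @param block_len Alignment block length (last `block_len` nt; default 300).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_introns = 5000L,
                         seed,
                         length_meanlog = log(700),
                         length_sdlog = 0.5,
                         length_range = c(320L, 3000L),
                         bg_probs = c(A = 0.27, C = 0.22, G = 0.22, T = 0.29),
                         bp_pos_weights = c(0.96, 0.036, 0.004),
                         bp_peak = -24L, bp_sd = 7,
                         proximal_window = c(-55L, -15L),
                         mid_range = c(-100L, -56L),
                         deep_range = c(-300L, -101L),
                         motif_marginals = default_motif_marginals(),
                         motif_dependency = 0.35,
                         planted_cores = NULL,
                         ppt_gap_max = 2L,
                         ppt_len_range = c(12L, 25L),
                         ppt_t_prob = 0.7,
                         ppt_purine_rate = 0.1,
                         ag_free = TRUE,
                         grace = 12L,
                         species = c(
                           "human", "chimp", "macaque", "mouse",
                           "rat", "dog", "cow"
                         ),
                         cons_background = 0.9,
                         cons_bp = 0.95,
                         gap_rate = 0,
                         block_len = 300L) {
  if (missing(seed)) stop("a seed is mandatory for dataset generation")
  stopifnot(
    abs(sum(bg_probs) - 1) < 1e-9,
    abs(sum(bp_pos_weights) - 1) < 1e-9,
    all(abs(rowSums(motif_marginals) - 1) < 1e-9),
    motif_dependency >= 0, motif_dependency <= 0.5
  )
  if (!is.null(planted_cores) &&
      !all(grepl("^.T.A.$", planted_cores))) {
    stop("planted cores must match the pattern NTNAN")
  }
  structure(
    as.list(environment()),
    class = "synth_config"
  )
}

#' Default planted-motif marginals
#'
#' Per-position nucleotide probabilities of the planted BP 9-mer's free
#' positions (1, 2, 3, 5, 7, 8, 9), consistent with the degenerate YTNAY
#' consensus: pyrimidine-rich at -1/+1 of the branch A, T-depleted between
#' the fixed T and A, weakly informative flanks.
#'
#' @return A 7 x 4 matrix (columns A, C, G, T).
#' @export
default_motif_marginals <- function() {
  m <- rbind(
    c(0.30, 0.15, 0.15, 0.40), # pos 1
    c(0.20, 0.20, 0.15, 0.45), # pos 2
    c(0.10, 0.30, 0.15, 0.45), # pos 3 (Y-rich)
    c(0.35, 0.25, 0.30, 0.10), # pos 5 (T rare)
    c(0.20, 0.30, 0.15, 0.35), # pos 7 (Y-rich)
    c(0.30, 0.20, 0.20, 0.30), # pos 8
    c(0.25, 0.25, 0.20, 0.30) # pos 9
  )
  dimnames(m) <- list(c(1, 2, 3, 5, 7, 8, 9), c("A", "C", "G", "T"))
  m
}

# Adjacent free positions co-vary in pyrimidine/purine class:
# P(b | a) = marg_j(b) * (1 + eps * s(a) * (s(b) - m_j)) with s = +1 for
# pyrimidines, -1 for purines and m_j = E[s] under marg_j. This preserves
# the per-position marginals exactly (so the planted consensus stays YTNAY
# with T rare at the central position) while giving the chain genuine
# first-order dependencies that a PWM cannot capture.
sample_planted_ninemer <- function(config) {
  marg <- config$motif_marginals
  eps <- config$motif_dependency
  s_class <- c(A = -1, C = 1, G = -1, T = 1)
  free <- character(7)
  free[1] <- sample(NTS, 1L, prob = marg[1, ])
  for (j in 2:7) {
    m_j <- sum(marg[j, ] * s_class)
    probs <- marg[j, ] * (1 + eps * s_class[free[j - 1]] * (s_class - m_j))
    free[j] <- sample(NTS, 1L, prob = probs)
  }
  nm <- c(free[1:3], "T", free[4], "A", free[5:7])
  if (!is.null(config$planted_cores)) {
    core <- sample(config$planted_cores, 1L)
    nm[3:7] <- seq_to_chars(core)
  }
  nm
}

sample_bp_position <- function(config, max_depth) {
  repeat {
    comp <- sample.int(3L, 1L, prob = config$bp_pos_weights)
    pos <- switch(comp,
      {
        # truncated discretized normal (rejection, so no boundary pile-up)
        repeat {
          p <- round(stats::rnorm(1, config$bp_peak, config$bp_sd))
          if (p >= config$proximal_window[1] &&
              p <= config$proximal_window[2]) {
            break
          }
        }
        p
      },
      sample(config$mid_range[1]:config$mid_range[2], 1L),
      sample(config$deep_range[1]:config$deep_range[2], 1L)
    )
    if (pos >= -max_depth) {
      return(as.integer(pos))
    }
  }
}

# A tract passing the PPT rules by construction: pyrimidine blocks (>= 2 nt)
# separated by isolated single purines.
sample_ppt_tract <- function(config, len) {
  pyr <- function(n) {
    sample(c("T", "C"), n,
      replace = TRUE,
      prob = c(config$ppt_t_prob, 1 - config$ppt_t_prob)
    )
  }
  out <- pyr(2L)
  while (length(out) < len) {
    if (length(out) <= len - 3L && stats::runif(1) < config$ppt_purine_rate) {
      out <- c(out, sample(c("A", "G"), 1L), pyr(2L))
    } else {
      out <- c(out, pyr(1L))
    }
  }
  out[seq_len(len)]
}

generate_one_intron <- function(config, id) {
  L <- round(stats::rlnorm(1, config$length_meanlog, config$length_sdlog))
  L <- as.integer(min(max(L, config$length_range[1]), config$length_range[2]))
  b <- sample_bp_position(config, max_depth = L - 40L)
  chars <- sample(NTS, L, replace = TRUE, prob = config$bg_probs)
  chars[1:2] <- c("G", "T")
  idx <- function(p) p + L + 1L
  chars[idx(b - 5L):idx(b + 3L)] <- sample_planted_ninemer(config)
  # plant the PPT downstream of the 9-mer; squeeze towards the adenosine for
  # proximal branch points that leave little room
  len <- sample(config$ppt_len_range[1]:config$ppt_len_range[2], 1L)
  gap <- sample(0:config$ppt_gap_max, 1L)
  start <- b + 4L + gap
  room <- -3L - start + 1L
  if (room < 9L) {
    start <- b + 1L
    room <- -3L - start + 1L
  }
  len <- min(len, room)
  chars[idx(start):idx(start + len - 1L)] <- sample_ppt_tract(config, len)
  chars[c(L - 1L, L)] <- c("A", "G")
  if (isTRUE(config$ag_free)) {
    scrub <- idx(b):(idx(-3L))
    for (i in scrub) {
      p <- i - L - 1L
      if (p < -config$grace && chars[i] == "A" && chars[i + 1L] == "G") {
        chars[i + 1L] <- "C"
      }
    }
  }
  tibble::tibble(
    intron_id = id,
    sequence = paste(chars, collapse = ""),
    length = L,
    bp_pos = b,
    ninemer = paste(chars[idx(b - 5L):idx(b + 3L)], collapse = "")
  )
}

#' Generate synthetic introns with planted branch points
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per intron: `intron_id`, `sequence`,
#'   `length`, and the planted truth `bp_pos`, `ninemer`. The intron columns
#'   feed directly into the prediction functions; `bp_pos`/`ninemer` are the
#'   ground truth for evaluation.
#' @export
generate_introns <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    dplyr::bind_rows(lapply(
      seq_len(config$n_introns),
      function(i) generate_one_intron(config, sprintf("synth_%05d", i))
    ))
  })
}

#' Write a synthetic dataset to FASTA + truth TSV
#'
#' Byte-identical outputs for identical configs (including the seed). The
#' config is echoed alongside as JSON for provenance.
#'
#' @param config A [synth_config()].
#' @param fasta,truth,config_json Output paths (`config_json = NULL` skips
#'   the echo).
#' @return The generated tibble, invisibly.
#' @export
generate_dataset <- function(config, fasta, truth, config_json = NULL) {
  dat <- generate_introns(config)
  write_intron_fasta(dat, fasta)
  utils::write.table(
    dat[c("intron_id", "bp_pos", "ninemer")],
    truth,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(config_json)) {
    cfg <- unclass(config)
    cfg$motif_marginals <- as.data.frame(cfg$motif_marginals)
    jsonlite::write_json(
      cfg, config_json,
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(dat)
}

#' Generate multi-species alignment blocks with a planted BP pentamer
#'
#' Takes the last `block_len` nucleotides of each generated intron as the
#' reference row and derives the other species by per-site substitution at
#' rate `1 - cons_background`; the planted central pentamer (9-mer positions
#' 3-7) is left intact with probability `cons_bp` per species, so its
#' conserved instances accumulate at the planted positions. Optional single
#' deletions model alignment gaps.
#'
#' @param config A [synth_config()]; `n_introns` blocks are produced.
#' @return A list with `blocks` (tibble `intron_id`, `species`, `alignment`;
#'   reference row first per intron) and `truth` (tibble `intron_id`,
#'   `bp_pos`, `ninemer`, `core_pentamer`).
#' @export
generate_alignment_blocks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dat <- generate_introns(config)
  nsp <- length(config$species)
  with_seed(config$seed + 1L, {
    blocks <- dplyr::bind_rows(lapply(seq_len(nrow(dat)), function(i) {
      L <- dat$length[i]
      bl <- config$block_len
      ref <- seq_to_chars(substring(dat$sequence[i], L - bl + 1L, L))
      b <- dat$bp_pos[i]
      core_cols <- (b - 3L):(b + 1L) + bl + 1L # 9-mer positions 3..7
      core_cols <- core_cols[core_cols >= 1L & core_cols <= bl]
      rows <- matrix("", nrow = nsp, ncol = bl)
      rows[1, ] <- ref
      for (s in 2:nsp) {
        row <- ref
        mut <- stats::runif(bl) > config$cons_background
        if (any(mut)) {
          row[mut] <- vapply(
            ref[mut],
            function(nt) sample(setdiff(NTS, nt), 1L),
            character(1), USE.NAMES = FALSE
          )
        }
        if (stats::runif(1) < config$cons_bp) {
          row[core_cols] <- ref[core_cols]
        }
        if (config$gap_rate > 0 && stats::runif(1) < config$gap_rate) {
          gapable <- setdiff(seq_len(bl), core_cols)
          row[sample(gapable, 1L)] <- "-"
        }
        rows[s, ] <- row
      }
      tibble::tibble(
        intron_id = dat$intron_id[i],
        species = config$species,
        alignment = apply(rows, 1, paste, collapse = "")
      )
    }))
    truth <- dat[c("intron_id", "bp_pos", "ninemer")]
    truth$core_pentamer <- substring(truth$ninemer, 3L, 7L)
    list(blocks = blocks, truth = truth)
  })
}

#' Detectability diagnostics of a generator configuration
#'
#' Monte-Carlo estimate of the expected log2-odds gap between the planted
#' 9-mer model and the background composition over the free positions — an
#' upper bound on the per-candidate motif information available to any
#' scoring scheme on data from this generator.
#'
#' @param config A [synth_config()].
#' @param n Number of sampled 9-mers.
#' @return A tibble with `mean_log2_odds` and `sd_log2_odds`.
#' @export
synth_detectability <- function(config, n = 2000L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 2L, {
    nms <- vapply(
      seq_len(n),
      function(i) paste(sample_planted_ninemer(config), collapse = ""),
      character(1)
    )
    pos <- fit_mm1(nms, pseudocount = 1)
    bg <- fit_mm1(
      vapply(seq_len(n), function(i) {
        paste(
          replace(
            sample(NTS, 9L, replace = TRUE, prob = config$bg_probs),
            c(4L, 6L), c("T", "A")
          ),
          collapse = ""
        )
      }, character(1)),
      pseudocount = 1
    )
    lo <- mm1_score(pos, bg, nms)
    tibble::tibble(mean_log2_odds = mean(lo), sd_log2_odds = stats::sd(lo))
  })
}
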