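#' Default polypyrimidine-tract scoring weights
#'
#' Per-nucleotide weights of the linear tract score
#' `score = sum_n w_n * f_n` (f_n = absolute count of nucleotide n in the
#' tract). The published weight values are not legible in the source
#' describing the scheme, so these defaults are a documented stand-in chosen
#' to satisfy its qualitative constraints: T dominates, C counts positively,
#' purine interruptions are penalized. Downstream models retrain around any
#' fixed affine rescaling of the score, so substitute your own weights via
#' the `weights` arguments if you have the reference values.
#'
#' @return Named numeric vector with elements A, C, G, T.
#' @export
ppt_weights <- function() {
  c(A = -2, C = 2, G = -1, T = 3)
}

# Structural PPT rules, applied while scanning:
#   1. both ends pyrimidines;
#   2. internal purine runs of length at most 2;
#   3. a purine run of length L needs >= L pyrimidines on each side and
#      >= 4L in total (flanks truncated at the tract ends);
#   4. T(GT)n stretches are exempt: a lone G flanked by T on both sides
#      passes regardless of rule 3;
#   5. reported tracts must have length >= 9 or at least 5 T's.
# N acts as a hard break.

# All containment-maximal structural tracts of one sequence, as a matrix of
# (start, end) 1-based offsets. Works on run-length-encoded
# pyrimidine/purine/N segments: extending a tract leftwards within a
# pyrimidine run only lengthens the first purine run's upstream flank, so
# every containment-maximal tract starts at the first position of a
# pyrimidine run; the walk from each such start advances segment by segment
# until a rule can no longer be satisfied.
ppt_maximal_tracts <- function(chars, is_pyr) {
  n <- length(chars)
  if (n == 0L) {
    return(cbind(start = integer(), end = integer()))
  }
  cls <- integer(n) # 0 = pyrimidine, 1 = purine, 2 = N
  cls[!is_pyr] <- 1L
  cls[chars == "N"] <- 2L
  r <- rle(cls)
  vals <- r$values
  lens <- r$lengths
  nseg <- length(lens)
  seg_end <- cumsum(lens)
  seg_start <- seg_end - lens + 1L
  pyr_segs <- which(vals == 0L)
  if (length(pyr_segs) == 0L) {
    return(cbind(start = integer(), end = integer()))
  }
  ends <- vapply(pyr_segs, function(i) {
    last_valid <- seg_end[i]
    up <- lens[i]
    j <- i + 1L
    while (j + 1L <= nseg) {
      if (vals[j] != 1L) break # N wall
      run_len <- lens[j]
      if (run_len > 2L || vals[j + 1L] != 0L) break
      exempt <- run_len == 1L && chars[seg_start[j]] == "G" &&
        chars[seg_start[j] - 1L] == "T" && chars[seg_end[j] + 1L] == "T"
      if (!exempt && up < run_len) break
      need <- if (exempt) 0L else max(run_len, 4L * run_len - up)
      dn <- lens[j + 1L]
      if (dn < need) break # down-flank closed short by the next purine
      last_valid <- seg_end[j + 1L]
      up <- dn
      j <- j + 2L
    }
    last_valid
  }, integer(1))
  starts <- seg_start[pyr_segs]
  keep <- ends > c(-1L, cummax(ends)[-length(ends)])
  cbind(start = starts[keep], end = ends[keep])
}

# Greedy longest-first (ties 3'-most) non-overlap selection with re-scan:
# a selected tract acts as a wall, so the remainder decomposes into the
# independent subregions left and right of it.
ppt_select_region <- function(chars, is_pyr, lo, hi) {
  if (hi - lo + 1L < 5L) {
    return(NULL)
  }
  idx <- lo:hi
  tracts <- ppt_maximal_tracts(chars[idx], is_pyr[idx])
  if (nrow(tracts) == 0L) {
    return(NULL)
  }
  tracts <- tracts + (lo - 1L)
  len <- tracts[, 2] - tracts[, 1] + 1L
  n_t <- vapply(
    seq_len(nrow(tracts)),
    function(k) sum(chars[tracts[k, 1]:tracts[k, 2]] == "T"),
    integer(1)
  )
  ok <- len >= 9L | n_t >= 5L
  if (!any(ok)) {
    return(NULL)
  }
  tracts <- tracts[ok, , drop = FALSE]
  len <- len[ok]
  best <- which(len == max(len))
  best <- best[which.max(tracts[best, 1])]
  s <- tracts[best, 1]
  e <- tracts[best, 2]
  rbind(
    ppt_select_region(chars, is_pyr, lo, s - 1L),
    c(s, e),
    ppt_select_region(chars, is_pyr, e + 1L, hi)
  )
}

#' Find polypyrimidine tracts
#'
#' Detects maximal polypyrimidine tracts under five structural rules: both
#' ends pyrimidines; no three contiguous purines; every internal purine run
#' of length L flanked by pyrimidine stretches of length >= L on both sides
#' totalling >= 4L (which keeps the pyrimidine fraction above 2/3 around
#' interruptions); T(GT)n stretches allowed; and a reported tract must be at
#' least 9 nt long or contain at least 5 T's. N breaks tracts.
#'
#' Overlapping maximal tracts are resolved greedily: the longest (ties going
#' to the 3'-most) is kept, its region is masked, and the remaining sequence
#' is re-scanned, so the output is non-overlapping and ordered 5'->3'.
#'
#' @param introns Tibble with `intron_id` and `sequence`, a named character
#'   vector, or a single sequence string.
#' @param weights Scoring weights, see [ppt_weights()].
#' @return A tibble with columns `intron_id`, `start`, `end` (3SS-anchored,
#'   inclusive), `length`, `sequence`, `f_A`, `f_C`, `f_G`, `f_T`, `score`.
#' @examples
#' find_ppts("AAAATTTTCTTTTGAAA")
#' @export
find_ppts <- function(introns, weights = ppt_weights()) {
  introns <- as_intron_tbl(introns)
  rows <- purrr::map2(introns$intron_id, introns$sequence, function(id, seq) {
    L <- nchar(seq)
    chars <- seq_to_chars(seq)
    is_pyr <- chars == "C" | chars == "T"
    sel <- ppt_select_region(chars, is_pyr, 1L, L)
    if (is.null(sel)) {
      return(NULL)
    }
    sel <- sel[order(sel[, 1]), , drop = FALSE]
    dimnames(sel) <- NULL
    counts <- t(vapply(seq_len(nrow(sel)), function(k) {
      tabulate(
        factor(chars[sel[k, 1]:sel[k, 2]], levels = c("A", "C", "G", "T")),
        nbins = 4L
      )
    }, integer(4)))
    tibble::tibble(
      intron_id = id,
      start = sel[, 1] - L - 1L,
      end = sel[, 2] - L - 1L,
      length = sel[, 2] - sel[, 1] + 1L,
      sequence = substring(seq, sel[, 1], sel[, 2]),
      f_A = counts[, 1], f_C = counts[, 2],
      f_G = counts[, 3], f_T = counts[, 4]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      intron_id = character(), start = integer(), end = integer(),
      length = integer(), sequence = character(),
      f_A = integer(), f_C = integer(), f_G = integer(), f_T = integer()
    )
  }
  out$score <- ppt_score(out, weights)
  out
}

#' Score polypyrimidine tracts
#'
#' Linear length-and-composition score `sum_n w_n * f_n` over the absolute
#' nucleotide counts of each tract.
#'
#' @param tracts Tibble with count columns `f_A`, `f_C`, `f_G`, `f_T`
#'   (as produced by [find_ppts()]).
#' @param weights Named weights, see [ppt_weights()].
#' @return Numeric vector of scores, one per tract (0 for an empty tibble).
#' @export
ppt_score <- function(tracts, weights = ppt_weights()) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(weights)))
  if (nrow(tracts) == 0L) {
    return(numeric())
  }
  weights[["A"]] * tracts$f_A + weights[["C"]] * tracts$f_C +
    weights[["G"]] * tracts$f_G + weights[["T"]] * tracts$f_T
}

#' Closest downstream polypyrimidine tract of each BP candidate
#'
#' For each candidate, finds the nearest tract lying downstream of the
#' branch adenosine and reports its distance (`tract start - bp_pos - 1`, so
#' a tract starting right after the adenosine is at distance 0) and score.
#' A tract that overlaps the adenosine itself — the branch A is a purine and
#' can be absorbed into a long tract as an allowed isolated interruption —
#' is trimmed to its part downstream of the adenosine; the trimmed part
#' counts (with its own composition score) provided it still passes all
#' tract rules. When no downstream tract exists the sentinel distance
#' (default 500, the scan-window length) and score 0 are returned.
#'
#' @param candidates Tibble with `intron_id` and `bp_pos`
#'   (from [enumerate_candidates()]).
#' @param tracts Tibble from [find_ppts()] on the same introns.
#' @param sentinel Distance reported when no downstream tract exists.
#' @param weights Scoring weights for trimmed tracts, see [ppt_weights()].
#' @return `candidates` with `ppt_distance` and `ppt_score` columns added.
#' @export
closest_downstream_ppt <- function(candidates, tracts, sentinel = 500L,
                                   weights = ppt_weights()) {
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(
      candidates,
      ppt_distance = integer(), ppt_score = numeric()
    ))
  }
  tr <- split(
    tracts[c("start", "end", "sequence", "score")],
    factor(tracts$intron_id, levels = unique(candidates$intron_id))
  )
  res <- purrr::map2(candidates$intron_id, candidates$bp_pos, function(id, bp) {
    t <- tr[[id]]
    if (is.null(t) || nrow(t) == 0L) {
      return(c(sentinel, 0))
    }
    down <- t$start >= bp + 1L
    best <- if (any(down)) {
      k <- which(down)[which.min(t$start[down])]
      c(t$start[k] - bp - 1L, t$score[k])
    } else {
      c(sentinel, 0)
    }
    ov <- which(t$start <= bp & t$end > bp)
    if (length(ov) == 1L) {
      chars <- seq_to_chars(t$sequence[ov])
      rel <- bp + 1L - t$start[ov] + 1L # tract-local index of bp + 1
      chars <- chars[rel:length(chars)]
      lead <- which(chars %in% c("C", "T"))
      if (length(lead) > 0L) {
        chars <- chars[lead[1]:length(chars)]
        if (ppt_rules_ok(chars)) {
          start <- bp + 1L + (lead[1] - 1L)
          counts <- tabulate(
            factor(chars, levels = c("A", "C", "G", "T")),
            nbins = 4L
          )
          score <- sum(weights[c("A", "C", "G", "T")] * counts)
          if (start - bp - 1L < best[1]) best <- c(start - bp - 1L, score)
        }
      }
    }
    best
  })
  res <- do.call(rbind, res)
  candidates$ppt_distance <- as.integer(res[, 1])
  candidates$ppt_score <- res[, 2]
  candidates
}

# full rule check (structure + size) of a putative tract, used when trimming
# tracts at a branch adenosine
ppt_rules_ok <- function(chars) {
  n <- length(chars)
  if (n == 0L || any(chars == "N")) {
    return(FALSE)
  }
  pyr <- chars == "C" | chars == "T"
  if (!pyr[1] || !pyr[n]) {
    return(FALSE)
  }
  if (n < 9L && sum(chars == "T") < 5L) {
    return(FALSE)
  }
  r <- rle(pyr)
  if (length(r$lengths) == 1L) {
    return(TRUE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(!r$values)) {
    run_len <- r$lengths[j]
    exempt <- run_len == 1L && chars[starts[j]] == "G" &&
      chars[starts[j] - 1L] == "T" && chars[ends[j] + 1L] == "T"
    if (exempt) next
    if (run_len > 2L) {
      return(FALSE)
    }
    up <- r$lengths[j - 1L]
    dn <- r$lengths[j + 1L]
    if (up < run_len || dn < run_len || up + dn < 4L * run_len) {
      return(FALSE)
    }
  }
  TRUE
}
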