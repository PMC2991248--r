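#' Conserved k-mer instances in multi-species alignment blocks
#'
#' An alignment block covers the 3'-terminal region (typically the last 300
#' nt) of one intron, one gapped row per species, all rows of equal gapped
#' length; the first row per intron is the reference (human) row. A k-mer
#' instance of the reference is *conserved* when its k reference bases sit in
#' k consecutive alignment columns that are gap-free and identical in every
#' species. Positions are reported for the reference sequence, 3SS-anchored
#' (last reference base = -1).
#'
#' @param blocks Tibble with columns `intron_id`, `species`, `alignment`
#'   (gapped sequence; `-` for gaps), reference row first within each intron.
#' @param k K-mer size (default 5).
#' @return Tibble `intron_id`, `kmer`, `pos` (3SS-anchored start of the
#'   instance in the reference sequence), ordered 5'->3' within intron.
#' @export
conserved_kmer_instances <- function(blocks, k = 5L) {
  k <- as.integer(k)
  stopifnot(all(c("intron_id", "species", "alignment") %in% names(blocks)))
  by_intron <- split(blocks, factor(blocks$intron_id, unique(blocks$intron_id)))
  rows <- purrr::map(by_intron, function(b) {
    aln <- vapply(b$alignment, toupper, character(1), USE.NAMES = FALSE)
    if (length(unique(nchar(aln))) != 1L) {
      stop("block '", b$intron_id[1], "': rows have unequal gapped lengths")
    }
    mat <- matrix(
      unlist(strsplit(aln, "", fixed = TRUE)),
      nrow = length(aln), byrow = TRUE
    )
    ref <- mat[1, ]
    ref_cols <- which(ref != "-")
    n <- length(ref_cols)
    if (n < k) {
      return(NULL)
    }
    col_ok <- colSums(
      mat == matrix(ref, nrow(mat), ncol(mat), byrow = TRUE)
    ) == nrow(mat) & ref != "-" & ref != "N"
    ok_run <- c(0L, cumsum(col_ok))
    starts <- seq_len(n - k + 1L)
    first_col <- ref_cols[starts]
    last_col <- ref_cols[starts + k - 1L]
    consecutive <- (last_col - first_col) == (k - 1L)
    all_ok <- (ok_run[last_col + 1L] - ok_run[first_col]) == k
    keep <- consecutive & all_ok
    if (!any(keep)) {
      return(NULL)
    }
    ref_seq <- paste(ref[ref_cols], collapse = "")
    tibble::tibble(
      intron_id = b$intron_id[1],
      kmer = substring(ref_seq, starts[keep], starts[keep] + k - 1L),
      pos = starts[keep] - 1L - n
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      intron_id = character(), kmer = character(), pos = integer()
    )
  }
  out
}

#' Positional profiles of the TNA-containing pentamers
#'
#' For each of the 184 TNA-containing pentamers (see
#' [tna_pentamer_patterns()]), collects the start positions of all instances
#' in the reference rows and of the conserved instances across species.
#'
#' @param blocks Alignment-block tibble (see [conserved_kmer_instances()]).
#' @return Tibble with one row per pentamer: `pentamer`, `n_all`,
#'   `n_conserved`, and list-columns `positions_all`, `positions_conserved`
#'   (3SS-anchored start positions).
#' @export
pentamer_profiles <- function(blocks) {
  pents <- tna_pentamer_patterns()
  cons <- conserved_kmer_instances(blocks, k = 5L)
  refs <- dplyr::slice_head(
    dplyr::group_by(blocks, .data$intron_id),
    n = 1L
  )
  refs <- dplyr::ungroup(refs)
  ref_seqs <- gsub("-", "", toupper(refs$alignment), fixed = TRUE)
  all_inst <- purrr::map_dfr(ref_seqs, function(s) {
    n <- nchar(s)
    if (n < 5L) {
      return(NULL)
    }
    starts <- seq_len(n - 4L)
    tibble::tibble(kmer = substring(s, starts, starts + 4L), pos = starts - 1L - n)
  })
  tibble::tibble(
    pentamer = pents,
    positions_all = purrr::map(
      pents, function(p) all_inst$pos[all_inst$kmer == p]
    ),
    positions_conserved = purrr::map(
      pents, function(p) cons$pos[cons$kmer == p]
    )
  ) |>
    dplyr::mutate(
      n_all = lengths(.data$positions_all),
      n_conserved = lengths(.data$positions_conserved)
    )
}

#' Classify pentamers by the positional bias of their conserved instances
#'
#' Three tests on the conserved-instance start positions of each pentamer:
#' (1) non-uniformity over the scanned region (Kolmogorov-Smirnov against a
#' uniform distribution), (2) enrichment inside the BP window (one-sided
#' binomial test with expected proportion = window width / scan width), and
#' (3) the smoothed distribution peak falling inside the window. Pentamers
#' failing test 1 or 2 get label `"none"`; those passing both are `"bp"` when
#' the peak lies inside the window and `"ppt"` otherwise (in practice
#' pyrimidine-rich pentamers peaking between the window and the 3SS).
#'
#' The peak is the mode of a 5-nt-binned histogram after a centered 3-bin
#' moving average, ties resolved towards the 3SS.
#'
#' @param profiles Tibble from [pentamer_profiles()] (needs `pentamer` and
#'   `positions_conserved`).
#' @param alpha Significance level for both tests (default 0.001).
#' @param window BP window, default `c(-55, -15)`.
#' @param scan Scanned region, default `c(-300, -1)`.
#' @return `profiles` with columns `ks_p`, `enrich_p`, `peak`, `label` added.
#' @export
classify_pentamers <- function(profiles, alpha = 0.001,
                               window = c(-55L, -15L), scan = c(-300L, -1L)) {
  stats_tbl <- purrr::map_dfr(profiles$positions_conserved, function(pos) {
    if (length(pos) < 1L) {
      return(tibble::tibble(
        ks_p = NA_real_, enrich_p = NA_real_, peak = NA_real_, label = "none"
      ))
    }
    ks_p <- suppressWarnings(
      stats::ks.test(pos, "punif", scan[1], scan[2])$p.value
    )
    p0 <- (window[2] - window[1] + 1) / (scan[2] - scan[1] + 1)
    x <- sum(pos >= window[1] & pos <= window[2])
    enrich_p <- stats::binom.test(
      x, length(pos),
      p = p0, alternative = "greater"
    )$p.value
    peak <- histogram_peak(pos, scan)
    label <- if (is.na(ks_p) || ks_p >= alpha || enrich_p >= alpha) {
      "none"
    } else if (peak >= window[1] && peak <= window[2]) {
      "bp"
    } else {
      "ppt"
    }
    tibble::tibble(ks_p = ks_p, enrich_p = enrich_p, peak = peak, label = label)
  })
  dplyr::bind_cols(profiles, stats_tbl)
}

# mode of a 5-nt-binned histogram after a centered 3-bin moving average;
# ties go to the 3'-most bin; returns the bin center
histogram_peak <- function(pos, scan = c(-300L, -1L), binwidth = 5L) {
  breaks <- seq(scan[1] - 0.5, scan[2] + binwidth, by = binwidth)
  counts <- tabulate(
    findInterval(pos, breaks, rightmost.closed = TRUE),
    nbins = length(breaks) - 1L
  )
  n <- length(counts)
  smooth <- (c(0, counts[-n]) + counts + c(counts[-1], 0)) /
    c(2, rep(3, n - 2L), 2)
  best <- max(which(smooth == max(smooth)))
  breaks[best] + binwidth / 2
}

#' Build the set of unique conserved TNA instances (consTNA)
#'
#' Selects introns whose reference region contains exactly one conserved TNA
#' trinucleotide instance (T, any base, then the branch A) and whose
#' adenosine lies inside the BP window, and collects the reference 9-mer
#' with the TNA in its central positions (4-6).
#'
#' @param blocks Alignment-block tibble.
#' @param window BP window for the adenosine, default `c(-55, -15)`.
#' @return Tibble `intron_id`, `bp_pos` (adenosine position), `ninemer` —
#'   exactly one row per qualifying intron.
#' @export
build_cons_tna <- function(blocks, window = c(-55L, -15L)) {
  tri <- conserved_kmer_instances(blocks, k = 3L)
  tri <- tri[grepl("^T.A$", tri$kmer), ]
  unique_introns <- dplyr::filter(
    dplyr::add_count(tri, .data$intron_id), n == 1L
  )
  unique_introns$bp_pos <- unique_introns$pos + 2L
  unique_introns <- dplyr::filter(
    unique_introns,
    .data$bp_pos >= window[1] & .data$bp_pos <= window[2]
  )
  if (nrow(unique_introns) == 0L) {
    return(tibble::tibble(
      intron_id = character(), bp_pos = integer(), ninemer = character()
    ))
  }
  refs <- dplyr::slice_head(dplyr::group_by(blocks, .data$intron_id), n = 1L)
  refs <- dplyr::ungroup(refs)
  ref_seq <- gsub("-", "", toupper(refs$alignment), fixed = TRUE)
  names(ref_seq) <- refs$intron_id
  seqs <- ref_seq[unique_introns$intron_id]
  n <- nchar(seqs)
  start1 <- unique_introns$bp_pos - 5L + n + 1L # 1-based start of the 9-mer
  ok <- start1 >= 1L & start1 + 8L <= n
  out <- tibble::tibble(
    intron_id = unique_introns$intron_id[ok],
    bp_pos = unique_introns$bp_pos[ok],
    ninemer = unname(substring(seqs[ok], start1[ok], start1[ok] + 8L))
  )
  dplyr::arrange(out, .data$intron_id)
}

#' Filter consTNA by BP-associated pentamer support in every species
#'
#' Keeps a consTNA instance only if, in every species' ungapped sequence,
#' at least one BP-associated pentamer occurrence overlaps the conserved TNA
#' instance. Overlap means sharing at least one position with the TNA
#' trinucleotide (`overlap = "tna"`, default) or with the whole 9-mer
#' (`overlap = "ninemer"`).
#'
#' @param cons_tna Tibble from [build_cons_tna()].
#' @param bp_pentamers Character vector of BP-associated pentamers (e.g.
#'   pentamers labeled `"bp"` by [classify_pentamers()]).
#' @param blocks The alignment-block tibble the set was built from.
#' @param overlap Overlap rule, `"tna"` or `"ninemer"`.
#' @return The subset of `cons_tna` rows passing the filter.
#' @export
filter_bp5 <- function(cons_tna, bp_pentamers, blocks,
                       overlap = c("tna", "ninemer")) {
  overlap <- match.arg(overlap)
  if (length(bp_pentamers) == 0L) stop("bp_pentamers must be nonempty")
  if (nrow(cons_tna) == 0L) {
    return(cons_tna)
  }
  by_intron <- split(blocks, factor(blocks$intron_id, unique(blocks$intron_id)))
  keep <- purrr::map2_lgl(
    cons_tna$intron_id, cons_tna$bp_pos,
    function(id, bp) {
      b <- by_intron[[id]]
      aln <- toupper(b$alignment)
      mat <- matrix(
        unlist(strsplit(aln, "", fixed = TRUE)),
        nrow = length(aln), byrow = TRUE
      )
      ref_cols <- which(mat[1, ] != "-")
      n_ref <- length(ref_cols)
      # alignment columns of the conserved TNA (reference positions
      # bp-2 .. bp) and, for the "ninemer" rule, of the whole 9-mer
      span_ref <- if (overlap == "tna") (bp - 2L):bp else (bp - 5L):(bp + 3L)
      span_idx <- span_ref + n_ref + 1L # 1-based ungapped reference offsets
      span_idx <- span_idx[span_idx >= 1L & span_idx <= n_ref]
      span_cols <- ref_cols[span_idx]
      all(vapply(seq_len(nrow(mat)), function(r) {
        row <- mat[r, ]
        nongap <- row != "-"
        seq_r <- paste(row[nongap], collapse = "")
        # ungapped species coordinates of the TNA columns
        cum <- cumsum(nongap)
        span_sp <- cum[span_cols][nongap[span_cols]]
        if (length(span_sp) == 0L) {
          return(FALSE)
        }
        # a pentamer overlapping the span must start within 4 nt of it
        lo <- max(1L, min(span_sp) - 4L)
        hi <- min(nchar(seq_r) - 4L, max(span_sp))
        if (hi < lo) {
          return(FALSE)
        }
        windows <- substring(seq_r, lo:hi, lo:hi + 4L)
        any(windows %in% bp_pentamers)
      }, logical(1)))
    }
  )
  cons_tna[keep, ]
}
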