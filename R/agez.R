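#' Delimit the AG exclusion zone (AGEZ) of each intron
#'
#' The AGEZ is the 3'-terminal intron region devoid of competing AG
#' dinucleotides, within which the branch point is normally located. Scanning
#' 5'-ward from the 3' splice site, AG dinucleotides whose A lies within the
#' last `grace` nucleotides are ignored (they compete with the acceptor itself
#' rather than delimiting the zone); the first AG beyond the grace region is
#' the AGEZ-defining AG, and the zone spans from that AG (the A excluded) to
#' position -3, i.e. up to but excluding the acceptor AG.
#'
#' With `rank = k > 0` the same rule is applied iteratively to return the
#' k-th AGEZ upstream: the previous defining AG's A becomes the anchor, AGs
#' with A within `grace` of the anchor are ignored, and the zone ends at
#' anchor - 1.
#'
#' If no defining AG occurs within `max_extent` nucleotides of the anchor (or
#' before the intron start), the zone is truncated there and `defining_ag` is
#' `NA`.
#'
#' @param introns Tibble from [read_intron_fasta()] (columns `intron_id`,
#'   `sequence`), or a character vector of sequences.
#' @param grace AGs whose A lies within this many nucleotides of the anchor do
#'   not terminate the zone (default 12 nt).
#' @param rank Which AGEZ to return: 0 = the 3'-most (default), 1 = the next
#'   one upstream, and so on.
#' @param max_extent Maximum zone extent scanned upstream of the anchor
#'   (default 500 nt).
#' @return A tibble with one row per intron: `intron_id`, `rank`,
#'   `agez_start` and `agez_end` (3SS-anchored, inclusive; the first and last
#'   nucleotide inside the zone), `agez_length`, `defining_ag` (position of
#'   the A of the defining AG, `NA` when truncated), and `truncated`.
#' @examples
#' introns <- tibble::tibble(
#'   intron_id = "i1",
#'   sequence = paste0("GTAAG", strrep("C", 20), "AG", strrep("T", 25), "CAG")
#' )
#' find_agez(introns)
#' @export
find_agez <- function(introns, grace = 12L, rank = 0L, max_extent = 500L) {
  introns <- as_intron_tbl(introns)
  grace <- as.integer(grace)
  rank <- as.integer(rank)
  max_extent <- as.integer(max_extent)
  stopifnot(grace >= 0L, rank >= 0L, max_extent > grace)
  rows <- purrr::map2(introns$intron_id, introns$sequence, function(id, seq) {
    L <- nchar(seq)
    if (L < grace + 2L) {
      stop("intron '", id, "' is shorter than grace + 2 (", grace + 2L, " nt)")
    }
    chars <- seq_to_chars(seq)
    # 3SS-anchored positions of the A of every internal AG (excluding the 3SS
    # AG itself at -2).
    ag_a <- which(chars[-L] == "A" & chars[-1] == "G") - 1L - L
    ag_a <- ag_a[ag_a <= -3L]
    anchor <- -2L # rank 0: the acceptor's own A
    defining <- NA_integer_
    for (k in seq_len(rank + 1L)) {
      lo_scan <- max(anchor - max_extent, -L)
      eligible <- ag_a[ag_a < anchor - grace + 2L & ag_a >= lo_scan]
      if (length(eligible) == 0L) {
        defining <- NA_integer_
        start <- lo_scan
      } else {
        defining <- max(eligible)
        start <- defining + 1L
      }
      end <- anchor - 1L
      if (k <= rank) {
        if (is.na(defining)) {
          stop(
            "intron '", id, "' has no rank-", k, " defining AG; ",
            "AGEZ of rank ", rank, " does not exist"
          )
        }
        anchor <- defining
      }
    }
    tibble::tibble(
      intron_id = id,
      rank = rank,
      agez_start = start,
      agez_end = end,
      agez_length = end - start + 1L,
      defining_ag = defining,
      truncated = is.na(defining)
    )
  })
  dplyr::bind_rows(rows)
}

#' Enumerate canonical branch-point candidate 9-mers
#'
#' A canonical candidate is a 9-nucleotide window with T at position 4 and A
#' at position 6 (1-based); the position-6 adenosine is the putative branch
#' point. Candidates are reported when the adenosine lies inside the search
#' region, at least `min_dist` nucleotides from the intron end, and the 9-mer
#' fits fully inside the intron. Windows containing N are skipped.
#'
#' @param introns Tibble with `intron_id` and `sequence`, or character vector.
#' @param region Either the AGEZ tibble from [find_agez()] (joined by
#'   `intron_id`) or an integer vector `c(from, to)` of 3SS-anchored bounds
#'   applied to every intron. `NULL` (default) computes the rank-0 AGEZ with
#'   default parameters.
#' @param min_dist Minimum distance of the branch adenosine from the intron
#'   end (default 15 nt, i.e. `bp_pos <= -15`).
#' @return A tibble ordered 5'->3' within each intron: `intron_id`, `bp_pos`
#'   (position of the adenosine), `ninemer`.
#' @examples
#' introns <- tibble::tibble(
#'   intron_id = "i1",
#'   sequence = paste0(strrep("C", 10), "TGGTAACAA", strrep("T", 18), "CAG")
#' )
#' enumerate_candidates(introns, region = c(-40, -3))
#' @export
enumerate_candidates <- function(introns, region = NULL, min_dist = 15L) {
  introns <- as_intron_tbl(introns)
  min_dist <- as.integer(min_dist)
  stopifnot(min_dist >= 3L)
  if (is.null(region)) region <- find_agez(introns)
  if (is.numeric(region)) {
    stopifnot(length(region) == 2L)
    bounds <- tibble::tibble(
      intron_id = introns$intron_id,
      agez_start = as.integer(min(region)),
      agez_end = as.integer(max(region))
    )
  } else {
    bounds <- dplyr::select(
      region, "intron_id", "agez_start", "agez_end"
    )
  }
  joined <- dplyr::inner_join(introns, bounds, by = "intron_id")
  rows <- purrr::pmap(
    list(joined$intron_id, joined$sequence, joined$agez_start, joined$agez_end),
    function(id, seq, from, to) {
      cands <- candidate_positions(seq, from, to, min_dist)
      if (length(cands) == 0L) {
        return(NULL)
      }
      L <- nchar(seq)
      o <- cands + L # 0-based offset of the adenosine
      tibble::tibble(
        intron_id = id,
        bp_pos = cands,
        ninemer = substring(seq, o - 4L, o + 4L)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      intron_id = character(), bp_pos = integer(), ninemer = character()
    )
  }
  out
}

# 3SS-anchored adenosine positions of canonical TNA 9-mers in one sequence,
# restricted to [from, to] and <= -min_dist; N-containing windows skipped.
candidate_positions <- function(seq, from, to, min_dist) {
  L <- nchar(seq)
  chars <- seq_to_chars(seq)
  # adenosine 0-based offset o needs o-5 >= 0 and o+3 <= L-1
  o <- which(chars == "A") - 1L
  o <- o[o >= 5L & o <= L - 4L]
  o <- o[chars[o - 2L + 1L] == "T"]
  if (length(o) == 0L) {
    return(integer())
  }
  pos <- o - L
  keep <- pos >= from & pos <= to & pos <= -min_dist
  o <- o[keep]
  pos <- pos[keep]
  if (length(o) == 0L) {
    return(integer())
  }
  has_n <- vapply(
    o,
    function(oo) any(chars[(oo - 5L + 1L):(oo + 3L + 1L)] == "N"),
    logical(1)
  )
  sort(pos[!has_n])
}

#' All TNA-containing pentamers
#'
#' The 5-mers matching at least one of the patterns TNANN, NTNAN, NNTNA
#' (N = any nucleotide): a T followed two bases later by an A, anywhere in
#' the pentamer. There are exactly 184 of them.
#'
#' @return A character vector of 184 pentamers in lexicographic order.
#' @examples
#' length(tna_pentamer_patterns())
#' @export
tna_pentamer_patterns <- function() {
  nts <- c("A", "C", "G", "T")
  all5 <- do.call(
    paste0,
    expand.grid(nts, nts, nts, nts, nts, stringsAsFactors = FALSE)[5:1]
  )
  hit <- grepl("^T.A", all5) | grepl("^.T.A", all5) | grepl("T.A$", all5)
  sort(all5[hit])
}

# Coerce a character vector (or tibble) to the intron tibble shape.
as_intron_tbl <- function(introns) {
  if (is.character(introns)) {
    ids <- names(introns)
    if (is.null(ids)) ids <- paste0("intron_", seq_along(introns))
    introns <- tibble::tibble(intron_id = ids, sequence = unname(introns))
  }
  stopifnot(all(c("intron_id", "sequence") %in% names(introns)))
  introns
}
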