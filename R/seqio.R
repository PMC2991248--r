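#' Read introns from a FASTA file
#'
#' Reads a multi-record FASTA file of intron sequences. Each sequence must be
#' given 5'->3' on the transcribed strand and is expected to end at the 3'
#' splice site, i.e. its last two nucleotides should be the acceptor "AG".
#' Records that do not end in AG are kept but flagged non-canonical, so that
#' default pipelines can exclude them.
#'
#' Sequences are uppercased and U is mapped to T. Header lines are split at the
#' first whitespace to obtain the intron id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per intron: `intron_id`, `sequence`, `length`,
#'   `canonical_acceptor` (logical; `TRUE` when the sequence ends in "AG") and
#'   `source` (the file path).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">i1 some description", "acgttgcaucctttcctttacagCAG"), fa)
#' read_intron_fasta(fa)
#' @export
read_intron_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- unname(toupper(as.character(set)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(
      "non-IUPAC characters (outside A/C/G/T/N/U) in record(s): ",
      paste(ids[bad], collapse = ", ")
    )
  }
  tibble::tibble(
    intron_id = ids,
    sequence = unname(seqs),
    length = nchar(seqs),
    canonical_acceptor = endsWith(seqs, "AG"),
    source = path
  )
}

#' Write introns to a FASTA file
#'
#' Inverse of [read_intron_fasta()]: a file written here and read back yields
#' byte-identical sequences.
#'
#' @param introns Tibble with columns `intron_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_fasta <- function(introns, path) {
  stopifnot(all(c("intron_id", "sequence") %in% names(introns)))
  set <- Biostrings::BStringSet(introns$sequence)
  names(set) <- introns$intron_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read introns from a BED-like coordinate table plus a genome FASTA
#'
#' The table must have columns `chrom`, `start` (0-based), `end` (half-open),
#' `name`, and `strand` ("+"/"-"); a 6th BED `score` column, if present, is
#' ignored. Minus-strand introns are reverse-complemented so the returned
#' sequence reads 5'->3' on the transcript, ending at the acceptor AG.
#'
#' @param path Path to a tab-separated BED-like file without header.
#' @param genome Path to a genome FASTA, or a named `DNAStringSet`.
#' @return A tibble in the shape of [read_intron_fasta()], plus genomic
#'   coordinate columns `chrom`, `start`, `end`, `strand`.
#' @export
read_intron_table <- function(path, genome) {
  tab <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand")[
      seq_len(max(utils::count.fields(path, sep = "\t")))
    ],
    fill = TRUE
  )
  required <- c("chrom", "start", "end", "name", "strand")
  if (!all(required %in% names(tab))) {
    stop("intron table needs columns chrom, start, end, name, strand")
  }
  if (any(is.na(tab$strand)) || !all(tab$strand %in% c("+", "-"))) {
    stop("every row must carry a '+' or '-' strand")
  }
  if (any(tab$start >= tab$end)) {
    stop("degenerate interval: start must be < end (0-based half-open)")
  }
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- vapply(
      strsplit(names(genome), "\\s+"), `[`, character(1), 1L
    )
  }
  missing_chrom <- setdiff(unique(tab$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    stop("contig(s) absent from genome: ", paste(missing_chrom, collapse = ", "))
  }
  widths <- Biostrings::width(genome)[match(tab$chrom, names(genome))]
  if (any(tab$end > widths) || any(tab$start < 0L)) {
    stop("coordinates outside contig bounds")
  }
  seqs <- vapply(seq_len(nrow(tab)), function(i) {
    s <- Biostrings::subseq(
      genome[[tab$chrom[i]]],
      start = tab$start[i] + 1L, end = tab$end[i]
    )
    if (tab$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  seqs <- toupper(seqs)
  tibble::tibble(
    intron_id = tab$name,
    sequence = seqs,
    length = nchar(seqs),
    canonical_acceptor = endsWith(seqs, "AG"),
    source = path,
    chrom = tab$chrom,
    start = tab$start,
    end = tab$end,
    strand = tab$strand
  )
}

#' Convert between 0-based offsets and 3SS-anchored positions
#'
#' All positions in this package are anchored at the 3' splice site: the last
#' intron nucleotide is position -1, so the acceptor AG occupies -2,-1 and a
#' branch point "at -23" has its adenosine 23 nt from the intron end. For an
#' intron of length L, a 0-based offset `o` maps to `o - L`.
#'
#' @param offset0 Integer vector of 0-based offsets into the intron.
#' @param length Intron length L (scalar or vector recycled against `offset0`).
#' @return Integer vector of negative 3SS-anchored positions.
#' @examples
#' to_3ss(99, 100) # last nucleotide -> -1
#' from_3ss(to_3ss(0:99, 100), 100) # round-trips
#' @export
to_3ss <- function(offset0, length) {
  offset0 <- as.integer(offset0)
  length <- as.integer(length)
  if (any(offset0 < 0L | offset0 >= length)) {
    stop("offset out of range [0, L)")
  }
  offset0 - length
}

#' @rdname to_3ss
#' @param pos Integer vector of 3SS-anchored positions (<= -1).
#' @export
from_3ss <- function(pos, length) {
  pos <- as.integer(pos)
  length <- as.integer(length)
  if (any(pos > -1L | pos < -length)) {
    stop("position out of range [-L, -1]")
  }
  pos + length
}

#' Read a truth table of mapped branch-point positions
#'
#' @param path Tab-separated file with columns `intron_id` and `bp_pos`
#'   (3SS-anchored position of the branch adenosine, negative). A header line
#'   is auto-detected.
#' @return A tibble with columns `intron_id` (character) and `bp_pos`
#'   (integer); an intron with several mapped BPs occupies several rows.
#' @export
read_truth_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("intron_id", first, fixed = TRUE)
  tab <- utils::read.table(
    path,
    sep = "\t", header = has_header, stringsAsFactors = FALSE
  )
  if (!has_header) names(tab)[1:2] <- c("intron_id", "bp_pos")
  tibble::tibble(
    intron_id = as.character(tab$intron_id),
    bp_pos = as.integer(tab$bp_pos)
  )
}

# Split sequences into one character matrix row per sequence (equal lengths).
seq_to_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}
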