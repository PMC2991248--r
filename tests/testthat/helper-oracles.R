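# Independent brute-force oracles used by the fuzz tests. These deliberately
# re-derive each definition in the most literal way possible (position-by-
# position checks, exhaustive substring enumeration) and share no code with
# the package internals.

random_seq <- function(n, probs = c(0.27, 0.22, 0.22, 0.29)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
    collapse = ""
  )
}

# --- AGEZ oracle: list every AG, apply the grace rule literally -------------
oracle_agez <- function(seq, grace = 12, max_extent = 500) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  ag_a <- integer()
  for (i in seq_len(L - 1)) {
    if (chars[i] == "A" && chars[i + 1] == "G") ag_a <- c(ag_a, i - 1L - L)
  }
  ag_a <- ag_a[ag_a <= -3] # internal AGs only
  eligible <- ag_a[ag_a < -grace & ag_a >= max(-max_extent, -L)]
  if (length(eligible) == 0) {
    list(defining = NA_integer_, start = as.integer(max(-max_extent, -L)), end = -3L)
  } else {
    d <- as.integer(max(eligible))
    list(defining = d, start = d + 1L, end = -3L)
  }
}

# --- candidate oracle: check every window explicitly ------------------------
oracle_candidates <- function(seq, from, to, min_dist = 15) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- integer()
  for (a in seq_len(L)) { # 1-based index of a putative branch A
    pos <- a - 1L - L
    if (pos < from || pos > to || pos > -min_dist) next
    s <- a - 5
    e <- a + 3
    if (s < 1 || e > L) next
    w <- chars[s:e]
    if (w[4] == "T" && w[6] == "A" && !any(w == "N")) out <- c(out, pos)
  }
  out
}

# --- PPT rule checker over an explicit substring ----------------------------
oracle_ppt_valid <- function(chars) {
  n <- length(chars)
  pyr <- chars %in% c("C", "T")
  if (any(chars == "N")) {
    return(FALSE)
  }
  if (!pyr[1] || !pyr[n]) {
    return(FALSE)
  }
  i <- 1
  while (i <= n) {
    if (!pyr[i]) {
      j <- i
      while (j < n && !pyr[j + 1]) j <- j + 1
      run_len <- j - i + 1
      exempt <- run_len == 1 && chars[i] == "G" &&
        i > 1 && chars[i - 1] == "T" && j < n && chars[j + 1] == "T"
      if (!exempt) {
        if (run_len > 2) {
          return(FALSE)
        }
        up <- 0
        k <- i - 1
        while (k >= 1 && pyr[k]) {
          up <- up + 1
          k <- k - 1
        }
        dn <- 0
        k <- j + 1
        while (k <= n && pyr[k]) {
          dn <- dn + 1
          k <- k + 1
        }
        if (up < run_len || dn < run_len || up + dn < 4 * run_len) {
          return(FALSE)
        }
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  n >= 9 || sum(chars == "T") >= 5
}

# all valid tracts by exhaustive substring enumeration, as a (start, end)
# matrix; maximal = not contained in another valid tract
oracle_ppt_maximal <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  valid <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (oracle_ppt_valid(chars[s:e])) valid[[length(valid) + 1]] <- c(s, e)
    }
  }
  if (length(valid) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  v <- do.call(rbind, valid)
  keep <- vapply(seq_len(nrow(v)), function(i) {
    !any(v[, 1] <= v[i, 1] & v[, 2] >= v[i, 2] &
      (v[, 1] != v[i, 1] | v[, 2] != v[i, 2]))
  }, logical(1))
  v[keep, , drop = FALSE]
}

# greedy longest-first / 3'-most selection with masking, on oracle tracts
oracle_ppt_selected <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sel <- matrix(integer(), ncol = 2)
  repeat {
    v <- oracle_ppt_maximal(paste(chars, collapse = ""))
    if (nrow(v) == 0) break
    len <- v[, 2] - v[, 1] + 1
    best <- which(len == max(len))
    best <- best[which.max(v[best, 1])]
    sel <- rbind(sel, v[best, ])
    chars[v[best, 1]:v[best, 2]] <- "N"
  }
  sel[order(sel[, 1]), , drop = FALSE]
}

# --- conserved k-mer oracle: column-by-column check -------------------------
oracle_conserved <- function(rows, k) {
  # rows: character vector of gapped sequences, reference first
  mat <- do.call(rbind, strsplit(rows, ""))
  ref_cols <- which(mat[1, ] != "-")
  n <- length(ref_cols)
  out <- list()
  for (i in seq_len(max(0, n - k + 1))) {
    cols <- ref_cols[i:(i + k - 1)]
    if (cols[k] - cols[1] != k - 1) next
    ok <- TRUE
    for (cc in cols) {
      col <- mat[, cc]
      if (any(col == "-") || any(col == "N") || length(unique(col)) != 1) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      out[[length(out) + 1]] <- list(
        kmer = paste(mat[1, cols], collapse = ""),
        pos = i - 1L - n
      )
    }
  }
  out
}

# --- Hamming oracle ---------------------------------------------------------
oracle_hamming <- function(seq, consensus, window, max_dist) {
  chars <- strsplit(seq, "")[[1]]
  cons <- strsplit(consensus, "")[[1]]
  L <- length(chars)
  out <- NULL
  for (a in seq_len(L)) {
    pos <- a - 1L - L
    if (pos < -window || pos > -4) next
    s <- a - 5
    e <- a + 3
    if (s < 1 || e > L) next
    w <- chars[s:e]
    if (any(w == "N")) next
    d <- sum(w != cons)
    if (d <= max_dist) out <- rbind(out, c(pos, d))
  }
  out
}

# small synthetic intron tibble helper
toy_introns <- function(seqs) {
  tibble::tibble(
    intron_id = paste0("t", seq_along(seqs)),
    sequence = seqs
  )
}
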