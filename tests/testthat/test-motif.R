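rand_canonical <- function(n) {
  vapply(seq_len(n), function(i) {
    x <- sample(c("A", "C", "G", "T"), 9, replace = TRUE)
    x[4] <- "T"
    x[6] <- "A"
    paste(x, collapse = "")
  }, character(1))
}

test_that("frequency model probabilities follow the pseudocount formula", {
  m <- fit_frequency_model(c("AAATAAAAA", "AAATAAAAA"), pseudocount = 1)
  expect_equal(unname(m$probs[1, ]), c(3, 1, 1, 1) / 6)
  expect_equal(unname(m$counts[1, "A"]), 2)
  expect_equal(rowSums(m$probs), rep(1, 9), ignore_attr = TRUE)
  # counts equal an independent tally
  set.seed(21)
  seqs <- rand_canonical(40)
  m2 <- fit_frequency_model(seqs)
  tally <- matrix(0L, 9, 4, dimnames = list(1:9, c("A", "C", "G", "T")))
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    for (i in 1:9) tally[i, ch[i]] <- tally[i, ch[i]] + 1L
  }
  expect_equal(unname(m2$counts), unname(tally))
  expect_error(fit_frequency_model(character()), "empty")
  expect_error(fit_frequency_model("ACGT"), "9-mers")
})

test_that("information content spans 0 bits (uniform) to 2 bits (invariant)", {
  uniform <- fit_frequency_model(
    c("AAAAAAAAA", "CCCTCACCC", "GGGTGAGGG", "TTTTTATTT"),
    pseudocount = 0
  )
  ic <- information_content(uniform)
  expect_equal(ic$per_position[1], 0)
  single <- fit_frequency_model("ACGTGACGT", pseudocount = 0)
  ic2 <- information_content(single)
  expect_equal(ic2$per_position, rep(2, 9))
  expect_equal(ic2$total, 18)
  # always within [0, 2] per position
  set.seed(31)
  ic3 <- information_content(fit_frequency_model(rand_canonical(30)))
  expect_true(all(ic3$per_position >= 0 & ic3$per_position <= 2))
})

test_that("mutual information is symmetric, blank at fixed positions, and
           matches closed forms", {
  # two perfectly coupled columns, each 50% A / 50% C -> exactly 1 bit
  seqs <- c(rep("AAATAAAAA", 5), rep("CCCTCACCC", 5))
  mi <- mutual_information(seqs)
  expect_equal(mi[1, 2], 1)
  expect_true(all(is.na(mi[4, ])) && all(is.na(mi[, 6])))
  expect_equal(mi, t(mi))
  # independent shuffled columns -> MI near 0
  set.seed(41)
  cols <- replicate(9, sample(c("A", "C", "G", "T"), 400, replace = TRUE))
  cols[, 4] <- "T"
  cols[, 6] <- "A"
  mi2 <- mutual_information(apply(cols, 1, paste, collapse = ""))
  expect_lt(max(mi2[upper.tri(mi2)], na.rm = TRUE), 0.05)
})

test_that("MM1 probabilities are properly normalized and match bigram tallies", {
  set.seed(51)
  seqs <- rand_canonical(60)
  m <- fit_mm1(seqs)
  expect_equal(sum(unname(m$initial)), 1)
  for (tr in m$transitions) expect_equal(rowSums(tr), rep(1, 4),
    ignore_attr = TRUE
  )
  # total probability over the whole canonical 9-mer space is 1
  total <- sum(2^lariatr:::mm1_log2prob(m, all_canonical_ninemers()))
  expect_equal(total, 1, tolerance = 1e-6)
  # conditionals match a brute-force bigram tally along the chain 1-2-3-5-7-8-9
  chain <- c(1, 2, 3, 5, 7, 8, 9)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (s in seq_len(6)) {
    from <- mat[, chain[s]]
    to <- mat[, chain[s + 1]]
    for (a in c("A", "C", "G", "T")) {
      for (b in c("A", "C", "G", "T")) {
        n_ab <- sum(from == a & to == b)
        n_a <- sum(from == a)
        expect_equal(m$transitions[[s]][a, b], (n_ab + 1) / (n_a + 4))
      }
    }
  }
  expect_error(fit_mm1("AAAAAAAAA"), "non-canonical")
})

test_that("a single sequence with zero pseudocount has model probability 1", {
  m <- fit_mm1("CTGTAACAT", pseudocount = 0)
  expect_equal(lariatr:::mm1_log2prob(m, "CTGTAACAT"), 0)
})

test_that("log-odds scores behave like log-odds", {
  set.seed(61)
  pos <- fit_mm1(rand_canonical(30))
  expect_equal(mm1_score(pos, pos, rand_canonical(10)), rep(0, 10))
  pw <- fit_frequency_model(rand_canonical(30))
  expect_equal(pwm_score(pw, pw, rand_canonical(10)), rep(0, 10))
  # hand-built two-sequence models equal direct formula evaluation
  pos2 <- fit_mm1(c("CTGTAACAT", "TTCTCATAC"), pseudocount = 1)
  neg2 <- fit_mm1(c("AAATGAGGG", "CCGTCAACC"), pseudocount = 1)
  x <- "CTGTCATAC"
  hand <- function(m, x) {
    ch <- strsplit(x, "")[[1]]
    chain <- c(1, 2, 3, 5, 7, 8, 9)
    lp <- log2(m$initial[ch[1]])
    for (s in 1:6) {
      lp <- lp + log2(m$transitions[[s]][ch[chain[s]], ch[chain[s + 1]]])
    }
    unname(lp)
  }
  expect_equal(mm1_score(pos2, neg2, x), hand(pos2, x) - hand(neg2, x))
  expect_error(mm1_score(pos2, neg2, "AAAAAAAAA"), "non-canonical")
})

test_that("PWM and MM1 scores coincide when the transitions factorize", {
  # hand-build a pair of models whose MM1 conditionals do not depend on the
  # conditioning nucleotide: every transition row equals the target
  # position's marginal, so the chain is an independence model
  set.seed(81)
  nts <- c("A", "C", "G", "T")
  chain <- c(1, 2, 3, 5, 7, 8, 9)
  make_pair <- function() {
    probs <- matrix(0.25, 9, 4, dimnames = list(1:9, nts))
    for (i in chain) {
      p <- stats::runif(4) + 0.1
      probs[i, ] <- p / sum(p)
    }
    probs[4, ] <- c(0, 0, 0, 1)
    probs[6, ] <- c(1, 0, 0, 0)
    freq <- structure(
      list(
        counts = probs * 100, probs = probs, n_seqs = 100, pseudocount = 0
      ),
      class = "bp_freq_model"
    )
    transitions <- lapply(seq_len(6), function(s) {
      matrix(probs[chain[s + 1], ], 4, 4,
        byrow = TRUE, dimnames = list(nts, nts)
      )
    })
    mm1 <- structure(
      list(
        initial = probs[1, ], transitions = transitions, chain = chain,
        n_seqs = 100, pseudocount = 0
      ),
      class = "bp_mm1_model"
    )
    list(freq = freq, mm1 = mm1)
  }
  pos <- make_pair()
  neg <- make_pair()
  x <- rand_canonical(50)
  expect_equal(
    mm1_score(pos$mm1, neg$mm1, x),
    pwm_score(pos$freq, neg$freq, x)
  )
  # and the PWM score is monotone in a per-position probability ratio
  base <- pos$freq
  base$probs[1, ] <- rep(0.25, 4)
  bumped <- base
  bumped$probs[1, ] <- c(0.7, 0.1, 0.1, 0.1)
  a_first <- substring(x, 1, 1) == "A"
  delta <- pwm_score(bumped, neg$freq, x) - pwm_score(base, neg$freq, x)
  expect_true(all(delta[a_first] > 0) && all(delta[!a_first] < 0))
})

test_that("motif models survive a serialization round-trip", {
  set.seed(71)
  seqs <- rand_canonical(25)
  dir <- withr::local_tempdir()
  m1 <- fit_mm1(seqs)
  f1 <- file.path(dir, "mm1.json")
  write_motif_model(m1, f1)
  back <- read_motif_model(f1)
  expect_equal(back$initial, m1$initial)
  expect_equal(back$transitions, m1$transitions, ignore_attr = TRUE)
  m2 <- fit_frequency_model(seqs)
  f2 <- file.path(dir, "freq.json")
  write_motif_model(m2, f2)
  back2 <- read_motif_model(f2)
  expect_equal(back2$probs, m2$probs, ignore_attr = TRUE)
  x <- rand_canonical(10)
  expect_equal(mm1_score(back, m1, x), rep(0, 10))
})

test_that("U2 duplex energies favor the perfect complement", {
  backend <- Sys.which("RNAcofold")
  if (!nzchar(backend)) {
    expect_error(u2_duplex_energy("TACTAACAC"), "disabled")
  } else {
    perfect <- "TACTAACAC"
    variants <- vapply(c(1, 3, 8), function(i) {
      x <- strsplit(perfect, "")[[1]]
      x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
      paste(x, collapse = "")
    }, character(1))
    e <- u2_duplex_energy(c(perfect, variants))
    expect_true(all(e[1] <= e[-1]))
    # deterministic for a fixed backend
    expect_identical(e, u2_duplex_energy(c(perfect, variants)))
  }
})
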