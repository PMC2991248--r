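make_block <- function(rows, id = "b1",
                       species = paste0("sp", seq_along(rows))) {
  tibble::tibble(intron_id = id, species = species, alignment = rows)
}

test_that("conserved instances require identity and gap-freedom in all rows", {
  # identical ungapped rows: every pentamer instance is conserved
  seq <- "ACGTACGTACGT"
  b <- make_block(rep(seq, 3))
  got <- conserved_kmer_instances(b, k = 5)
  expect_equal(nrow(got), nchar(seq) - 4L)
  expect_equal(got$pos, seq(-12L, -5L))
  # one species differing at one column breaks the pentamers covering it
  rows <- rep(seq, 3)
  substr(rows[2], 6, 6) <- "T" # column 6 (ungapped position 6)
  got2 <- conserved_kmer_instances(make_block(rows), k = 5)
  # instances whose window covers ungapped position 6 are gone
  covered <- vapply(got2$pos, function(p) {
    start1 <- p + nchar(seq) + 1L
    6 >= start1 && 6 <= start1 + 4L
  }, logical(1))
  expect_false(any(covered))
  expect_equal(nrow(got2), nchar(seq) - 4L - 5L)
  # a gap column breaks conservation the same way
  rows3 <- rep(seq, 3)
  substr(rows3[3], 6, 6) <- "-"
  got3 <- conserved_kmer_instances(make_block(rows3), k = 5)
  expect_equal(got3$pos, got2$pos)
})

test_that("conserved instances match the column-by-column oracle on fuzz", {
  set.seed(2001)
  for (i in 1:60) {
    n <- sample(20:60, 1)
    ref <- random_seq(n)
    rows <- c(ref, vapply(1:3, function(s) {
      ch <- strsplit(ref, "")[[1]]
      mut <- runif(n) < 0.15
      ch[mut] <- sample(c("A", "C", "G", "T", "-"), sum(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1)))
    got <- conserved_kmer_instances(make_block(rows), k = 5)
    want <- oracle_conserved(rows, 5)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$pos, vapply(want, `[[`, integer(1), "pos"))
      expect_equal(got$kmer, vapply(want, `[[`, character(1), "kmer"))
    }
  }
})

test_that("pentamer classification separates uniform, peaked and 3'-biased
           position profiles", {
  set.seed(2002)
  profiles <- tibble::tibble(
    pentamer = c("CTAAC", "TTAAT", "CTCTC"),
    positions_conserved = list(
      # uniform over the scan region -> none
      sample(-300:-1, 400, replace = TRUE),
      # tight peak at -24 -> bp
      pmax(pmin(round(rnorm(400, -24, 5)), -15), -55),
      # PPT-like: peaked just downstream of the window (still enriched in
      # it, but with the mode outside) -> ppt
      pmin(pmax(round(rnorm(400, -12, 6)), -300), -1)
    )
  )
  got <- classify_pentamers(profiles, alpha = 0.001)
  expect_equal(got$label, c("none", "bp", "ppt"))
  expect_true(got$peak[2] >= -55 && got$peak[2] <= -15)
  # no conserved instances -> none, deterministic
  empty <- classify_pentamers(tibble::tibble(
    pentamer = "TAAAA", positions_conserved = list(integer())
  ))
  expect_equal(empty$label, "none")
})

test_that("classification is deterministic given positions and alpha", {
  set.seed(2003)
  pos <- round(rnorm(200, -30, 8))
  profiles <- tibble::tibble(
    pentamer = "CTGAC", positions_conserved = list(pos)
  )
  a <- classify_pentamers(profiles)
  b <- classify_pentamers(profiles)
  expect_identical(a$label, b$label)
  expect_identical(a$ks_p, b$ks_p)
})

test_that("consTNA keeps only unique, window-positioned conserved TNA
           instances with one record per intron", {
  # one conserved TNA at -24 (A position), plenty of context
  base <- strrep("C", 300)
  plant <- function(seq, tri, a_pos) {
    start1 <- a_pos - 2L + 300L + 1L # T position, 1-based
    paste0(
      substr(seq, 1, start1 - 1), tri,
      substr(seq, start1 + 3, 300)
    )
  }
  s1 <- plant(base, "TGA", -24L)
  b1 <- make_block(rep(s1, 3), id = "one_tna")
  # two conserved TNAs -> excluded by uniqueness
  s2 <- plant(plant(base, "TGA", -24L), "TCA", -40L)
  b2 <- make_block(rep(s2, 3), id = "two_tna")
  # unique TNA but outside the window -> excluded
  s3 <- plant(base, "TGA", -60L)
  b3 <- make_block(rep(s3, 3), id = "deep_tna")
  blocks <- dplyr::bind_rows(b1, b2, b3)
  got <- build_cons_tna(blocks)
  expect_equal(got$intron_id, "one_tna")
  expect_equal(got$bp_pos, -24L)
  expect_equal(nchar(got$ninemer), 9L)
  expect_equal(substring(got$ninemer, 4, 6), "TGA")
  expect_equal(dplyr::count(got, intron_id)$n, 1L)
})

test_that("the BP5 filter demands an overlapping BP pentamer in every
           species", {
  # reference block where the TNA sits in a TACTAAC context in all species
  ctx <- paste0(
    strrep("C", 300 - 31), "TACTAACAC", strrep("C", 22)
  ) # TNA: T at -28, A at -26
  b_ok <- make_block(rep(ctx, 3), id = "kept")
  # same reference, but one species loses the context around the (still
  # conserved) TNA
  other <- ctx
  substr(other, 276, 276) <- "G" # CTAAC -> CTAAG in this species only
  b_drop <- make_block(c(ctx, ctx, other), id = "dropped")
  blocks <- dplyr::bind_rows(b_ok, b_drop)
  cons <- build_cons_tna(blocks)
  expect_setequal(cons$intron_id, c("kept", "dropped"))
  kept <- filter_bp5(cons, bp_pentamers = c("CTAAC"), blocks)
  expect_equal(kept$intron_id, "kept")
  # output is always a subset of the input
  expect_true(all(kept$intron_id %in% cons$intron_id))
  expect_error(filter_bp5(cons, character(), blocks), "nonempty")
})
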