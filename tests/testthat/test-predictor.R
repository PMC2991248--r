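# small shared fixture: a modest synthetic cohort + trained bundle
local_cohort <- local({
  cohort <- NULL
  function() {
    if (is.null(cohort)) {
      cfg <- synth_config(n_introns = 120L, seed = 314L)
      dat <- generate_introns(cfg)
      tracts <- find_ppts(dat)
      bundle <- train_bp_model(
        dat, dat[c("intron_id", "bp_pos")],
        seed = 9L, tracts = tracts
      )
      cohort <<- list(dat = dat, tracts = tracts, bundle = bundle)
    }
    cohort
  }
})

test_that("extracted features match an independent recomputation", {
  co <- local_cohort()
  dat <- co$dat
  cand <- enumerate_candidates(dat, region = c(-500, -3))
  cand <- cand[sample.int(nrow(cand), 100), ]
  f <- extract_features(
    cand, dat, co$tracts,
    co$bundle$pos_mm1, co$bundle$neg_mm1
  )
  expect_true(all(f$py_content >= 0 & f$py_content <= 1))
  expect_true(all(f$ppt_distance >= 0))
  for (k in sample.int(nrow(f), 25)) {
    seq <- dat$sequence[dat$intron_id == f$intron_id[k]]
    L <- nchar(seq)
    gap_chars <- strsplit(
      substr(seq, f$bp_pos[k] + L + 2, L - 2), ""
    )[[1]]
    expect_equal(f$py_content[k], mean(gap_chars %in% c("C", "T")))
    expect_equal(
      f$motif_score[k],
      mm1_score(co$bundle$pos_mm1, co$bundle$neg_mm1, f$ninemer[k])
    )
  }
  # BP right at -15 with an all-pyrimidine gap
  s <- paste0(strrep("G", 30), "CCTCA", "TTTTTTTTTTTT", "AG")
  toy <- toy_introns(s)
  cand1 <- tibble::tibble(
    intron_id = "t1", bp_pos = -15L,
    ninemer = substr(s, nchar(s) - 19, nchar(s) - 11)
  )
  f1 <- extract_features(
    cand1, toy, NULL, co$bundle$pos_mm1, co$bundle$neg_mm1
  )
  expect_equal(f1$py_content, 1)
})

test_that("negative sampling is seeded, exclusive, and near-uniform", {
  co <- local_cohort()
  dat <- co$dat
  pos <- dat[c("intron_id", "bp_pos")]
  n1 <- sample_negatives(dat, 200L, seed = 5L, exclude = pos)
  n2 <- sample_negatives(dat, 200L, seed = 5L, exclude = pos)
  expect_identical(n1, n2)
  # never coincides with an excluded (intron, position) pair
  expect_equal(
    nrow(dplyr::inner_join(n1, pos, by = c("intron_id", "bp_pos"))), 0L
  )
  expect_error(sample_negatives(dat, 10^7, seed = 1L), "smaller")
  # uniformity over the pool: chi-square on repeated draws from a tiny pool
  small <- dat[1:3, ]
  pool <- enumerate_candidates(small, region = c(-500, -3))
  draws <- table(unlist(lapply(1:400, function(i) {
    s <- sample_negatives(small, 5L, seed = i)
    paste(s$intron_id, s$bp_pos)
  })))
  expect_equal(length(draws), nrow(pool))
  p <- stats::chisq.test(as.vector(draws))$p.value
  expect_gt(p, 1e-4)
})

test_that("the SVM separates separable classes and is deterministic", {
  set.seed(99)
  fpos <- tibble::tibble(
    motif_score = rnorm(60, 3), py_content = runif(60, 0.7, 1),
    ppt_distance = rpois(60, 3), ppt_score = rnorm(60, 50, 5)
  )
  fneg <- tibble::tibble(
    motif_score = rnorm(60, -3), py_content = runif(60, 0, 0.3),
    ppt_distance = rpois(60, 300), ppt_score = rnorm(60, 5, 2)
  )
  m1 <- train_bp_svm(fpos, fneg, seed = 2L)
  expect_true(all(svm_decision(m1, fpos) > 0))
  expect_true(all(svm_decision(m1, fneg) < 0))
  m2 <- train_bp_svm(fpos, fneg, seed = 2L)
  expect_identical(svm_decision(m1, fpos), svm_decision(m2, fpos))
  expect_error(train_bp_svm(fpos[0, ], fneg), "nonempty")
  expect_error(
    train_bp_svm(dplyr::mutate(fpos, motif_score = Inf), fneg),
    "finite"
  )
  # balanced training downsamples the majority class
  m3 <- train_bp_svm(fpos, fneg[1:10, ], seed = 3L)
  expect_equal(m3$n_pos, 10L)
  expect_equal(m3$n_neg, 10L)
})

test_that("per-intron prediction partitions categories and ranks totally", {
  co <- local_cohort()
  pred <- predict_branch_points(co$dat, co$bundle, tracts = co$tracts)
  g <- glance(pred)
  expect_equal(
    g$no_candidates + g$none_in_agez + g$negative_scoring + g$positive_scoring,
    nrow(co$dat)
  )
  cand <- pred$candidates
  in_agez <- cand[!is.na(cand$rank), ]
  by_intron <- split(in_agez, in_agez$intron_id)
  for (b in by_intron) {
    expect_identical(sort(b$rank), seq_len(nrow(b)))
    expect_equal(b$svm_score[b$rank == 1], max(b$svm_score))
  }
  # permuting the intron input order leaves ranks unchanged
  perm <- co$dat[sample.int(nrow(co$dat)), ]
  pred2 <- predict_branch_points(perm, co$bundle, tracts = co$tracts)
  a <- dplyr::arrange(pred$candidates, intron_id, bp_pos)
  b <- dplyr::arrange(pred2$candidates, intron_id, bp_pos)
  expect_equal(a$rank, b$rank)
  expect_equal(a$svm_score, b$svm_score)
  # scan output is a superset of the AGEZ-restricted candidates
  expect_true(all(!is.na(cand$bp_pos)))
  expect_gte(nrow(cand), nrow(in_agez))
  # distant flag: only best candidates beyond 100 nt
  preds <- pred$predictions
  expect_equal(
    preds$is_distant,
    !is.na(preds$bp_pos) & preds$bp_pos < -100L
  )
})

test_that("degenerate intron inputs land in the right categories", {
  co <- local_cohort()
  # no canonical 9-mer anywhere: C/G only
  s_none <- paste0(strrep("CG", 100), "CAG")
  # candidates exist in the scan region but the AGEZ is candidate-free:
  # an AG at -16 confines the AGEZ to the last 15 nt (min_dist excludes it)
  s_out <- paste0(
    strrep("C", 60), "TTCTAACTT", strrep("C", 20),
    "AG", strrep("C", 13), "AG"
  )
  pred <- predict_branch_points(
    toy_introns(c(s_none, s_out)), co$bundle
  )
  expect_equal(
    pred$predictions$category,
    c("no_candidates", "none_in_agez")
  )
  expect_true(all(is.na(pred$predictions$bp_pos)))
})

test_that("position histograms re-anchor without losing mass", {
  co <- local_cohort()
  pred <- predict_branch_points(co$dat, co$bundle, tracts = co$tracts)
  h3 <- position_histogram(pred, anchor = "3ss")
  n_best <- sum(!is.na(pred$predictions$bp_pos))
  expect_equal(sum(h3$n), n_best)
  hag <- position_histogram(pred, anchor = "defining_ag")
  n_ag <- sum(!is.na(pred$predictions$bp_pos) &
    !is.na(pred$predictions$defining_ag))
  expect_equal(sum(hag$n), n_ag)
  # single prediction -> unit mass at its position
  one <- pred$predictions[!is.na(pred$predictions$bp_pos), ][1, ]
  h1 <- position_histogram(one)
  expect_equal(h1$n, 1L)
  expect_equal(h1$position, one$bp_pos)
})

test_that("model bundles survive a save/load round-trip", {
  co <- local_cohort()
  dir <- withr::local_tempdir()
  write_model_bundle(co$bundle, dir)
  back <- read_model_bundle(dir)
  sub <- co$dat[1:10, ]
  p1 <- predict_branch_points(sub, co$bundle)
  p2 <- predict_branch_points(sub, back)
  expect_equal(p1$predictions$svm_score, p2$predictions$svm_score)
  expect_equal(p1$predictions$category, p2$predictions$category)
  expect_error(
    suppressWarnings(read_model_bundle(withr::local_tempdir())),
    "cannot|bundle"
  )
})

test_that("tidy and glance summarize fitted objects broom-style", {
  co <- local_cohort()
  w <- tidy(co$bundle$svm)
  expect_setequal(
    w$term,
    c("(intercept)", "motif_score", "py_content", "ppt_distance", "ppt_score")
  )
  # downstream-PPT distance should hurt, pyrimidine content should help
  expect_lt(w$estimate[w$term == "ppt_distance"], 0)
  expect_gt(w$estimate[w$term == "py_content"], 0)
  g <- glance(co$bundle$svm)
  expect_equal(g$kernel, "linear")
  pred <- predict_branch_points(co$dat[1:20, ], co$bundle)
  expect_s3_class(tidy(pred), "tbl_df")
  expect_equal(glance(pred)$n_introns, 20L)
})
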