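test_that("empirical ROC construction handles separated, reversed and tied toys", {
  rc <- build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_true(any(rc$points$sensitivity == 1 & rc$points$specificity == 1))
  expect_equal(rc$points$sensitivity[1], 0)
  expect_equal(rc$points$specificity[1], 1)
  expect_equal(rc$points$sensitivity[nrow(rc$points)], 1)
  expect_equal(rc$points$specificity[nrow(rc$points)], 0)

  anti <- build_roc(c(4, 3, 2, 1), c(0, 0, 1, 1))
  interior <- anti$points[anti$points$sensitivity %in% c(0, 1) == FALSE, ]
  expect_true(all(interior$sensitivity + interior$specificity < 1))

  tied <- build_roc(rep(1, 4), c(1, 1, 0, 0))
  expect_equal(nrow(tied$points), 2)  # only the trivial endpoints
})

test_that("ROC points sit on the k/n_pos and j/n_neg grids, monotonically", {
  set.seed(42)
  for (rep in 1:20) {
    n_pos <- sample(3:12, 1); n_neg <- sample(3:12, 1)
    scores <- round(c(rnorm(n_pos, 1), rnorm(n_neg)), 1)
    labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    rc <- build_roc(scores, labels)
    expect_true(all(abs(rc$points$sensitivity * n_pos -
                          round(rc$points$sensitivity * n_pos)) < 1e-9))
    expect_true(all(abs(rc$points$specificity * n_neg -
                          round(rc$points$specificity * n_neg)) < 1e-9))
    expect_true(all(diff(rc$points$sensitivity) >= 0))
    expect_true(all(diff(rc$points$specificity) <= 0))
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- rlnorm(30)
  labels <- runif(30) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  rc <- build_roc(scores, labels)
  for (f in list(log, sqrt, function(x) 3 * x + 2)) {
    rc2 <- build_roc(f(scores), labels)
    expect_equal(rc2$points$sensitivity, rc$points$sensitivity)
    expect_equal(rc2$points$specificity, rc$points$specificity)
  }
  # positive_if_less mirrors negation
  rc3 <- build_roc(-scores, labels, "positive_if_less")
  expect_equal(rc3$points$sensitivity, rc$points$sensitivity)
  expect_equal(rc3$points$specificity, rc$points$specificity)
})

test_that("single-class labels are rejected as degenerate", {
  expect_error(build_roc(1:4, c(1, 1, 1, 1)), "degenerate")
  expect_error(build_roc(1:4, c(0, 0, 0, 0)), "degenerate")
})

test_that("partial AUC has the analytic limiting values on the 90-100% band", {
  perfect <- build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(pauc_sensitivity_band(perfect, c(0.9, 1)), 0.10, tolerance = 1e-9)
  # a constant score interpolates to the chance diagonal: int_{.9}^{1}(1-s)ds
  diag <- build_roc(rep(1, 4), c(1, 1, 0, 0))
  expect_equal(pauc_sensitivity_band(diag, c(0.9, 1)), 0.005, tolerance = 1e-9)
  anti <- build_roc(c(4, 3, 2, 1), c(0, 0, 1, 1))
  expect_equal(pauc_sensitivity_band(anti, c(0.9, 1)), 0)
})

test_that("partial AUC is additive over bands and totals the AUC", {
  set.seed(11)
  scores <- rnorm(40)
  labels <- runif(40) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  rc <- build_roc(scores, labels)
  full <- pauc_sensitivity_band(rc, c(0, 1))
  parts <- pauc_sensitivity_band(rc, c(0, 0.37)) +
    pauc_sensitivity_band(rc, c(0.37, 0.9)) +
    pauc_sensitivity_band(rc, c(0.9, 1))
  expect_equal(parts, full, tolerance = 1e-12)
  expect_gte(pauc_sensitivity_band(rc, c(0.9, 1)), 0)
  expect_lte(pauc_sensitivity_band(rc, c(0.9, 1)), 0.1 + 1e-12)
  expect_error(pauc_sensitivity_band(rc, c(0.9, 1.1)), "band")
})

test_that("full-band pAUC agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(60)
  labels <- runif(60) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  rc <- build_roc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        quiet = TRUE)))
  expect_equal(pauc_sensitivity_band(rc, c(0, 1)), ref, tolerance = 1e-9)
})

test_that("constrained operating point maximizes specificity on the attained grid", {
  # perfect toy: the (1, 1) corner qualifies
  perfect <- build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
  op <- operating_point_at_sensitivity(perfect, 0.9)
  expect_equal(unname(op["sensitivity"]), 1)
  expect_equal(unname(op["specificity"]), 1)
  # the (1, 0) endpoint always qualifies, so a point is always returned
  anti <- build_roc(c(4, 3, 2, 1), c(0, 0, 1, 1))
  op2 <- operating_point_at_sensitivity(anti, 0.9)
  expect_equal(unname(op2["sensitivity"]), 1)
  expect_equal(unname(op2["specificity"]), 0)
  # returned point dominates every other attained point in the band
  set.seed(5)
  scores <- rnorm(50); labels <- runif(50) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  rc <- build_roc(scores, labels)
  op3 <- operating_point_at_sensitivity(rc, 0.9)
  in_band <- rc$points[rc$points$sensitivity >= 0.9, ]
  expect_equal(unname(op3["specificity"]), max(in_band$specificity))
})

test_that("attainable sensitivities with 33 events form the k/33 grid", {
  # scores built so that each of the 33 events peels off one at a time
  scores <- c(33:1, -(1:49))
  labels <- rep(c(TRUE, FALSE), c(33, 49))
  rc <- build_roc(scores, labels)
  sens <- sort(unique(rc$points$sensitivity))
  expect_equal(sens, (0:33) / 33)
  below_100 <- max(sens[sens < 1])
  expect_equal(below_100, 32 / 33)
  expect_equal(unname(sens_spec_from_counts(32, 1, 1, 1)["sensitivity"]), 97.0)
  expect_equal(min(sens[sens >= 0.9]), 30 / 33)
})

test_that("confusion-count arithmetic matches hand-computed percentages", {
  expect_equal(unname(sens_spec_from_counts(tp = 30, fn = 3, tn = 11, fp = 38)),
               c(90.9, 22.4))
  expect_equal(unname(sens_spec_from_counts(tp = 30, fn = 3, tn = 29, fp = 20)),
               c(90.9, 59.2))
  expect_equal(unname(sens_spec_from_counts(tp = 5, fn = 0, tn = 1, fp = 1)[1]),
               100)
  # half-up rounding at the .x5 boundary (banker's rounding would give 12.4)
  expect_equal(unname(sens_spec_from_counts(tp = 1, fn = 7, tn = 1, fp = 1)[1]),
               12.5)
  expect_error(sens_spec_from_counts(0, 0, 1, 1), "margin")
  expect_error(sens_spec_from_counts(-1, 1, 1, 1), "non-negative")
})

test_that("stratified bootstrap is reproducible, degenerate-safe and sane", {
  scores <- c(4, 3, 2, 1); labels <- c(1, 1, 0, 0)
  const <- bootstrap_ci(scores, labels, function(s, l) 5, n_boot = 100, seed = 1)
  expect_equal(unname(const), c(5, 5))
  # perfect separation survives stratified resampling
  sep <- bootstrap_ci(scores, labels, function(s, l)
    pauc_sensitivity_band(build_roc(s, l), c(0.9, 1)), n_boot = 200, seed = 1)
  expect_equal(unname(sep), c(0.10, 0.10))
  # reproducibility and RNG hygiene
  set.seed(99); before <- runif(1)
  a <- bootstrap_ci(scores, labels, function(s, l) mean(s[l]), n_boot = 100, seed = 2)
  b <- bootstrap_ci(scores, labels, function(s, l) mean(s[l]), n_boot = 100, seed = 2)
  expect_identical(a, b)
  set.seed(99); expect_identical(runif(1), before)
  expect_error(bootstrap_ci(scores, labels, function(s, l) 1, n_boot = 50),
               "n_boot")
})

test_that("bootstrap interval usually contains the point estimate", {
  set.seed(1)
  n_pos <- 33; n_neg <- 49
  labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  hit <- 0; n_rep <- 25
  for (r in seq_len(n_rep)) {
    scores <- c(rnorm(n_pos, 1), rnorm(n_neg))
    est <- unname(operating_point_at_sensitivity(build_roc(scores, labels),
                                                 0.9)["specificity"])
    ci <- bootstrap_ci(scores, labels, function(s, l)
      unname(operating_point_at_sensitivity(build_roc(s, l), 0.9)["specificity"]),
      n_boot = 300, seed = r)
    if (ci["low"] <= est && est <= ci["high"]) hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.9)
})
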