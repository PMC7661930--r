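published_style_panel <- function() {
  panel_definition(list(
    marker_rule("hcts_sum", 4, "positive_if_greater"),
    marker_rule("il10", 0.48, "positive_if_less"),
    marker_rule("ab40", 7.38, "positive_if_greater")
  ), min_positive = 2)
}

test_that("panel scoring counts strictly satisfied rules", {
  p <- published_style_panel()
  rec <- data.frame(hcts_sum = 5, il10 = 0.30, ab40 = 10.0)
  expect_identical(panel_score(p, rec), 3L)
  # exact boundary values satisfy nothing: comparisons are strict
  boundary <- data.frame(hcts_sum = 4, il10 = 0.48, ab40 = 7.38)
  expect_identical(panel_score(p, boundary), 0L)
  expect_error(panel_definition(list()), "at least one rule")
  expect_error(panel_score(p, data.frame(hcts_sum = 1, il10 = NA, ab40 = 1)),
               "missing")
  expect_error(panel_score(p, data.frame(hcts_sum = 1, il10 = 0.2)), "lacks")
})

test_that("panel classification applies the inclusive min-positive cut", {
  p <- published_style_panel()
  recs <- data.frame(hcts_sum = c(5, 5, 4), il10 = c(0.3, 0.6, 0.3),
                     ab40 = c(10, 2, 10))
  # scores 3, 1, 2 against min_positive = 2
  expect_identical(panel_score(p, recs), c(3L, 1L, 2L))
  expect_identical(panel_classify(p, recs), c(TRUE, FALSE, TRUE))
})

test_that("panel definitions reject duplicates and out-of-range cuts", {
  r <- marker_rule("a", 1)
  expect_error(panel_definition(list(r, marker_rule("a", 2)), 1), "duplicate")
  expect_error(panel_definition(list(r), 2), "min_positive")
  expect_error(marker_rule("a", Inf), "finite")
})

test_that("a single-rule panel reduces to the dichotomized marker", {
  set.seed(21)
  d <- data.frame(x = rnorm(40))
  labels <- d$x + rnorm(40, sd = 0.5) > 0
  labels[1:2] <- c(TRUE, FALSE)
  p <- panel_definition(list(marker_rule("x", 0.2)), 1)
  perf <- evaluate_panel(p, d, labels, n_boot = 0)
  pred <- d$x > 0.2
  expect_equal(perf$sensitivity, sum(pred & labels) / sum(labels))
  expect_equal(perf$specificity, sum(!pred & !labels) / sum(!labels))
  expect_equal(sum(perf$counts), nrow(d))
  # and its ROC is the marker's own two-point curve over the same cut
  marker_curve <- build_roc(as.numeric(pred), labels)
  expect_equal(perf$pauc,
               pauc_sensitivity_band(marker_curve, c(0.9, 1)))
})

test_that("evaluate_panel counts, listwise exclusion and CIs are coherent", {
  p <- published_style_panel()
  set.seed(4)
  n <- 60
  d <- data.frame(hcts_sum = sample(-3:14, n, TRUE),
                  il10 = rlnorm(n), ab40 = rlnorm(n, 2))
  labels <- runif(n) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  d$il10[1:5] <- NA
  perf <- evaluate_panel(p, d, labels, n_boot = 200, seed = 1)
  expect_equal(perf$n_excluded, 5)
  expect_equal(sum(perf$counts), n - 5)
  ss <- sens_spec_from_counts(perf$counts["tp"], perf$counts["fn"],
                              perf$counts["tn"], perf$counts["fp"])
  expect_equal(unname(ss["sensitivity"]),
               round_half_up(100 * perf$sensitivity, 1))
  expect_equal(unname(ss["specificity"]),
               round_half_up(100 * perf$specificity, 1))
  expect_true(all(perf$ci[, "low"] <= perf$ci[, "high"]))
  # all-satisfied panel: sensitivity 1, specificity 0
  loose <- panel_definition(list(marker_rule("ab40", -1)), 1)
  perf2 <- evaluate_panel(loose, d, labels, n_boot = 0)
  expect_equal(perf2$sensitivity, 1)
  expect_equal(perf2$specificity, 0)
})

test_that("candidate thresholds: midpoints and quantile grids", {
  expect_equal(candidate_thresholds(c(1, 2, 4), "midpoints"), c(1.5, 3))
  expect_message(out <- candidate_thresholds(c(5, 5, 5), "midpoints"),
                 "no candidate thresholds")
  expect_length(out, 0)
  # quantile grid against direct order-statistic interpolation
  set.seed(8)
  v <- rlnorm(1000)
  q <- candidate_thresholds(v, "quantiles", grid_size = 19)
  expect_length(q, 19)
  sv <- sort(v)
  direct <- vapply(seq_len(19) / 20, function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }, 0)
  expect_equal(q, direct, tolerance = 1e-12)
  expect_false(is.unsorted(q))
})

test_that("panel JSON round-trips", {
  p <- published_style_panel()
  txt <- panel_to_json(p)
  p2 <- panel_from_json(txt)
  expect_equal(p2, p)
  f <- tempfile(fileext = ".json")
  panel_to_json(p, f)
  expect_equal(panel_from_json(f), p)
})

test_that("optimizer matches brute-force enumeration on tiny cohorts", {
  for (seed in 1:20) {
    tc <- random_tiny_cohort(n = sample(6:12, 1), n_markers = 3, seed = seed)
    fit <- optimize_panel(tc$data, names(tc$data), tc$labels, max_size = 3,
                          min_sens = 0.9, strategy = "midpoints")
    oracle <- oracle_panel_search(tc$data, names(tc$data), tc$labels,
                                  max_size = 3, min_sens = 0.9)
    expect_equal(fit$constraint_met, oracle$feasible)
    got <- fit$performance
    want <- if (oracle$feasible) oracle$best else oracle$fallback
    if (oracle$feasible) {
      expect_equal(got$specificity, want$spec, tolerance = 1e-9)
      expect_equal(got$pauc, want$pauc, tolerance = 1e-9)
      expect_gte(got$sensitivity, 0.9 - 1e-9)
    } else {
      expect_equal(got$sensitivity, want$sens, tolerance = 1e-9)
      expect_equal(got$specificity, want$spec, tolerance = 1e-9)
    }
  }
})

test_that("optimizer recovers a planted two-rule AND panel", {
  tc <- planted_and_cohort(seed = 101)
  fit <- optimize_panel(tc$data, c("A", "B", "C"), tc$labels, max_size = 2,
                        min_sens = 0.9, strategy = "midpoints")
  expect_true(fit$constraint_met)
  expect_equal(fit$performance$sensitivity, 1)
  expect_equal(fit$performance$specificity, 1)
  mk <- sort(vapply(fit$panel$rules, `[[`, "", "marker"))
  expect_equal(mk, c("A", "B"))
  expect_equal(fit$panel$min_positive, 2L)
  dirs <- vapply(fit$panel$rules, `[[`, "", "direction")
  names(dirs) <- vapply(fit$panel$rules, `[[`, "", "marker")
  expect_equal(unname(dirs["A"]), "positive_if_greater")
  expect_equal(unname(dirs["B"]), "positive_if_less")
})

test_that("enlarging the search space never hurts constrained specificity", {
  set.seed(31)
  n <- 50
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  labels <- (d$a + 0.8 * d$b + rnorm(n, sd = 0.8)) > 0
  labels[1:2] <- c(TRUE, FALSE)
  spec_at <- function(markers, size) {
    fit <- optimize_panel(d, markers, labels, max_size = size, min_sens = 0.8,
                          strategy = "midpoints")
    if (fit$constraint_met) fit$performance$specificity else -1
  }
  s1 <- spec_at("a", 1)
  s2 <- spec_at(c("a", "b"), 2)
  s3 <- spec_at(c("a", "b", "c"), 3)
  expect_gte(s2, s1)
  expect_gte(s3, s2)
})

test_that("infeasible constraints return a flagged sensitivity-maximizing panel", {
  # the two positives sit at opposite extremes, so no single midpoint rule
  # can capture both of them in either direction
  d <- data.frame(x = c(-2, 2, -1, 0, 1))
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  fit <- optimize_panel(d, "x", labels, max_size = 1, min_sens = 0.99,
                        strategy = "midpoints")
  oracle <- oracle_panel_search(d, "x", labels, max_size = 1, min_sens = 0.99)
  expect_false(fit$constraint_met)
  expect_equal(fit$performance$sensitivity, oracle$fallback$sens)
})
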