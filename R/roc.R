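#' Build an empirical ROC curve
#'
#' Constructs the empirical ROC curve of a continuous (or ordinal) score for
#' a binary outcome. Positivity is by strict comparison with a threshold:
#' `score > t` when `direction = "positive_if_greater"` or `score < t` when
#' `direction = "positive_if_less"` (used for markers whose *low* values flag
#' the adverse outcome, such as IL-10 inside panels). One operating point is
#' produced per distinct score value (ties collapse), plus the trivial
#' endpoints (sensitivity 0, specificity 1) and (sensitivity 1,
#' specificity 0).
#'
#' @param scores Numeric vector of marker values; must be finite.
#' @param labels Binary outcome per patient (`TRUE`/1 = event, i.e. the
#'   outcome the score is meant to detect).
#' @param direction `"positive_if_greater"` (default) or
#'   `"positive_if_less"`.
#' @return An object of class `roc_curve`: a list with `points` (data frame
#'   with `threshold`, `sensitivity`, `specificity`, ordered by
#'   non-decreasing sensitivity), `direction`, `n_pos`, `n_neg`.
#' @examples
#' build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
#' @export
build_roc <- function(scores, labels,
                      direction = c("positive_if_greater", "positive_if_less")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite and non-missing", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate cohort: both outcome classes are required to build a ROC curve",
         call. = FALSE)
  }
  u <- sort(unique(scores))
  if (direction == "positive_if_greater") {
    # t = max gives (0, 1); t = -Inf gives (1, 0)
    thresholds <- c(rev(u), -Inf)
    pos_at <- function(t) scores > t
  } else {
    thresholds <- c(u, Inf)
    pos_at <- function(t) scores < t
  }
  sens <- vapply(thresholds, function(t) sum(pos_at(t) & labels) / n_pos, 0)
  spec <- vapply(thresholds, function(t) sum(!pos_at(t) & !labels) / n_neg, 0)
  structure(
    list(points = data.frame(threshold = thresholds, sensitivity = sens,
                             specificity = spec),
         direction = direction, n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d operating points, %d events / %d non-events, %s\n",
              nrow(x$points), x$n_pos, x$n_neg, x$direction))
  cat(sprintf("AUC %.4f; pAUC(0.90-1.00) %.4f of the unit square\n",
              pauc_sensitivity_band(x, c(0, 1)),
              pauc_sensitivity_band(x, c(0.9, 1))))
  invisible(x)
}

#' Partial AUC over a sensitivity band
#'
#' Integrates specificity as a function of sensitivity over a sensitivity
#' band (default 0.90-1.00), with linear interpolation between adjacent
#' empirical operating points and exact partial trapezoids at the band
#' edges. The value is a fraction of the unit square: for the 0.90-1.00 band
#' the ceiling is 0.10 (a perfect classifier), the uninformative
#' (chance-diagonal) value is 0.005, and reports conventionally multiply by
#' 100 (so 10% and 0.5%). The full band `c(0, 1)` recovers the total AUC.
#'
#' @param curve A `roc_curve` from [build_roc()].
#' @param band Numeric `c(low, high)` with `0 <= low < high <= 1`.
#' @return Single numeric, on the unit-square scale.
#' @examples
#' rc <- build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
#' pauc_sensitivity_band(rc, c(0.9, 1))  # 0.10: perfect separation
#' @export
pauc_sensitivity_band <- function(curve, band = c(0.9, 1)) {
  stopifnot(inherits(curve, "roc_curve"))
  if (length(band) != 2 || anyNA(band) || band[1] < 0 || band[2] > 1 ||
      band[1] >= band[2]) {
    stop("band must be c(low, high) with 0 <= low < high <= 1", call. = FALSE)
  }
  pts <- curve$points
  k <- nrow(pts)
  sum(band_segment_area(pts$sensitivity[-k], pts$sensitivity[-1],
                        pts$specificity[-k], pts$specificity[-1],
                        band[1], band[2]))
}

#' Best operating point at a minimum sensitivity
#'
#' Among attained operating points with sensitivity at or above `min_sens`,
#' returns the one with maximal specificity; ties are broken toward higher
#' sensitivity, then toward the more extreme threshold. The (sensitivity 1,
#' specificity 0) endpoint always qualifies, so a point is always returned;
#' a returned specificity of 0 means the score cannot operate usefully in
#' the requested band.
#'
#' @param curve A `roc_curve` from [build_roc()].
#' @param min_sens Minimum sensitivity, in (0, 1].
#' @return Named numeric vector `c(threshold, sensitivity, specificity)`.
#' @examples
#' rc <- build_roc(c(4, 3, 2, 1), c(1, 1, 0, 0))
#' operating_point_at_sensitivity(rc, 0.9)
#' @export
operating_point_at_sensitivity <- function(curve, min_sens = 0.9) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.numeric(min_sens) || length(min_sens) != 1 || min_sens <= 0 ||
      min_sens > 1) {
    stop("min_sens must be a single value in (0, 1]", call. = FALSE)
  }
  pts <- curve$points
  ok <- pts$sensitivity >= min_sens - 1e-12
  pts <- pts[ok, , drop = FALSE]
  extreme <- if (curve$direction == "positive_if_greater") -pts$threshold else pts$threshold
  best <- order(-pts$specificity, -pts$sensitivity, extreme)[1]
  c(threshold = pts$threshold[best],
    sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best])
}

#' Sensitivity and specificity from confusion counts
#'
#' Computes sensitivity = 100 * tp / (tp + fn) and specificity =
#' 100 * tn / (tn + fp), in percent, rounded half-up to one decimal (the
#' reporting convention used throughout the package; rounding is applied
#' only here, never inside computations).
#'
#' @param tp,fn,tn,fp Non-negative integer counts; both margins must be
#'   non-empty.
#' @return Named numeric vector `c(sensitivity, specificity)`, in percent.
#' @examples
#' sens_spec_from_counts(tp = 32, fn = 1, tn = 11, fp = 38)
#' # sensitivity 97.0, specificity 22.4
#' @export
sens_spec_from_counts <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn < 1 || tn + fp < 1) {
    stop("empty margin: need at least one event and one non-event", call. = FALSE)
  }
  c(sensitivity = round_half_up(100 * tp / (tp + fn), 1),
    specificity = round_half_up(100 * tn / (tn + fp), 1))
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples patients with replacement *within* each outcome class (so every
#' replicate keeps both classes represented, and class sizes are preserved),
#' recomputes a statistic on each replicate, and returns the percentile
#' interval. Reproducible under a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param scores Numeric vector (or any per-patient values the statistic
#'   consumes).
#' @param labels Binary outcome per patient.
#' @param statistic `function(scores, labels)` returning a numeric scalar or
#'   a named numeric vector (all components are bootstrapped jointly from
#'   the same resamples).
#' @param n_boot Number of bootstrap replicates (>= 100; default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A matrix with one row per statistic component and columns `low`,
#'   `high`; for a scalar statistic a named vector `c(low, high)`.
#' @examples
#' sc <- c(4, 3, 2, 1); lb <- c(1, 1, 0, 0)
#' bootstrap_ci(sc, lb, function(s, l)
#'   pauc_sensitivity_band(build_roc(s, l), c(0.9, 1)), n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(scores, labels, statistic, n_boot = 2000, seed = 1,
                         conf = 0.95) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), is.function(statistic))
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  pos <- which(labels)
  neg <- which(!labels)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("degenerate cohort: both classes required for a stratified bootstrap",
         call. = FALSE)
  }
  proto <- statistic(scores, labels)
  reps <- with_preserved_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      as.numeric(statistic(scores[idx], labels[idx]))
    }, FUN.VALUE = as.numeric(proto))
  })
  alpha <- (1 - conf) / 2
  if (is.matrix(reps)) {
    out <- t(apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                   names = FALSE, type = 7))
    dimnames(out) <- list(names(proto), c("low", "high"))
    out
  } else {
    q <- stats::quantile(reps, probs = c(alpha, 1 - alpha), names = FALSE,
                         type = 7)
    c(low = q[1], high = q[2])
  }
}
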