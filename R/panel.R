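#' Single-marker threshold rule
#'
#' A rule declares a patient "rule-positive" when the marker value is
#' strictly beyond the threshold in the stated direction: `value > threshold`
#' for `positive_if_greater`, `value < threshold` for `positive_if_less`.
#' Comparisons are strict throughout, matching the conventional panel
#' notation "HCTS (>4)", "IL-10 (<0.48 pg/ml)".
#'
#' @param marker Column name of the marker in the cohort table.
#' @param threshold Finite numeric cutoff (pg/ml for biomarkers, unitless for
#'   an integer CT score).
#' @param direction `"positive_if_greater"` or `"positive_if_less"`.
#' @return An object of class `marker_rule`.
#' @examples
#' marker_rule("il10", 0.48, "positive_if_less")
#' @export
marker_rule <- function(marker,
                        threshold,
                        direction = c("positive_if_greater", "positive_if_less")) {
  direction <- match.arg(direction)
  stopifnot(is.character(marker), length(marker) == 1, nzchar(marker))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    stop("threshold must be a single finite number", call. = FALSE)
  }
  structure(list(marker = marker, threshold = threshold, direction = direction),
            class = "marker_rule")
}

#' @export
format.marker_rule <- function(x, ...) {
  op <- if (x$direction == "positive_if_greater") ">" else "<"
  sprintf("%s (%s%g)", x$marker, op, x$threshold)
}

#' @export
print.marker_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Threshold-panel definition
#'
#' A panel combines one to three marker rules through a
#' minimum-positive-count decision cut: a patient is panel-positive when at
#' least `min_positive` of the rules are satisfied.
#'
#' @param rules A list of [marker_rule()] objects (1-3 rules, distinct
#'   markers).
#' @param min_positive Decision cut, between 1 and the number of rules.
#' @return An object of class `panel_definition`.
#' @examples
#' panel_definition(list(
#'   marker_rule("hcts_sum", 4, "positive_if_greater"),
#'   marker_rule("il10", 0.48, "positive_if_less")
#' ), min_positive = 2)
#' @export
panel_definition <- function(rules, min_positive = length(rules)) {
  if (!is.list(rules) || length(rules) < 1) {
    stop("a panel needs at least one rule", call. = FALSE)
  }
  if (length(rules) > 3) {
    stop("panels are limited to three rules", call. = FALSE)
  }
  if (!all(vapply(rules, inherits, TRUE, "marker_rule"))) {
    stop("rules must be marker_rule objects", call. = FALSE)
  }
  markers <- vapply(rules, `[[`, "", "marker")
  if (anyDuplicated(markers)) {
    stop("duplicate marker in panel: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(min_positive) || length(min_positive) != 1 ||
      min_positive < 1 || min_positive > length(rules) ||
      min_positive != floor(min_positive)) {
    stop("min_positive must be an integer between 1 and the number of rules",
         call. = FALSE)
  }
  structure(list(rules = rules, min_positive = as.integer(min_positive)),
            class = "panel_definition")
}

#' @export
format.panel_definition <- function(x, ...) {
  sprintf("%s [>=%d positive]",
          paste(vapply(x$rules, format, ""), collapse = " + "),
          x$min_positive)
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("Threshold panel:", format(x), "\n")
  invisible(x)
}

panel_markers <- function(panel) vapply(panel$rules, `[[`, "", "marker")

#' Count satisfied panel rules per patient
#'
#' @param panel A [panel_definition()].
#' @param data Cohort data frame containing every panel marker; records with
#'   missing panel-marker values must be excluded beforehand (an NA here is
#'   an error, never a silent score).
#' @return Integer vector in `[0, n_rules]`, one per row of `data`.
#' @examples
#' p <- panel_definition(list(marker_rule("a", 1), marker_rule("b", 2)), 1)
#' panel_score(p, data.frame(a = c(0, 2), b = c(3, 0)))
#' @export
panel_score <- function(panel, data) {
  stopifnot(inherits(panel, "panel_definition"), is.data.frame(data))
  markers <- panel_markers(panel)
  missing_cols <- setdiff(markers, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort lacks panel marker(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(data[markers])
  if (anyNA(vals)) {
    stop("missing panel-marker values: exclude incomplete records before scoring",
         call. = FALSE)
  }
  score <- integer(nrow(data))
  for (r in panel$rules) {
    v <- vals[, r$marker]
    hit <- if (r$direction == "positive_if_greater") v > r$threshold else v < r$threshold
    score <- score + as.integer(hit)
  }
  score
}

#' Classify patients with a threshold panel
#'
#' Panel-positive iff the number of satisfied rules is at least the panel's
#' `min_positive` cut (boundary inclusive).
#'
#' @inheritParams panel_score
#' @return Logical vector.
#' @export
panel_classify <- function(panel, data) {
  panel_score(panel, data) >= panel$min_positive
}

#' Evaluate a panel against observed outcomes
#'
#' Builds the panel's ROC curve from its integer rule-count score (operating
#' points at every decision cut 1..n_rules), computes the partial AUC over
#' the sensitivity band, the confusion counts and sensitivity/specificity at
#' the panel's own `min_positive` cut, and (optionally) stratified bootstrap
#' confidence intervals for all three statistics. Records with a missing
#' value in any panel marker are excluded listwise, and the exclusion count
#' is reported.
#'
#' @inheritParams panel_score
#' @param labels Binary outcome per row of `data` (`TRUE` = the event the
#'   panel detects).
#' @param band Sensitivity band for the partial AUC (default 0.90-1.00).
#' @param n_boot Bootstrap replicates for the confidence intervals; `0`
#'   skips interval estimation.
#' @param seed Seed for the bootstrap.
#' @return An object of class `panel_performance`: list with `pauc`,
#'   `sensitivity`, `specificity` (fractions), `counts` (tp, fp, tn, fn),
#'   `ci` (matrix or NULL), `n_excluded`, `band`, `panel`.
#' @export
evaluate_panel <- function(panel, data, labels, band = c(0.9, 1),
                           n_boot = 2000, seed = 1) {
  stopifnot(inherits(panel, "panel_definition"), is.data.frame(data))
  labels <- as_binary_labels(labels)
  stopifnot(nrow(data) == length(labels))
  markers <- panel_markers(panel)
  missing_cols <- setdiff(markers, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort lacks panel marker(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[markers]) & !is.na(labels)
  n_excluded <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("degenerate cohort: both outcome classes required after exclusions",
         call. = FALSE)
  }
  score <- panel_score(panel, data)
  curve <- build_roc(score, labels, "positive_if_greater")
  pauc <- pauc_sensitivity_band(curve, band)
  pred <- score >= panel$min_positive
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
  ci <- NULL
  if (n_boot > 0) {
    m <- panel$min_positive
    ci <- bootstrap_ci(score, labels, function(s, l) {
      cv <- build_roc(s, l, "positive_if_greater")
      p <- s >= m
      c(pauc = pauc_sensitivity_band(cv, band),
        sensitivity = sum(p & l) / sum(l),
        specificity = sum(!p & !l) / sum(!l))
    }, n_boot = n_boot, seed = seed)
  }
  structure(
    list(pauc = pauc,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
         ci = ci, n_excluded = n_excluded, band = band, panel = panel),
    class = "panel_performance"
  )
}

#' @export
print.panel_performance <- function(x, ...) {
  cat("Panel:", format(x$panel), "\n")
  cat(sprintf("pAUC(%.0f-%.0f%% sens) %.1f%%; sensitivity %.1f%%; specificity %.1f%%\n",
              100 * x$band[1], 100 * x$band[2], 100 * x$pauc,
              round_half_up(100 * x$sensitivity, 1),
              round_half_up(100 * x$specificity, 1)))
  cat(sprintf("counts: tp=%d fp=%d tn=%d fn=%d (excluded: %d)\n",
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"],
              x$n_excluded))
  invisible(x)
}

#' Candidate cutoffs for a marker
#'
#' Two strategies: `"midpoints"` places a cutoff halfway between every pair
#' of consecutive distinct observed values (the exhaustive grid — any
#' threshold between the same two data points classifies identically);
#' `"quantiles"` places `grid_size` cutoffs at equally spaced quantiles
#' (probabilities `1/(g+1), ..., g/(g+1)`), the coarser grid used for larger
#' cohorts. Both are deduplicated and returned sorted.
#'
#' @param values Numeric marker values (NAs dropped).
#' @param strategy `"midpoints"` or `"quantiles"`.
#' @param grid_size Number of quantile cuts (quantile strategy only).
#' @return Sorted numeric vector of cutoffs; empty (with a message) when all
#'   values are identical, in which case the marker is unusable.
#' @examples
#' candidate_thresholds(c(1, 2, 4), "midpoints")  # 1.5 3.0
#' @export
candidate_thresholds <- function(values,
                                 strategy = c("midpoints", "quantiles"),
                                 grid_size = 19) {
  strategy <- match.arg(strategy)
  values <- values[!is.na(values)]
  u <- sort(unique(values))
  if (length(u) < 2) {
    message("marker has no distinct values; no candidate thresholds")
    return(numeric(0))
  }
  if (strategy == "midpoints") {
    (u[-1] + u[-length(u)]) / 2
  } else {
    stopifnot(is.numeric(grid_size), grid_size >= 1)
    probs <- seq_len(grid_size) / (grid_size + 1)
    sort(unique(stats::quantile(values, probs = probs, names = FALSE, type = 7)))
  }
}

#' Serialize / deserialize a panel definition as JSON
#'
#' @param panel A [panel_definition()].
#' @param path Optional file path; if omitted, the JSON string is returned.
#' @return `panel_to_json`: the JSON string (invisibly when written to
#'   `path`); `panel_from_json`: a `panel_definition`.
#' @export
panel_to_json <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  obj <- list(
    rules = lapply(panel$rules, function(r)
      list(marker = r$marker, threshold = r$threshold, direction = r$direction)),
    min_positive = panel$min_positive
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @rdname panel_to_json
#' @param json JSON string or file path to read.
#' @export
panel_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r)
    marker_rule(r$marker, r$threshold, r$direction))
  panel_definition(rules, obj$min_positive)
}
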