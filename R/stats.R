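#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test with midrank tie handling. For combined
#' sample sizes up to 12 the null distribution of U is enumerated exactly
#' over all label assignments; beyond that a normal approximation with
#' tie-corrected variance and continuity correction is used. The returned U
#' is that of the first group (`U = R_a - n_a(n_a+1)/2`).
#'
#' @param group_a,group_b Non-empty numeric vectors (NAs dropped).
#' @return A list with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approximation"`), and the group sizes.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))  # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (N <= 12) {
    combos <- utils::combn(N, na)
    ranksums <- colSums(matrix(r[combos], nrow = na))
    uvals <- ranksums - na * (na + 1) / 2
    p_low <- mean(uvals <= u + 1e-9)
    p_high <- mean(uvals >= u - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate"
    } else {
      d <- u - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)  # continuity-corrected
      p <- min(1, 2 * min(stats::pnorm(z), 1 - stats::pnorm(z)))
      method <- "normal_approximation"
    }
  }
  list(U = u, p_value = p, method = method, n_a = na, n_b = nb)
}

.default_variable_spec <- function() {
  c(age = "normal", sex = "categorical", gcs = "ordinal", iss = "ordinal",
    hcts_sum = "ordinal",
    ab40 = "skewed", ab42 = "skewed", gfap = "skewed", hfabp = "skewed",
    il10 = "skewed", nfl = "skewed", s100b = "skewed", ttau = "skewed")
}

.fmt_num <- function(x) formatC(x, digits = 1, format = "f")

.summarize_variable <- function(v, type) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_character_)
  switch(type,
    normal = sprintf("%s ± %s", .fmt_num(mean(v)), .fmt_num(stats::sd(v))),
    ordinal = sprintf("%s [%g–%g]", .fmt_num(stats::median(v)),
                      min(v), max(v)),
    skewed = sprintf("%s (IQR %s)", .fmt_num(stats::median(v)),
                     .fmt_num(stats::IQR(v, type = 7))),
    categorical = {
      x <- if (is.logical(v)) v else v == sort(unique(v))[length(unique(v))]
      sprintf("%d (%d%%)", sum(x), round(100 * mean(x)))
    })
}

#' Group-comparison summary table for a cohort
#'
#' Per variable, emits the declared summary format for each group and the
#' declared test's two-sided p-value: Welch t-test for normally distributed
#' demographics, Mann-Whitney U for skewed or ordinal variables, and a
#' proportion test for categoricals. The variable-to-test mapping is
#' declared, not inferred from the data, so results are deterministic.
#' Records with missing values are excluded per variable and the missing
#' counts are reported.
#'
#' @param cohort Cohort data frame.
#' @param grouping Name of a binary grouping column (logical or 0/1), e.g.
#'   `"outcome_favorable"`.
#' @param variables Named character vector mapping variable names to one of
#'   `"normal"`, `"ordinal"`, `"skewed"`, `"categorical"`; defaults cover
#'   the standard cohort columns.
#' @return A data frame with columns `variable`, `group_a_summary`
#'   (grouping == TRUE), `group_b_summary`, `p_value`, `test`,
#'   `n_missing_a`, `n_missing_b`, `note`.
#' @export
summarize_cohort <- function(cohort, grouping,
                             variables = .default_variable_spec()) {
  stopifnot(is.data.frame(cohort), grouping %in% names(cohort))
  g <- as_binary_labels(cohort[[grouping]])
  if (anyNA(g)) stop("grouping column contains NA", call. = FALSE)
  variables <- variables[names(variables) %in% names(cohort)]
  rows <- lapply(names(variables), function(vn) {
    type <- variables[[vn]]
    va <- cohort[[vn]][g]
    vb <- cohort[[vn]][!g]
    if (is.character(va)) { va <- factor(va); vb <- factor(vb) }
    if (is.factor(va)) { va <- as.numeric(va); vb <- as.numeric(vb) }
    if (is.logical(va)) { va <- as.numeric(va); vb <- as.numeric(vb) }
    n_miss_a <- sum(is.na(va)); n_miss_b <- sum(is.na(vb))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    note <- ""
    if (length(va) == 0 || length(vb) == 0) {
      p <- NA_real_; test <- NA_character_; note <- "not comparable"
    } else if (stats::var(c(va, vb)) == 0) {
      p <- 1; note <- "degenerate"
      test <- switch(type, normal = "t_test", categorical = "proportion_test",
                     "mann_whitney")
    } else if (type == "normal") {
      p <- stats::t.test(va, vb)$p.value  # Welch
      test <- "t_test"
    } else if (type == "categorical") {
      tab <- rbind(c(sum(va == max(c(va, vb))), sum(va != max(c(va, vb)))),
                   c(sum(vb == max(c(va, vb))), sum(vb != max(c(va, vb)))))
      p <- suppressWarnings(stats::prop.test(tab)$p.value)
      test <- "proportion_test"
    } else {
      p <- mann_whitney_u(va, vb)$p_value
      test <- "mann_whitney"
    }
    data.frame(variable = vn,
               group_a_summary = .summarize_variable(cohort[[vn]][g], type),
               group_b_summary = .summarize_variable(cohort[[vn]][!g], type),
               p_value = p, test = test,
               n_missing_a = n_miss_a, n_missing_b = n_miss_b,
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
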