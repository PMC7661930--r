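#' Fit a lognormal distribution from a median and an IQR
#'
#' The two-parameter lognormal is identifiable from exactly the pair of
#' summaries clinical papers print for skewed biomarkers: the median and the
#' interquartile range. The log-location is `log(median)`; the log-scale is
#' the unique sigma >= 0 solving
#' `exp(mu + z*sigma) - exp(mu - z*sigma) = iqr` with `z = qnorm(0.75)`,
#' found by bracketed monotone root-finding to an IQR residual below 1e-9.
#' An IQR of zero yields a degenerate point mass at the median.
#'
#' @param median Median, > 0 (pg/ml for biomarkers).
#' @param iqr Interquartile range, >= 0.
#' @return Named numeric `c(meanlog, sdlog)` usable with [stats::rlnorm()].
#' @examples
#' p <- fit_lognormal_from_median_iqr(36.9, 57.6)
#' qlnorm(0.75, p["meanlog"], p["sdlog"]) - qlnorm(0.25, p["meanlog"], p["sdlog"])
#' @export
fit_lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(is.numeric(median), is.numeric(iqr), length(median) == 1,
            length(iqr) == 1)
  if (!is.finite(median) || median <= 0) stop("median must be > 0", call. = FALSE)
  if (!is.finite(iqr) || iqr < 0) stop("iqr must be >= 0", call. = FALSE)
  mu <- log(median)
  if (iqr == 0) return(c(meanlog = mu, sdlog = 0))
  z <- stats::qnorm(0.75)
  f <- function(s) exp(mu + z * s) - exp(mu - z * s) - iqr
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  sigma <- stats::uniroot(f, c(0, upper), tol = 1e-14)$root
  if (abs(f(sigma)) > 1e-9) {
    sigma <- stats::uniroot(f, c(0, upper), tol = .Machine$double.eps)$root
  }
  c(meanlog = mu, sdlog = sigma)
}

.marker_names <- c("ab40", "ab42", "gfap", "hfabp", "il10", "nfl", "s100b", "ttau")

.marker_row <- function(marker, stratum, median, iqr, provenance) {
  data.frame(marker = marker, stratum = stratum, median = median, iqr = iqr,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Default synthetic-cohort configuration
#'
#' Encodes the statistical structure the generator emulates: the cohort
#' split (82 CT-positive = 49 favorable + 33 unfavorable; 55 CT-negative =
#' 51 + 4), per-outcome-group CT-feature prevalences among CT-positive
#' patients, published per-group median/IQR pairs for NF-L and
#' beta-amyloid 1-42, and the below-detection substitution floor of 1 pg/ml
#' for S100B. Markers whose per-group summaries were never published carry
#' documented placeholder distributions flagged `provenance = "assumed"`;
#' they give the pipeline realistic skewed inputs but must not be used as
#' numeric reference values.
#'
#' @return An object of class `cohort_config` (a named list); see
#'   [generate_cohort()].
#' @export
default_config <- function() {
  md <- rbind(
    # CT-positive, by outcome -- NF-L and Abeta42 published; rest assumed
    .marker_row("nfl",  "ct_pos_favorable",   36.9,  57.6, "published"),
    .marker_row("nfl",  "ct_pos_unfavorable", 99.9, 120.0, "published"),
    .marker_row("ab42", "ct_pos_favorable",   16.9,  16.4, "published"),
    .marker_row("ab42", "ct_pos_unfavorable", 21.9,  40.6, "published"),
    .marker_row("ab40", "ct_pos_favorable",   18.0,  16.0, "assumed"),
    .marker_row("ab40", "ct_pos_unfavorable", 19.5,  22.0, "assumed"),
    .marker_row("gfap", "ct_pos_favorable",   60.0, 140.0, "assumed"),
    .marker_row("gfap", "ct_pos_unfavorable", 180.0, 420.0, "assumed"),
    .marker_row("hfabp", "ct_pos_favorable",   11.0,  14.0, "assumed"),
    .marker_row("hfabp", "ct_pos_unfavorable", 21.0,  32.0, "assumed"),
    .marker_row("il10", "ct_pos_favorable",    0.6,   1.1, "assumed"),
    .marker_row("il10", "ct_pos_unfavorable",  1.3,   2.6, "assumed"),
    .marker_row("s100b", "ct_pos_favorable",  85.0, 130.0, "assumed"),
    .marker_row("s100b", "ct_pos_unfavorable", 160.0, 310.0, "assumed"),
    .marker_row("ttau", "ct_pos_favorable",    3.2,   6.0, "assumed"),
    .marker_row("ttau", "ct_pos_unfavorable",  8.5,  16.0, "assumed"),
    # CT-negative, by outcome -- all assumed (milder injuries, lower levels)
    .marker_row("nfl",  "ct_neg_favorable",    8.0,  12.0, "assumed"),
    .marker_row("nfl",  "ct_neg_unfavorable", 22.0,  30.0, "assumed"),
    .marker_row("ab42", "ct_neg_favorable",   12.0,  12.0, "assumed"),
    .marker_row("ab42", "ct_neg_unfavorable", 14.0,  16.0, "assumed"),
    .marker_row("ab40", "ct_neg_favorable",   10.0,  10.0, "assumed"),
    .marker_row("ab40", "ct_neg_unfavorable", 18.0,  15.0, "assumed"),
    .marker_row("gfap", "ct_neg_favorable",    0.3,   0.5, "assumed"),
    .marker_row("gfap", "ct_neg_unfavorable",  0.8,   1.2, "assumed"),
    .marker_row("hfabp", "ct_neg_favorable",   4.0,   6.0, "assumed"),
    .marker_row("hfabp", "ct_neg_unfavorable", 8.0,  10.0, "assumed"),
    .marker_row("il10", "ct_neg_favorable",    0.3,   0.5, "assumed"),
    .marker_row("il10", "ct_neg_unfavorable",  0.6,   1.0, "assumed"),
    .marker_row("s100b", "ct_neg_favorable",  40.0,  60.0, "assumed"),
    .marker_row("s100b", "ct_neg_unfavorable", 80.0, 120.0, "assumed"),
    .marker_row("ttau", "ct_neg_favorable",    1.5,   2.5, "assumed"),
    .marker_row("ttau", "ct_neg_unfavorable",  3.0,   5.0, "assumed")
  )
  structure(list(
    n_ct_positive = 82L, n_ct_negative = 55L,
    n_favorable = 49L, n_unfavorable = 33L,            # within CT-positive
    n_neg_favorable = 51L, n_neg_unfavorable = 4L,     # within CT-negative
    p_complete_given_favorable = 10 / 49,              # GOSE 8 among CT+ favorable
    p_neg_complete_given_favorable = 23 / 51,
    marker_distributions = md,
    # per-outcome-group CT-feature prevalences among CT-positive patients
    ct_feature_prevalence = list(
      favorable = list(sdh = 27 / 49, ich = 27 / 49, edh = 7 / 49,
                       mass_gt25 = 10 / 49, ivh = 9 / 49,
                       cisterns = c(normal = 33 / 49, compressed = 13 / 49,
                                    obliterated = 3 / 49)),
      unfavorable = list(sdh = 26 / 33, ich = 26 / 33, edh = 4 / 33,
                         mass_gt25 = 16 / 33, ivh = 12 / 33,
                         cisterns = c(normal = 14 / 33, compressed = 18 / 33,
                                      obliterated = 1 / 33))
    ),
    below_lod_rule = list(marker = "s100b", floor = 1),
    covariates = list(
      age = list(ct_pos_favorable = c(mean = 44.69, sd = 19.55),
                 ct_pos_unfavorable = c(mean = 59.03, sd = 18.67),
                 ct_neg = c(mean = 43.67, sd = 18.21)),
      p_male = list(ct_pos_favorable = 37 / 49, ct_pos_unfavorable = 27 / 33,
                    ct_neg = 34 / 55),
      gcs_median = list(ct_pos_favorable = 14, ct_pos_unfavorable = 9,
                        ct_neg = 15),
      iss = list(ct_pos_favorable = c(mean = 17, sd = 9),
                 ct_pos_unfavorable = c(mean = 24, sd = 10),
                 ct_neg = c(mean = 8, sd = 8)),
      delay_h = c(mean = 13.1, sd = 10.4)
    ),
    seed = 1L
  ), class = "cohort_config")
}

.validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config") || is.list(config))
  with(config, {
    if (n_favorable + n_unfavorable != n_ct_positive) {
      stop("CT-positive outcome group sizes must sum to n_ct_positive",
           call. = FALSE)
    }
    if (n_neg_favorable + n_neg_unfavorable != n_ct_negative) {
      stop("CT-negative outcome group sizes must sum to n_ct_negative",
           call. = FALSE)
    }
  })
  for (grp in config$ct_feature_prevalence) {
    pr <- unlist(grp)
    if (any(pr < 0 | pr > 1)) stop("prevalences must be in [0, 1]", call. = FALSE)
    if (abs(sum(grp$cisterns) - 1) > 1e-9) {
      stop("cistern category probabilities must sum to 1", call. = FALSE)
    }
  }
  md <- config$marker_distributions
  if (any(md$median <= 0) || any(md$iqr < 0)) {
    stop("marker medians must be > 0 and IQRs >= 0", call. = FALSE)
  }
  invisible(config)
}

.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

.draw_markers <- function(md, stratum, n) {
  rows <- md[md$stratum == stratum, , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    p <- fit_lognormal_from_median_iqr(rows$median[i], rows$iqr[i])
    stats::rlnorm(n, p["meanlog"], p["sdlog"])
  })
  names(out) <- rows$marker
  as.data.frame(out)[.marker_names]
}

.draw_findings <- function(prev, n) {
  data.frame(
    sdh = stats::runif(n) < prev$sdh,
    edh = stats::runif(n) < prev$edh,
    ich = stats::runif(n) < prev$ich,
    mass_gt25 = stats::runif(n) < prev$mass_gt25,
    ivh = stats::runif(n) < prev$ivh,
    cisterns = sample(names(prev$cisterns), n, replace = TRUE,
                      prob = prev$cisterns),
    stringsAsFactors = FALSE
  )
}

.draw_gose <- function(n, favorable, p_complete) {
  if (favorable) {
    ifelse(stats::runif(n) < p_complete, 8L, sample(5:7, n, replace = TRUE))
  } else {
    sample(1:4, n, replace = TRUE)
  }
}

.draw_stratum <- function(config, n, ct_positive, favorable, stratum_key) {
  cov <- config$covariates
  age_par <- cov$age[[if (ct_positive) stratum_key else "ct_neg"]]
  pm <- cov$p_male[[if (ct_positive) stratum_key else "ct_neg"]]
  gcs_med <- cov$gcs_median[[if (ct_positive) stratum_key else "ct_neg"]]
  iss_par <- cov$iss[[if (ct_positive) stratum_key else "ct_neg"]]
  mk_stratum <- if (ct_positive) stratum_key else
    if (favorable) "ct_neg_favorable" else "ct_neg_unfavorable"

  gose <- .draw_gose(n, favorable,
                     if (ct_positive) config$p_complete_given_favorable
                     else config$p_neg_complete_given_favorable)
  markers <- .draw_markers(config$marker_distributions, mk_stratum, n)
  if (ct_positive) {
    prev <- config$ct_feature_prevalence[[if (favorable) "favorable" else "unfavorable"]]
    f <- .draw_findings(prev, n)
    hcts <- suppressWarnings(score_hcts(f))
  } else {
    f <- hcts_findings(sdh = rep(FALSE, n))
    hcts <- integer(n)
  }
  data.frame(
    ct_positive = rep(ct_positive, n),
    gose = gose,
    outcome_favorable = gose >= 5,
    outcome_complete = gose == 8,
    markers,
    f,
    hcts_sum = hcts,
    age = round(.rtrunc_norm(n, age_par["mean"], age_par["sd"], 18, 95), 1),
    sex = ifelse(stats::runif(n) < pm, "male", "female"),
    gcs = pmin(15L, pmax(3L, as.integer(round(.rtrunc_norm(n, gcs_med, 3, 3, 15))))),
    iss = pmin(75L, pmax(1L, as.integer(round(.rtrunc_norm(n, iss_par["mean"], iss_par["sd"], 1, 75))))),
    delay_h = round(.rtrunc_norm(n, cov$delay_h["mean"], cov$delay_h["sd"], 0, Inf), 1),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic TBI cohort
#'
#' Draws a patient-level cohort table reproducing the configured group
#' structure: CT-positive and CT-negative strata split into favorable
#' (GOSE 5-8) and unfavorable (GOSE 1-4) outcomes, lognormal biomarker
#' levels per group, CT findings sampled independently per feature at the
#' configured per-group prevalences (CT-negative patients have all-negative
#' findings and a CT score of 0), a below-detection floor applied per the
#' substitution rule, and demographic covariates for interface completeness.
#' Deterministic under the seed; the caller's RNG state is preserved.
#'
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Data frame with one row per patient and columns `id`,
#'   `ct_positive`, `gose`, `outcome_favorable`, `outcome_complete`, the
#'   eight biomarkers (`ab40`, `ab42`, `gfap`, `hfabp`, `il10`, `nfl`,
#'   `s100b`, `ttau`, pg/ml), the CT findings (`sdh`, `edh`, `ich`,
#'   `mass_gt25`, `ivh`, `cisterns`), `hcts_sum`, and covariates (`age`,
#'   `sex`, `gcs`, `iss`, `delay_h`).
#' @examples
#' cohort <- generate_cohort(default_config(), seed = 7)
#' nrow(cohort)  # 137
#' @export
generate_cohort <- function(config = default_config(), seed = config$seed) {
  .validate_config(config)
  cohort <- with_preserved_seed(seed, function() {
    rbind(
      .draw_stratum(config, config$n_favorable, TRUE, TRUE, "ct_pos_favorable"),
      .draw_stratum(config, config$n_unfavorable, TRUE, FALSE, "ct_pos_unfavorable"),
      .draw_stratum(config, config$n_neg_favorable, FALSE, TRUE, "ct_neg"),
      .draw_stratum(config, config$n_neg_unfavorable, FALSE, FALSE, "ct_neg")
    )
  })
  lod <- config$below_lod_rule
  if (!is.null(lod)) {
    v <- cohort[[lod$marker]]
    cohort[[lod$marker]] <- ifelse(v < lod$floor, lod$floor, v)
  }
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  rownames(cohort) <- NULL
  cohort
}

.cohort_columns <- c("id", "ct_positive", "gose", "outcome_favorable",
                     "outcome_complete", .marker_names,
                     "sdh", "edh", "ich", "mass_gt25", "ivh", "cisterns",
                     "hcts_sum", "age", "sex", "gcs", "iss", "delay_h")

#' Read / write a cohort CSV
#'
#' Plain-CSV serialization of the cohort table with schema validation on
#' read (all marker, findings and outcome columns must be present).
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort`: the validated data frame; `write_cohort`: the
#'   path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- setdiff(.cohort_columns, c("id", "hcts_sum"))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("ct_positive", "outcome_favorable", "outcome_complete",
              "sdh", "edh", "ich", "mass_gt25", "ivh")) {
    cohort[[f]] <- as.logical(cohort[[f]])
  }
  cohort
}
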