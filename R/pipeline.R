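# Report-level orchestration: single-marker tables, baseline-vs-panel
# tables, and the full report directory. Dichotomy definitions are fixed in
# one place: favorable = GOSE 5-8, complete recovery = GOSE 8; the "event"
# the classifiers detect is always the adverse side (unfavorable outcome,
# incomplete recovery).

.dichotomies <- c("favorable_vs_unfavorable", "complete_vs_incomplete")

adverse_labels <- function(cohort, dichotomy = .dichotomies) {
  dichotomy <- match.arg(dichotomy)
  if (dichotomy == "favorable_vs_unfavorable") {
    !as_binary_labels(cohort$outcome_favorable)
  } else {
    !as_binary_labels(cohort$outcome_complete)
  }
}

.fmt_pct <- function(x) .fmt_num(round_half_up(100 * x, 1))

.fmt_ci <- function(lo, hi) sprintf("(%s–%s)", .fmt_pct(lo), .fmt_pct(hi))

#' Single-marker prognostic performance table
#'
#' For each marker (the eight plasma biomarkers plus the CT score by
#' default): picks the positivity direction with the larger partial AUC over
#' the sensitivity band, finds the operating point maximizing specificity at
#' sensitivity >= `min_sens`, and attaches stratified-bootstrap confidence
#' intervals for pAUC, specificity and sensitivity. Rows are sorted by pAUC
#' descending. A marker that cannot attain the sensitivity constraint except
#' at specificity 0 is reported at the trivial (sensitivity 100%,
#' specificity 0%) endpoint with threshold `NA` (printed "–").
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for the schema).
#' @param dichotomy `"favorable_vs_unfavorable"` (event = unfavorable,
#'   GOSE 1-4) or `"complete_vs_incomplete"` (event = incomplete, GOSE < 8).
#' @param markers Marker columns to evaluate.
#' @param min_sens Sensitivity constraint (default 0.90).
#' @param band Partial-AUC sensitivity band.
#' @param n_boot Bootstrap replicates (0 skips intervals).
#' @param seed Bootstrap seed.
#' @param directions Optional named character vector fixing the positivity
#'   direction for specific markers (e.g. `c(hcts_sum =
#'   "positive_if_greater")`); unnamed markers get the direction with the
#'   larger partial AUC.
#' @return Data frame of class `single_marker_table` with numeric columns
#'   (`pauc`, `specificity`, `sensitivity` as fractions plus `_low`/`_high`
#'   bounds) and the chosen `threshold` and `direction`.
#' @export
run_single_marker_analysis <- function(cohort,
                                       dichotomy = .dichotomies,
                                       markers = c("hcts_sum", .marker_names),
                                       min_sens = 0.9, band = c(0.9, 1),
                                       n_boot = 2000, seed = 1,
                                       directions = NULL) {
  dichotomy <- match.arg(dichotomy)
  missing_cols <- setdiff(markers, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks marker column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  labels <- adverse_labels(cohort, dichotomy)
  rows <- lapply(markers, function(mk) {
    v <- cohort[[mk]]
    keep <- !is.na(v) & !is.na(labels)
    v <- v[keep]; l <- labels[keep]
    if (length(unique(v)) < 2) {
      # constant marker: only the trivial endpoints exist
      return(data.frame(marker = mk, direction = "positive_if_greater",
                        threshold = NA_real_, pauc = 0,
                        pauc_low = NA_real_, pauc_high = NA_real_,
                        specificity = 0, spec_low = NA_real_, spec_high = NA_real_,
                        sensitivity = 1, sens_low = NA_real_, sens_high = NA_real_,
                        n_missing = sum(!keep), stringsAsFactors = FALSE))
    }
    fixed <- if (!is.null(directions) && mk %in% names(directions) &&
                 directions[[mk]] != "both") directions[[mk]] else NULL
    if (is.null(fixed)) {
      curves <- list(greater = build_roc(v, l, "positive_if_greater"),
                     lesser = build_roc(v, l, "positive_if_less"))
      paucs <- vapply(curves, pauc_sensitivity_band, 0, band = band)
      direction <- if (paucs["lesser"] > paucs["greater"] + 1e-12)
        "positive_if_less" else "positive_if_greater"
      curve <- if (direction == "positive_if_greater") curves$greater else curves$lesser
    } else {
      direction <- fixed
      curve <- build_roc(v, l, direction)
    }
    op <- operating_point_at_sensitivity(curve, min_sens)
    thr <- if (op["specificity"] <= 0) NA_real_ else unname(op["threshold"])
    ci <- NULL
    if (n_boot > 0) {
      ci <- bootstrap_ci(v, l, function(s, lab) {
        cv <- build_roc(s, lab, direction)
        o <- operating_point_at_sensitivity(cv, min_sens)
        c(pauc = pauc_sensitivity_band(cv, band),
          specificity = unname(o["specificity"]),
          sensitivity = unname(o["sensitivity"]))
      }, n_boot = n_boot, seed = seed)
    }
    data.frame(
      marker = mk, direction = direction, threshold = thr,
      pauc = pauc_sensitivity_band(curve, band),
      pauc_low = if (is.null(ci)) NA_real_ else ci["pauc", "low"],
      pauc_high = if (is.null(ci)) NA_real_ else ci["pauc", "high"],
      specificity = unname(op["specificity"]),
      spec_low = if (is.null(ci)) NA_real_ else ci["specificity", "low"],
      spec_high = if (is.null(ci)) NA_real_ else ci["specificity", "high"],
      sensitivity = unname(op["sensitivity"]),
      sens_low = if (is.null(ci)) NA_real_ else ci["sensitivity", "low"],
      sens_high = if (is.null(ci)) NA_real_ else ci["sensitivity", "high"],
      n_missing = sum(!keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pauc, out$marker), ]
  rownames(out) <- NULL
  attr(out, "dichotomy") <- dichotomy
  attr(out, "min_sens") <- min_sens
  class(out) <- c("single_marker_table", "data.frame")
  out
}

#' Format a performance table for reporting
#'
#' Renders the numeric columns of a [run_single_marker_analysis()] or
#' [run_panel_analysis()] table in the conventional printed style: percent,
#' one decimal, half-up rounding, confidence intervals in parentheses, and
#' "–" for an unattainable threshold. Rounding happens only here.
#'
#' @param table A `single_marker_table` or `panel_table`.
#' @return Data frame of formatted strings.
#' @export
format_marker_table <- function(table) {
  lab <- if ("marker" %in% names(table)) table$marker else table$model
  data.frame(
    marker = lab,
    threshold = ifelse(is.na(table$threshold), "–",
                       formatC(table$threshold, digits = 4, format = "g")),
    pauc_pct = ifelse(is.na(table$pauc_low), .fmt_pct(table$pauc),
                      paste(.fmt_pct(table$pauc),
                            .fmt_ci(table$pauc_low, table$pauc_high))),
    specificity_pct = ifelse(is.na(table$spec_low), .fmt_pct(table$specificity),
                             paste(.fmt_pct(table$specificity),
                                   .fmt_ci(table$spec_low, table$spec_high))),
    sensitivity_pct = ifelse(is.na(table$sens_low), .fmt_pct(table$sensitivity),
                             paste(.fmt_pct(table$sensitivity),
                                   .fmt_ci(table$sens_low, table$sens_high))),
    stringsAsFactors = FALSE
  )
}

#' Baseline-vs-panel comparison table
#'
#' Evaluates the baseline marker alone at its constrained operating point,
#' then one optimized panel per entry of `max_sizes` (conventionally first
#' two, then three covariates). When the baseline cannot operate at the
#' sensitivity constraint except at specificity 0, it has no clinically
#' meaningful performance in this dichotomy and panel construction is
#' skipped (the reason is attached as the `"skip_reason"` attribute).
#'
#' @inheritParams run_single_marker_analysis
#' @param baseline_marker Column evaluated alone as the reference row.
#' @param candidate_markers Pool for the panel search (baseline included).
#' @param max_sizes Panel sizes to optimize, e.g. `c(2, 3)`.
#' @param strategy,grid_size Candidate-threshold grid.
#' @param directions Per-marker direction restriction passed to
#'   [optimize_panel()]; by default the CT score only enters with
#'   `positive_if_greater`.
#' @return Data frame of class `panel_table`: one baseline row plus one row
#'   per optimized panel, with a `model` label, rule `description`,
#'   performance columns as in [run_single_marker_analysis()], and a
#'   `constraint_met` flag. Panels are also attached as the `"panels"`
#'   attribute (a list of [panel_definition()]s).
#' @export
run_panel_analysis <- function(cohort,
                               dichotomy = .dichotomies,
                               baseline_marker = "hcts_sum",
                               candidate_markers = c("hcts_sum", .marker_names),
                               max_sizes = c(2, 3), min_sens = 0.9,
                               band = c(0.9, 1),
                               strategy = c("quantiles", "midpoints"),
                               grid_size = 19,
                               directions = c(hcts_sum = "positive_if_greater"),
                               n_boot = 2000, seed = 1) {
  dichotomy <- match.arg(dichotomy)
  strategy <- match.arg(strategy)
  stopifnot(baseline_marker %in% names(cohort))
  labels <- adverse_labels(cohort, dichotomy)

  base_tab <- run_single_marker_analysis(cohort, dichotomy,
                                         markers = baseline_marker,
                                         min_sens = min_sens, band = band,
                                         n_boot = n_boot, seed = seed,
                                         directions = directions)
  rows <- data.frame(
    model = "baseline",
    description = sprintf("%s (>%s)", baseline_marker,
                          formatC(base_tab$threshold, format = "g")),
    threshold = base_tab$threshold,
    pauc = base_tab$pauc, pauc_low = base_tab$pauc_low,
    pauc_high = base_tab$pauc_high,
    specificity = base_tab$specificity, spec_low = base_tab$spec_low,
    spec_high = base_tab$spec_high,
    sensitivity = base_tab$sensitivity, sens_low = base_tab$sens_low,
    sens_high = base_tab$sens_high,
    constraint_met = base_tab$sensitivity >= min_sens - 1e-12 &
      base_tab$specificity > 0,
    stringsAsFactors = FALSE
  )
  panels <- list()
  skip_reason <- NULL
  if (base_tab$specificity <= 0) {
    skip_reason <- paste0("baseline marker '", baseline_marker,
                          "' has no clinically meaningful operating point at sensitivity >= ",
                          min_sens, "; panel construction skipped")
    message(skip_reason)
  } else {
    for (sz in max_sizes) {
      fit <- optimize_panel(cohort, candidate_markers, labels, max_size = sz,
                            min_sens = min_sens, strategy = strategy,
                            grid_size = grid_size, directions = directions,
                            band = band)
      perf <- evaluate_panel(fit$panel, cohort, labels, band = band,
                             n_boot = n_boot, seed = seed)
      ci <- perf$ci
      rows <- rbind(rows, data.frame(
        model = sprintf("panel_max%d", sz),
        description = format(fit$panel),
        threshold = NA_real_,
        pauc = perf$pauc,
        pauc_low = if (is.null(ci)) NA_real_ else ci["pauc", "low"],
        pauc_high = if (is.null(ci)) NA_real_ else ci["pauc", "high"],
        specificity = perf$specificity,
        spec_low = if (is.null(ci)) NA_real_ else ci["specificity", "low"],
        spec_high = if (is.null(ci)) NA_real_ else ci["specificity", "high"],
        sensitivity = perf$sensitivity,
        sens_low = if (is.null(ci)) NA_real_ else ci["sensitivity", "low"],
        sens_high = if (is.null(ci)) NA_real_ else ci["sensitivity", "high"],
        constraint_met = fit$constraint_met,
        stringsAsFactors = FALSE
      ))
      panels[[sprintf("panel_max%d", sz)]] <- fit$panel
    }
  }
  rownames(rows) <- NULL
  attr(rows, "dichotomy") <- dichotomy
  attr(rows, "panels") <- panels
  attr(rows, "skip_reason") <- skip_reason
  class(rows) <- c("panel_table", "data.frame")
  rows
}

.config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis report
#'
#' End-to-end orchestration on a cohort table: cohort summary of the
#' CT-positive stratum by outcome, single-marker tables for both
#' dichotomies in CT-positive patients and both dichotomies in CT-negative
#' patients, and baseline-vs-panel tables (CT score baseline, panel sizes 2
#' and 3) for the favorable/unfavorable dichotomy. Writes CSV tables, panel
#' JSON files, a metadata block (seed, config hash, package version,
#' rounding policy) and a plain-text log into `out_dir`. Deterministic:
#' identical inputs and seed give byte-identical outputs.
#'
#' @param cohort Cohort data frame.
#' @param out_dir Output directory (created if needed).
#' @param min_sens Sensitivity constraint.
#' @param n_boot Bootstrap replicates for confidence intervals.
#' @param seed Seed for all resampling.
#' @return Invisibly, a list with all computed tables.
#' @export
run_report <- function(cohort, out_dir, min_sens = 0.9, n_boot = 2000,
                       seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  ctp <- cohort[cohort$ct_positive, , drop = FALSE]
  ctn <- cohort[!cohort$ct_positive, , drop = FALSE]
  note("cohort: %d patients (%d CT-positive, %d CT-negative)",
       nrow(cohort), nrow(ctp), nrow(ctn))

  summary_tab <- summarize_cohort(ctp, "outcome_favorable")
  utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  tables <- list(cohort_summary = summary_tab)
  single_specs <- list(
    table3_like = list(data = ctp, dichotomy = "favorable_vs_unfavorable",
                       markers = c("hcts_sum", .marker_names)),
    table4_like = list(data = ctp, dichotomy = "complete_vs_incomplete",
                       markers = c("hcts_sum", .marker_names)),
    table6_like = list(data = ctn, dichotomy = "favorable_vs_unfavorable",
                       markers = .marker_names),
    table7_like = list(data = ctn, dichotomy = "complete_vs_incomplete",
                       markers = .marker_names)
  )
  for (nm in names(single_specs)) {
    sp <- single_specs[[nm]]
    tab <- run_single_marker_analysis(sp$data, sp$dichotomy, sp$markers,
                                      min_sens = min_sens, n_boot = n_boot,
                                      seed = seed)
    utils::write.csv(format_marker_table(tab), file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
    tables[[nm]] <- tab
    note("%s: %s, top marker %s (pAUC %s%%)", nm, sp$dichotomy,
         tab$marker[1], .fmt_pct(tab$pauc[1]))
  }

  panel_tab <- run_panel_analysis(ctp, "favorable_vs_unfavorable",
                                  min_sens = min_sens, n_boot = n_boot,
                                  seed = seed)
  tables$panel_favorable <- panel_tab
  keep2 <- panel_tab$model %in% c("baseline", "panel_max2")
  utils::write.csv(format_marker_table(panel_tab[keep2, ]) |>
                     cbind(description = panel_tab$description[keep2]),
                   file.path(out_dir, "table5a_like.csv"), row.names = FALSE)
  keep3 <- panel_tab$model %in% c("baseline", "panel_max3")
  utils::write.csv(format_marker_table(panel_tab[keep3, ]) |>
                     cbind(description = panel_tab$description[keep3]),
                   file.path(out_dir, "table5b_like.csv"), row.names = FALSE)
  for (nm in names(attr(panel_tab, "panels"))) {
    panel_to_json(attr(panel_tab, "panels")[[nm]],
                  file.path(out_dir, paste0(nm, ".json")))
  }
  # The complete/incomplete dichotomy gets a panel analysis only when the
  # baseline operates meaningfully there; otherwise the reason is logged.
  panel_ci <- run_panel_analysis(ctp, "complete_vs_incomplete",
                                 min_sens = min_sens, n_boot = n_boot,
                                 seed = seed)
  tables$panel_complete <- panel_ci
  if (!is.null(attr(panel_ci, "skip_reason"))) {
    note("%s", attr(panel_ci, "skip_reason"))
  }

  meta <- list(seed = seed, min_sens = min_sens, n_boot = n_boot,
               n_patients = nrow(cohort),
               config_hash = .config_hash(cohort),
               package_version = as.character(utils::packageVersion("tbipanel")),
               rounding = "half-up, one decimal, percent, reporting layer only")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(out_dir, "metadata.json"))
  writeLines(log_lines, file.path(out_dir, "report.log"))
  invisible(tables)
}
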