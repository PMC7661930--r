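# Exhaustive panel search.
#
# The search space is: marker subsets of size 1..max_size, per-marker
# candidate thresholds, both positivity directions, and every
# min-positive-count decision cut. Counting patients that satisfy >= m rules
# reduces, by inclusion-exclusion, to single / pairwise / triple rule
# intersection counts, which are computed for *all* threshold combinations
# at once with cross-products of 0/1 rule-indicator matrices. That keeps the
# full exhaustive search (about 10^6 candidate panels for 9 markers on a
# 19-point grid) to a few seconds.

# Per-subset counts of patients satisfying >= m rules, for every threshold
# combination. Plist: 0/1 indicator matrices (rows = patients of one class),
# csums: their column sums. Returns a list ge[[m]] of arrays with one cell
# per threshold combination.
.ge_counts <- function(Plist, csums) {
  size <- length(Plist)
  if (size == 1) return(list(csums[[1]]))
  if (size == 2) {
    n11 <- crossprod(Plist[[1]], Plist[[2]])
    ge1 <- outer(csums[[1]], csums[[2]], "+") - n11
    return(list(ge1, n11))
  }
  k <- vapply(Plist, ncol, 0L)
  AB <- crossprod(Plist[[1]], Plist[[2]])
  AC <- crossprod(Plist[[1]], Plist[[3]])
  BC <- crossprod(Plist[[2]], Plist[[3]])
  Tarr <- array(0, dim = k)
  for (i in seq_len(k[1])) {
    Tarr[i, , ] <- crossprod(Plist[[2]] * Plist[[1]][, i], Plist[[3]])
  }
  aA <- array(csums[[1]], dim = k)
  aB <- array(rep(csums[[2]], each = k[1]), dim = k)
  aC <- array(rep(csums[[3]], each = k[1] * k[2]), dim = k)
  aAB <- array(AB, dim = k)
  aAC <- aperm(array(AC, dim = c(k[1], k[3], k[2])), c(1, 3, 2))
  aBC <- aperm(array(BC, dim = c(k[2], k[3], k[1])), c(3, 1, 2))
  list(aA + aB + aC - aAB - aAC - aBC + Tarr,   # >= 1 of 3
       aAB + aAC + aBC - 2 * Tarr,              # >= 2 of 3
       Tarr)                                    # all 3
}

# Partial AUC of the panel's rule-count ROC for selected threshold
# combinations (vectorized). The panel ROC has operating points at each cut
# m = 1..size plus the trivial endpoints.
.panel_pauc_at <- function(sens_list, spec_list, idx, band) {
  size <- length(sens_list)
  n <- length(idx)
  S <- matrix(0, n, size)
  P <- matrix(0, n, size)
  for (m in seq_len(size)) {
    S[, m] <- sens_list[[m]][idx]
    P[, m] <- spec_list[[m]][idx]
  }
  # path in ascending sensitivity: (0,1), cut size, ..., cut 1, (1,0)
  sp <- cbind(0, S[, size:1, drop = FALSE], 1)
  pp <- cbind(1, P[, size:1, drop = FALSE], 0)
  area <- numeric(n)
  for (j in seq_len(ncol(sp) - 1)) {
    area <- area + band_segment_area(sp[, j], sp[, j + 1], pp[, j], pp[, j + 1],
                                     band[1], band[2])
  }
  area
}

#' Optimize a threshold panel under a sensitivity constraint
#'
#' Exhaustive search over marker subsets (size up to `max_size`), per-marker
#' candidate thresholds (see [candidate_thresholds()]), both positivity
#' directions, and every minimum-positive-count decision cut. Among
#' candidates attaining sensitivity at least `min_sens`, the panel maximizing
#' specificity is returned; ties are broken by higher partial AUC, then
#' smaller panel, then a deterministic lexicographic order over (marker
#' names, thresholds, decision cut). The search is fully deterministic given
#' the grid; `seed` is accepted for interface stability but unused by the
#' exhaustive engine.
#'
#' If no candidate attains `min_sens`, the sensitivity-maximizing panel is
#' returned with `constraint_met = FALSE`.
#'
#' Records with a missing value in any candidate marker are excluded
#' listwise across the whole pool (so that every candidate panel is scored
#' on the same patients), and the exclusion count is reported.
#'
#' @param data Cohort data frame.
#' @param markers Character vector of candidate marker columns (at most 8-10
#'   for an exhaustive size-3 search).
#' @param labels Binary outcome per row (`TRUE` = event to detect).
#' @param max_size Maximum rules per panel, 1-3.
#' @param min_sens Sensitivity constraint (default 0.90).
#' @param strategy,grid_size Candidate-threshold grid, see
#'   [candidate_thresholds()].
#' @param directions Optional named character vector restricting the search
#'   direction per marker (`"positive_if_greater"`, `"positive_if_less"` or
#'   `"both"`); unnamed markers search both directions. An integer severity
#'   score such as the Helsinki CT score is conventionally restricted to
#'   `"positive_if_greater"`.
#' @param band Sensitivity band for the tie-breaking partial AUC.
#' @param seed Unused by the exhaustive engine; reserved.
#' @return An object of class `panel_fit`: list with `panel`
#'   ([panel_definition()]), `performance` ([evaluate_panel()] without
#'   bootstrap), `constraint_met`, `n_excluded`, and `search` metadata.
#' @examples
#' set.seed(1)
#' d <- data.frame(a = c(rnorm(10, 2), rnorm(10)), b = rnorm(20))
#' optimize_panel(d, c("a", "b"), rep(c(TRUE, FALSE), each = 10),
#'                max_size = 2, strategy = "midpoints")
#' @export
optimize_panel <- function(data, markers, labels, max_size = 3,
                           min_sens = 0.9,
                           strategy = c("quantiles", "midpoints"),
                           grid_size = 19, directions = NULL,
                           band = c(0.9, 1), seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(data), is.character(markers), length(markers) >= 1)
  if (!max_size %in% 1:3) stop("max_size must be 1, 2 or 3", call. = FALSE)
  missing_cols <- setdiff(markers, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort lacks candidate marker(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  labels <- as_binary_labels(labels)
  stopifnot(nrow(data) == length(labels))
  pool <- sort(unique(markers))

  keep <- stats::complete.cases(data[pool]) & !is.na(labels)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " record(s) excluded for missing candidate-marker values")
  }
  data_c <- data[keep, , drop = FALSE]
  labels_c <- labels[keep]
  n_pos <- sum(labels_c)
  n_neg <- sum(!labels_c)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate cohort: both outcome classes required", call. = FALSE)
  }

  dir_for <- function(m) {
    d <- if (!is.null(directions) && m %in% names(directions))
      directions[[m]] else "both"
    if (d == "both") c("positive_if_greater", "positive_if_less") else d
  }

  # Per-marker rule tables and indicator matrices, in canonical order
  # (threshold ascending; at equal threshold, greater before less).
  rules <- list(); Ppos <- list(); Pneg <- list()
  for (m in pool) {
    thr <- candidate_thresholds(data_c[[m]], strategy, grid_size)
    if (length(thr) == 0) next
    dirs <- dir_for(m)
    tab <- expand.grid(direction = dirs, threshold = thr,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[order(tab$threshold, match(tab$direction,
                                          c("positive_if_greater",
                                            "positive_if_less"))),
               c("threshold", "direction")]
    v <- data_c[[m]]
    P <- matrix(FALSE, length(v), nrow(tab))
    gt <- tab$direction == "positive_if_greater"
    if (any(gt))  P[, gt]  <- outer(v, tab$threshold[gt], ">")
    if (any(!gt)) P[, !gt] <- outer(v, tab$threshold[!gt], "<")
    rules[[m]] <- tab
    Ppos[[m]] <- P[labels_c, , drop = FALSE] * 1
    Pneg[[m]] <- P[!labels_c, , drop = FALSE] * 1
  }
  usable <- names(rules)
  if (length(usable) == 0) {
    stop("no candidate marker has distinct values; nothing to search",
         call. = FALSE)
  }

  eps <- 1e-9
  best <- NULL      # feasible optimum
  fallback <- NULL  # sensitivity-maximizing candidate (constraint unmet case)
  n_candidates <- 0

  consider <- function(subset, k, combo_idx, m, sens, spec, pauc) {
    i <- combo_idx - 1
    row_idx <- integer(length(k))
    for (d in seq_along(k)) {
      row_idx[d] <- (i %% k[d]) + 1
      i <- i %/% k[d]
    }
    rl <- lapply(seq_along(subset), function(d) {
      tab <- rules[[subset[d]]]
      marker_rule(subset[d], tab$threshold[row_idx[d]], tab$direction[row_idx[d]])
    })
    list(panel = panel_definition(rl, m), sens = sens, spec = spec, pauc = pauc)
  }

  for (size in seq_len(max_size)) {
    if (length(usable) < size) break
    subsets <- utils::combn(usable, size, simplify = FALSE)
    for (subset in subsets) {
      k <- vapply(subset, function(m) nrow(rules[[m]]), 0L)
      K <- prod(k)
      if (K * size > 5e7) {
        stop("candidate grid too large for exhaustive search; reduce grid_size",
             call. = FALSE)
      }
      gpos <- .ge_counts(Ppos[subset], lapply(Ppos[subset], colSums))
      gneg <- .ge_counts(Pneg[subset], lapply(Pneg[subset], colSums))
      sens_list <- lapply(gpos, function(g) as.vector(g) / n_pos)
      spec_list <- lapply(gneg, function(g) 1 - as.vector(g) / n_neg)
      sensv <- unlist(sens_list, use.names = FALSE)
      specv <- unlist(spec_list, use.names = FALSE)
      m_of <- rep(seq_len(size), each = K)
      combo <- rep.int(seq_len(K), size)
      n_candidates <- n_candidates + length(sensv)

      feas <- sensv >= min_sens - eps
      if (any(feas)) {
        smax <- max(specv[feas])
        if (is.null(best) || smax > best$spec + eps ||
            (smax > best$spec - eps)) {
          tied <- which(feas & specv >= smax - eps)
          ucombo <- unique(combo[tied])
          pa_u <- .panel_pauc_at(sens_list, spec_list, ucombo, band)
          pa <- pa_u[match(combo[tied], ucombo)]
          pmax <- max(pa)
          if (is.null(best) || smax > best$spec + eps || pmax > best$pauc + eps) {
            tied2 <- tied[pa >= pmax - eps]
            o <- order(combo[tied2], m_of[tied2])
            pick <- tied2[o[1]]
            best <- consider(subset, k, combo[pick], m_of[pick],
                             sensv[pick], specv[pick], pmax)
          }
        }
      }
      # fallback bookkeeping (max sensitivity, then specificity)
      smax_s <- max(sensv)
      if (is.null(fallback) || smax_s > fallback$sens + eps ||
          (smax_s > fallback$sens - eps)) {
        cand_i <- which(sensv >= smax_s - eps)
        sp_best <- max(specv[cand_i])
        if (is.null(fallback) || smax_s > fallback$sens + eps ||
            sp_best > fallback$spec + eps) {
          cand_i <- cand_i[specv[cand_i] >= sp_best - eps]
          o <- order(combo[cand_i], m_of[cand_i])
          pick <- cand_i[o[1]]
          pa <- .panel_pauc_at(sens_list, spec_list, combo[pick], band)
          fallback <- consider(subset, k, combo[pick], m_of[pick],
                               sensv[pick], specv[pick], pa)
        }
      }
    }
  }

  constraint_met <- !is.null(best)
  chosen <- if (constraint_met) best else fallback
  perf <- evaluate_panel(chosen$panel, data_c, labels_c, band = band, n_boot = 0)
  structure(
    list(panel = chosen$panel, performance = perf,
         constraint_met = constraint_met, n_excluded = n_excluded,
         search = list(strategy = strategy, grid_size = grid_size,
                       min_sens = min_sens, max_size = max_size,
                       markers = usable, n_candidates = n_candidates)),
    class = "panel_fit"
  )
}

#' @export
print.panel_fit <- function(x, ...) {
  cat("Optimized threshold panel", if (!x$constraint_met)
    "(sensitivity constraint UNMET)" else "", "\n")
  print(x$panel)
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, pAUC %.1f%% (%d candidates searched)\n",
              round_half_up(100 * x$performance$sensitivity, 1),
              round_half_up(100 * x$performance$specificity, 1),
              round_half_up(100 * x$performance$pauc, 1),
              x$search$n_candidates))
  invisible(x)
}
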