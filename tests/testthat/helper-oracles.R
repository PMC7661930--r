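# Independent oracles used by the tests. These reimplement the quantities
# under test by direct enumeration / explicit geometry, deliberately sharing
# no code with the package internals they check.

# Exact area of a piecewise-linear ROC path (points in ascending
# sensitivity) over a sensitivity window, by per-segment closed-form
# integration of the chord.
oracle_pauc_points <- function(sens, spec, lo = 0.9, hi = 1) {
  total <- 0
  for (i in seq_len(length(sens) - 1)) {
    s1 <- sens[i]; s2 <- sens[i + 1]
    p1 <- spec[i]; p2 <- spec[i + 1]
    if (s2 <= s1) next
    a <- max(s1, lo); b <- min(s2, hi)
    if (b <= a) next
    slope <- (p2 - p1) / (s2 - s1)
    # integral of p1 + slope*(s - s1) from a to b
    total <- total + p1 * (b - a) + slope * ((b - s1)^2 - (a - s1)^2) / 2
  }
  total
}

# ROC path of an integer 0..size panel score: operating points at every cut
# m = size..1 plus the trivial endpoints.
oracle_panel_points <- function(score, labels, size) {
  sens <- c(0, vapply(size:1, function(m) mean(score[labels] >= m), 0), 1)
  spec <- c(1, vapply(size:1, function(m) mean(score[!labels] < m), 0), 0)
  list(sens = sens, spec = spec)
}

# Brute-force panel search: every marker subset (size <= max_size), every
# midpoint threshold, both directions, every min-positive cut. Objective
# mirrors the contract: among candidates with sensitivity >= min_sens,
# maximize specificity, then partial AUC; if nothing is feasible, maximize
# sensitivity (then specificity).
oracle_panel_search <- function(data, markers, labels, max_size = 3,
                                min_sens = 0.9, lo = 0.9, hi = 1) {
  labels <- as.logical(labels)
  hits <- list(); meta <- list()
  for (m in markers) {
    thr <- candidate_thresholds(data[[m]], "midpoints")
    H <- NULL; info <- list()
    for (t in thr) {
      H <- cbind(H, data[[m]] > t, data[[m]] < t)
      info <- c(info, list(c(t, 1), c(t, -1)))
    }
    hits[[m]] <- H; meta[[m]] <- info
  }
  best <- NULL; fallback <- NULL
  for (size in seq_len(max_size)) {
    for (sub in utils::combn(markers, size, simplify = FALSE)) {
      ks <- vapply(sub, function(m) ncol(hits[[m]]), 0L)
      grid <- do.call(expand.grid, lapply(ks, seq_len))
      for (r in seq_len(nrow(grid))) {
        score <- rowSums(vapply(seq_along(sub), function(j)
          hits[[sub[j]]][, grid[r, j]], logical(nrow(data))))
        pts <- oracle_panel_points(score, labels, size)
        pa <- oracle_pauc_points(pts$sens, pts$spec, lo, hi)
        for (m in seq_len(size)) {
          sens <- mean(score[labels] >= m)
          spec <- mean(score[!labels] < m)
          if (sens >= min_sens - 1e-9) {
            if (is.null(best) || spec > best$spec + 1e-9 ||
                (abs(spec - best$spec) <= 1e-9 && pa > best$pauc + 1e-9)) {
              best <- list(spec = spec, sens = sens, pauc = pa)
            }
          }
          if (is.null(fallback) || sens > fallback$sens + 1e-9 ||
              (abs(sens - fallback$sens) <= 1e-9 && spec > fallback$spec + 1e-9)) {
            fallback <- list(spec = spec, sens = sens, pauc = pa)
          }
        }
      }
    }
  }
  list(best = best, fallback = fallback, feasible = !is.null(best))
}

# Small random cohort with both outcome classes guaranteed.
random_tiny_cohort <- function(n = 10, n_markers = 3, seed = 1) {
  set.seed(seed)
  labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
  d <- as.data.frame(lapply(seq_len(n_markers), function(j)
    round(rnorm(n, mean = 2 * labels * (j %% 2), sd = 1), 2)))
  names(d) <- paste0("m", seq_len(n_markers))
  list(data = d, labels = labels)
}

# Planted AND-rule cohort: positive iff A > a AND B < b. Each planted cutoff
# is bracketed by "anchor" patients just inside and just outside the decision
# boundary, with all other values kept a clear margin away, so the optimal
# thresholds are identifiable (the perfect-threshold interval around each
# cutoff contains a single candidate midpoint). The negatives violate one
# conjunct each, so neither marker separates alone.
planted_and_cohort <- function(seed, n_per_arm = 13, a = 5, b = 3,
                               margin = 0.4, tight = 0.15) {
  set.seed(seed)
  away <- function(n, center) {  # values clear of the boundary window
    side <- runif(n) < 0.5
    ifelse(side, runif(n, center + margin, center + 2),
           runif(n, center - 2, center - margin))
  }
  pos <- data.frame(A = runif(n_per_arm, a + margin, a + 2),
                    B = runif(n_per_arm, b - 2, b - margin))
  negA <- data.frame(A = runif(n_per_arm, a - 2, a - margin),
                     B = away(n_per_arm, b))
  negB <- data.frame(A = away(n_per_arm, a),
                     B = runif(n_per_arm, b + margin, b + 2))
  anchors <- data.frame(
    A = c(a + tight, a - tight, a + 1),   # positive, A-violator, B-violator
    B = c(b - tight, b - 1, b + tight))
  d <- rbind(pos, negA, negB, anchors)
  d$C <- rnorm(nrow(d))  # pure noise marker
  list(data = d,
       labels = c(rep(c(TRUE, FALSE, FALSE), each = n_per_arm),
                  TRUE, FALSE, FALSE),
       a = a, b = b)
}

all_findings_grid <- function() {
  expand.grid(sdh = c(FALSE, TRUE), edh = c(FALSE, TRUE), ich = c(FALSE, TRUE),
              mass_gt25 = c(FALSE, TRUE), ivh = c(FALSE, TRUE),
              cisterns = c("normal", "compressed", "obliterated"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
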