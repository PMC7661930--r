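# Helpers shared across modules.

#' Round half away from zero
#'
#' The package's reporting convention: percentages are rounded half-up to
#' one decimal. `base::round()` rounds half to even, which changes reported
#' one-decimal percentages at the `.x5` boundary.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(12.45)  # 12.5 (base round gives 12.4)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run fn() under a fixed seed, restoring the caller's RNG state afterwards
# so library calls never perturb a user's random stream.
with_preserved_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Area under the piecewise-linear chord from (s1, p1) to (s2, p2), clipped to
# the sensitivity window [lo, hi]. Vectorized over segments; zero-width
# (vertical) segments contribute nothing.
band_segment_area <- function(s1, s2, p1, p2, lo, hi) {
  a <- pmax(s1, lo)
  b <- pmin(s2, hi)
  w <- b - a
  ok <- w > 0 & s2 > s1
  area <- numeric(length(w))
  if (any(ok)) {
    fa <- (a[ok] - s1[ok]) / (s2[ok] - s1[ok])
    fb <- (b[ok] - s1[ok]) / (s2[ok] - s1[ok])
    pa <- p1[ok] + (p2[ok] - p1[ok]) * fa
    pb <- p1[ok] + (p2[ok] - p1[ok]) * fb
    area[ok] <- w[ok] * (pa + pb) / 2
  }
  area
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.factor(labels) && nlevels(labels) == 2) return(labels == levels(labels)[2])
  stop("labels must be logical, 0/1, or a two-level factor", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
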