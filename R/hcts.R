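#' Helsinki CT score component weights
#'
#' Returns the component weight table of the Helsinki CT score (HCTS). The
#' weights are shipped as a versioned JSON constant under
#' `inst/extdata/hcts_weights.json` rather than hard-coded, so that a revised
#' or alternative CT score can be swapped in without touching the scoring
#' code. With these weights the achievable score range is exactly -3 to 14.
#'
#' @return A list with elements `sdh`, `ich`, `edh`, `mass_gt25`, `ivh`
#'   (integer weights for the binary findings) and `cisterns` (a named list
#'   of weights for the suprasellar cistern state: `normal`, `compressed`,
#'   `obliterated`).
#' @examples
#' hcts_weights()$ivh  # 3
#' @export
hcts_weights <- function() {
  w <- .hcts_cache$weights
  if (is.null(w)) {
    path <- system.file("extdata", "hcts_weights.json", package = "tbipanel")
    w <- jsonlite::read_json(path, simplifyVector = TRUE)$weights
    .hcts_cache$weights <- w
  }
  w
}

.hcts_cache <- new.env(parent = emptyenv())

.cistern_levels <- c("normal", "compressed", "obliterated")

#' Construct a head-CT findings record
#'
#' Convenience constructor for the structured CT findings that feed the
#' Helsinki CT score: the three mass-lesion types (subdural, epidural and
#' intracerebral hematoma/contusion), mass lesion volume above 25 cm3,
#' intraventricular hemorrhage, and the suprasellar cistern state.
#'
#' @param sdh,edh,ich,mass_gt25,ivh Logical flags (vectors are recycled to a
#'   common length).
#' @param cisterns Character, one of `"normal"`, `"compressed"`,
#'   `"obliterated"`.
#' @return A data frame with one row per patient and the six findings columns.
#' @examples
#' hcts_findings(sdh = TRUE, ivh = TRUE, cisterns = "compressed")
#' @export
hcts_findings <- function(sdh = FALSE, edh = FALSE, ich = FALSE,
                          mass_gt25 = FALSE, ivh = FALSE,
                          cisterns = "normal") {
  data.frame(sdh = as.logical(sdh), edh = as.logical(edh),
             ich = as.logical(ich), mass_gt25 = as.logical(mass_gt25),
             ivh = as.logical(ivh), cisterns = as.character(cisterns),
             stringsAsFactors = FALSE)
}

.validate_findings <- function(findings, strict = FALSE) {
  needed <- c("sdh", "edh", "ich", "mass_gt25", "ivh", "cisterns")
  missing_cols <- setdiff(needed, names(findings))
  if (length(missing_cols) > 0) {
    stop("findings lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("sdh", "edh", "ich", "mass_gt25", "ivh")) {
    v <- findings[[f]]
    if (!(is.logical(v) || (is.numeric(v) && all(v %in% c(0, 1), na.rm = TRUE)))) {
      stop("finding '", f, "' must be logical or 0/1", call. = FALSE)
    }
    if (anyNA(v)) stop("finding '", f, "' contains NA", call. = FALSE)
    findings[[f]] <- as.logical(v)
  }
  cis <- as.character(findings$cisterns)
  bad <- !(cis %in% .cistern_levels)
  if (any(bad)) {
    stop("invalid suprasellar cistern category: ",
         paste(unique(cis[bad]), collapse = ", "),
         " (must be one of ", paste(.cistern_levels, collapse = "/"), ")",
         call. = FALSE)
  }
  findings$cisterns <- cis
  # A >25 cm3 mass lesion without any recorded mass-lesion type is suspect
  # but not impossible to tabulate (type and size are tallied independently),
  # so the default is a warning, not a rejection.
  orphan <- findings$mass_gt25 & !(findings$sdh | findings$edh | findings$ich)
  if (any(orphan)) {
    msg <- sprintf("mass_gt25 set without any mass-lesion flag in %d record(s)",
                   sum(orphan))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  findings
}

#' Compute the Helsinki CT score
#'
#' Sums the component weights of the Helsinki CT score over the recorded CT
#' findings. The achievable range under the shipped weight table is -3
#' (isolated epidural hematoma) to 14 (all positive-weight findings plus
#' obliterated cisterns, without an epidural hematoma).
#'
#' @param findings A data frame (or single-row list) with columns `sdh`,
#'   `edh`, `ich`, `mass_gt25`, `ivh` (logical or 0/1) and `cisterns`
#'   (`"normal"`, `"compressed"` or `"obliterated"`), e.g. from
#'   [hcts_findings()].
#' @param weights Weight table as returned by [hcts_weights()].
#' @param strict If `TRUE`, a `mass_gt25` flag without any mass-lesion type
#'   flag is an error instead of a warning.
#' @return Integer vector of scores, one per row of `findings`.
#' @examples
#' score_hcts(hcts_findings())                      # 0
#' score_hcts(hcts_findings(edh = TRUE))            # -3
#' @export
score_hcts <- function(findings, weights = hcts_weights(), strict = FALSE) {
  if (!is.data.frame(findings)) findings <- as.data.frame(findings)
  findings <- .validate_findings(findings, strict = strict)
  cw <- unlist(weights$cisterns)
  score <- findings$sdh * weights$sdh +
    findings$edh * weights$edh +
    findings$ich * weights$ich +
    findings$mass_gt25 * weights$mass_gt25 +
    findings$ivh * weights$ivh +
    cw[findings$cisterns]
  as.integer(unname(score))
}

#' Dichotomize a Helsinki CT score at a decision threshold
#'
#' Predicts unfavorable outcome when the score strictly exceeds the
#' threshold; the comparison is strict (`score > threshold`), so a score
#' equal to the threshold is classified negative.
#'
#' @param score Integer score(s), e.g. from [score_hcts()].
#' @param threshold Decision threshold; the conventional cut for unfavorable
#'   outcome is `> 1`.
#' @return Logical vector: `TRUE` = predicted unfavorable.
#' @examples
#' classify_hcts(c(1, 2, 5), threshold = 1)  # FALSE TRUE TRUE
#' @export
classify_hcts <- function(score, threshold = 1) {
  stopifnot(is.numeric(score), is.numeric(threshold), length(threshold) == 1)
  score > threshold
}
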