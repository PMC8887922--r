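## Batch quality metrics: summary statistics over hRMSD collections,
## the linear error-propagation trend of serial functionalization runs,
## and directory-level batch comparison by matching filenames.

#' Summary statistics of an RMSD collection
#'
#' @param values numeric vector (Angstrom), nonempty.
#' @return list with `mean`, `sd` (population standard deviation), `max`,
#'   `n`. The standard deviation is reported on the Angstrom scale of the
#'   inputs.
#' @examples
#' rmsdSummary(c(1, 1, 1))
#' @export
rmsdSummary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("need a nonempty numeric vector without NAs")
  m <- mean(values)
  list(mean = m,
       sd = sqrt(mean((values - m)^2)),
       max = max(values), n = length(values))
}

#' Fit the serial error-propagation trend
#'
#' In a serial functionalization run the deviation from a higher-level
#' reference grows nearly linearly with the number of placed groups,
#' because each placement builds on the (slightly off) geometry of the
#' previous one. This fits `hrmsd ~ slope * N + intercept` by least
#' squares and predicts the first step at which the fitted deviation
#' reaches a user threshold — the point where an intermediate higher-level
#' re-optimization is advisable.
#'
#' @param series data.frame with columns `N` (functionalization step,
#'   starting from 0) and `hrmsd` (Angstrom); optionally `skeleton`.
#'   At least 3 points.
#' @param threshold Angstrom threshold for the predicted crossing
#'   (default `NA`: no prediction).
#' @return list with `slope` (Angstrom per step), `intercept`,
#'   `rSquared`, and `predictedThresholdStep` (smallest integer `N >= 0`
#'   whose fitted value reaches the threshold; `NA` when the slope is
#'   non-positive or no threshold given).
#' @export
rmsdTrendFit <- function(series, threshold = NA_real_) {
  if (!all(c("N", "hrmsd") %in% names(series)))
    stop("series needs columns N and hrmsd")
  if (nrow(series) < 3) stop("need at least 3 points for a trend fit")
  fit <- stats::lm(hrmsd ~ N, data = series)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((series$hrmsd - mean(series$hrmsd))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  crossing <- NA_integer_
  if (!is.na(threshold)) {
    if (intercept >= threshold) {
      crossing <- 0L
    } else if (slope > 1e-12) {
      step <- ceiling((threshold - intercept) / slope)
      if (step <= .Machine$integer.max) crossing <- as.integer(max(0, step))
    }
  }
  list(slope = slope, intercept = intercept, rSquared = r2,
       predictedThresholdStep = crossing)
}

#' Compare two directories of structures by filename
#'
#' Matches `.mol`/`.xyz` files with identical stems in two directories and
#' computes the heavy-atom RMSD for each pair — the batch workflow for
#' comparing force-field-placed geometries against re-optimized ones.
#'
#' @param dirA,dirB directories of structure files.
#' @param reorder passed to [hrmsd()].
#' @return data.frame with columns `name`, `hrmsd`, plus attribute
#'   `summary` (a [rmsdSummary()]).
#' @export
compareDirectories <- function(dirA, dirB, reorder = FALSE) {
  readAny <- function(path) {
    if (grepl("\\.mol$", path)) readMolfile(path) else readXYZ(path)
  }
  listStems <- function(d) {
    f <- list.files(d, pattern = "\\.(mol|xyz)$")
    stats::setNames(file.path(d, f), sub("\\.(mol|xyz)$", "", f))
  }
  fa <- listStems(dirA); fb <- listStems(dirB)
  common <- sort(intersect(names(fa), names(fb)))
  if (length(common) == 0) stop("no matching filenames between ",
                                dirA, " and ", dirB)
  vals <- vapply(common, function(stem)
    hrmsd(readAny(fa[[stem]]), readAny(fb[[stem]]), reorder = reorder),
    numeric(1))
  out <- data.frame(name = common, hrmsd = unname(vals))
  attr(out, "summary") <- rmsdSummary(out$hrmsd)
  out
}
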