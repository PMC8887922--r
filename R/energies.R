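## Reaction-energy bookkeeping for geometry-quality assessment along the
## energy dimension: the reactive adsorption H-X + M-L -> M(X)-L(H) and
## the difference between a reaction energy on fully optimized geometries
## and the same reaction from single-point evaluations on cheaper
## geometries.

HARTREE_TO_KCALMOL <- 627.5094740631
EV_TO_KCALMOL <- 23.060547830619026

.toKcalMol <- function(x, unit) {
  switch(unit,
         "kcal/mol" = x,
         "hartree" = x * HARTREE_TO_KCALMOL,
         "eV" = x * EV_TO_KCALMOL,
         stop("unknown energy unit ", sQuote(unit),
              " (use kcal/mol, hartree or eV)"))
}

#' Reaction energy of reactive adsorption
#'
#' For the reaction `H-X + M-L -> M(X)-L(H)` (X = H, Br, OH, i-PrO, ...),
#' computes `deltaE = E(product) - E(M-L) - E(H-X)` in kcal/mol. All three
#' energies must come from the same level of theory; when `levels` are
#' given they are checked for consistency.
#'
#' @param eProduct energy of the adduct complex M(X)-L(H).
#' @param eComplex energy of the bare complex M-L.
#' @param eAdduct energy of the free H-X species.
#' @param unit input unit: `"kcal/mol"` (default), `"hartree"` or `"eV"`.
#' @param levels optional character vector (length 3 or 1) of level-of-
#'   theory labels for product, complex, adduct; mixing levels is an error.
#' @return Reaction energy in kcal/mol. Vectorized over the energies.
#' @examples
#' reactionEnergy(-10, -4, -4)  # -2 kcal/mol
#' @export
reactionEnergy <- function(eProduct, eComplex, eAdduct, unit = "kcal/mol",
                           levels = NULL) {
  if (!is.null(levels) && length(unique(levels)) > 1L)
    stop("mixed level-of-theory labels: ",
         paste(unique(levels), collapse = " vs "))
  stopifnot(is.finite(eProduct), is.finite(eComplex), is.finite(eAdduct))
  .toKcalMol(eProduct - eComplex - eAdduct, unit)
}

#' Geometry-quality energy difference
#'
#' `ddE = deltaE_opt - deltaE_sp`: the reaction energy from fully
#' optimized geometries minus the same reaction energy evaluated
#' single-point on cheaper (e.g. force-field-placed) geometries. Small
#' magnitudes mean the cheap geometries are energetically faithful.
#' Antisymmetric in its arguments; vectorized over reaction pairs.
#'
#' @param deltaEOpt reaction energy on optimized geometries (kcal/mol).
#' @param deltaESp reaction energy from single points on the cheaper
#'   geometries (kcal/mol), same reactions and single-point level.
#' @return Signed differences in kcal/mol.
#' @seealso [ddESummary()] for batch statistics.
#' @export
ddE <- function(deltaEOpt, deltaESp) {
  stopifnot(length(deltaEOpt) == length(deltaESp))
  deltaEOpt - deltaESp
}

#' Batch statistics of geometry-quality energy differences
#'
#' @inheritParams ddE
#' @return A [rmsdSummary()]-style list (mean, population sd, max, n) over
#'   the per-reaction `ddE` values, in kcal/mol.
#' @export
ddESummary <- function(deltaEOpt, deltaESp) {
  rmsdSummary(ddE(deltaEOpt, deltaESp))
}
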