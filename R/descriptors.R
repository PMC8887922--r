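## Coulomb-matrix featurization and the gradient-boosted regression
## harness for HOMO-LUMO-gap prediction from 3D structures alone.

#' Coulomb-matrix descriptor of a structure
#'
#' Builds the standard Coulomb matrix: diagonal `0.5 * Z^2.4`, off-diagonal
#' `Z_i * Z_j / d_ij` with interatomic distances in Angstrom (no unit
#' conversion; supply pre-scaled coordinates if another length unit is
#' required). Rows and columns are sorted by descending row norm, which
#' canonicalizes atom order, and the matrix is zero-padded to `size` atoms.
#' The returned vector is the upper triangle including the diagonal of the
#' sorted padded matrix, length `size * (size + 1) / 2` — a fixed-length,
#' rotation/translation/permutation-invariant regression input.
#'
#' @param mol a [Molecule-class] with at most `size` atoms.
#' @param size padded atom capacity (default 200).
#' @param sorting only `"row-norm"` is supported.
#' @return list of class `CoulombDescriptor` with `vector`, `size`,
#'   `sorting`, `natoms`.
#' @examples
#' h <- Molecule("H", c(0, 0, 0))
#' coulombMatrix(h, size = 2)$vector  # 0.5 and zero padding
#' @export
coulombMatrix <- function(mol, size = 200L, sorting = "row-norm") {
  if (!identical(sorting, "row-norm"))
    stop("unsupported sorting ", sQuote(sorting), " (only 'row-norm')")
  n <- natoms(mol)
  if (n > size)
    stop("structure has ", n, " atoms, exceeding descriptor size ", size)
  if (n == 0) stop("cannot featurize an empty structure")
  z <- atomicNumber(elements(mol))
  M <- outer(z, z)
  if (n > 1) {
    d <- as.matrix(stats::dist(coords(mol)))
    off <- upper.tri(M) | lower.tri(M)
    M[off] <- M[off] / d[off]
  }
  diag(M) <- 0.5 * z^2.4
  ord <- order(sqrt(rowSums(M^2)), decreasing = TRUE)
  M <- M[ord, ord, drop = FALSE]
  padded <- matrix(0, size, size)
  padded[seq_len(n), seq_len(n)] <- M
  structure(list(vector = padded[upper.tri(padded, diag = TRUE)],
                 size = as.integer(size), sorting = sorting,
                 natoms = n),
            class = "CoulombDescriptor")
}

#' Stack descriptors into a feature matrix
#'
#' @param descriptors list of [coulombMatrix()] results with identical
#'   `size` and `sorting`.
#' @return numeric matrix, one row per structure.
#' @export
descriptorMatrix <- function(descriptors) {
  sizes <- vapply(descriptors, function(d) d$size, integer(1))
  if (length(unique(sizes)) > 1)
    stop("descriptors were built with different sizes")
  do.call(rbind, lapply(descriptors, function(d) d$vector))
}

#' Train a gradient-boosted HOMO-LUMO-gap regressor
#'
#' Fits an extreme-gradient-boosted tree ensemble on a random
#' train/test split (default 75-25) of Coulomb-matrix features against
#' gap values in eV, and reports test-set performance. Both the
#' coefficient of determination (the headline `rSquared`) and the squared
#' Pearson correlation (`pearsonR2`) are reported, since "R^2" is used for
#' either in practice.
#'
#' @param X numeric feature matrix (rows = structures), e.g. from
#'   [descriptorMatrix()].
#' @param y numeric gap values in eV, one per row of `X`; at least 8.
#' @param split training fraction (default 0.75).
#' @param seed integer seed making split and fit reproducible.
#' @param nrounds boosting rounds (default 200).
#' @param params named list of extra booster parameters (library
#'   defaults otherwise).
#' @return list of class `GapModel` with `booster`, `report` (rSquared,
#'   pearsonR2, rmse (eV), split, seed, nTrain, nTest), `trainIndex`,
#'   `featureLength`.
#' @seealso [predictGap()]
#' @export
trainGapModel <- function(X, y, split = 0.75, seed = 1L, nrounds = 200L,
                          params = list()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("X and y disagree in length (", nrow(X), " vs ", length(y), ")")
  if (length(y) < 8) stop("need at least 8 labelled structures")
  set.seed(seed)
  nTrain <- max(2L, round(split * nrow(X)))
  trainIdx <- sort(sample(nrow(X), nTrain))
  testIdx <- setdiff(seq_len(nrow(X)), trainIdx)
  if (length(testIdx) < 2) stop("fewer than 2 test points; lower `split`")
  base <- list(objective = "reg:squarederror", nthread = 1,
               seed = as.integer(seed))
  booster <- xgboost::xgb.train(
    params = utils::modifyList(base, params),
    data = xgboost::xgb.DMatrix(X[trainIdx, , drop = FALSE],
                                label = y[trainIdx]),
    nrounds = nrounds, verbose = 0)
  pred <- stats::predict(booster,
                         xgboost::xgb.DMatrix(X[testIdx, , drop = FALSE]))
  obs <- y[testIdx]
  ssRes <- sum((obs - pred)^2)
  ssTot <- sum((obs - mean(obs))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  pr2 <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
    stats::cor(obs, pred)^2 else 0
  structure(list(
    booster = booster,
    report = list(rSquared = r2, pearsonR2 = pr2,
                  rmse = sqrt(mean((obs - pred)^2)),
                  split = split, seed = as.integer(seed),
                  nTrain = length(trainIdx), nTest = length(testIdx)),
    trainIndex = trainIdx,
    featureLength = ncol(X)),
    class = "GapModel")
}

#' Predict HOMO-LUMO gaps
#'
#' @param model a [trainGapModel()] result.
#' @param X feature matrix built with the training-time descriptor size
#'   and sorting.
#' @return numeric predictions in eV, one per row (empty input gives an
#'   empty vector).
#' @export
predictGap <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != model$featureLength)
    stop("descriptor length ", ncol(X), " does not match the model's ",
         model$featureLength)
  stats::predict(model$booster, xgboost::xgb.DMatrix(X))
}
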