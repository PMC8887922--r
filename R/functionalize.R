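## The core placement engine: orient a substituent with a rotation matrix,
## put its central atom on the anchor->site ray at a covalent-radius
## distance, delete the replaced atom, merge connectivity, and iterate
## serially so that each functionalized structure feeds the next step.

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalise a zero vector")
  v / nv
}

.crossProd <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix aligning one direction onto another
#'
#' Returns the minimal proper rotation `R` with
#' `R %*% unit(vFrom) == unit(vTo)` (Rodrigues construction). For the
#' antiparallel degenerate case the rotation is 180 degrees about a
#' deterministic perpendicular axis: the Cartesian basis vector least
#' aligned with `vFrom`, Gram-Schmidt-orthogonalised against it.
#'
#' @param vFrom,vTo nonzero 3-vectors.
#' @return A 3 x 3 rotation matrix (det +1).
#' @examples
#' R <- rotationToAlign(c(1, 0, 0), c(0, 1, 0))
#' R %*% c(1, 0, 0)
#' @export
rotationToAlign <- function(vFrom, vTo) {
  u <- .unit(vFrom)
  w <- .unit(vTo)
  c0 <- sum(u * w)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # antiparallel: 180 degrees about a deterministic perpendicular axis
    basis <- diag(3)
    k0 <- basis[, which.min(abs(u))]
    axis <- .unit(k0 - sum(k0 * u) * u)
    K <- rbind(c(0, -axis[3], axis[2]),
               c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    return(diag(3) + 2 * K %*% K)  # I + sin(pi) K + (1-cos(pi)) K^2
  }
  axis <- .unit(.crossProd(u, w))
  s <- sqrt(max(0, 1 - c0^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + s * K + (1 - c0) * (K %*% K)
}

.validatePair <- function(skeleton, b, a, step = NULL) {
  where <- if (is.null(step)) "" else sprintf(" (step %d)", step)
  n <- natoms(skeleton)
  if (b < 1L || b > n || a < 1L || a > n)
    stop(sprintf("functionalization pair [%d, %d]%s: index out of range (%d atoms)",
                 b, a, where, n))
  if (a == b)
    stop(sprintf("functionalization pair [%d, %d]%s: indices must differ",
                 b, a, where))
  nb <- .neighbours(skeleton, b)
  if (length(nb) != 1L)
    stop(sprintf(
      "atom %d%s is not terminal (has %d bonds); only terminal atoms can be replaced",
      b, where, length(nb)))
  if (nb != a)
    stop(sprintf(
      "atom %d%s is not bonded to anchor atom %d (bonded to %d)",
      b, where, a, nb))
  invisible(TRUE)
}

#' Place a substituent on a functionalization site
#'
#' Implements one placement: the site is an ordered pair `[b, a]` where `b`
#' is the terminal atom to be replaced (typically an H) and `a` the scaffold
#' anchor that receives the new bond. The substituent is rotated so that its
#' attachment direction (centroid point -> central atom) points at `a`,
#' i.e. antiparallel to the a->b direction, its central atom is put on the
#' a->b ray at the bond-length-policy distance, atom `b` is deleted, the
#' substituent atoms are appended after the surviving skeleton atoms, and a
#' single bond a-central is added. Surviving skeleton coordinates are
#' copied, never recomputed, so they stay bit-identical; all new atoms get
#' `skeletonMask` `FALSE`.
#'
#' @param skeleton a [Molecule-class].
#' @param pair integer pair `c(b, a)`: atom replaced, scaffold anchor.
#' @param sub a [Substituent-class].
#' @param bondLength new a-central bond length in Angstrom; default the sum
#'   of the two covalent radii.
#' @param torsionScan when `TRUE`, after alignment the substituent is spun
#'   about the new bond over 12 torsions at 30-degree increments and the
#'   one maximising the minimum substituent-skeleton nonbonded distance is
#'   kept (ties broken by the smallest angle). Default `FALSE`: the
#'   residual orientation of the minimal rotation is used and steric
#'   conflicts are left to the relaxation step.
#' @return The functionalized [Molecule-class].
#' @seealso [runSerial()], [relaxSubstituent()]
#' @export
placeSubstituent <- function(skeleton, pair, sub, bondLength = NULL,
                             torsionScan = FALSE) {
  b <- as.integer(pair[1]); a <- as.integer(pair[2])
  .validatePair(skeleton, b, a)
  geom <- sub@geometry
  nsub <- natoms(geom)
  posA <- coords(skeleton)[a, ]
  posB <- coords(skeleton)[b, ]
  uSite <- .unit(posB - posA)               # a -> b direction
  centralEl <- elements(geom)[sub@centralAtom]
  d <- if (is.null(bondLength)) {
    covalentRadius(elements(skeleton)[a]) + covalentRadius(centralEl)
  } else {
    as.numeric(bondLength)
  }
  newCentral <- posA + d * uSite

  centralPos <- coords(geom)[sub@centralAtom, ]
  if (nsub > 1L) {
    uAttach <- .unit(centralPos - sub@centroidPoint)
    R <- rotationToAlign(uAttach, -uSite)   # free valence points at a
    subXYZ <- sweep(coords(geom), 2, centralPos) %*% t(R)
  } else {
    subXYZ <- matrix(0, 1, 3)               # single atom: orientation moot
  }
  subXYZ <- sweep(subXYZ, 2, newCentral, "+")

  skelIdx <- setdiff(seq_len(natoms(skeleton)), b)
  if (torsionScan && nsub > 1L) {
    skelXYZ <- coords(skeleton)[skelIdx, , drop = FALSE]
    best <- NULL; bestScore <- -Inf
    for (k in 0:11) {
      theta <- k * pi / 6
      Rt <- .axisRotation(uSite, theta)
      cand <- sweep(sweep(subXYZ, 2, newCentral) %*% t(Rt), 2, newCentral, "+")
      other <- setdiff(seq_len(nsub), sub@centralAtom)
      score <- if (length(other) == 0) Inf else
        min(.crossDistances(cand[other, , drop = FALSE],
                            skelXYZ[-match(a, skelIdx), , drop = FALSE]))
      if (score > bestScore + 1e-9) { bestScore <- score; best <- cand }
    }
    subXYZ <- best
  }

  # delete b (indices above b shift down), then append the substituent
  oldB <- bonds(skeleton)
  keep <- !(oldB$i == b | oldB$j == b)
  shift <- function(ix) ix - (ix > b)
  newBonds <- data.frame(i = shift(oldB$i[keep]), j = shift(oldB$j[keep]),
                         order = oldB$order[keep])
  nSkel <- length(skelIdx)
  subBonds <- bonds(geom)
  if (nrow(subBonds) > 0)
    subBonds <- data.frame(i = subBonds$i + nSkel, j = subBonds$j + nSkel,
                           order = subBonds$order)
  attachBond <- data.frame(i = shift(a), j = nSkel + sub@centralAtom,
                           order = 1L)
  Molecule(
    elements = c(elements(skeleton)[skelIdx], elements(geom)),
    coords = rbind(coords(skeleton)[skelIdx, , drop = FALSE], subXYZ),
    bonds = rbind(newBonds, subBonds, attachBond),
    charges = c(formalCharges(skeleton)[skelIdx], formalCharges(geom)),
    name = molName(skeleton),
    skeletonMask = c(skeletonMask(skeleton)[skelIdx], rep(FALSE, nsub))
  )
}

## rotation about an arbitrary unit axis
.axisRotation <- function(axis, theta) {
  axis <- .unit(axis)
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## all pairwise distances between two coordinate blocks
.crossDistances <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(Inf)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Build a functionalization spec
#'
#' A spec is an ordered list of site pairs with a parallel list of
#' substituent names and a relaxation configuration. Pairs are written
#' against the numbering of the structure *current at that step*: deleting
#' atom `b` shifts all higher indices down by one before the substituent is
#' appended, so later pairs must account for earlier deletions (see
#' [autoFunctionalizationSpec()], which does this bookkeeping for you).
#'
#' @param pairs integer matrix with columns `b`, `a` (one row per step), or
#'   a data.frame with columns `b` and `a`.
#' @param substituents character vector of library names, one per step.
#' @param relax a [relaxationConfig()] applied after each placement.
#' @return A `FunctionalizationSpec` (list with class attribute).
#' @export
functionalizationSpec <- function(pairs, substituents,
                                  relax = relaxationConfig()) {
  if (is.data.frame(pairs)) pairs <- cbind(pairs$b, pairs$a)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) != length(substituents))
    stop("pairs and substituents must have equal length (",
         nrow(pairs), " vs ", length(substituents), ")")
  structure(list(pairs = pairs, substituents = as.character(substituents),
                 relax = relax),
            class = "FunctionalizationSpec")
}

#' Read a functionalization list from CSV
#'
#' Plain-text spec with one `b,a,substituent` triple per row (header
#' required). Indices are 1-based into the structure current at each step.
#'
#' @param path CSV path with columns `b`, `a`, `substituent`.
#' @param relax a [relaxationConfig()].
#' @return A [functionalizationSpec()].
#' @export
readFunctionalizationList <- function(path, relax = relaxationConfig()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("b", "a", "substituent")
  if (!all(need %in% names(df)))
    stop("functionalization list needs columns b, a, substituent")
  for (k in seq_len(nrow(df))) {
    if (is.na(df$b[k]) || is.na(df$a[k]) || !nzchar(df$substituent[k]))
      stop("invalid functionalization list row ", k, " in ", path)
  }
  functionalizationSpec(cbind(df$b, df$a), df$substituent, relax = relax)
}

#' Run a serial functionalization
#'
#' Applies the spec's steps one after another: each step's functionalized
#' output is the next step's input skeleton, mirroring a serial build-up of
#' a decorated complex. At the start of every step the *entire* current
#' structure is re-frozen (its skeleton mask set `TRUE`), so constrained
#' relaxation may move only the atoms placed in that step; the original
#' skeleton therefore stays bit-identical across the whole run.
#'
#' @param skeleton the input [Molecule-class].
#' @param spec a [functionalizationSpec()].
#' @param library a [SubstituentLibrary-class] resolving the spec's names.
#' @param bondLength optional fixed new-bond length override (Angstrom);
#'   default covalent-radius sums per step.
#' @param torsionScan passed to [placeSubstituent()].
#' @return A list with `structures` (one [Molecule-class] per step; in each,
#'   `skeletonMask` is `FALSE` exactly on that step's new atoms) and `log`
#'   (data.frame with step, substituent, natoms, backend, converged,
#'   objectiveBefore, objectiveAfter).
#' @seealso [enumerateBatch()] for batch strategies.
#' @export
runSerial <- function(skeleton, spec, library, bondLength = NULL,
                      torsionScan = FALSE) {
  stopifnot(inherits(spec, "FunctionalizationSpec"))
  nstep <- nrow(spec$pairs)
  structures <- vector("list", nstep)
  log <- vector("list", nstep)
  current <- skeleton
  for (k in seq_len(nstep)) {
    skeletonMask(current) <- rep(TRUE, natoms(current))
    b <- spec$pairs[k, 1]; a <- spec$pairs[k, 2]
    .validatePair(current, b, a, step = k)
    sub <- getSubstituent(library, spec$substituents[k])
    placed <- placeSubstituent(current, c(b, a), sub,
                               bondLength = bondLength,
                               torsionScan = torsionScan)
    relaxed <- relaxSubstituent(placed, config = spec$relax)
    structures[[k]] <- relaxed$molecule
    log[[k]] <- data.frame(
      step = k, substituent = spec$substituents[k],
      natoms = natoms(relaxed$molecule), backend = relaxed$backend,
      converged = relaxed$converged,
      objectiveBefore = relaxed$objectiveBefore,
      objectiveAfter = relaxed$objectiveAfter)
    current <- relaxed$molecule
  }
  list(structures = structures,
       log = if (nstep > 0) do.call(rbind, log) else data.frame(
         step = integer(0), substituent = character(0), natoms = integer(0),
         backend = character(0), converged = logical(0),
         objectiveBefore = numeric(0), objectiveAfter = numeric(0)))
}

#' Plan a serial spec automatically
#'
#' Index bookkeeping across a serial run is error-prone: deleting the
#' replaced atom shifts every higher index before the substituent is
#' appended. This helper dry-runs the topology updates and, at each step,
#' picks the lowest-index terminal hydrogen of the current structure as the
#' site, yielding a spec whose pairs are valid against the evolving
#' numbering.
#'
#' @param skeleton the input [Molecule-class].
#' @param substituents character vector of library names, one per step.
#' @param library a [SubstituentLibrary-class].
#' @param relax a [relaxationConfig()] stored in the resulting spec.
#' @return A [functionalizationSpec()].
#' @export
autoFunctionalizationSpec <- function(skeleton, substituents, library,
                                      relax = relaxationConfig()) {
  current <- skeleton
  nstep <- length(substituents)
  pairs <- matrix(NA_integer_, nstep, 2)
  for (k in seq_len(nstep)) {
    term <- .terminalAtoms(current)
    sites <- term[elements(current)[term] == "H"]
    if (length(sites) == 0L)
      stop("no terminal hydrogen site left at step ", k)
    b <- sites[1]
    a <- .neighbours(current, b)
    pairs[k, ] <- c(b, a)
    sub <- getSubstituent(library, substituents[k])
    current <- placeSubstituent(current, c(b, a), sub)
  }
  functionalizationSpec(pairs, substituents, relax = relax)
}

#' Enumerate a batch generation plan
#'
#' A batch strategy crosses a set of skeletons with a set of serial specs;
#' every serial intermediate is emitted, so the total structure count is
#' the sum of spec lengths over all (skeleton, spec) pairs — e.g. 10
#' skeletons x 4 specs of 28 steps each gives 1120 structures.
#'
#' @param skeletons list of [Molecule-class] skeletons (named or not).
#' @param specs list of [functionalizationSpec()] objects.
#' @return A `BatchPlan`: data.frame with columns `skeleton`, `spec`,
#'   `nSteps`, plus attribute `totalStructures`.
#' @seealso [executeBatch()]
#' @export
enumerateBatch <- function(skeletons, specs) {
  skelIds <- if (is.null(names(skeletons))) seq_along(skeletons) else
    names(skeletons)
  specIds <- if (is.null(names(specs))) seq_along(specs) else names(specs)
  grid <- expand.grid(skeleton = skelIds, spec = specIds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$nSteps <- vapply(grid$spec, function(s)
    nrow(specs[[s]]$pairs), integer(1))
  attr(grid, "totalStructures") <- sum(grid$nSteps)
  class(grid) <- c("BatchPlan", class(grid))
  grid
}

#' Execute a batch plan
#'
#' Runs [runSerial()] for every (skeleton, spec) pair of the plan. When
#' `outDir` is given, each intermediate is written as
#' `<skeleton>_func_<k>.mol` with zero-padded step index `k` (plus `.xyz`
#' when requested), the naming the batch RMSD matcher expects.
#'
#' @param plan a [enumerateBatch()] result.
#' @param skeletons,specs the lists the plan was built from.
#' @param library a [SubstituentLibrary-class].
#' @param outDir optional output directory.
#' @param writeXyz also write XYZ copies.
#' @param keepStructures keep all structures in memory (default `TRUE`;
#'   set `FALSE` for large batches when only counts/logs are needed).
#' @return list with `count` (total structures produced), `structures`
#'   (nested list, or `NULL`), and `log` (row-bound per-step logs with
#'   skeleton/spec ids).
#' @export
executeBatch <- function(plan, skeletons, specs, library, outDir = NULL,
                         writeXyz = FALSE, keepStructures = TRUE) {
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  total <- 0L
  logs <- list()
  structures <- if (keepStructures) vector("list", nrow(plan)) else NULL
  for (r in seq_len(nrow(plan))) {
    skelId <- plan$skeleton[r]; specId <- plan$spec[r]
    res <- runSerial(skeletons[[skelId]], specs[[specId]], library)
    total <- total + length(res$structures)
    lg <- res$log
    if (nrow(lg) > 0) {
      lg$skeleton <- skelId; lg$spec <- specId
    }
    logs[[r]] <- lg
    if (keepStructures) structures[[r]] <- res$structures
    if (!is.null(outDir)) {
      width <- max(2L, nchar(as.character(length(res$structures))))
      for (k in seq_along(res$structures)) {
        stem <- sprintf("%s_%s_func_%0*d", skelId, specId, width, k)
        writeMolfile(res$structures[[k]], file.path(outDir,
                                                    paste0(stem, ".mol")))
        if (writeXyz)
          writeXYZ(res$structures[[k]], file.path(outDir,
                                                  paste0(stem, ".xyz")))
      }
    }
  }
  list(count = total, structures = structures, log = do.call(rbind, logs))
}
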