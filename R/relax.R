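## Constrained steric relaxation: relieve clashes of newly placed
## substituents while the skeleton stays frozen. External force-field
## backends (GAFF/UFF via Open Babel) are invoked out-of-process through
## Molfile exchange; a builtin gradient minimizer guarantees the package
## works with no external binaries. Whatever the backend does, frozen
## coordinates are restored by copy afterwards, making the frozen-skeleton
## invariant exact rather than numerical.

#' Relaxation configuration
#'
#' @param backends ordered character vector from `"gaff"`, `"uff"`,
#'   `"builtin"`, `"none"`; the first available backend runs. The external
#'   force fields require the `obabel` program (option
#'   `ScaffoldSpace.obabel` overrides the binary name).
#' @param maxSteps iteration cap of the builtin minimizer (and step cap
#'   passed to external minimizers).
#' @param tol builtin convergence threshold on the gradient infinity norm
#'   (arbitrary steric units).
#' @param allowFallback when an external backend is unavailable, fall
#'   through to the next backend instead of erroring.
#' @param seed recorded for provenance; the relaxation itself is
#'   deterministic.
#' @return A `RelaxationConfig` list.
#' @export
relaxationConfig <- function(backends = "builtin", maxSteps = 500L,
                             tol = 1e-3, allowFallback = TRUE, seed = 1L) {
  stopifnot(maxSteps > 0, tol > 0)
  bad <- setdiff(backends, c("gaff", "uff", "builtin", "none"))
  if (length(bad) > 0)
    stop("unknown relaxation backend(s): ", paste(bad, collapse = ", "))
  structure(list(backends = backends, maxSteps = as.integer(maxSteps),
                 tol = tol, allowFallback = isTRUE(allowFallback),
                 seed = as.integer(seed)),
            class = "RelaxationConfig")
}

## Precompute the interaction lists the steric objective needs:
## bonds touching a movable atom (harmonic, r0 = covalent-radius sum,
## k = 1) and nonbonded pairs with at least one movable atom
## (repulsive (sigma/r)^12, sigma = 0.8 x covalent-radius sum).
.stericTerms <- function(mol, movable) {
  n <- natoms(mol)
  r <- covalentRadius(elements(mol))
  isMov <- rep(FALSE, n); isMov[movable] <- TRUE
  b <- bonds(mol)
  touch <- isMov[b$i] | isMov[b$j]
  bi <- b$i[touch]; bj <- b$j[touch]
  bondKey <- rep(FALSE, n * n)
  if (nrow(b) > 0)
    bondKey[(pmin(b$i, b$j) - 1L) * n + pmax(b$i, b$j)] <- TRUE
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- (isMov[pr[, 1]] | isMov[pr[, 2]]) &
    !bondKey[(pr[, 1] - 1L) * n + pr[, 2]]
  pi_ <- pr[keep, 1]; pj <- pr[keep, 2]
  list(
    bi = bi, bj = bj, r0 = r[bi] + r[bj],
    pi = pi_, pj = pj, sigma = 0.8 * (r[pi_] + r[pj]),
    movable = movable, n = n
  )
}

.stericValueGrad <- function(xyz, terms, wantGrad = TRUE) {
  val <- 0
  g <- if (wantGrad) matrix(0, terms$n, 3) else NULL
  if (length(terms$bi) > 0) {
    dv <- xyz[terms$bi, , drop = FALSE] - xyz[terms$bj, , drop = FALSE]
    rr <- sqrt(rowSums(dv^2))
    val <- val + sum((rr - terms$r0)^2)
    if (wantGrad) {
      coef <- 2 * (rr - terms$r0) / pmax(rr, 1e-12)
      gb <- dv * coef
      for (c3 in 1:3) {
        g[, c3] <- g[, c3] +
          tabulate2(terms$bi, gb[, c3], terms$n) -
          tabulate2(terms$bj, gb[, c3], terms$n)
      }
    }
  }
  if (length(terms$pi) > 0) {
    dv <- xyz[terms$pi, , drop = FALSE] - xyz[terms$pj, , drop = FALSE]
    rr2 <- rowSums(dv^2)
    rr <- sqrt(pmax(rr2, 1e-12))
    e <- (terms$sigma / rr)^12
    val <- val + sum(e)
    if (wantGrad) {
      coef <- -12 * e / rr2
      gp <- dv * coef
      for (c3 in 1:3) {
        g[, c3] <- g[, c3] +
          tabulate2(terms$pi, gp[, c3], terms$n) -
          tabulate2(terms$pj, gp[, c3], terms$n)
      }
    }
  }
  if (wantGrad) {
    frozen <- setdiff(seq_len(terms$n), terms$movable)
    g[frozen, ] <- 0
  }
  list(value = val, gradient = g)
}

## sum weights by index (sparse accumulate)
tabulate2 <- function(ix, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, ix)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Builtin steric objective and gradient
#'
#' The objective used by the builtin relaxation backend: a harmonic term
#' `sum k (r - r0)^2` (k = 1, r0 = covalent-radius sum) over bonds touching
#' movable atoms plus a pure repulsion `sum (sigma/r)^12`
#' (sigma = 0.8 x covalent-radius sum) over nonbonded pairs with at least
#' one movable atom. Units are arbitrary: this is steric relief, not a
#' physical force field. The analytic gradient is zeroed on frozen atoms.
#'
#' @param mol a [Molecule-class] with bonds present.
#' @param movable integer indices of movable atoms (default: atoms with
#'   `skeletonMask` `FALSE`).
#' @return list with `value` (scalar) and `gradient` (n x 3, zero rows for
#'   frozen atoms).
#' @export
stericObjective <- function(mol, movable = which(!skeletonMask(mol))) {
  terms <- .stericTerms(mol, as.integer(movable))
  .stericValueGrad(coords(mol), terms)
}

## Steepest descent with backtracking (Armijo) line search on movable
## atoms; terminates at max|g| <= tol or maxSteps accepted steps.
.builtinMinimize <- function(mol, movable, maxSteps, tol) {
  terms <- .stericTerms(mol, movable)
  xyz <- coords(mol)
  cur <- .stericValueGrad(xyz, terms)
  alpha <- 0.05
  steps <- 0L
  converged <- max(abs(cur$gradient)) <= tol
  while (!converged && steps < maxSteps) {
    gnorm2 <- sum(cur$gradient^2)
    if (gnorm2 < tol^2 * 1e-6) break
    accepted <- FALSE
    for (try in 1:30) {
      cand <- xyz - alpha * cur$gradient
      candVal <- .stericValueGrad(cand, terms, wantGrad = FALSE)$value
      if (candVal <= cur$value - 1e-4 * alpha * gnorm2) {
        xyz <- cand
        cur <- .stericValueGrad(xyz, terms)
        alpha <- min(alpha * 1.5, 1)
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    steps <- steps + 1L
    if (!accepted) break                    # line search stalled
    converged <- max(abs(cur$gradient)) <= tol
  }
  list(xyz = xyz, value = cur$value, steps = steps, converged = converged)
}

.obabelBinary <- function() getOption("ScaffoldSpace.obabel", "obabel")

.obabelAvailable <- function() nzchar(Sys.which(.obabelBinary()))

.externalFFMinimize <- function(mol, ff, maxSteps) {
  wd <- tempfile("relax")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  inp <- file.path(wd, "in.mol"); out <- file.path(wd, "out.mol")
  writeMolfile(mol, inp)
  status <- suppressWarnings(system2(
    .obabelBinary(),
    c(inp, "-O", out, "--minimize", "--sd", "--ff", toupper(ff),
      "--steps", as.character(maxSteps)),
    stdout = TRUE, stderr = TRUE))
  if (!file.exists(out) || !is.null(attr(status, "status")))
    stop("external ", toupper(ff), " minimization failed:\n",
         paste(status, collapse = "\n"))
  res <- readMolfile(out)
  if (natoms(res) != natoms(mol) ||
      !identical(elements(res), elements(mol)))
    stop("external ", toupper(ff), " minimization altered the atom list")
  coords(res)
}

#' Constrained relaxation of placed substituents
#'
#' Runs the first available backend of the configuration on the movable
#' atoms (those with `skeletonMask` `FALSE` by default). Frozen atoms never
#' move: their input coordinates are copied onto the result regardless of
#' backend numerics. Non-convergence within the step budget yields a
#' warning and the best structure found, flagged in the returned log
#' fields.
#'
#' @param mol a [Molecule-class] with bonds present.
#' @param movable indices of movable atoms; default from the skeleton mask.
#' @param config a [relaxationConfig()].
#' @return list with `molecule` (relaxed [Molecule-class]), `backend`
#'   (the backend that ran), `converged`, `steps`, `objectiveBefore`,
#'   `objectiveAfter` (builtin steric objective before/after, for logging).
#' @export
relaxSubstituent <- function(mol, movable = which(!skeletonMask(mol)),
                             config = relaxationConfig()) {
  movable <- as.integer(movable)
  before <- stericObjective(mol, movable)$value
  if (length(movable) == 0L)
    return(list(molecule = mol, backend = "none", converged = TRUE,
                steps = 0L, objectiveBefore = before,
                objectiveAfter = before))
  frozen <- setdiff(seq_len(natoms(mol)), movable)
  inputXYZ <- coords(mol)
  tried <- character(0)
  for (backend in config$backends) {
    if (backend == "none")
      return(list(molecule = mol, backend = "none", converged = TRUE,
                  steps = 0L, objectiveBefore = before,
                  objectiveAfter = before))
    if (backend %in% c("gaff", "uff")) {
      if (!.obabelAvailable()) {
        tried <- c(tried, backend)
        if (config$allowFallback) next
        stop("external backend ", sQuote(backend), " requires ",
             sQuote(.obabelBinary()), " on PATH and no fallback is allowed")
      }
      xyz <- tryCatch(.externalFFMinimize(mol, backend, config$maxSteps),
                      error = function(e) e)
      if (inherits(xyz, "error")) {
        tried <- c(tried, backend)
        if (config$allowFallback) next
        stop(xyz)
      }
      xyz[frozen, ] <- inputXYZ[frozen, , drop = FALSE]  # exact freeze
      out <- mol
      coords(out) <- xyz
      after <- stericObjective(out, movable)$value
      return(list(molecule = out, backend = backend, converged = TRUE,
                  steps = NA_integer_, objectiveBefore = before,
                  objectiveAfter = after))
    }
    # builtin
    res <- .builtinMinimize(mol, movable, config$maxSteps, config$tol)
    if (!res$converged)
      warning("builtin relaxation did not reach tolerance within ",
              config$maxSteps, " steps (returning best structure)")
    xyz <- res$xyz
    xyz[frozen, ] <- inputXYZ[frozen, , drop = FALSE]    # exact freeze
    out <- mol
    coords(out) <- xyz
    bk <- if (length(tried) > 0)
      paste0("builtin (fallback from ", paste(tried, collapse = ","), ")")
    else "builtin"
    return(list(molecule = out, backend = bk, converged = res$converged,
                steps = res$steps, objectiveBefore = before,
                objectiveAfter = res$value))
  }
  stop("no usable relaxation backend in sequence: ",
       paste(config$backends, collapse = ", "))
}

#' Full-structure optimization hook for an external program
#'
#' Hands the whole structure to an external geometry optimizer (e.g. a
#' semiempirical tight-binding code) through XYZ files and reads the
#' optimized geometry back. Unlike [relaxSubstituent()], the skeleton may
#' move here — this is the optional higher-level intermediate optimization
#' of a serial run. Atom order and identity must be preserved by the
#' program; the skeleton mask is carried over unchanged.
#'
#' The command is invoked as `command <args...> <input.xyz> <output.xyz>`.
#'
#' @param mol a [Molecule-class].
#' @param command external program (path or name on PATH); `NULL` disables
#'   the hook and returns the input unchanged.
#' @param args extra arguments placed before the input/output paths.
#' @param workdir working directory for the exchange files (default a
#'   fresh temporary directory).
#' @return The re-optimized [Molecule-class].
#' @export
fullStructureHook <- function(mol, command = NULL, args = character(0),
                              workdir = tempfile("hook")) {
  if (is.null(command)) return(mol)
  if (!nzchar(Sys.which(command)) && !file.exists(command))
    stop("external optimizer ", sQuote(command), " not found on PATH")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  inp <- file.path(workdir, "input.xyz")
  out <- file.path(workdir, "output.xyz")
  writeXYZ(mol, inp)
  res <- suppressWarnings(system2(command, c(args, inp, out),
                                  stdout = TRUE, stderr = TRUE))
  code <- attr(res, "status")
  if (!is.null(code) && code != 0)
    stop("external optimizer exited with status ", code, ":\n",
         paste(res, collapse = "\n"))
  if (!file.exists(out))
    stop("external optimizer produced no output file:\n",
         paste(res, collapse = "\n"))
  opt <- tryCatch(readXYZ(out), error = function(e)
    stop("could not parse optimizer output: ", conditionMessage(e)))
  if (natoms(opt) != natoms(mol) ||
      !identical(elements(opt), elements(mol)))
    stop("external optimizer altered the atom list")
  result <- mol
  coords(result) <- coords(opt)
  result
}
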