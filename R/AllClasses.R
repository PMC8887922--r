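#' @import methods
NULL

.emptyBonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0))
}

#' Molecule: a 3D molecular structure
#'
#' The universal structure record of the package: an ordered set of atoms
#' with Cartesian coordinates (Angstrom), a bond list with orders, per-atom
#' formal charges, and a per-atom logical `skeletonMask` marking atoms that
#' belong to the original (frozen) scaffold.
#'
#' Bond orders are stored as integers 1, 2, 3 with 4 meaning aromatic (the
#' Molfile convention); orders never influence geometry operations, they are
#' topology bookkeeping carried through the functionalization loop. All atom
#' indices are 1-based.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @slot bonds data.frame with integer columns `i`, `j`, `order`; each
#'   unordered pair appears once, stored with `i < j`.
#' @slot charges integer vector of formal charges, one per atom.
#' @slot name free-text molecule name.
#' @slot skeletonMask logical vector, one per atom; `TRUE` marks atoms of
#'   the original skeleton, which constrained relaxation keeps frozen.
#'
#' @seealso [Molecule()], [readMolfile()], [readXYZ()], [placeSubstituent()]
#' @export
setClass("Molecule",
  representation(
    elements = "character",
    coords = "matrix",
    bonds = "data.frame",
    charges = "integer",
    name = "character",
    skeletonMask = "logical"
  ),
  prototype(
    elements = character(0),
    coords = matrix(numeric(0), ncol = 3),
    bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
    charges = integer(0),
    name = "",
    skeletonMask = logical(0)
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msgs <- character(0)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must be a numeric matrix with 3 columns")
  else if (nrow(object@coords) != n)
    msgs <- c(msgs, "coords must have one row per atom")
  else if (n > 0 && !all(is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(object@charges) != n)
    msgs <- c(msgs, "charges must have one entry per atom")
  if (length(object@skeletonMask) != n)
    msgs <- c(msgs, "skeletonMask must have one entry per atom")
  if (n > 0 && !all(.isKnownElement(object@elements)))
    msgs <- c(msgs, paste0("unknown element symbol(s): ",
      paste(unique(object@elements[!.isKnownElement(object@elements)]),
            collapse = ", ")))
  b <- object@bonds
  if (!all(c("i", "j", "order") %in% names(b)))
    msgs <- c(msgs, "bonds must have columns i, j, order")
  else if (nrow(b) > 0) {
    if (any(b$i < 1L) || any(b$j < 1L) || any(b$i > n) || any(b$j > n))
      msgs <- c(msgs, "bond atom indices out of range")
    else {
      if (any(b$i == b$j))
        msgs <- c(msgs, "a bond cannot join an atom to itself")
      key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
      if (anyDuplicated(key))
        msgs <- c(msgs, "duplicate bond between the same atom pair")
      if (!all(b$order %in% 1:4))
        msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
    }
  }
  if (n > 1 && length(msgs) == 0) {
    dmin <- min(stats::dist(object@coords))
    if (dmin < 0.3 - 1e-9)
      msgs <- c(msgs, sprintf(
        "two atoms are only %.3f Angstrom apart (< 0.3)", dmin))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix (Angstrom); a single atom may be given
#'   as a length-3 vector.
#' @param bonds data.frame with columns `i`, `j` and optionally `order`
#'   (default 1); indices 1-based.
#' @param charges integer formal charges (default all 0).
#' @param name molecule name.
#' @param skeletonMask logical per-atom mask (default all `TRUE`).
#' @return A [Molecule-class] object.
#' @examples
#' water <- Molecule(
#'   elements = c("O", "H", "H"),
#'   coords = rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0))
#' )
#' natoms(water)
#' @export
Molecule <- function(elements, coords, bonds = NULL, charges = NULL,
                     name = "", skeletonMask = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- length(elements)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- .emptyBonds()
  } else {
    if (is.null(bonds$order)) bonds$order <- 1L
    bonds <- data.frame(
      i = as.integer(pmin(bonds$i, bonds$j)),
      j = as.integer(pmax(bonds$i, bonds$j)),
      order = as.integer(bonds$order)
    )
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  if (is.null(charges)) charges <- rep(0L, n)
  if (is.null(skeletonMask)) skeletonMask <- rep(TRUE, n)
  new("Molecule",
      elements = as.character(elements), coords = coords, bonds = bonds,
      charges = as.integer(charges), name = as.character(name),
      skeletonMask = as.logical(skeletonMask))
}

#' Substituent: a library entry for placement
#'
#' A substituent is a [Molecule-class] together with the index of its
#' central atom (the atom that forms the new bond to the scaffold) and the
#' centroid point of that atom's bonded neighbours. The unit vector from the
#' centroid point to the central atom is the attachment direction: it points
#' along the free valence, away from the substituent's existing bonds, and
#' is aimed at the scaffold's anchor atom during placement.
#'
#' @slot name identifier, unique within a library.
#' @slot geometry the substituent [Molecule-class].
#' @slot centralAtom 1-based index of the central atom.
#' @slot centroidPoint numeric length-3 centroid of the central atom's
#'   bonded neighbours (Angstrom).
#' @seealso [computeCentroidPoint()], [loadSubstituentLibrary()]
#' @export
setClass("Substituent",
  representation(
    name = "character",
    geometry = "Molecule",
    centralAtom = "integer",
    centroidPoint = "numeric"
  )
)

setValidity("Substituent", function(object) {
  msgs <- character(0)
  n <- length(object@geometry@elements)
  if (length(object@centralAtom) != 1L || is.na(object@centralAtom) ||
      object@centralAtom < 1L || object@centralAtom > n)
    msgs <- c(msgs, "centralAtom index out of range")
  if (length(object@centroidPoint) != 3L || !all(is.finite(object@centroidPoint)))
    msgs <- c(msgs, "centroidPoint must be a finite 3-vector")
  if (length(msgs) == 0) {
    cpos <- object@geometry@coords[object@centralAtom, ]
    if (sqrt(sum((cpos - object@centroidPoint)^2)) < 1e-8)
      msgs <- c(msgs, "centroidPoint coincides with the central atom")
  }
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Substituent
#'
#' If `centroidPoint` is omitted it is computed from the bonded neighbours
#' of the central atom via [computeCentroidPoint()] (perceiving bonds first
#' when the geometry has none). Single-atom substituents (H, F, ...) have no
#' neighbours, so an explicit `centroidPoint` is required for them; their
#' orientation is irrelevant at placement time, only the stored direction's
#' existence is.
#'
#' @param name identifier.
#' @param geometry a [Molecule-class].
#' @param centralAtom 1-based index of the atom that bonds to the scaffold.
#' @param centroidPoint optional explicit centroid point (3-vector).
#' @return A [Substituent-class].
#' @export
Substituent <- function(name, geometry, centralAtom, centroidPoint = NULL) {
  if (is.null(centroidPoint))
    centroidPoint <- computeCentroidPoint(geometry, centralAtom)
  new("Substituent", name = as.character(name), geometry = geometry,
      centralAtom = as.integer(centralAtom),
      centroidPoint = as.numeric(centroidPoint))
}

#' SubstituentLibrary: named collection of substituents
#'
#' @slot entries named list of [Substituent-class] objects.
#' @slot sourceDir directory the geometries were loaded from ("" when built
#'   in memory).
#' @seealso [loadSubstituentLibrary()], [addSubstituent()]
#' @export
setClass("SubstituentLibrary",
  representation(entries = "list", sourceDir = "character"),
  prototype(entries = list(), sourceDir = "")
)

setValidity("SubstituentLibrary", function(object) {
  msgs <- character(0)
  nm <- names(object@entries)
  if (length(object@entries) > 0) {
    if (is.null(nm) || any(!nzchar(nm)))
      msgs <- c(msgs, "all entries must be named")
    else if (anyDuplicated(nm))
      msgs <- c(msgs, "duplicate substituent names")
    ok <- vapply(object@entries, is, logical(1), class2 = "Substituent")
    if (!all(ok)) msgs <- c(msgs, "entries must be Substituent objects")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SubstituentLibrary from Substituent objects
#'
#' @param ... [Substituent-class] objects (or a single list of them).
#' @param sourceDir optional source directory annotation.
#' @return A [SubstituentLibrary-class].
#' @export
SubstituentLibrary <- function(..., sourceDir = "") {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !is(entries[[1]], "Substituent"))
    entries <- entries[[1]]
  names(entries) <- vapply(entries, function(s) s@name, character(1))
  new("SubstituentLibrary", entries = entries,
      sourceDir = as.character(sourceDir))
}

#' AlignmentResult: rigid superposition of two point sets
#'
#' @slot rotation 3 x 3 proper rotation matrix (det +1) applied to the
#'   first point set.
#' @slot translation length-3 translation completing the map
#'   `q = R p + t`.
#' @slot rmsd root-mean-square deviation (Angstrom) after superposition.
#' @slot mapping integer permutation mapping atoms of the first structure
#'   onto the second (length 0 when correspondence was by index).
#' @seealso [kabschAlign()], [quaternionAlign()], [hrmsd()]
#' @export
setClass("AlignmentResult",
  representation(
    rotation = "matrix",
    translation = "numeric",
    rmsd = "numeric",
    mapping = "integer"
  )
)

setValidity("AlignmentResult", function(object) {
  msgs <- character(0)
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    msgs <- c(msgs, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msgs <- c(msgs, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msgs <- c(msgs, "rotation must be proper (det +1)")
  }
  if (length(object@rmsd) != 1L || object@rmsd < 0)
    msgs <- c(msgs, "rmsd must be a single non-negative number")
  if (length(object@mapping) > 0 &&
      !identical(sort(object@mapping), seq_along(object@mapping)))
    msgs <- c(msgs, "mapping must be a permutation")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Molecule", function(object) {
  n <- length(object@elements)
  cat("Molecule", if (nzchar(object@name)) sQuote(object@name) else "",
      "with", n, "atoms,", nrow(object@bonds), "bonds\n")
  if (n > 0) {
    tab <- table(object@elements)
    cat("  formula:",
        paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = ""), "\n")
    cat("  skeleton atoms:", sum(object@skeletonMask), "frozen /",
        n - sum(object@skeletonMask), "placed\n")
  }
  invisible(object)
})

setMethod("show", "Substituent", function(object) {
  cat("Substituent", sQuote(object@name), "-",
      length(object@geometry@elements), "atoms, central atom",
      object@centralAtom,
      sprintf("(%s)\n", object@geometry@elements[object@centralAtom]))
  invisible(object)
})

setMethod("show", "SubstituentLibrary", function(object) {
  cat("SubstituentLibrary with", length(object@entries), "entries:",
      paste(names(object@entries), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: rmsd %.6f Angstrom%s\n", object@rmsd,
              if (length(object@mapping)) " (atoms reordered)" else ""))
  invisible(object)
})
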