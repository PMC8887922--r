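#' Number of atoms in a structure
#' @param x a [Molecule-class] (or object containing one).
#' @return integer atom count.
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' @rdname natoms
#' @export
setMethod("natoms", "Molecule", function(x) length(x@elements))

#' Element symbols of a structure
#' @param x a [Molecule-class].
#' @return character vector of element symbols, in atom order.
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname elements
#' @export
setMethod("elements", "Molecule", function(x) x@elements)

#' Cartesian coordinates (Angstrom)
#' @param x a [Molecule-class].
#' @return numeric n x 3 matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Molecule", function(x) x@coords)

#' Replace coordinates
#' @param x a [Molecule-class].
#' @param value numeric n x 3 matrix.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname coords-set
#' @export
setMethod("coords<-", "Molecule", function(x, value) {
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  dimnames(value) <- NULL
  x@coords <- value
  validObject(x)
  x
})

#' Bond table of a structure
#' @param x a [Molecule-class].
#' @return data.frame with columns `i`, `j`, `order` (1-based indices,
#'   `i < j`; order 4 = aromatic).
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)

#' Formal charges per atom
#' @param x a [Molecule-class].
#' @return integer vector.
#' @export
setGeneric("formalCharges", function(x) standardGeneric("formalCharges"))

#' @rdname formalCharges
#' @export
setMethod("formalCharges", "Molecule", function(x) x@charges)

#' Skeleton mask
#'
#' `TRUE` marks atoms of the original scaffold; these stay frozen during
#' constrained relaxation, while `FALSE` marks placed substituent atoms.
#'
#' @param x a [Molecule-class].
#' @return logical vector, one entry per atom.
#' @export
setGeneric("skeletonMask", function(x) standardGeneric("skeletonMask"))

#' @rdname skeletonMask
#' @export
setMethod("skeletonMask", "Molecule", function(x) x@skeletonMask)

#' Replace the skeleton mask
#' @param x a [Molecule-class].
#' @param value logical vector, one entry per atom.
#' @export
setGeneric("skeletonMask<-",
           function(x, value) standardGeneric("skeletonMask<-"))

#' @rdname skeletonMask-set
#' @export
setMethod("skeletonMask<-", "Molecule", function(x, value) {
  x@skeletonMask <- as.logical(value)
  validObject(x)
  x
})

#' Molecule name
#' @param x a [Molecule-class].
#' @return character name.
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' @rdname molName
#' @export
setMethod("molName", "Molecule", function(x) x@name)

#' Substituent accessors
#' @param x a [Substituent-class].
#' @return `substituentGeometry`: the [Molecule-class]; `centralAtom`: the
#'   1-based central-atom index; `centroidPoint`: the neighbour-centroid
#'   3-vector; `attachmentDirection`: unit vector from the centroid point to
#'   the central atom (the free-valence direction aimed at the scaffold).
#' @name substituent-accessors
NULL

#' @rdname substituent-accessors
#' @export
setGeneric("substituentGeometry",
           function(x) standardGeneric("substituentGeometry"))

#' @rdname substituent-accessors
#' @export
setMethod("substituentGeometry", "Substituent", function(x) x@geometry)

#' @rdname substituent-accessors
#' @export
setGeneric("centralAtom", function(x) standardGeneric("centralAtom"))

#' @rdname substituent-accessors
#' @export
setMethod("centralAtom", "Substituent", function(x) x@centralAtom)

#' @rdname substituent-accessors
#' @export
setGeneric("centroidPoint", function(x) standardGeneric("centroidPoint"))

#' @rdname substituent-accessors
#' @export
setMethod("centroidPoint", "Substituent", function(x) x@centroidPoint)

#' @rdname substituent-accessors
#' @export
setGeneric("attachmentDirection",
           function(x) standardGeneric("attachmentDirection"))

#' @rdname substituent-accessors
#' @export
setMethod("attachmentDirection", "Substituent", function(x) {
  v <- x@geometry@coords[x@centralAtom, ] - x@centroidPoint
  v / sqrt(sum(v^2))
})

#' Library accessors
#' @param x a [SubstituentLibrary-class].
#' @param name substituent name to fetch.
#' @return `substituentNames`: character vector; `getSubstituent`: the named
#'   [Substituent-class] (error when absent).
#' @name library-accessors
NULL

#' @rdname library-accessors
#' @export
setGeneric("substituentNames",
           function(x) standardGeneric("substituentNames"))

#' @rdname library-accessors
#' @export
setMethod("substituentNames", "SubstituentLibrary",
          function(x) names(x@entries))

#' @rdname library-accessors
#' @export
setGeneric("getSubstituent",
           function(x, name) standardGeneric("getSubstituent"))

#' @rdname library-accessors
#' @export
setMethod("getSubstituent", "SubstituentLibrary", function(x, name) {
  if (!name %in% names(x@entries))
    stop("substituent ", sQuote(name), " not in library (has: ",
         paste(names(x@entries), collapse = ", "), ")")
  x@entries[[name]]
})

#' AlignmentResult accessors
#' @param x an [AlignmentResult-class].
#' @return `alignRotation`: 3 x 3 rotation; `alignTranslation`: length-3
#'   translation; `alignRmsd`: the RMSD in Angstrom.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
setGeneric("alignRotation", function(x) standardGeneric("alignRotation"))

#' @rdname alignment-accessors
#' @export
setMethod("alignRotation", "AlignmentResult", function(x) x@rotation)

#' @rdname alignment-accessors
#' @export
setGeneric("alignTranslation",
           function(x) standardGeneric("alignTranslation"))

#' @rdname alignment-accessors
#' @export
setMethod("alignTranslation", "AlignmentResult", function(x) x@translation)

#' @rdname alignment-accessors
#' @export
setGeneric("alignRmsd", function(x) standardGeneric("alignRmsd"))

#' @rdname alignment-accessors
#' @export
setMethod("alignRmsd", "AlignmentResult", function(x) x@rmsd)
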