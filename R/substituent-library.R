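## Substituent library management: per-substituent geometry files plus a
## CSV index that records, for each entry, the coordinates of the central
## atom (the atom that bonds to the scaffold) and of the centroid point of
## its bonded neighbours. The centroid vector (central atom -> centroid)
## defines the direction of the substituent's existing bonds; placement
## uses its negation so that the free valence always points toward the
## scaffold anchor.

.libraryCsvColumns <- c("name", "central_atom_index",
                        "central_x", "central_y", "central_z",
                        "centroid_x", "centroid_y", "centroid_z")

#' Centroid point of a central atom's bonded neighbours
#'
#' For a tetrahedral group such as CH3 this is the centroid of the triangle
#' formed by the three hydrogens; for a planar group such as NH2 it is the
#' midpoint of the line joining the two hydrogens. The definition
#' generalises to any coordination: the arithmetic mean of the positions of
#' all atoms bonded to `centralAtom`. When the geometry carries no bonds
#' they are perceived first with [perceiveBonds()].
#'
#' @param geometry a [Molecule-class].
#' @param centralAtom 1-based index of the central atom.
#' @return Numeric length-3 centroid point (Angstrom).
#' @examples
#' nh2 <- Molecule(c("N", "H", "H"),
#'                 rbind(c(0, 0, 0), c(0.8, -0.6, 0), c(-0.8, -0.6, 0)),
#'                 bonds = data.frame(i = c(1, 1), j = c(2, 3)))
#' computeCentroidPoint(nh2, 1)  # (0, -0.6, 0)
#' @export
computeCentroidPoint <- function(geometry, centralAtom) {
  centralAtom <- as.integer(centralAtom)
  if (centralAtom < 1L || centralAtom > natoms(geometry))
    stop("central atom index ", centralAtom, " out of range")
  if (nrow(bonds(geometry)) == 0L) geometry <- perceiveBonds(geometry)
  nb <- .neighbours(geometry, centralAtom)
  if (length(nb) == 0L)
    stop("central atom ", centralAtom,
         " has no bonded neighbours; cannot define a centroid vector")
  colMeans(coords(geometry)[nb, , drop = FALSE])
}

.readSubstituentGeometry <- function(geometryDir, name) {
  molPath <- file.path(geometryDir, paste0(name, ".mol"))
  xyzPath <- file.path(geometryDir, paste0(name, ".xyz"))
  if (file.exists(molPath)) {
    readMolfile(molPath)
  } else if (file.exists(xyzPath)) {
    perceiveBonds(readXYZ(xyzPath))
  } else {
    stop("no geometry file for substituent ", sQuote(name), ": expected ",
         molPath, " or ", xyzPath)
  }
}

#' Load a substituent library from a CSV index
#'
#' The CSV has one row per substituent with columns `name`,
#' `central_atom_index` (1-based), `central_x/y/z` and `centroid_x/y/z`.
#' Geometries are read from `geometryDir/<name>.mol`, falling back to
#' `<name>.xyz` plus bond perception. The stored central-atom coordinates
#' are cross-checked against the geometry file.
#'
#' @param csvPath path to the index CSV.
#' @param geometryDir directory holding the geometry files.
#' @return A [SubstituentLibrary-class].
#' @seealso [writeSubstituentLibrary()], [addSubstituent()]
#' @export
loadSubstituentLibrary <- function(csvPath, geometryDir) {
  if (!file.exists(csvPath)) stop("index CSV not found: ", csvPath)
  idx <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  missing <- setdiff(.libraryCsvColumns, names(idx))
  if (length(missing) > 0)
    stop("index CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(idx$name))
    stop("duplicate substituent name(s) in index: ",
         paste(unique(idx$name[duplicated(idx$name)]), collapse = ", "))
  entries <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    row <- idx[k, ]
    geom <- .readSubstituentGeometry(geometryDir, row$name)
    ca <- as.integer(row$central_atom_index)
    if (ca < 1L || ca > natoms(geom))
      stop("substituent ", sQuote(row$name), ": central atom index ", ca,
           " out of range (", natoms(geom), " atoms)")
    stored <- c(row$central_x, row$central_y, row$central_z)
    if (max(abs(coords(geom)[ca, ] - stored)) > 1e-3)
      warning("substituent ", sQuote(row$name), ": stored central-atom ",
              "coordinates disagree with the geometry file; using the file")
    entries[[k]] <- Substituent(
      name = row$name, geometry = geom, centralAtom = ca,
      centroidPoint = c(row$centroid_x, row$centroid_y, row$centroid_z))
  }
  names(entries) <- idx$name
  new("SubstituentLibrary", entries = entries,
      sourceDir = normalizePath(geometryDir))
}

#' Serialize a library's CSV index (and optionally its geometries)
#'
#' @param library a [SubstituentLibrary-class].
#' @param csvPath output CSV path.
#' @param geometryDir when non-`NULL`, each entry's geometry is also
#'   written there as `<name>.mol`.
#' @return Invisibly, `csvPath`.
#' @export
writeSubstituentLibrary <- function(library, csvPath, geometryDir = NULL) {
  entries <- library@entries
  idx <- do.call(rbind, lapply(entries, function(s) {
    cpos <- coords(s@geometry)[s@centralAtom, ]
    data.frame(name = s@name, central_atom_index = s@centralAtom,
               central_x = cpos[1], central_y = cpos[2], central_z = cpos[3],
               centroid_x = s@centroidPoint[1],
               centroid_y = s@centroidPoint[2],
               centroid_z = s@centroidPoint[3])
  }))
  if (is.null(idx)) idx <- as.data.frame(
    setNames(rep(list(numeric(0)), length(.libraryCsvColumns)),
             .libraryCsvColumns))
  utils::write.csv(idx, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(geometryDir)) {
    dir.create(geometryDir, recursive = TRUE, showWarnings = FALSE)
    for (s in entries)
      writeMolfile(s@geometry, file.path(geometryDir, paste0(s@name, ".mol")))
  }
  invisible(csvPath)
}

#' Add a substituent to a library from a geometry file
#'
#' The entry name is the file stem; the centroid point is computed from the
#' bonded neighbours of `centralAtom` (bonds perceived for bond-less XYZ
#' input). A geometry in which some atom is unreachable from the central
#' atom through bonds is accepted with a warning, since placement moves all
#' atoms rigidly.
#'
#' @param library a [SubstituentLibrary-class].
#' @param geometryFile path to a `.mol` or `.xyz` file.
#' @param centralAtom 1-based index of the atom that bonds to the scaffold.
#' @return The enlarged [SubstituentLibrary-class].
#' @export
addSubstituent <- function(library, geometryFile, centralAtom) {
  name <- sub("\\.(mol|xyz)$", "", basename(geometryFile))
  if (name %in% names(library@entries))
    stop("substituent ", sQuote(name), " already in library")
  geom <- if (grepl("\\.mol$", geometryFile)) {
    readMolfile(geometryFile)
  } else {
    perceiveBonds(readXYZ(geometryFile))
  }
  if (nrow(bonds(geom)) == 0L) geom <- perceiveBonds(geom)
  reach <- .connectedComponent(geom, as.integer(centralAtom))
  if (length(reach) < natoms(geom))
    warning("substituent ", sQuote(name), ": ", natoms(geom) - length(reach),
            " atom(s) not reachable from the central atom via bonds")
  sub <- Substituent(name = name, geometry = geom, centralAtom = centralAtom)
  library@entries[[name]] <- sub
  validObject(library)
  library
}

## breadth-first search over the bond graph
.connectedComponent <- function(mol, start) {
  n <- natoms(mol)
  adj <- vector("list", n)
  b <- bonds(mol)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}
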