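## Structure I/O: XYZ and MDL Molfile (V2000) readers/writers plus
## covalent-radius bond perception. Atom order is never permuted by any of
## these operations, and Molfile round-trips preserve elements, coordinates
## (4 decimals), bonds and formal charges so that connectivity survives the
## functionalization loop.

.fmtErr <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read an XYZ file
#'
#' Standard XYZ: first line the atom count, second a free-text comment,
#' then one `symbol x y z` record per atom. The result has an empty bond
#' list (use [perceiveBonds()]) and an all-`TRUE` skeleton mask.
#'
#' @param path path to the file.
#' @return A [Molecule-class] with no bonds.
#' @seealso [readMolfile()] which conserves bonding information.
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) .fmtErr(path, 1L, "empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) .fmtErr(path, 1L, "malformed atom count")
  if (length(lines) < n + 2L)
    .fmtErr(path, length(lines), sprintf("expected %d atom records", n))
  elements <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- 2L + k
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) .fmtErr(path, ln, "expected 'symbol x y z'")
    if (!.isKnownElement(tok[1]))
      .fmtErr(path, ln, paste0("unknown element symbol ", sQuote(tok[1])))
    pos <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(pos)) .fmtErr(path, ln, "coordinate parse failure")
    elements[k] <- tok[1]
    xyz[k, ] <- pos
  }
  name <- if (length(lines) >= 2L) trimws(lines[2]) else ""
  if (!nzchar(name)) name <- sub("\\.xyz$", "", basename(path))
  Molecule(elements = elements, coords = xyz, name = name)
}

#' Write an XYZ file
#'
#' @param mol a [Molecule-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeXYZ <- function(mol, path) {
  n <- natoms(mol)
  lines <- c(
    as.character(n),
    molName(mol),
    if (n > 0) sprintf("%-3s %14.8f %14.8f %14.8f", elements(mol),
                       coords(mol)[, 1], coords(mol)[, 2], coords(mol)[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an MDL Molfile (V2000)
#'
#' Reads the counts line, atom block, bond block and `M  CHG` properties of
#' a V2000 connection table. Atom order is preserved exactly; bond indices
#' are converted from the format's 1-based convention (which matches this
#' package's). V3000 input is rejected rather than silently coerced.
#'
#' @param path path to the `.mol` file.
#' @return A [Molecule-class] with bonds and formal charges populated.
#' @export
readMolfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) .fmtErr(path, length(lines), "truncated Molfile")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE))
    stop(path, ": V3000 connection tables are not supported (V2000 only)",
         call. = FALSE)
  natom <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natom) || is.na(nbond))
    .fmtErr(path, 4L, "malformed V2000 counts line")
  if (length(lines) < 4L + natom + nbond)
    .fmtErr(path, length(lines), "truncated atom/bond block")
  elements <- character(natom)
  xyz <- matrix(NA_real_, natom, 3)
  for (k in seq_len(natom)) {
    ln <- 4L + k
    rec <- lines[ln]
    pos <- suppressWarnings(as.numeric(c(
      substr(rec, 1, 10), substr(rec, 11, 20), substr(rec, 21, 30))))
    sym <- trimws(substr(rec, 32, 34))
    if (anyNA(pos)) .fmtErr(path, ln, "coordinate parse failure")
    if (!.isKnownElement(sym))
      .fmtErr(path, ln, paste0("unknown element symbol ", sQuote(sym)))
    elements[k] <- sym
    xyz[k, ] <- pos
  }
  bi <- bj <- bo <- integer(nbond)
  for (k in seq_len(nbond)) {
    ln <- 4L + natom + k
    rec <- lines[ln]
    i <- suppressWarnings(as.integer(substr(rec, 1, 3)))
    j <- suppressWarnings(as.integer(substr(rec, 4, 6)))
    o <- suppressWarnings(as.integer(substr(rec, 7, 9)))
    if (is.na(i) || is.na(j)) .fmtErr(path, ln, "malformed bond record")
    if (i < 1L || j < 1L || i > natom || j > natom)
      .fmtErr(path, ln, sprintf("bond index out of range (%d-%d)", i, j))
    bi[k] <- i; bj[k] <- j
    bo[k] <- if (is.na(o) || o < 1L) 1L else o
  }
  charges <- rep(0L, natom)
  for (ln in seq_along(lines)) {
    rec <- lines[ln]
    if (startsWith(rec, "M  CHG")) {
      cnt <- suppressWarnings(as.integer(substr(rec, 7, 9)))
      if (is.na(cnt)) .fmtErr(path, ln, "malformed M  CHG record")
      for (e in seq_len(cnt)) {
        off <- 10L + (e - 1L) * 8L
        at <- suppressWarnings(as.integer(substr(rec, off, off + 3L)))
        ch <- suppressWarnings(as.integer(substr(rec, off + 4L, off + 7L)))
        if (is.na(at) || is.na(ch) || at < 1L || at > natom)
          .fmtErr(path, ln, "malformed M  CHG entry")
        charges[at] <- ch
      }
    }
    if (startsWith(rec, "M  END")) break
  }
  name <- trimws(lines[1])
  if (!nzchar(name)) name <- sub("\\.mol$", "", basename(path))
  Molecule(elements = elements, coords = xyz,
           bonds = data.frame(i = bi, j = bj, order = bo),
           charges = charges, name = name)
}

#' Write an MDL Molfile (V2000)
#'
#' Emits fixed-width V2000 records with coordinates to 4 decimals, an
#' `M  CHG` property line when any formal charge is nonzero, and the
#' `M  END` terminator. V2000's fixed-width fields cap the atom count at
#' 999.
#'
#' @param mol a [Molecule-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMolfile <- function(mol, path) {
  n <- natoms(mol)
  if (n > 999L)
    stop("V2000 Molfiles hold at most 999 atoms (got ", n, ")")
  b <- bonds(mol)
  header <- c(molName(mol), "  ScaffoldSpace", "")
  countsLine <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                        n, nrow(b))
  atomLines <- if (n > 0) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords(mol)[, 1], coords(mol)[, 2], coords(mol)[, 3],
            elements(mol))
  } else character(0)
  bondLines <- if (nrow(b) > 0) {
    sprintf("%3d%3d%3d  0", b$i, b$j, b$order)
  } else character(0)
  chg <- which(formalCharges(mol) != 0L)
  chgLines <- character(0)
  if (length(chg) > 0) {
    # at most 8 atom/charge pairs per M  CHG line
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      chgLines <- c(chgLines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, formalCharges(mol)[grp]),
               collapse = "")))
    }
  }
  writeLines(c(header, countsLine, atomLines, bondLines, chgLines, "M  END"),
             path)
  invisible(path)
}

#' Perceive bonds from interatomic distances
#'
#' Adds a single bond for every atom pair whose distance does not exceed
#' `tolerance` times the sum of the two covalent radii (bundled Cordero
#' values). Existing bonds are kept unchanged, making the operation
#' idempotent; perceived bond orders are always 1 — downstream relaxation
#' treats orders as topology, not chemistry.
#'
#' @param mol a [Molecule-class].
#' @param tolerance scale factor on the covalent-radius sum (default 1.15).
#' @return A [Molecule-class] with the perceived bonds merged in.
#' @examples
#' h2 <- Molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' nrow(bonds(perceiveBonds(h2, tolerance = 1.25)))
#' @export
perceiveBonds <- function(mol, tolerance = 1.15) {
  n <- natoms(mol)
  if (n < 2L) return(mol)
  r <- covalentRadius(elements(mol))  # errors on unknown symbols
  d <- as.matrix(stats::dist(coords(mol)))
  thr <- outer(r, r, "+") * tolerance
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  b <- bonds(mol)
  if (nrow(hit) > 0) {
    newb <- data.frame(i = hit[, 1], j = hit[, 2], order = 1L)
    if (nrow(b) > 0) {
      have <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
      newb <- newb[!paste(newb$i, newb$j) %in% have, , drop = FALSE]
    }
    b <- rbind(b, newb)
  }
  Molecule(elements = elements(mol), coords = coords(mol), bonds = b,
           charges = formalCharges(mol), name = molName(mol),
           skeletonMask = skeletonMask(mol))
}

## neighbours of atom k in the bond table
.neighbours <- function(mol, k) {
  b <- mol@bonds
  sort(c(b$j[b$i == k], b$i[b$j == k]))
}

## indices of terminal atoms (exactly one bond)
.terminalAtoms <- function(mol) {
  b <- mol@bonds
  deg <- tabulate(c(b$i, b$j), nbins = natoms(mol))
  which(deg == 1L)
}
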