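## Synthetic fixture generator: deterministic toy skeletons and a small
## substituent library so every workflow in the package is runnable and
## testable offline, standing in for DFT-optimized input skeletons.

#' Toy planar macrocycle skeleton
#'
#' A planar 12-membered carbon ring (bond length ~1.40 Angstrom) carrying
#' four outward-pointing terminal hydrogens on alternating positions — a
#' 16-atom macrocycle-like stand-in for a porphyrin-type scaffold with
#' four functionalization sites.
#'
#' @return A [Molecule-class] with 16 atoms and 16 bonds.
#' @export
toyMacrocycle <- function() {
  nring <- 12L
  side <- 1.40
  radius <- side / (2 * sin(pi / nring))
  ang <- 2 * pi * (seq_len(nring) - 1) / nring
  ringXYZ <- cbind(radius * cos(ang), radius * sin(ang), 0)
  hOn <- c(1L, 4L, 7L, 10L)
  hXYZ <- ringXYZ[hOn, ] * (radius + 1.09) / radius
  ringBonds <- data.frame(i = seq_len(nring),
                          j = c(seq_len(nring)[-1], 1L), order = 1L)
  hBonds <- data.frame(i = hOn, j = nring + seq_along(hOn), order = 1L)
  Molecule(
    elements = c(rep("C", nring), rep("H", length(hOn))),
    coords = rbind(ringXYZ, hXYZ),
    bonds = rbind(ringBonds, hBonds),
    name = "toy_macrocycle")
}

#' Toy square-planar metal template
#'
#' A Pd centre with four planar NH2 donor groups at 2.0 Angstrom along the
#' +-x/+-y axes: a minimal square-planar complex with eight terminal
#' hydrogen sites for placement tests on a metal-bearing scaffold.
#'
#' @return A [Molecule-class] with 13 atoms (Pd + 4 N + 8 H).
#' @export
squarePlanarTemplate <- function() {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  elements <- "Pd"; xyz <- matrix(0, 1, 3)
  b <- list()
  for (k in 1:4) {
    u <- dirs[k, ]
    perp <- c(-u[2], u[1], 0)
    npos <- 2.0 * u
    nIdx <- nrow(xyz) + 1L
    h1 <- npos + 1.01 * (cos(pi / 3) * u + sin(pi / 3) * perp)
    h2 <- npos + 1.01 * (cos(pi / 3) * u - sin(pi / 3) * perp)
    xyz <- rbind(xyz, npos, h1, h2)
    elements <- c(elements, "N", "H", "H")
    b[[length(b) + 1]] <- data.frame(i = c(1L, nIdx, nIdx),
                                     j = c(nIdx, nIdx + 1L, nIdx + 2L),
                                     order = 1L)
  }
  Molecule(elements = elements, coords = xyz, bonds = do.call(rbind, b),
           name = "square_planar_template")
}

#' Benzene
#'
#' Idealized benzene (C-C 1.39, C-H 1.09 Angstrom, aromatic ring bonds):
#' six equivalent terminal hydrogen sites.
#'
#' @return A [Molecule-class] with 12 atoms.
#' @export
benzeneMolecule <- function() {
  ang <- 2 * pi * (0:5) / 6
  rc <- 1.39
  cXYZ <- cbind(rc * cos(ang), rc * sin(ang), 0)
  hXYZ <- cbind((rc + 1.09) * cos(ang), (rc + 1.09) * sin(ang), 0)
  Molecule(
    elements = c(rep("C", 6), rep("H", 6)),
    coords = rbind(cXYZ, hXYZ),
    bonds = rbind(
      data.frame(i = 1:6, j = c(2:6, 1), order = 4L),
      data.frame(i = 1:6, j = 7:12, order = 1L)),
    name = "benzene")
}

.tetrahedralGroup <- function(centralEl, ligEl, bondLen) {
  theta <- acos(-1 / 3)                      # 109.47 degrees from +z
  zc <- bondLen * cos(theta)
  rxy <- bondLen * sin(theta)
  phi <- 2 * pi * (0:2) / 3
  xyz <- rbind(c(0, 0, 0), cbind(rxy * cos(phi), rxy * sin(phi), zc))
  Molecule(elements = c(centralEl, rep(ligEl, 3)), coords = xyz,
           bonds = data.frame(i = 1L, j = 2:4, order = 1L),
           name = paste0(centralEl, ligEl, "3"))
}

#' Built-in toy substituent library
#'
#' Five small substituents with precomputed anchors: H, CH3 (tetrahedral,
#' attachment along +z), NH2 (planar, attachment along +y), OH and F. The
#' single-atom entries (H, F) carry an explicit centroid point since an
#' isolated atom has no bonded neighbours; their orientation is irrelevant
#' at placement time.
#'
#' @return A [SubstituentLibrary-class] with entries H, CH3, NH2, OH, F.
#' @export
fixtureSubstituentLibrary <- function() {
  ch3 <- .tetrahedralGroup("C", "H", 1.09)
  nh2 <- Molecule(c("N", "H", "H"),
                  rbind(c(0, 0, 0), c(0.8, -0.6, 0), c(-0.8, -0.6, 0)),
                  bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L)),
                  name = "NH2")
  oh <- Molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, -0.96, 0)),
                 bonds = data.frame(i = 1L, j = 2L), name = "OH")
  h1 <- Molecule("H", c(0, 0, 0), name = "H")
  f1 <- Molecule("F", c(0, 0, 0), name = "F")
  SubstituentLibrary(
    Substituent("H", h1, 1L, centroidPoint = c(0, 0, -1)),
    Substituent("CH3", ch3, 1L),
    Substituent("NH2", nh2, 1L),
    Substituent("OH", oh, 1L),
    Substituent("F", f1, 1L, centroidPoint = c(0, 0, -1))
  )
}

#' Generate the offline fixture set on disk
#'
#' Writes the three toy skeletons as Molfiles, the substituent library
#' (geometries plus CSV index) and a ready-made 3-step functionalization
#' list per skeleton, so the whole pipeline can be exercised from files
#' without any download. Output is deterministic: two calls with the same
#' seed produce byte-identical files.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed, recorded in the manifest.
#' @return Invisibly, a list of the written paths (`skeletons`,
#'   `libraryCsv`, `libraryDir`, `specs`, `manifest`).
#' @export
generateFixtures <- function(outDir, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  skeletons <- list(toy_macrocycle = toyMacrocycle(),
                    square_planar_template = squarePlanarTemplate(),
                    benzene = benzeneMolecule())
  skelPaths <- character(0)
  for (nm in names(skeletons)) {
    p <- file.path(outDir, paste0(nm, ".mol"))
    writeMolfile(skeletons[[nm]], p)
    skelPaths[nm] <- p
  }
  lib <- fixtureSubstituentLibrary()
  libDir <- file.path(outDir, "substituents")
  csvPath <- file.path(outDir, "substituents.csv")
  writeSubstituentLibrary(lib, csvPath, geometryDir = libDir)
  specPaths <- character(0)
  for (nm in names(skeletons)) {
    spec <- autoFunctionalizationSpec(skeletons[[nm]],
                                      c("CH3", "NH2", "OH"), lib)
    p <- file.path(outDir, paste0(nm, "_spec.csv"))
    utils::write.csv(
      data.frame(b = spec$pairs[, 1], a = spec$pairs[, 2],
                 substituent = spec$substituents),
      p, row.names = FALSE, quote = FALSE)
    specPaths[nm] <- p
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(seed = seed, skeletons = basename(skelPaths),
         substituents = substituentNames(lib),
         specs = basename(specPaths)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(skeletons = skelPaths, libraryCsv = csvPath,
                 libraryDir = libDir, specs = specPaths,
                 manifest = manifest))
}

#' Batch-scale fixture inputs
#'
#' Builds the ingredients of a batch enumeration at the scale of the
#' porphyrin study design: `nSkeletons` variants of the toy macrocycle,
#' each pre-functionalized with one CH3 group after a rigid in-plane
#' rotation of the parent ring (mimicking a family of decorated parent
#' skeletons that share one atom numbering), and `nSets` serial specs of
#' `nSteps` substituents drawn from the library's entries. Because all
#' variants share a topology, each auto-planned spec is valid on every
#' skeleton and the crossed plan enumerates
#' `nSkeletons * nSets * nSteps` structures.
#'
#' @param nSkeletons number of skeleton variants (default 10).
#' @param nSets number of substituent sets (default 4).
#' @param nSteps serial steps per run (default 28).
#' @param relax a [relaxationConfig()] stored in every spec.
#' @return list with `skeletons`, `specs`, `library`.
#' @export
batchFixture <- function(nSkeletons = 10L, nSets = 4L, nSteps = 28L,
                         relax = relaxationConfig()) {
  lib <- fixtureSubstituentLibrary()
  base <- toyMacrocycle()
  skeletons <- vector("list", nSkeletons)
  for (k in seq_len(nSkeletons)) {
    parent <- base
    Rz <- .axisRotation(c(0, 0, 1), (k - 1) * 2 * pi / 37)
    coords(parent) <- coords(base) %*% t(Rz)
    spec0 <- autoFunctionalizationSpec(parent, "CH3", lib)
    parent <- runSerial(parent, spec0, lib)$structures[[1]]
    skeletonMask(parent) <- rep(TRUE, natoms(parent))
    parent@name <- sprintf("skeleton_%02d", k)
    skeletons[[k]] <- parent
  }
  names(skeletons) <- vapply(skeletons, molName, character(1))
  sets <- list(rep("CH3", nSteps),
               rep("NH2", nSteps),
               rep(c("CH3", "OH"), length.out = nSteps),
               rep(c("NH2", "CH3", "OH", "H"), length.out = nSteps))
  specs <- lapply(seq_len(nSets), function(s) {
    subs <- sets[[1 + (s - 1) %% length(sets)]]
    autoFunctionalizationSpec(skeletons[[1]], subs, lib, relax = relax)
  })
  names(specs) <- sprintf("set_%d", seq_len(nSets))
  list(skeletons = skeletons, specs = specs, library = lib)
}
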