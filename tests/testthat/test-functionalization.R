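# Placement engine: rotation alignment, single placements, serial runs
# and batch enumeration arithmetic.

test_that("rotationToAlign maps directions and stays a proper rotation", {
  expect_equal(rotationToAlign(c(0, 0, 1), c(0, 0, 1)), diag(3))

  R <- rotationToAlign(c(1, 0, 0), c(0, 1, 0))
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-10)

  # antiparallel degenerate case: still proper, still maps
  R2 <- rotationToAlign(c(0, 0, 2), c(0, 0, -5))
  expect_equal(det(R2), 1, tolerance = 1e-10)
  expect_equal(as.numeric(R2 %*% c(0, 0, 1)), c(0, 0, -1),
               tolerance = 1e-10)

  set.seed(7)
  for (k in 1:50) {
    vf <- rnorm(3); vt <- rnorm(3)
    R <- rotationToAlign(vf, vt)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
    expect_lt(max(abs(R %*% (vf / sqrt(sum(vf^2))) - vt / sqrt(sum(vt^2)))),
              1e-8)
  }
  expect_error(rotationToAlign(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("identity-like replacement on H2 reproduces the two-atom bond", {
  h2 <- Molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)),
                 bonds = data.frame(i = 1L, j = 2L))
  lib <- fixtureSubstituentLibrary()
  out <- placeSubstituent(h2, c(2L, 1L), getSubstituent(lib, "H"))
  expect_equal(natoms(out), 2L)
  expect_equal(nrow(bonds(out)), 1L)
  expect_equal(sqrt(sum((coords(out)[2, ] - coords(out)[1, ])^2)),
               2 * covalentRadius("H"), tolerance = 1e-10)
})

test_that("methane + CH3 placement obeys count and geometry contracts", {
  m <- methaneMolecule()
  lib <- fixtureSubstituentLibrary()
  ch3 <- getSubstituent(lib, "CH3")
  out <- placeSubstituent(m, c(2L, 1L), ch3)

  # counts: atoms 5 - 1 + 4; bonds 4 - 1 + 3 + 1
  expect_equal(natoms(out), 8L)
  expect_equal(nrow(bonds(out)), 7L)

  # surviving skeleton coordinates are bit-identical, mask split is right
  expect_identical(coords(out)[1:4, ], coords(m)[-2, ])
  expect_identical(skeletonMask(out), c(rep(TRUE, 4), rep(FALSE, 4)))

  # new C-C bond at the covalent-radius sum, along the old a->b ray
  cIdx <- 5L
  d <- sqrt(sum((coords(out)[cIdx, ] - coords(out)[1, ])^2))
  expect_equal(d, 2 * covalentRadius("C"), tolerance = 1e-6)
  uRay <- (coords(m)[2, ] - coords(m)[1, ])
  uRay <- uRay / sqrt(sum(uRay^2))
  uNew <- (coords(out)[cIdx, ] - coords(out)[1, ])
  uNew <- uNew / sqrt(sum(uNew^2))
  expect_equal(uNew, uRay, tolerance = 1e-10)

  # attachment direction of the placed group is antiparallel to a->central
  placedCentroid <- colMeans(coords(out)[6:8, ])
  uAttach <- coords(out)[cIdx, ] - placedCentroid
  uAttach <- uAttach / sqrt(sum(uAttach^2))
  ang <- acos(max(-1, min(1, sum(uAttach * uNew))))
  expect_lt(abs(ang - pi), 1e-6)

  # explicit bond-length policy override
  out2 <- placeSubstituent(m, c(2L, 1L), ch3, bondLength = 1.8)
  expect_equal(sqrt(sum((coords(out2)[5, ] - coords(out2)[1, ])^2)), 1.8,
               tolerance = 1e-10)
})

test_that("invalid functionalization pairs are rejected with context", {
  m <- methaneMolecule()
  lib <- fixtureSubstituentLibrary()
  h <- getSubstituent(lib, "H")
  expect_error(placeSubstituent(m, c(1L, 2L), h), "not terminal")
  expect_error(placeSubstituent(m, c(2L, 3L), h), "not bonded to anchor")
  expect_error(placeSubstituent(m, c(2L, 99L), h), "out of range")
  expect_error(placeSubstituent(m, c(2L, 2L), h), "differ")
})

test_that("torsion scan keeps the placement contracts and reduces clash", {
  ring <- toyMacrocycle()
  lib <- fixtureSubstituentLibrary()
  nh2 <- getSubstituent(lib, "NH2")
  plain <- placeSubstituent(ring, c(13L, 1L), nh2)
  scanned <- placeSubstituent(ring, c(13L, 1L), nh2, torsionScan = TRUE)
  for (out in list(plain, scanned)) {
    expect_identical(coords(out)[1:15, ], coords(ring)[-13, ])
    d <- sqrt(sum((coords(out)[16, ] - coords(out)[1, ])^2))
    expect_equal(d, covalentRadius("C") + covalentRadius("N"),
                 tolerance = 1e-6)
  }
  minNonbonded <- function(mol) {
    subAtoms <- which(!skeletonMask(mol))[-1]  # exclude bonded central
    min(ScaffoldSpace:::.crossDistances(
      coords(mol)[subAtoms, , drop = FALSE],
      coords(mol)[which(skeletonMask(mol)), , drop = FALSE]))
  }
  expect_gte(minNonbonded(scanned) + 1e-9, minNonbonded(plain))
})

test_that("serial runs chain outputs to inputs and stay frozen", {
  ring <- toyMacrocycle()
  lib <- fixtureSubstituentLibrary()

  empty <- functionalizationSpec(matrix(integer(0), ncol = 2),
                                 character(0))
  res0 <- runSerial(ring, empty, lib)
  expect_length(res0$structures, 0L)

  spec <- autoFunctionalizationSpec(ring, c("CH3", "NH2", "OH"), lib)
  res <- runSerial(ring, spec, lib)
  expect_length(res$structures, 3L)
  counts <- vapply(res$structures, natoms, integer(1))
  expect_true(all(diff(c(natoms(ring), counts)) > 0))
  expectFrozenAcrossRun(ring, res, spec)
  expect_equal(nrow(res$log), 3L)
  expect_identical(res$log$substituent, c("CH3", "NH2", "OH"))

  # a pair invalid at its step names the step
  badSpec <- functionalizationSpec(rbind(spec$pairs[1, ], c(1L, 2L)),
                                   c("CH3", "OH"))
  expect_error(runSerial(ring, badSpec, lib), "step 2")
})

test_that("serial runs are deterministic", {
  ring <- squarePlanarTemplate()
  lib <- fixtureSubstituentLibrary()
  spec <- autoFunctionalizationSpec(ring, c("NH2", "CH3"), lib)
  r1 <- runSerial(ring, spec, lib)
  r2 <- runSerial(ring, spec, lib)
  expect_identical(coords(r1$structures[[2]]), coords(r2$structures[[2]]))
  d <- withr::local_tempdir()
  writeMolfile(r1$structures[[2]], file.path(d, "a.mol"))
  writeMolfile(r2$structures[[2]], file.path(d, "b.mol"))
  expect_identical(readLines(file.path(d, "a.mol")),
                   readLines(file.path(d, "b.mol")))
})

test_that("batch plans count every serial intermediate", {
  lib <- fixtureSubstituentLibrary()
  ring <- toyMacrocycle()
  spec3 <- autoFunctionalizationSpec(ring, c("CH3", "NH2", "OH"), lib)
  spec1 <- autoFunctionalizationSpec(ring, "CH3", lib)

  plan <- enumerateBatch(list(a = ring, b = toyMacrocycle()),
                         list(s = spec3))
  expect_equal(attr(plan, "totalStructures"), 6L)
  out <- executeBatch(plan, list(a = ring, b = toyMacrocycle()),
                      list(s = spec3), lib)
  expect_equal(out$count, 6L)
  expect_equal(nrow(out$log), 6L)

  plan1 <- enumerateBatch(list(ring), list(spec1))
  expect_equal(attr(plan1, "totalStructures"), 1L)

  # the porphyrin-style strategy: 10 skeletons x 4 sets x 28 sites
  bf <- batchFixture(nSkeletons = 10L, nSets = 4L, nSteps = 28L)
  planFull <- enumerateBatch(bf$skeletons, bf$specs)
  expect_equal(attr(planFull, "totalStructures"), 1120L)
})

test_that("batch output files follow the step-indexed naming", {
  lib <- fixtureSubstituentLibrary()
  ring <- toyMacrocycle()
  spec <- autoFunctionalizationSpec(ring, c("CH3", "NH2"), lib)
  plan <- enumerateBatch(list(ring = ring), list(s1 = spec))
  d <- withr::local_tempdir()
  out <- executeBatch(plan, list(ring = ring), list(s1 = spec), lib,
                      outDir = d, keepStructures = FALSE)
  expect_setequal(list.files(d),
                  c("ring_s1_func_01.mol", "ring_s1_func_02.mol"))
  back <- readMolfile(file.path(d, "ring_s1_func_02.mol"))
  expect_equal(natoms(back), natoms(ring) - 2L + 4L + 3L)
})
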