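# Superposition, heavy-atom RMSD, batch statistics, trend fitting and
# reaction-energy arithmetic.

test_that("superposition is exact on rigidly moved copies", {
  set.seed(3)
  P <- matrix(rnorm(15), 5, 3)
  res <- kabschAlign(P, P)
  expect_equal(alignRmsd(res), 0, tolerance = 1e-10)
  expect_equal(alignRotation(res), diag(3), tolerance = 1e-8)

  shifted <- sweep(P, 2, c(5, 5, 5), "+")
  expect_equal(alignRmsd(kabschAlign(P, shifted)), 0, tolerance = 1e-10)
  expect_equal(alignRmsd(quaternionAlign(P, shifted)), 0, tolerance = 1e-10)

  expect_error(kabschAlign(P, P[1:3, ]), "differ in size")
})

test_that("Kabsch and quaternion routes agree on random point sets", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- P %*% t(randomRotation()) + matrix(rnorm(3 * n, sd = 0.1), n, 3)
    rk <- alignRmsd(kabschAlign(P, Q))
    rq <- alignRmsd(quaternionAlign(P, Q))
    expect_lt(abs(rk - rq), 1e-8)
    # the transform reported actually achieves the reported rmsd
    res <- kabschAlign(P, Q)
    mapped <- P %*% t(alignRotation(res)) +
      matrix(alignTranslation(res), n, 3, byrow = TRUE)
    expect_equal(sqrt(sum((mapped - Q)^2) / n), rk, tolerance = 1e-10)
  }
})

test_that("Kabsch never loses to a 10-degree brute-force rotation grid", {
  set.seed(202)
  for (k in 1:4) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- P %*% t(randomRotation()) + matrix(rnorm(12, sd = 0.15), 4, 3)
    expect_lte(alignRmsd(kabschAlign(P, Q)), gridMinRmsd(P, Q) + 1e-3)
  }
})

test_that("degenerate collinear points still yield a proper rotation", {
  P <- cbind(0:3, 0, 0)
  Q <- cbind(0, 0:3, 0)
  for (res in list(kabschAlign(P, Q), quaternionAlign(P, Q))) {
    R <- alignRotation(res)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
    expect_equal(alignRmsd(res), 0, tolerance = 1e-8)
  }
})

test_that("hrmsd strips hydrogens and honours the reorder flag", {
  ring <- toyMacrocycle()
  expect_equal(hrmsd(ring, ring), 0, tolerance = 1e-10)

  # permuting heavy atoms of an asymmetric molecule: index-matched
  # correspondence sees a difference, assignment-based reordering
  # recovers zero (a cyclic shift of the bare symmetric ring would not:
  # that permutation is realizable by a rotation)
  set.seed(12)
  asym <- Molecule(c("C", "C", "N", "O", "C", "H"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0.2),
                         c(-0.8, 1.0, -0.4), c(0.3, -1.5, 0.6),
                         c(5, 5, 5)))
  perm <- c(2, 1, 3, 4, 5, 6)              # swap the two inequivalent C
  permuted <- Molecule(elements(asym)[perm], coords(asym)[perm, ],
                       name = "permuted")
  expect_gt(hrmsd(asym, permuted, reorder = FALSE), 0.1)
  expect_equal(hrmsd(asym, permuted, reorder = TRUE), 0, tolerance = 1e-8)

  expect_error(hrmsd(ring, methaneMolecule()), "heavy-atom counts differ")
  co2 <- Molecule(c("C", "O", "O"),
                  rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.16, 0, 0)))
  cs2 <- Molecule(c("C", "S", "S"),
                  rbind(c(0, 0, 0), c(1.55, 0, 0), c(-1.55, 0, 0)))
  expect_error(hrmsd(co2, cs2, reorder = TRUE), "element multisets")
})

test_that("hrmsd equals direct formula evaluation on toy conformers", {
  # two hand-built 5-heavy-atom conformers (plus hydrogens that must be
  # ignored); oracle: direct sqrt(mean squared deviation) minimised over
  # the 10-degree rotation grid after centering
  A <- Molecule(c("C", "C", "O", "N", "C", "H", "H"),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                      c(-0.7, 1.2, 0.4), c(0.4, -1.4, 0.3),
                      c(3.0, 3.0, 1.0), c(-2.0, -2.0, -1.0)))
  B <- Molecule(c("C", "C", "O", "N", "C", "H", "H"),
                rbind(c(0.1, 0.0, 0.1), c(1.4, 0.3, -0.1),
                      c(2.3, 1.0, 0.5), c(-0.8, 1.1, 0.2),
                      c(0.5, -1.5, 0.1),
                      c(3.0, 3.0, 1.0), c(-2.0, -2.0, -1.0)))
  heavyA <- coords(A)[1:5, ]
  heavyB <- coords(B)[1:5, ]
  got <- hrmsd(A, B)
  # optimal superposition beats any rotation on the coarse 10-degree grid
  expect_lte(got, gridMinRmsd(heavyA, heavyB) + 1e-9)
  # and the refined brute-force search pins the value to 1e-3
  expect_lt(abs(got - refinedMinRmsd(heavyA, heavyB)), 1e-3)

  # hrmsd with alignment disabled is the raw index-matched deviation
  raw <- sqrt(sum((heavyA - heavyB)^2) / 5)
  expect_equal(hrmsd(A, B, align = FALSE), raw, tolerance = 1e-12)
})

test_that("hrmsd is symmetric and rigid-motion invariant", {
  # two genuinely different conformers of one heavy-atom skeleton
  ring <- toyMacrocycle()
  bent <- ring
  xyz <- coords(ring)
  xyz[1, 3] <- xyz[1, 3] + 0.4              # pucker one ring atom
  coords(bent) <- xyz
  base <- hrmsd(ring, bent)
  expect_gt(base, 0.01)
  set.seed(5)
  for (k in 1:5) {
    R <- randomRotation(); t <- rnorm(3, sd = 4)
    moved <- Molecule(elements(ring),
                      sweep(coords(ring) %*% t(R), 2, t, "+"))
    expect_lt(abs(hrmsd(moved, bent) - base), 1e-8)
  }
  expect_lt(abs(hrmsd(ring, bent) - hrmsd(bent, ring)), 1e-8)
})

test_that("Hungarian assignment matches brute-force permutation search", {
  set.seed(9)
  for (n in c(2, 3, 4, 5)) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n), n, n)
      got <- ScaffoldSpace:::.solveAssignment(cost)
      oracle <- bruteForceAssignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), got)]), oracle$cost,
                   tolerance = 1e-12)
    }
  }
})

test_that("rmsd summaries report mean, population sd, max and n", {
  s <- rmsdSummary(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  expect_equal(s$max, 1); expect_equal(s$n, 3L)
  s2 <- rmsdSummary(c(0, 2))
  expect_equal(s2$mean, 1); expect_equal(s2$max, 2)
  expect_equal(s2$sd, 1)
  expect_error(rmsdSummary(numeric(0)), "nonempty")
})

test_that("trend fit recovers constructed and planted slopes", {
  exact <- data.frame(N = 0:27, hrmsd = 0.05 * (0:27))
  fit <- rmsdTrendFit(exact, threshold = 1.0)
  expect_equal(fit$slope, 0.05, tolerance = 1e-10)
  expect_equal(fit$rSquared, 1, tolerance = 1e-10)
  expect_equal(fit$predictedThresholdStep, 20L)

  flat <- data.frame(N = 0:10, hrmsd = rep(0.3, 11))
  fitFlat <- rmsdTrendFit(flat, threshold = 1.0)
  expect_equal(fitFlat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(fitFlat$predictedThresholdStep))

  set.seed(77)
  noisy <- data.frame(N = 0:27,
                      hrmsd = 0.04 * (0:27) + rnorm(28, sd = 0.02))
  fitNoisy <- rmsdTrendFit(noisy)
  expect_lt(abs(fitNoisy$slope - 0.04), 0.01)

  expect_error(rmsdTrendFit(exact[1:2, ]), "at least 3")
})

test_that("directory comparison matches stems and summarises", {
  lib <- fixtureSubstituentLibrary()
  ring <- toyMacrocycle()
  spec <- autoFunctionalizationSpec(ring, c("CH3", "NH2"), lib)
  run <- runSerial(ring, spec, lib)
  dA <- withr::local_tempdir(); dB <- withr::local_tempdir()
  for (k in 1:2) {
    writeMolfile(run$structures[[k]], file.path(dA, sprintf("s%02d.mol", k)))
    jig <- run$structures[[k]]
    coords(jig) <- coords(jig) + 0.01       # rigid shift: hrmsd stays 0
    writeMolfile(jig, file.path(dB, sprintf("s%02d.mol", k)))
  }
  cmp <- compareDirectories(dA, dB)
  expect_equal(nrow(cmp), 2L)
  expect_lt(max(cmp$hrmsd), 1e-3)           # Molfile stores 4 decimals
  expect_equal(attr(cmp, "summary")$n, 2L)
})

test_that("reaction energies and ddE follow the bookkeeping contracts", {
  expect_equal(reactionEnergy(0, 0, 0), 0)
  expect_equal(reactionEnergy(-10, -4, -4), -2)
  # hartree inputs convert with the fixed constant
  expect_equal(reactionEnergy(-0.01, 0, 0, unit = "hartree"),
               -0.01 * 627.5094740631, tolerance = 1e-9)
  expect_error(reactionEnergy(1, 1, 1, levels = c("dft", "dft", "ff")),
               "mixed level")

  expect_equal(ddE(10.0, 2.8), 7.2)
  expect_equal(ddE(5, 5), 0)
  expect_equal(ddE(3, 7), -ddE(7, 3))      # antisymmetric
  s <- ddESummary(c(10, 12, 8), c(2.8, 4.8, 0.8))
  expect_equal(s$mean, 7.2, tolerance = 1e-12)
  expect_equal(s$n, 3L)

  # linearity in each argument
  expect_equal(reactionEnergy(4, 1, 1) + reactionEnergy(2, 0, 0),
               reactionEnergy(6, 1, 1))
})
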