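# XYZ / Molfile readers and writers, and covalent-radius bond perception.

test_that("XYZ files round-trip coordinates and atom order", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "lone hydrogen", "H 0 0 0"), f)
  m <- readXYZ(f)
  expect_equal(natoms(m), 1L)
  expect_equal(nrow(bonds(m)), 0L)
  expect_true(all(skeletonMask(m)))

  water <- Molecule(c("O", "H", "H"),
                    rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0)),
                    name = "water")
  g <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(water, g)
  back <- readXYZ(g)
  expect_identical(elements(back), elements(water))
  expect_equal(coords(back), coords(water), tolerance = 1e-4)
  expect_equal(nrow(bonds(back)), 0L)
  expect_equal(nrow(bonds(perceiveBonds(back))), 2L)

  empty <- Molecule(character(0), matrix(numeric(0), ncol = 3))
  e <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(empty, e)
  expect_equal(readLines(e)[1], "0")
  expect_equal(natoms(readXYZ(e)), 0L)
})

test_that("malformed XYZ input raises errors naming the line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("abc", "", "H 0 0 0"), f)
  expect_error(readXYZ(f), "line 1.*atom count")
  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(readXYZ(f), "line 3.*unknown element")
  writeLines(c("1", "", "H 0 zero 0"), f)
  expect_error(readXYZ(f), "line 3.*coordinate")
})

test_that("Molfile round-trips preserve atoms, bonds, orders and charges", {
  m <- methaneMolecule()
  m@charges <- c(0L, 0L, -1L, 0L, 1L)
  f <- withr::local_tempfile(fileext = ".mol")
  writeMolfile(m, f)
  r1 <- readMolfile(f)
  expect_identical(elements(r1), elements(m))
  expect_equal(coords(r1), coords(m), tolerance = 1e-4)
  expect_identical(bonds(r1), bonds(m))
  expect_identical(formalCharges(r1), formalCharges(m))

  # read(write(read(f))) identical to read(f)
  g <- withr::local_tempfile(fileext = ".mol")
  writeMolfile(r1, g)
  r2 <- readMolfile(g)
  expect_identical(elements(r2), elements(r1))
  expect_identical(coords(r2), coords(r1))
  expect_identical(bonds(r2), bonds(r1))
  expect_identical(formalCharges(r2), formalCharges(r1))

  # aromatic order 4 survives
  benz <- benzeneMolecule()
  writeMolfile(benz, f)
  expect_identical(bonds(readMolfile(f)), bonds(benz))
})

test_that("Molfile writer emits the fixed-width V2000 dialect", {
  m <- Molecule(c("C", "H", "H"),
                rbind(c(0, 0, 0), c(1.09, 0, 0), c(-1.09, 0, 0)),
                bonds = data.frame(i = 1L, j = 2:3),
                charges = c(0L, 0L, -1L))
  f <- withr::local_tempfile(fileext = ".mol")
  writeMolfile(m, f)
  lines <- readLines(f)
  expect_match(lines[4], "^  3  2.*V2000$")
  expect_true("M  CHG  1   3  -1" %in% lines)
  expect_identical(lines[length(lines)], "M  END")

  bondless <- Molecule("He", c(0, 0, 0))
  writeMolfile(bondless, f)
  expect_match(readLines(f)[4], "^  1  0")
})

test_that("unsupported or corrupt Molfiles are rejected with context", {
  f <- withr::local_tempfile(fileext = ".mol")
  writeLines(c("x", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000"), f)
  expect_error(readMolfile(f), "V3000")
  writeLines(c("x", "", "",
               "  1  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  9  1  0", "M  END"), f)
  expect_error(readMolfile(f), "out of range")
  big <- Molecule(rep("C", 1000),
                  cbind(seq_len(1000) * 2, 0, 0))
  expect_error(writeMolfile(big, f), "999")
})

test_that("bond perception follows the covalent-radius threshold", {
  # H2 at 0.74 A: threshold 1.15*(0.31+0.31) = 0.713 < 0.74 -> no bond,
  # while 1.25 * 0.62 = 0.775 -> bond appears
  h2 <- Molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(bonds(perceiveBonds(h2, tolerance = 1.15))), 0L)
  expect_equal(nrow(bonds(perceiveBonds(h2, tolerance = 1.25))), 1L)

  far <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(bonds(perceiveBonds(far))), 0L)

  # methane: brute force over all 10 pairs against the radius sums
  m <- methaneMolecule()
  bare <- Molecule(elements(m), coords(m))
  got <- bonds(perceiveBonds(bare))
  r <- covalentRadius(elements(m))
  expected <- 0L
  for (i in 1:4) for (j in (i + 1):5) {
    d <- sqrt(sum((coords(m)[i, ] - coords(m)[j, ])^2))
    if (d <= 1.15 * (r[i] + r[j])) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
  expect_equal(nrow(got), 4L)             # C-H only, no H-H
  expect_true(all(got$i == 1L))
})

test_that("bond perception is idempotent and order-independent", {
  m <- perceiveBonds(Molecule(elements(methaneMolecule()),
                              coords(methaneMolecule())))
  again <- perceiveBonds(m)
  expect_identical(bonds(again), bonds(m))
  # reversing atom order perceives the same bond set (relabelled)
  rev <- Molecule(rev(elements(methaneMolecule())),
                  coords(methaneMolecule())[5:1, ])
  b2 <- bonds(perceiveBonds(rev))
  remap <- function(ix) 6L - ix
  key1 <- sort(paste(pmin(bonds(m)$i, bonds(m)$j),
                     pmax(bonds(m)$i, bonds(m)$j)))
  key2 <- sort(paste(pmin(remap(b2$i), remap(b2$j)),
                     pmax(remap(b2$i), remap(b2$j))))
  expect_identical(key1, key2)
  expect_error(perceiveBonds(Molecule("H", c(0, 0, 0), name = "x")),
               NA)
})

test_that("Molecule validity rejects inconsistent objects", {
  expect_error(Molecule(c("C", "C"), rbind(c(0, 0, 0), c(0.1, 0, 0))),
               "apart")
  expect_error(
    Molecule(c("C", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
             bonds = data.frame(i = 1L, j = 3L)),
    "out of range")
  expect_error(
    Molecule(c("C", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
             bonds = data.frame(i = c(1L, 2L), j = c(2L, 1L))),
    "duplicate")
})
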