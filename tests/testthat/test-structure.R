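minimal_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134   2.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      12.560   6.351   2.100  1.00 20.00           C",
    "ATOM      3  C   ALA A   1      13.000   7.800   2.200  1.00 20.00           C",
    "END")
  writeLines(lines, path)
  path
}

test_that("PDB structures read with exact coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  minimal_pdb(f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(st$atoms$x, c(11.104, 12.560, 13.000))
  expect_equal(st$atoms$element, c("N", "C", "C"))
  expect_equal(st$atoms$name, c("N", "CA", "C"))
})

test_that("altloc resolution keeps the highest-occupancy copy, waters drop", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60 20.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40 20.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00 20.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00 20.00           O",
    "HETATM    5  C1  EST A 201       6.000   6.000   6.000  1.00 20.00           C",
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 2L)          # one CA kept, water+het dropped
  expect_equal(st$atoms$x[st$atoms$resno == 1], 1.000)
  st2 <- read_structure(f, keep_heteroatoms = TRUE)
  expect_true("EST" %in% st2$atoms$resid)
  expect_false("HOH" %in% st2$atoms$resid)
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty))
})

test_that("unknown elements need an explicit default radius", {
  expect_error(paleoprot:::atom_radii(c("C", "ZZ")), "ZZ")
  expect_equal(paleoprot:::atom_radii(c("C", "ZZ"), default_radius = 1.6),
               c(1.70, 1.60))
  expect_equal(unname(vdw_radii(0.2)["C"]), 1.90)
})

test_that("superposition recovers a known rigid transform", {
  sta <- synthetic_chain()
  expect_lt(superpose(sta, sta, "CA")$rmsd, 1e-6)
  R <- random_rotations(2, seed = 99)[[2]]
  stb <- transform_structure(sta, R, c(5, -3, 11))
  for (scope in c("CA", "backbone", "all-common")) {
    s <- superpose(sta, stb, scope)
    expect_lt(s$rmsd, 1e-6)
    expect_lt(max(abs(s$rotation - R)), 1e-6)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(as.numeric(s$translation) - c(5, -3, 11))), 1e-6)
  }
  # rmsd is invariant under pre-rotation of either structure
  R2 <- random_rotations(2, seed = 123)[[2]]
  noisy <- sta
  withr::with_seed(8, {
    noisy$atoms[, c("x", "y", "z")] <-
      noisy$atoms[, c("x", "y", "z")] + matrix(stats::rnorm(90, 0, 0.3), ncol = 3)
  })
  r_plain <- superpose(noisy, stb, "CA")$rmsd
  r_rot <- superpose(transform_structure(noisy, R2), stb, "CA")$rmsd
  expect_equal(r_plain, r_rot, tolerance = 1e-8)
})

test_that("superposition rmsd agrees with an independent implementation", {
  sta <- synthetic_chain()
  stb <- transform_structure(sta, random_rotations(2, seed = 17)[[2]],
                             c(2, 7, -4))
  withr::with_seed(18, {
    stb$atoms[, c("x", "y", "z")] <- stb$atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(90, 0, 0.5), ncol = 3)
  })
  mine <- superpose(sta, stb, "all-common")$rmsd
  xa <- as.numeric(t(as.matrix(sta$atoms[, c("x", "y", "z")])))
  xb <- as.numeric(t(as.matrix(stb$atoms[, c("x", "y", "z")])))
  theirs <- bio3d::rmsd(xa, xb, fit = TRUE)   # bio3d rounds to 3 decimals
  expect_equal(mine, theirs, tolerance = 1e-3)
})

test_that("degenerate superposition inputs are rejected", {
  line <- synthetic_chain()
  line$atoms$y <- 0; line$atoms$z <- 0       # collinear
  expect_error(superpose(line, line, "CA"), "collinear")
  tiny <- synthetic_chain()
  tiny$atoms <- tiny$atoms[tiny$atoms$resno == 1, ]
  tiny$atoms <- tiny$atoms[tiny$atoms$name == "CA", ]
  expect_error(superpose(tiny, tiny, "CA"), "fewer than 3")
})
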