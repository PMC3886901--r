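# A single committed shell fixture shared across cavity tests (building it
# validates probe-tightness by construction).
shell_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_structure(r_cav = 4, n_decoys = 12,
                                                     seed = 7)
    cache
  }
})

test_that("a compact solid cluster has no cavity", {
  withr::with_seed(2, {
    blob <- structure(list(atoms = data.frame(
      element = "C", name = "CB", resid = "BLB", resno = 1:10, chain = "A",
      x = stats::rnorm(10), y = stats::rnorm(10), z = stats::rnorm(10),
      occupancy = 1, type = "ATOM"), source = "blob"),
      class = "protein_structure")
  })
  cav <- cavity_volume(blob, cavity_params(n_orientations = 3, seed = 1))
  expect_true(cav$no_cavity)
  expect_equal(cav$mean, 0)
})

test_that("shell cavity volume matches the analytic sphere within 5%", {
  toy <- shell_fixture()
  cav <- cavity_volume(toy, cavity_params(grid_spacing = 0.5,
                                          n_orientations = 10, seed = 7))
  expect_lt(abs(cav$mean - toy$analytic_volume) / toy$analytic_volume, 0.05)
  expect_equal(cav$mean, mean(cav$volumes))
  expect_equal(cav$sd, stats::sd(cav$volumes))
  expect_true(all(cav$volumes >= 0))
  # a fixed pre-rotation changes the estimate by no more than the
  # orientation scatter it reports
  rot <- random_rotations(2, seed = 31)[[2]]
  cav_rot <- cavity_volume(transform_structure(toy$structure, rot),
                           cavity_params(grid_spacing = 0.5,
                                         n_orientations = 1))
  expect_lt(abs(cav_rot$mean - cav$mean), 5 * cav$sd + 1e-9)
})

test_that("grid refinement converges on the shell fixture", {
  toy <- shell_fixture()
  v <- vapply(c(0.5, 0.35, 0.25), function(h)
    cavity_volume(toy, cavity_params(grid_spacing = h,
                                     n_orientations = 3, seed = 7))$mean,
    numeric(1))
  # all refinements stay within the calibration band of the analytic value
  expect_true(all(abs(v - toy$analytic_volume) / toy$analytic_volume < 0.05))
  expect_lt(max(v) - min(v), 0.02 * toy$analytic_volume)
})

test_that("filler atoms monotonically shrink the cavity down to zero", {
  vols <- vapply(c(0, 5, 15, 60), function(nf) {
    toy <- make_toy_structure(r_cav = 4, n_filler = nf, seed = 7)
    cavity_volume(toy, cavity_params(grid_spacing = 0.5,
                                     n_orientations = 3, seed = 7))$mean
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_lt(vols[2], vols[1])            # strict decrease with filler
  expect_equal(vols[4], 0)
  # the analytic bound from the generator is an upper bound
  toy5 <- make_toy_structure(r_cav = 4, n_filler = 5, seed = 7)
  expect_lte(vols[2], toy5$analytic_volume_bound + 2)
})

test_that("molecular volume integrates unions of spheres", {
  one <- structure(list(atoms = data.frame(
    element = "C", name = "CB", resid = "X", resno = 1L, chain = "A",
    x = 0, y = 0, z = 0, occupancy = 1, type = "ATOM"), source = "one"),
    class = "protein_structure")
  v1 <- molecular_volume(one, cavity_params(grid_spacing = 0.3,
                                            n_orientations = 1))
  expect_lt(abs(v1$mean - 4 / 3 * pi * 1.7^3) / (4 / 3 * pi * 1.7^3), 0.02)
  two <- one; two$atoms <- rbind(one$atoms, one$atoms)   # fully overlapping
  v2 <- molecular_volume(two, cavity_params(grid_spacing = 0.3,
                                            n_orientations = 1))
  expect_equal(v2$mean, v1$mean)
  expect_error(molecular_volume(
    structure(list(atoms = one$atoms[0, ], source = "empty"),
              class = "protein_structure")), "empty")
})

test_that("pocket lining finds shell pseudo-residues and no decoys", {
  toy <- shell_fixture()
  cav <- cavity_volume(toy, cavity_params(n_orientations = 1))
  pl <- pocket_lining_residues(toy, cav, cutoff = 3.5)
  expect_gt(nrow(pl), 0)
  expect_true(all(pl$chain == "A"))
  expect_false(any(pl$resid == "DEC"))
  expect_true(all(diff(pl$min_distance) >= 0))      # sorted by distance
  expect_equal(nrow(pocket_lining_residues(toy, cav, cutoff = 0)), 0L)
})

test_that("candidate context flags pocket-proximal events only", {
  toy <- shell_fixture()
  cav <- cavity_volume(toy, cavity_params(n_orientations = 1))
  shell_res <- toy$structure$atoms$resno[toy$structure$atoms$chain == "A"][1]
  decoy_res <- toy$structure$atoms$resno[toy$structure$atoms$chain == "D"][1]
  ev <- data.frame(column = c(1L, 2L, 3L),
                   ancestral_state = c("L", "A", "H"),
                   derived_state = c("F", "W", "F"),
                   reference_number = c(shell_res, decoy_res, 9999L))
  ctx <- candidate_structural_context(ev, toy, cavity = cav, cutoff = 5)
  expect_true(ctx$pocket_proximal[1])
  expect_false(ctx$pocket_proximal[2])
  expect_gt(ctx$min_distance[2], 5)
  expect_true(ctx$unmapped[3])
  expect_false(ctx$pocket_proximal[3])
})
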