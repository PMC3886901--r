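test_that("simulation is seed-deterministic and leaves caller RNG alone", {
  m <- fixture_model()
  tr <- make_fixture_tree(6, 0.2, "balanced", seed = 1)
  withr::with_seed(500, before <- stats::runif(1))
  withr::with_seed(500, {
    stats::runif(0)
    s1 <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0.1), 50, seed = 9)
    after <- stats::runif(1)
  })
  expect_equal(after, before)            # RNG state untouched
  s2 <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0.1), 50, seed = 9)
  expect_identical(s1$alignment$matrix, s2$alignment$matrix)
  expect_identical(s1$ancestral, s2$ancestral)
  s3 <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0.1), 50, seed = 10)
  expect_false(identical(s1$alignment$matrix, s3$alignment$matrix))
})

test_that("zero branch lengths copy the root everywhere", {
  m <- fixture_model()
  tr <- make_fixture_tree(5, 0.2, "caterpillar", seed = 2)
  tr$edge.length[] <- 0
  sim <- simulate_alignment(tr, m, site_rate_model(1, 1, 0), 40, seed = 3)
  root_seq <- sim$ancestral[1, ]
  for (i in seq_len(nrow(sim$alignment$matrix)))
    expect_equal(unname(sim$alignment$matrix[i, ]), unname(root_seq))
})

test_that("invariant-class sites are identical across all nodes", {
  m <- fixture_model()
  tr <- make_fixture_tree(6, 0.3, "balanced", seed = 4)
  sim <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0.5), 200, seed = 5)
  inv_sites <- which(sim$site_class == 1L)
  expect_gt(length(inv_sites), 20)
  all_rows <- rbind(sim$alignment$matrix, sim$ancestral)
  for (s in inv_sites)
    expect_equal(length(unique(all_rows[, s])), 1L)
})

test_that("long-branch child frequencies relax to the stationary law", {
  m <- fixture_model()
  tr <- ape::read.tree(text = "(A:50,B:50);")
  sim <- simulate_alignment(tr, m, site_rate_model(1, 1, 0), 10000, seed = 11)
  counts <- table(factor(sim$alignment$matrix["A", ],
                         levels = aa_alphabet()$symbols))
  p <- stats::chisq.test(as.numeric(counts), p = as.numeric(m$pi))$p.value
  expect_gt(p, 0.001)
})

test_that("fixture trees have the requested shape and branch scale", {
  tr <- make_fixture_tree(4, 0.1, "balanced", seed = 6)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_equal(sort(unlist(node_clades(tr)[["6"]])), c("A", "B"))
  expect_identical(ape::write.tree(make_fixture_tree(4, 0.1, "balanced", 6)),
                   ape::write.tree(tr))
  cat_tree <- make_fixture_tree(7, 0.1, "caterpillar", seed = 6)
  expect_equal(cat_tree$Nnode, 6L)       # comb topology
  big <- make_fixture_tree(30, 0.1, "balanced", seed = 7)
  expect_equal(length(big$tip.label), 30L)
  draws <- make_fixture_tree(26, 0.1, "balanced", seed = 8)$edge.length
  expect_lt(abs(mean(draws) - 0.1) / 0.1, 0.3)
  expect_error(make_fixture_tree(1), "n_taxa")
})

test_that("toy structures are reproducible and carry their analytic volume", {
  t1 <- make_toy_structure(r_cav = 4, n_filler = 3, n_decoys = 5, seed = 12)
  t2 <- make_toy_structure(r_cav = 4, n_filler = 3, n_decoys = 5, seed = 12)
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  expect_equal(t1$analytic_volume, 4 / 3 * pi * 64, tolerance = 1e-12)
  expect_equal(round(t1$analytic_volume, 2), 268.08)
  expect_lt(t1$analytic_volume_bound, t1$analytic_volume)
  expect_error(make_toy_structure(r_cav = 1), "probe")
})

test_that("simulated fixtures survive the external formats round trip", {
  m <- fixture_model()
  tr <- make_fixture_tree(6, 0.15, "balanced", seed = 13)
  sim <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0), 80, seed = 14)
  fa <- withr::local_tempfile(fileext = ".fasta")
  nw <- withr::local_tempfile(fileext = ".nwk")
  seqs <- apply(sim$alignment$matrix, 1L, paste, collapse = "")
  write_fasta(seqs, fa)
  ape::write.tree(tr, nw)
  aln2 <- read_alignment(fa)
  tr2 <- read_tree(nw)
  expect_identical(aln2$matrix[sim$alignment$names, ], sim$alignment$matrix)
  expect_equal(total_log_likelihood(tr2, aln2, m, site_rate_model(0.7, 4, 0)),
               total_log_likelihood(tr, sim$alignment, m,
                                    site_rate_model(0.7, 4, 0)),
               tolerance = 1e-8)
})
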