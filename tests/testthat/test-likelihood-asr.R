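test_that("pruning likelihood matches closed forms", {
  m <- fixture_model()
  alpha <- aa_alphabet()$symbols
  # two taxa joined through the root: log[pi_a P_ab(t1 + t2)]
  tr <- ape::read.tree(text = "(A:0.2,B:0.35);")
  aln <- alignment_from_matrix(matrix(c("L", "F"), 2, 1,
                                      dimnames = list(c("A", "B"), NULL)))
  ia <- match("L", alpha); ib <- match("F", alpha)
  expect_equal(total_log_likelihood(tr, aln, m),
               log(m$pi[[ia]] * transition_matrix(m, 0.55)[ia, ib]),
               tolerance = 1e-12)
  # zero branches, identical sequences: sum of log stationary frequencies
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  states <- c("A", "W", "C")
  aln0 <- alignment_from_matrix(
    matrix(rep(states, each = 3), 3, 3,
           dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(total_log_likelihood(tr0, aln0, m),
               sum(log(m$pi[match(states, alpha)])), tolerance = 1e-12)
})

test_that("likelihood and posteriors equal exhaustive enumeration", {
  m <- fixture_model()
  cases <- expand.grid(n_taxa = c(3, 4, 5), k = c(1, 4),
                       p_inv = c(0, 0.2))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n_taxa[i]
    tr <- random_test_tree(n, seed = 100 + i)
    aln <- random_alignment(tr$tip.label, 3, seed = 200 + i,
                            gap_at = cbind(1, 2))    # one gap cell
    rates <- site_rate_model(0.6, cases$k[i], cases$p_inv[i])
    expect_equal(total_log_likelihood(tr, aln, m, rates),
                 oracle_total_loglik(tr, aln, m, rates), tolerance = 1e-9)
    node <- length(tr$tip.label) + 2L
    rec <- marginal_posteriors(tr, aln, m, rates, node)
    enc <- encode_alignment(aln)[tr$tip.label, , drop = FALSE]
    for (s in 1:3) {
      expect_equal(sum(rec$posterior[s, ]), 1, tolerance = 1e-9)
      expect_equal(unname(rec$posterior[s, ]),
                   unname(oracle_marginal_posterior(tr, enc[, s], m, rates,
                                                    node)),
                   tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant to root placement", {
  m <- fixture_model()
  tr <- random_test_tree(6, seed = 77)
  aln <- random_alignment(tr$tip.label, 5, seed = 78)
  rates <- site_rate_model(0.6, 4, 0.2)
  ll <- total_log_likelihood(tr, aln, m, rates)
  expect_equal(total_log_likelihood(ape::unroot(tr), aln, m, rates), ll,
               tolerance = 1e-8)
  for (og in c("t1", "t3")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(total_log_likelihood(rerooted, aln, m, rates), ll,
                 tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  m <- fixture_model()
  tr <- random_test_tree(8, seed = 5)
  sim <- simulate_alignment(tr, m, site_rate_model(0.8, 4, 0.15), 120,
                            seed = 6)
  pd <- phangorn::phyDat(sim$alignment$matrix, type = "AA")
  bf <- as.numeric(m$pi[toupper(attr(pd, "levels"))])
  fit <- phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 0.8,
                       inv = 0.15, bf = bf)
  expect_equal(total_log_likelihood(tr, sim$alignment, m,
                                    site_rate_model(0.8, 4, 0.15)),
               fit$logLik, tolerance = 1e-6)
})

test_that("a node adjacent to a leaf through a near-zero branch copies it", {
  m <- fixture_model()
  tr <- ape::read.tree(text = "((A:1e-9,B:0.4):0.3,C:0.5);")
  aln <- random_alignment(c("A", "B", "C"), 20, seed = 9)
  rec <- marginal_posteriors(tr, aln, m, site_rate_model(1, 4, 0.1),
                             clade_node(tr, c("A", "B")))
  leaf_states <- aln$matrix["A", ]
  pp_on_leaf <- rec$posterior[cbind(seq_len(20), match(leaf_states,
                                                       aa_alphabet()$symbols))]
  expect_true(all(pp_on_leaf >= 0.999))
  expect_equal(ml_sequence(rec), paste(leaf_states, collapse = ""))
})

test_that("posterior-derived sequences follow their contracts", {
  # argmax with alphabetical tie-break
  post <- matrix(0, 3, 20)
  post[1, c(1, 2)] <- 0.5                      # exact A/C tie -> A
  post[2, c(10, 5)] <- c(0.80, 0.20)           # L 0.8, F 0.2
  post[3, c(10, 5)] <- c(0.70, 0.30)           # L 0.7, F 0.3
  rec <- fake_reconstruction(post)
  expect_equal(ml_sequence(rec), "ALL")
  expect_equal(rec$ml_pp, c(0.5, 0.8, 0.7))
  expect_true(all(rec$ml_pp >= rec$runner_up_pp))
  # AltAll: runner-up only where strictly above threshold
  expect_equal(altall_sequence(rec, 0.25), "CLF")
  expect_equal(altall_sequence(rec, 0.5), "ALL")   # no strict exceedance
  expect_error(altall_sequence(rec, 0), "threshold")
  # summary arithmetic
  s <- reconstruction_summary(rec, sites = 2:3, threshold = 0.25)
  expect_equal(s$mean_pp, 0.75)
  expect_equal(s$n_ambiguous, 1L)
  expect_error(reconstruction_summary(rec, sites = integer(0)), "empty")
})

test_that("altall differs from ml exactly at flagged sites end to end", {
  m <- fixture_model()
  tr <- make_fixture_tree(8, 0.15, "balanced", seed = 3)
  sim <- simulate_alignment(tr, m, site_rate_model(0.7, 4, 0), 300, seed = 4)
  rec <- marginal_posteriors(tr, sim$alignment, m, site_rate_model(0.7, 4, 0),
                             clade_node(tr, LETTERS[1:4]))
  mlv <- strsplit(ml_sequence(rec), "")[[1]]
  aav <- strsplit(altall_sequence(rec, 0.25), "")[[1]]
  expect_identical(which(mlv != aav),
                   which(rec$runner_up_pp > 0.25))
  expect_identical(aav[mlv != aav], rec$runner_up_state[mlv != aav])
})

test_that("optimization improves from a wrong start and is stationary at a fit", {
  m <- fixture_model()
  tr <- make_fixture_tree(6, 0.15, "caterpillar", seed = 21)
  sim <- simulate_alignment(tr, m, site_rate_model(0.5, 4, 0), 250, seed = 22)
  fit <- optimize_parameters(tr, sim$alignment, m, site_rate_model(2, 4, 0),
                             free = "alpha")
  expect_gte(fit$loglik, fit$initial_loglik - 1e-6)
  expect_true(fit$converged)
  # restarting from the optimum barely moves the likelihood
  fit2 <- optimize_parameters(tr, sim$alignment, m, fit$rates, free = "alpha")
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-3)
  # k = 1 with p_inv fixed at 0 equals the homogeneous computation
  r1 <- site_rate_model(1, 1, 0)
  expect_identical(r1$k, 1L)
  expect_equal(total_log_likelihood(tr, sim$alignment, m, r1),
               total_log_likelihood(tr, sim$alignment, m,
                                    site_rate_model(5, 1, 0)))
  expect_error(optimize_parameters(tr, sim$alignment, m, r1,
                                   free = character(0)), "at least one")
})
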