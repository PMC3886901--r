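# Shared fixtures built in code at test time.

fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_substitution_model("JTT")
    cache
  }
})

random_alignment <- function(taxa, n_sites, seed, gap_at = NULL) {
  withr::with_seed(seed, {
    m <- matrix(sample(aa_alphabet()$symbols, length(taxa) * n_sites,
                       replace = TRUE),
                nrow = length(taxa), dimnames = list(taxa, NULL))
  })
  if (!is.null(gap_at)) m[gap_at] <- "-"
  alignment_from_matrix(m)
}

random_test_tree <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.05, 0.8))
  })
  tr
}

# a tiny synthetic two-chain "protein" for superposition tests
synthetic_chain <- function(n_res = 10, seed = 4) {
  withr::with_seed(seed, {
    nm <- rep(c("N", "CA", "C"), n_res)
    xyz <- cbind(cumsum(stats::rnorm(3 * n_res, 1, 0.3)),
                 cumsum(stats::rnorm(3 * n_res, 0.5, 0.3)),
                 cumsum(stats::rnorm(3 * n_res, 0.2, 0.3)))
  })
  resid3 <- rep(c("ALA", "LEU", "PHE", "GLY", "TRP",
                  "SER", "HIS", "LYS", "TYR", "VAL"),
                length.out = n_res)
  structure(list(atoms = data.frame(
    element = substr(nm, 1L, 1L), name = nm,
    resid = rep(resid3, each = 3L), resno = rep(seq_len(n_res), each = 3L),
    chain = "A", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, type = "ATOM", stringsAsFactors = FALSE),
    source = "synthetic chain"), class = "protein_structure")
}

# reconstruction object with a hand-set posterior (for the pure sequence
# derivation contracts)
fake_reconstruction <- function(posterior, threshold = 0.25) {
  alpha <- aa_alphabet()$symbols
  colnames(posterior) <- alpha
  top2 <- apply(posterior, 1L, function(pp) {
    i1 <- which.max(pp); pp2 <- pp; pp2[i1] <- -Inf; i2 <- which.max(pp2)
    c(i1, pp[i1], i2, pp[i2])
  })
  rec <- structure(list(
    node = NA_integer_, clade = NULL, posterior = posterior,
    ml_state = alpha[top2[1L, ]], ml_pp = top2[2L, ],
    runner_up_state = alpha[top2[3L, ]], runner_up_pp = top2[4L, ],
    altall_threshold = threshold,
    gap_fraction = rep(0, nrow(posterior))), class = "ancestral_reconstruction")
  rec$altall_state <- strsplit(altall_sequence(rec, threshold), "")[[1L]]
  rec
}
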