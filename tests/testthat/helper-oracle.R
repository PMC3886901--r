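# Brute-force likelihood and marginal-posterior oracle: exhaustive
# enumeration over all internal-node state assignments, mixed over rate
# classes. Deliberately independent of the pruning implementation — it only
# shares the model's transition_matrix (itself checked against closed
# forms) and works straight off the ape edge matrix.

oracle_site_likelihood_class <- function(tree, states, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  P <- lapply(seq_len(nrow(edge)), function(e)
    transition_matrix(model, tree$edge.length[e], rate))
  internal <- (ntip + 1L):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  assign_state <- function(v, row) {
    if (v <= ntip) states[v] else row[v - ntip]
  }
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  lik <- model$pi[grid[, root - ntip]]
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1L]; ch <- edge[e, 2L]
    sa <- grid[, pa - ntip]
    sc <- if (ch <= ntip) {
      s <- states[ch]
      if (is.na(s)) NULL else rep(s, nrow(grid))
    } else grid[, ch - ntip]
    if (is.null(sc)) next             # missing leaf: sums over states to 1
    lik <- lik * P[[e]][cbind(sa, sc)]
  }
  list(total = sum(lik), grid = grid, lik = lik)
}

# total log-likelihood of one site-pattern vector (NA = gap) under the
# full rate mixture
oracle_site_loglik <- function(tree, states, model, rates) {
  tot <- 0
  for (cl in seq_along(rates$class_weights)) {
    w <- rates$class_weights[cl]
    if (w <= 0) next
    r <- rates$class_rates[cl]
    if (r == 0) {
      s <- unique(states[!is.na(states)])
      l0 <- if (length(s) == 0L) 1 else if (length(s) == 1L) model$pi[s] else 0
      tot <- tot + w * l0
    } else {
      tot <- tot + w * oracle_site_likelihood_class(tree, states, model, r)$total
    }
  }
  log(tot)
}

oracle_total_loglik <- function(tree, alignment, model, rates) {
  enc <- matrix(
    suppressWarnings(encode_states(as.vector(alignment$matrix))),
    nrow = nrow(alignment$matrix), dimnames = dimnames(alignment$matrix))
  enc <- enc[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(enc)), function(s)
    oracle_site_loglik(tree, enc[, s], model, rates), numeric(1)))
}

# marginal posterior over the 20 states at internal node `node` for one site
oracle_marginal_posterior <- function(tree, states, model, rates, node) {
  ntip <- length(tree$tip.label)
  num <- numeric(20)
  for (cl in seq_along(rates$class_weights)) {
    w <- rates$class_weights[cl]
    if (w <= 0) next
    r <- rates$class_rates[cl]
    if (r == 0) {
      s <- unique(states[!is.na(states)])
      if (length(s) == 0L) num <- num + w * model$pi
      else if (length(s) == 1L) num[s] <- num[s] + w * model$pi[s]
    } else {
      bf <- oracle_site_likelihood_class(tree, states, model, r)
      node_states <- bf$grid[, node - ntip]
      for (s in 1:20) num[s] <- num[s] + w * sum(bf$lik[node_states == s])
    }
  }
  num / sum(num)
}
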