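# Felsenstein pruning over the tree viewed as an undirected graph.
#
# Orienting the edges away from an arbitrary "peel root" lets one routine
# serve both the total likelihood (any root gives the same value under a
# reversible model) and empirical-Bayes marginal posteriors (peel toward the
# node of interest, whose conditional then multiplies the stationary
# frequencies). Per-node rescaling with accumulated log scalers keeps
# partials representable on large trees.

# Orient tree edges away from `root_vertex`; returns list(parent, child,
# edge_index) with entries ordered so children are peeled before parents,
# plus the vertex visit order (postorder, root last).
orient_edges <- function(tree, root_vertex) {
  edge <- tree$edge
  n_edge <- nrow(edge)
  nv <- max(edge)
  adj <- vector("list", nv)
  for (e in seq_len(n_edge)) {
    a <- edge[e, 1L]; b <- edge[e, 2L]
    adj[[a]] <- c(adj[[a]], e)
    adj[[b]] <- c(adj[[b]], e)
  }
  parent <- integer(n_edge); child <- integer(n_edge); eidx <- integer(n_edge)
  order_v <- integer(0)
  stack <- root_vertex
  seen <- logical(nv); seen[root_vertex] <- TRUE
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_v <- c(order_v, v)
    for (e in adj[[v]]) {
      w <- if (edge[e, 1L] == v) edge[e, 2L] else edge[e, 1L]
      if (!seen[w]) {
        seen[w] <- TRUE
        k <- k + 1L
        parent[k] <- v; child[k] <- w; eidx[k] <- e
        stack <- c(stack, w)
      }
    }
  }
  # preorder vertex list reversed = valid postorder
  list(parent = parent[seq_len(k)], child = child[seq_len(k)],
       edge_index = eidx[seq_len(k)], postorder = rev(order_v))
}

# Leaf conditional vectors for one pattern matrix: list over tips of
# 20 x npat matrices (built lazily as needed in peel).
leaf_partial <- function(states, npat) {
  part <- matrix(0, 20L, npat)
  obs <- !is.na(states)
  part[cbind(states[obs], which(obs))] <- 1
  part[, !obs] <- 1
  part
}

# Peel one rate class (rate > 0). patterns: ntip x npat integer matrix with
# rows in tree tip order. Returns list(partial = 20 x npat at root,
# logscale = npat).
peel_class <- function(tree, ori, patterns, model, branch_rate) {
  ntip <- length(tree$tip.label)
  npat <- ncol(patterns)
  elen <- tree$edge.length
  partial <- vector("list", max(tree$edge))
  logscale <- vector("list", max(tree$edge))
  # map oriented child -> its oriented incoming edge index, grouped by parent
  kids_of <- split(seq_along(ori$child), ori$parent)
  for (v in ori$postorder) {
    if (v <= ntip) next
    rows <- kids_of[[as.character(v)]]
    part <- matrix(1, 20L, npat)
    sc <- numeric(npat)
    for (r in rows) {
      w <- ori$child[r]
      P <- transition_matrix(model, elen[ori$edge_index[r]], branch_rate)
      cp <- if (w <= ntip) leaf_partial(patterns[w, ], npat) else partial[[w]]
      part <- part * (P %*% cp)
      if (w > ntip) { sc <- sc + logscale[[w]]; partial[w] <- list(NULL) }
    }
    mx <- part[1L, ]
    for (i in 2:20) mx <- pmax(mx, part[i, ])
    if (any(mx <= 0))
      stop("zero site likelihood during peeling (impossible pattern?)")
    partial[[v]] <- part / rep(mx, each = 20L)
    logscale[[v]] <- sc + log(mx)
  }
  root <- ori$postorder[length(ori$postorder)]
  if (root <= ntip) stop("peel root must be an internal vertex")
  list(partial = partial[[root]], logscale = logscale[[root]])
}

# Invariant-class (rate 0) per-pattern log-likelihood in closed form: a
# pattern has nonzero likelihood only if all observed leaf states agree.
invariant_class_loglik <- function(patterns, pi) {
  apply(patterns, 2L, function(col) {
    s <- unique(col[!is.na(col)])
    if (length(s) == 0L) 0 else if (length(s) == 1L) log(pi[s]) else -Inf
  })
}

# log(sum(exp(x))) rowwise over a matrix of class columns
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = TRUE))
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Shared validation + encoding for likelihood/ASR entry points.
prepare_data <- function(tree, alignment, require_all_tips = TRUE) {
  stopifnot(inherits(alignment, "aa_alignment"))
  tree <- validate_tree(tree)
  missing <- setdiff(tree$tip.label, alignment$names)
  if (length(missing))
    stop("tree tips absent from alignment: ", paste(missing, collapse = ", "))
  enc <- encode_alignment(alignment)[tree$tip.label, , drop = FALSE]
  pat <- compress_patterns(enc)
  list(tree = tree, enc = enc, pat = pat)
}

# Per-pattern mixture log-likelihoods plus per-class peeled partials,
# reused by total_log_likelihood and marginal_posteriors.
pattern_logliks <- function(tree, ori, patterns, model, rates,
                            keep_partials = FALSE) {
  npat <- ncol(patterns)
  w <- rates$class_weights
  r <- rates$class_rates
  per_class <- matrix(-Inf, npat, length(w))
  partials <- if (keep_partials) vector("list", length(w)) else NULL
  for (cl in seq_along(w)) {
    if (w[cl] <= 0) next
    if (r[cl] == 0) {
      per_class[, cl] <- log(w[cl]) + invariant_class_loglik(patterns, model$pi)
      next
    }
    pk <- peel_class(tree, ori, patterns, model, r[cl])
    lik <- colSums(model$pi * pk$partial)
    per_class[, cl] <- log(w[cl]) + log(lik) + pk$logscale
    if (keep_partials) partials[[cl]] <- pk
  }
  list(site_loglik = row_logsumexp(per_class),
       per_class = per_class, partials = partials)
}

#' Total log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a reversible amino-acid model with a
#' gamma+invariant rate mixture. Gap and missing leaf states contribute
#' all-ones conditional vectors; per-node rescaling prevents underflow.
#' Under a reversible model the value is invariant to root placement.
#'
#' @param tree A `phylo` tree with branch lengths (substitutions/site).
#' @param alignment An [read_alignment()] object covering all tree tips.
#' @param model An [build_substitution_model()] rate matrix.
#' @param rates A [site_rate_model()] (default: single rate 1).
#' @return The total log-likelihood (finite, negative for nontrivial data).
#' @export
total_log_likelihood <- function(tree, alignment, model,
                                 rates = site_rate_model(1, k = 1L)) {
  stopifnot(inherits(model, "aa_rate_matrix"), inherits(rates, "site_rate_model"))
  d <- prepare_data(tree, alignment)
  ntip <- length(d$tree$tip.label)
  ori <- orient_edges(d$tree, ntip + 1L)
  pl <- pattern_logliks(d$tree, ori, d$pat$patterns, model, rates)
  ll <- sum(pl$site_loglik * d$pat$weights)
  if (!is.finite(ll))
    stop("non-finite log-likelihood: some site has zero likelihood")
  ll
}
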