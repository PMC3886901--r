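#' Simulate a protein alignment on a tree with recorded ancestral states
#'
#' Evolves sequences along the tree under exactly the likelihood model used
#' for inference: root states are drawn from the stationary frequencies,
#' each site draws a rate class from the mixture (the invariant class keeps
#' the site identical everywhere), and each branch's child states are drawn
#' from the finite-time transition matrix at (branch length x class rate).
#' Every internal-node sequence is recorded, so ancestral-reconstruction
#' accuracy can be measured against the truth.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param model An [build_substitution_model()] object.
#' @param rates A [site_rate_model()].
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   bit-for-bit (the caller's RNG state is untouched).
#'
#' @return Object of class `simulated_dataset`: list with `alignment`
#'   (leaf sequences), `ancestral` (character matrix, one row per internal
#'   node, rownames = ape node numbers), `node_clades` (descendant leaf
#'   sets keyed the same way), `site_class` (per-site rate-class index,
#'   1 = invariant), `tree`, `seed`, `params`.
#' @export
simulate_alignment <- function(tree, model, rates, n_sites, seed) {
  stopifnot(inherits(model, "aa_rate_matrix"), inherits(rates, "site_rate_model"))
  tree <- validate_tree(tree)
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  ntip <- length(tree$tip.label)
  nv <- ntip + tree$Nnode
  root <- ntip + 1L
  ori <- orient_edges(tree, root)
  preorder <- rev(ori$postorder)
  alpha <- aa_alphabet()$symbols

  withr::with_seed(seed, {
    cls <- sample.int(length(rates$class_weights), n_sites, replace = TRUE,
                      prob = rates$class_weights)
    states <- matrix(NA_integer_, nv, n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
    edge_of_child <- stats::setNames(seq_along(ori$child), ori$child)
    for (v in preorder) {
      if (v == root) next
      r <- edge_of_child[[as.character(v)]]
      p <- ori$parent[r]
      len <- tree$edge.length[ori$edge_index[r]]
      child <- states[p, ]
      for (cl in unique(cls)) {
        rate <- rates$class_rates[cl]
        if (rate == 0 || len == 0) next
        P <- transition_matrix(model, len, rate)
        at <- which(cls == cl)
        for (s in unique(states[p, at])) {
          here <- at[states[p, at] == s]
          child[here] <- sample.int(20L, length(here), replace = TRUE,
                                    prob = P[s, ])
        }
      }
      states[v, ] <- child
    }
  })

  to_char <- function(rows) {
    m <- matrix(alpha[states[rows, , drop = FALSE]], nrow = length(rows))
    rownames(m) <- if (all(rows <= ntip)) tree$tip.label[rows] else
      as.character(rows)
    m
  }
  leaf_m <- to_char(seq_len(ntip))
  anc_m <- to_char((ntip + 1L):nv)
  structure(list(
    alignment = alignment_from_matrix(leaf_m),
    ancestral = anc_m,
    node_clades = node_clades(tree),
    site_class = cls,
    tree = tree, seed = seed,
    params = list(alpha = rates$alpha, k = rates$k, p_inv = rates$p_inv,
                  n_sites = n_sites)
  ), class = "simulated_dataset")
}

#' True ancestral sequence of a simulated dataset at a node
#'
#' @param dataset A [simulate_alignment()] result.
#' @param node ape node number, or tip labels defining the clade.
#' @return Single sequence string.
#' @export
true_ancestral_sequence <- function(dataset, node) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (is.character(node)) node <- clade_node(dataset$tree, node)
  row <- as.character(node)
  if (!row %in% rownames(dataset$ancestral)) stop("unknown internal node: ", node)
  paste(dataset$ancestral[row, ], collapse = "")
}

#' Deterministic fixture trees
#'
#' Balanced (nested pairs) or caterpillar (comb) topologies with exponential
#' branch lengths of a stated mean, seeded. Tip labels are `A`, `B`, ... for
#' up to 26 taxa, else `t1..tn`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param branch_length_scale Mean of the exponential branch-length draw.
#' @param shape `"balanced"` or `"caterpillar"`.
#' @param seed Integer RNG seed.
#' @return A `phylo` tree.
#' @export
make_fixture_tree <- function(n_taxa, branch_length_scale = 0.1,
                              shape = c("balanced", "caterpillar"),
                              seed = 1L) {
  shape <- match.arg(shape)
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  labels <- if (n_taxa <= 26L) LETTERS[seq_len(n_taxa)] else
    paste0("t", seq_len(n_taxa))
  build_balanced <- function(lab) {
    if (length(lab) == 1L) return(lab)
    half <- ceiling(length(lab) / 2)
    paste0("(", build_balanced(lab[seq_len(half)]), ",",
           build_balanced(lab[-seq_len(half)]), ")")
  }
  newick <- if (shape == "balanced") {
    paste0(build_balanced(labels), ";")
  } else {
    # comb: (((A,B),C),D)...
    s <- paste0("(", labels[1L], ",", labels[2L], ")")
    for (i in seq_len(n_taxa - 2L)) s <- paste0("(", s, ",", labels[i + 2L], ")")
    paste0(s, ";")
  }
  tree <- ape::read.tree(text = newick)
  withr::with_seed(seed, {
    tree$edge.length <- stats::rexp(nrow(tree$edge),
                                    rate = 1 / branch_length_scale)
  })
  tree
}
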