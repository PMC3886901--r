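#' Read a phylogenetic tree with branch lengths from Newick
#'
#' Wraps [ape::read.tree()] with the validation this package requires: every
#' edge must carry a nonnegative branch length. Unrooted (multifurcating at
#' the base) trees are accepted; likelihood computations handle them
#' directly and, under a reversible model, are invariant to root placement.
#'
#' @param path Newick file.
#' @param default_branch_length If not `NULL`, edges lacking a length are
#'   given this value instead of being rejected.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, default_branch_length = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree, default_branch_length)
}

validate_tree <- function(tree, default_branch_length = NULL) {
  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths")
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has edges without branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s): ",
         paste(signif(tree$edge.length[tree$edge.length < 0], 3), collapse = ", "))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Find an internal node by its set of descendant leaves
#'
#' Internal nodes are addressed by the sorted set of leaf names below them,
#' which is stable across serialisations of the same rooted tree. The given
#' leaf set must match a clade exactly.
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of tip labels defining the clade.
#' @return The ape node number of the matching internal node.
#' @export
clade_node <- function(tree, leaves) {
  leaves <- sort(unique(leaves))
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(leaves) < 2L)
    stop("a clade needs at least two leaves")
  node <- ape::getMRCA(tree, leaves)
  below <- sort(tree$tip.label[unlist(
    phangorn_free_descendants(tree, node))])
  if (!identical(below, leaves))
    stop("leaf set is not a clade: its MRCA also contains ",
         paste(setdiff(below, leaves), collapse = ", "))
  node
}

# tip indices below an internal node (self-contained postorder walk,
# avoiding a hard dependency for one traversal)
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[as.character(v)]], rec))
  }
  list(rec(node))
}

#' Descendant leaf names of every internal node
#'
#' @param tree A `phylo` object.
#' @return Named list: for each internal node number, the sorted tip labels
#'   below it.
#' @export
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  out <- lapply(nodes, function(n)
    sort(tree$tip.label[unlist(phangorn_free_descendants(tree, n))]))
  names(out) <- nodes
  out
}
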