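#' Empirical-Bayes marginal ancestral reconstruction at one internal node
#'
#' Computes, for every alignment column, the posterior distribution over the
#' 20 amino acids at the chosen internal node, integrating over all other
#' nodes (by peeling toward the node) and over the rate-class mixture (each
#' class weighted by its prior weight times its likelihood contribution).
#' Under the reversible model, peeling toward the node and multiplying by
#' the stationary frequencies gives the exact marginal posterior.
#'
#' @param tree A rooted or unrooted `phylo` tree with branch lengths.
#' @param alignment Alignment covering all tree tips.
#' @param model An [build_substitution_model()] object (parameters fixed,
#'   typically after [optimize_parameters()]).
#' @param rates A [site_rate_model()].
#' @param node Either an ape internal node number or a character vector of
#'   tip labels whose clade defines the node (see [clade_node()]).
#' @param altall_threshold Posterior-probability threshold above which a
#'   runner-up state replaces the ML state in the AltAll sequence
#'   (default 0.25, strict inequality).
#'
#' @return Object of class `ancestral_reconstruction`: list with `node`
#'   (ape number), `clade` (sorted descendant leaves, if resolvable),
#'   `posterior` (n_sites x 20 matrix, rows sum to 1), `ml_state`, `ml_pp`,
#'   `runner_up_state`, `runner_up_pp`, `altall_state`, `altall_threshold`,
#'   and `gap_fraction` (fraction of gapped/missing leaves per column, so
#'   indel-dominated columns can be masked downstream).
#' @export
marginal_posteriors <- function(tree, alignment, model, rates, node,
                                altall_threshold = 0.25) {
  stopifnot(inherits(model, "aa_rate_matrix"), inherits(rates, "site_rate_model"))
  d <- prepare_data(tree, alignment)
  tree <- d$tree
  ntip <- length(tree$tip.label)
  if (is.character(node)) node <- clade_node(tree, node)
  node <- as.integer(node)
  if (node <= ntip) stop("node ", node, " is a leaf; choose an internal node")
  if (node > ntip + tree$Nnode) stop("unknown node: ", node)

  ori <- orient_edges(tree, node)
  pl <- pattern_logliks(tree, ori, d$pat$patterns, model, rates,
                        keep_partials = TRUE)
  npat <- ncol(d$pat$patterns)
  w <- rates$class_weights
  r <- rates$class_rates
  # log numerator: states x patterns, accumulated over classes
  lognum <- array(-Inf, dim = c(20L, npat, length(w)))
  logpi <- log(model$pi)
  for (cl in seq_along(w)) {
    if (w[cl] <= 0) next
    if (r[cl] == 0) {
      # invariant class: only states compatible with every observed leaf
      for (p in seq_len(npat)) {
        s <- unique(d$pat$patterns[, p][!is.na(d$pat$patterns[, p])])
        if (length(s) == 0L) lognum[, p, cl] <- log(w[cl]) + logpi
        else if (length(s) == 1L) lognum[s, p, cl] <- log(w[cl]) + logpi[s]
      }
    } else {
      pk <- pl$partials[[cl]]
      lognum[, , cl] <- log(w[cl]) + logpi + log(pk$partial) +
        rep(pk$logscale, each = 20L)
    }
  }
  # normalise per pattern across states and classes
  post_pat <- matrix(0, 20L, npat)
  for (p in seq_len(npat)) {
    m <- lognum[, p, ]
    mx <- max(m)
    e <- exp(m - mx)
    post_pat[, p] <- rowSums(e) / sum(e)
  }
  posterior <- t(post_pat[, d$pat$site_to_pattern, drop = FALSE])
  colnames(posterior) <- aa_alphabet()$symbols

  top2 <- apply(posterior, 1L, function(pp) {
    i1 <- which.max(pp)                     # first max = alphabetical tie-break
    pp2 <- pp; pp2[i1] <- -Inf
    i2 <- which.max(pp2)
    c(i1, pp[i1], i2, pp[i2])
  })
  alpha <- aa_alphabet()$symbols
  ml_state <- alpha[top2[1L, ]]
  ml_pp <- top2[2L, ]
  ru_state <- alpha[top2[3L, ]]
  ru_pp <- top2[4L, ]

  clade <- tryCatch(sort(tree$tip.label[unlist(
    phangorn_free_descendants(tree, node))]), error = function(e) NULL)
  gap_fraction <- colMeans(is.na(d$enc))

  rec <- structure(list(
    node = node, clade = clade,
    posterior = posterior,
    ml_state = ml_state, ml_pp = ml_pp,
    runner_up_state = ru_state, runner_up_pp = ru_pp,
    altall_threshold = altall_threshold,
    gap_fraction = gap_fraction
  ), class = "ancestral_reconstruction")
  rec$altall_state <- strsplit(altall_sequence(rec, altall_threshold), "")[[1L]]
  rec
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("ancestral_reconstruction at node", x$node, "—",
      nrow(x$posterior), "sites; mean ML PP",
      sprintf("%.3f", mean(x$ml_pp)), "\n")
  invisible(x)
}

#' Maximum-likelihood ancestral sequence
#'
#' Per-site argmax of the posterior; exact ties resolve to the state earlier
#' in the canonical alphabetical order (deterministic).
#'
#' @param reconstruction An [marginal_posteriors()] result.
#' @return Single string of length `n_sites`.
#' @export
ml_sequence <- function(reconstruction) {
  stopifnot(inherits(reconstruction, "ancestral_reconstruction"))
  paste(reconstruction$ml_state, collapse = "")
}

#' AltAll robustness sequence
#'
#' The "worst plausible case" ancestor: at every site whose runner-up state
#' has posterior probability strictly greater than `threshold`, the
#' runner-up replaces the ML state; all other sites keep the ML state.
#'
#' @param reconstruction An [marginal_posteriors()] result.
#' @param threshold Posterior threshold in (0, 1); default 0.25.
#' @return Single string of length `n_sites`.
#' @export
altall_sequence <- function(reconstruction, threshold = 0.25) {
  stopifnot(inherits(reconstruction, "ancestral_reconstruction"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  out <- reconstruction$ml_state
  swap <- reconstruction$runner_up_pp > threshold
  out[swap] <- reconstruction$runner_up_state[swap]
  paste(out, collapse = "")
}

#' Summary statistics of a reconstruction
#'
#' Mean ML-state posterior probability and the number of ambiguous sites
#' (runner-up PP strictly above the threshold), over all sites or a subset
#' of alignment columns (e.g. pocket-lining sites).
#'
#' @param reconstruction An [marginal_posteriors()] result.
#' @param sites Optional integer vector of 1-based alignment columns.
#' @param threshold Ambiguity threshold (default: the reconstruction's
#'   AltAll threshold).
#' @return List with `mean_pp`, `n_ambiguous`, `n_sites`, and `table` (a
#'   per-site data.frame: site, ML state/PP, runner-up state/PP, AltAll
#'   state, gap fraction).
#' @export
reconstruction_summary <- function(reconstruction, sites = NULL,
                                   threshold = reconstruction$altall_threshold) {
  stopifnot(inherits(reconstruction, "ancestral_reconstruction"))
  n <- nrow(reconstruction$posterior)
  if (is.null(sites)) sites <- seq_len(n)
  sites <- as.integer(sites)
  if (length(sites) == 0L) stop("empty site subset")
  if (any(sites < 1L | sites > n)) stop("site subset out of range 1..", n)
  ambiguous <- reconstruction$runner_up_pp[sites] > threshold
  tab <- data.frame(
    site = sites,
    ml_state = reconstruction$ml_state[sites],
    ml_pp = reconstruction$ml_pp[sites],
    runner_up_state = reconstruction$runner_up_state[sites],
    runner_up_pp = reconstruction$runner_up_pp[sites],
    altall_state = reconstruction$altall_state[sites],
    ambiguous = ambiguous,
    gap_fraction = reconstruction$gap_fraction[sites]
  )
  list(mean_pp = mean(reconstruction$ml_pp[sites]),
       n_ambiguous = sum(ambiguous),
       n_sites = length(sites),
       table = tab)
}

#' Write reconstruction outputs to files
#'
#' Writes the per-site posterior table as TSV, the ML and AltAll sequences
#' as FASTA, and the summary as JSON — the standard report bundle for one
#' reconstructed ancestor.
#'
#' @param reconstruction An [marginal_posteriors()] result.
#' @param dir Output directory (created if needed).
#' @param name Ancestor name used in file names and FASTA headers.
#' @return Named character vector of the files written, invisibly.
#' @export
write_reconstruction <- function(reconstruction, dir, name = "ancestor") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- aa_alphabet()$symbols
  tab <- data.frame(site = seq_len(nrow(reconstruction$posterior)),
                    round(reconstruction$posterior, 6))
  names(tab) <- c("site", paste0("pp_", alpha))
  tab$ml_state <- reconstruction$ml_state
  tab$ml_pp <- round(reconstruction$ml_pp, 6)
  tab$runner_up_state <- reconstruction$runner_up_state
  tab$runner_up_pp <- round(reconstruction$runner_up_pp, 6)
  tab$altall_state <- reconstruction$altall_state
  tab$gap_fraction <- round(reconstruction$gap_fraction, 4)
  f_tsv <- file.path(dir, paste0(name, "_posteriors.tsv"))
  utils::write.table(tab, f_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  f_fa <- file.path(dir, paste0(name, "_sequences.fasta"))
  write_fasta(stats::setNames(
    c(ml_sequence(reconstruction),
      altall_sequence(reconstruction, reconstruction$altall_threshold)),
    c(paste0(name, "_ML"), paste0(name, "_AltAll"))), f_fa)
  s <- reconstruction_summary(reconstruction)
  f_json <- file.path(dir, paste0(name, "_summary.json"))
  jsonlite::write_json(list(node = reconstruction$node,
                            clade = reconstruction$clade,
                            mean_pp = s$mean_pp,
                            n_ambiguous = s$n_ambiguous,
                            n_sites = s$n_sites,
                            altall_threshold = reconstruction$altall_threshold),
                       f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(posteriors = f_tsv, sequences = f_fa, summary = f_json))
}
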