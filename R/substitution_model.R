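#' Read an empirical exchangeability table in PAML .dat layout
#'
#' The file holds the lower triangle of the symmetric 20x20 exchangeability
#' matrix (19 rows of 1..19 numbers), a blank line, the 20 equilibrium
#' frequencies, and optionally a final line giving the residue order. When no
#' order line is present the classical PAML residue order
#' (A R N D C Q E G H I L K M F P S T W Y V) is assumed. The returned matrix
#' and frequency vector are reordered to the package's canonical alphabetical
#' order.
#'
#' @param path Path to the .dat file.
#' @return List with `exchangeabilities` (20x20 symmetric, zero diagonal,
#'   dimnames in canonical order) and `frequencies` (named, sums to 1).
#' @export
read_exchangeability_dat <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- lapply(strsplit(lines, "[ \t]+"), function(x) x[nzchar(x)])
  num <- suppressWarnings(lapply(toks, as.numeric))
  is_num <- vapply(num, function(v) !anyNA(v), logical(1))
  tri <- num[is_num][seq_len(19)]
  if (any(lengths(tri) != seq_len(19)))
    stop("malformed lower triangle in ", path)
  freqs <- num[is_num][[20L]]
  if (length(freqs) != 20L) stop("expected 20 frequencies in ", path)
  order_line <- toks[!is_num]
  ord <- if (length(order_line)) toupper(order_line[[length(order_line)]]) else
    c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  if (length(ord) != 20L || anyDuplicated(ord))
    stop("malformed residue-order line in ", path)
  S <- matrix(0, 20, 20, dimnames = list(ord, ord))
  for (i in 2:20) S[i, 1:(i - 1)] <- tri[[i - 1L]]
  S <- S + t(S)
  names(freqs) <- ord
  canon <- aa_alphabet()$symbols
  list(exchangeabilities = S[canon, canon],
       frequencies = freqs[canon] / sum(freqs))
}

#' The bundled JTT exchangeability table
#'
#' Returns the Jones-Taylor-Thornton (1992) amino-acid exchangeabilities and
#' equilibrium frequencies bundled with the package, in canonical
#' alphabetical residue order.
#'
#' @return As [read_exchangeability_dat()].
#' @export
jtt_table <- function() {
  read_exchangeability_dat(system.file("extdata", "jtt.dat",
                                       package = "paleoprot", mustWork = TRUE))
}

#' Observed amino-acid frequencies of an alignment
#'
#' Counts canonical residues over all cells of the alignment and adds a
#' pseudocount to every amino acid before normalising, so that no frequency
#' is zero (a zero frequency would break the reversible-generator
#' construction). Gaps and missing symbols are ignored.
#'
#' @param alignment An [read_alignment()] object or a character matrix of
#'   single residues.
#' @param pseudocount Count added to every amino acid (default 1).
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
observed_frequencies <- function(alignment, pseudocount = 1) {
  m <- if (inherits(alignment, "aa_alignment")) alignment$matrix else alignment
  alpha <- aa_alphabet()
  idx <- encode_states(as.vector(m), alpha)
  counts <- tabulate(idx, nbins = 20L) + pseudocount
  stats::setNames(counts / sum(counts), alpha$symbols)
}

#' Build a reversible amino-acid substitution model
#'
#' Constructs the generator Q of a time-reversible Markov substitution
#' process from an empirical exchangeability table S and equilibrium
#' frequencies pi: off-diagonals `Q[i,j] = S[i,j] * pi[j]`, diagonal set so
#' rows sum to zero, then the whole matrix rescaled so that the expected
#' substitution rate at stationarity, `-sum(pi * diag(Q))`, equals 1. Branch
#' lengths are then in expected substitutions per site.
#'
#' The spectral decomposition of the symmetrised generator
#' `B = diag(sqrt(pi)) Q diag(1/sqrt(pi))` is computed once and cached in the
#' returned object, so repeated transition-matrix evaluations cost one small
#' matrix product each.
#'
#' @param exchangeabilities `"JTT"` (the bundled table) or a symmetric 20x20
#'   matrix with nonnegative off-diagonals, dimnames in canonical order.
#' @param frequencies `"model"` (the table's own frequencies), `"observed"`
#'   (estimated from `alignment` with [observed_frequencies()]), or an
#'   explicit numeric vector of 20 positive values.
#' @param alignment Required when `frequencies = "observed"`.
#' @param pseudocount Passed to [observed_frequencies()].
#'
#' @return An object of class `aa_rate_matrix`: list with
#'   `exchangeabilities`, `pi`, `Q`, and cached spectral factors.
#' @examples
#' m <- build_substitution_model("JTT", frequencies = rep(0.05, 20))
#' range(rowSums(m$Q))  # ~0
#' @export
build_substitution_model <- function(exchangeabilities = "JTT",
                                     frequencies = "model",
                                     alignment = NULL,
                                     pseudocount = 1) {
  canon <- aa_alphabet()$symbols
  if (is.character(exchangeabilities) && length(exchangeabilities) == 1L) {
    if (toupper(exchangeabilities) != "JTT")
      stop("unknown exchangeability table: ", exchangeabilities)
    tab <- jtt_table()
    S <- tab$exchangeabilities
    model_freqs <- tab$frequencies
  } else {
    S <- as.matrix(exchangeabilities)
    if (!all(dim(S) == c(20L, 20L))) stop("exchangeability matrix must be 20x20")
    if (is.null(dimnames(S))) dimnames(S) <- list(canon, canon)
    if (max(abs(S - t(S))) > 1e-8) stop("exchangeability matrix must be symmetric")
    if (any(S[upper.tri(S)] < 0)) stop("exchangeabilities must be nonnegative")
    model_freqs <- NULL
  }
  diag(S) <- 0

  if (is.character(frequencies) && length(frequencies) == 1L) {
    pi <- switch(frequencies,
      model = {
        if (is.null(model_freqs))
          stop("frequencies = \"model\" needs a named table such as \"JTT\"")
        model_freqs
      },
      observed = {
        if (is.null(alignment))
          stop("frequencies = \"observed\" requires an alignment")
        observed_frequencies(alignment, pseudocount)
      },
      stop("frequencies must be \"model\", \"observed\" or a numeric 20-vector"))
  } else {
    pi <- as.numeric(frequencies)
    if (length(pi) != 20L) stop("frequencies must have length 20")
    if (any(pi <= 0)) stop("all frequencies must be strictly positive")
    pi <- stats::setNames(pi / sum(pi), canon)
  }

  Q <- S * rep(pi, each = 20L)       # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate model: zero overall substitution rate")
  Q <- Q / mu

  # symmetric similarity transform for a stable, cacheable exponential
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = 20L))    # B[i,j] = sq[i] Q[i,j] / sq[j]
  B <- (B + t(B)) / 2                    # clean tiny asymmetry
  eig <- eigen(B, symmetric = TRUE)
  structure(list(
    exchangeabilities = S,
    pi = pi,
    Q = Q,
    eig_values = eig$values,
    eig_left = eig$vectors / sq,                 # diag(1/sq) %*% U
    eig_right = t(eig$vectors * sq)              # t(U) %*% diag(sq)
  ), class = "aa_rate_matrix")
}

#' Transition probability matrix over a branch
#'
#' `P(t) = exp(Q * t * rate)` via the cached spectral decomposition of the
#' reversible generator. Small negative entries from roundoff are clipped to
#' zero and rows renormalised.
#'
#' @param model An [build_substitution_model()] object.
#' @param branch_length Branch length in expected substitutions per site
#'   (must be >= 0).
#' @param rate Positive rate multiplier (e.g. a gamma-category rate).
#' @return 20x20 row-stochastic matrix.
#' @examples
#' m <- build_substitution_model("JTT")
#' range(rowSums(transition_matrix(m, 0.37)))  # 1
#' @export
transition_matrix <- function(model, branch_length, rate = 1) {
  stopifnot(inherits(model, "aa_rate_matrix"))
  if (!is.finite(branch_length) || branch_length < 0)
    stop("branch_length must be a nonnegative finite number")
  if (rate < 0) stop("rate must be nonnegative")
  if (branch_length * rate == 0)
    return(diag(20L))
  P <- model$eig_left %*% (exp(model$eig_values * branch_length * rate) *
                           model$eig_right)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discretize a gamma rate distribution into equal-probability categories
#'
#' The mean-one gamma(shape = alpha, rate = alpha) distribution is cut into
#' `k` equal-probability bins and each category's rate is the conditional
#' mean within its bin, computed in closed form from the incomplete-gamma
#' identity `E[X; X <= q] = pgamma(q, alpha + 1, alpha)`. The category rates
#' therefore average exactly 1.
#'
#' @param alpha Positive gamma shape.
#' @param k Number of categories (>= 1).
#' @return List with `rates` (length `k`) and `weights` (each `1/k`).
#' @examples
#' discretize_gamma(0.5, 4)$rates
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (k == 1L) return(list(rates = 1, weights = 1))
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- k * diff(cum)          # conditional means, mean(rates) == 1
  rates <- rates / mean(rates)    # remove last-digit drift
  list(rates = rates, weights = rep(1 / k, k))
}

#' Site-rate mixture: discrete gamma plus an invariant class
#'
#' Builds the (k+1)-component rate mixture used throughout: an invariant
#' class at rate 0 with weight `p_inv`, and `k` equal-weight gamma categories
#' whose rates are rescaled by `1/(1 - p_inv)` so the grand mean rate over
#' all classes is exactly 1 and branch lengths keep their
#' substitutions-per-site meaning.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of gamma categories (default 4).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return Object of class `site_rate_model`: list with `alpha`, `k`,
#'   `p_inv`, `gamma_rates` (the k rescaled gamma rates), `class_rates`
#'   (length k+1, first is 0) and `class_weights` (length k+1, sums to 1).
#' @export
site_rate_model <- function(alpha = 1, k = 4L, p_inv = 0) {
  if (!is.finite(p_inv) || p_inv < 0 || p_inv >= 1)
    stop("p_inv must be in [0, 1)")
  g <- discretize_gamma(alpha, k)
  k <- length(g$rates)
  gamma_rates <- g$rates / (1 - p_inv)
  structure(list(
    alpha = alpha, k = k, p_inv = p_inv,
    gamma_rates = gamma_rates,
    class_rates = c(0, gamma_rates),
    class_weights = c(p_inv, rep((1 - p_inv) / k, k))
  ), class = "site_rate_model")
}
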