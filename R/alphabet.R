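#' The canonical amino-acid alphabet
#'
#' All likelihood machinery in this package works over the 20 canonical
#' amino acids in fixed alphabetical one-letter order. The ordering matters:
#' it is the tie-break order for maximum-likelihood ancestral states, so it
#' is frozen here and used everywhere.
#'
#' @param gap Character treated as an alignment gap (default `"-"`).
#' @param missing Characters treated as fully ambiguous residues
#'   (default `c("X", "?", ".", "*", "B", "Z", "J", "U", "O")`).
#'
#' @return An object of class `aa_alphabet`: a list with `symbols` (the 20
#'   canonical codes, fixed order), `gap_symbol` and `missing_symbols`.
#' @examples
#' aa_alphabet()$symbols
#' @export
aa_alphabet <- function(gap = "-",
                        missing = c("X", "?", ".", "*", "B", "Z", "J", "U", "O")) {
  symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  stopifnot(length(gap) == 1L, nchar(gap) == 1L)
  missing <- unique(toupper(missing))
  if (gap %in% symbols || any(missing %in% symbols) || gap %in% missing)
    stop("gap and missing symbols must be disjoint from the 20 canonical codes")
  structure(list(symbols = symbols, gap_symbol = gap, missing_symbols = missing),
            class = "aa_alphabet")
}

# Single shared instance; cheap to rebuild but handy as a default.
.aa <- function() aa_alphabet()

#' Encode residue characters as state indices
#'
#' Canonical residues map to 1..20 in alphabet order; the gap symbol and any
#' missing/ambiguity symbol map to `NA` (treated as missing data in all
#' likelihood computations). Unknown characters also map to `NA`, with a
#' warning naming them.
#'
#' @param x Character vector of single residue characters (any case).
#' @param alphabet An [aa_alphabet()].
#' @return Integer vector of the same length; `NA` for gap/missing.
#' @export
encode_states <- function(x, alphabet = aa_alphabet()) {
  x <- toupper(x)
  idx <- match(x, alphabet$symbols)
  bad <- is.na(idx) & !(x %in% c(alphabet$gap_symbol, alphabet$missing_symbols))
  if (any(bad)) {
    warning("unknown residue character(s) treated as missing: ",
            paste(sort(unique(x[bad])), collapse = " "))
  }
  idx
}
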