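#' Read a protein multiple sequence alignment from FASTA
#'
#' Sequences are uppercased; `-` is kept as the gap symbol; any character
#' outside the canonical alphabet, gap and known ambiguity codes is mapped to
#' the missing symbol `X` with a warning. All records must have equal length.
#'
#' @param path FASTA file.
#' @return Object of class `aa_alignment`: list with `names`, `matrix`
#'   (character matrix, taxa x sites, rownames = taxon names) and `n_sites`.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))   # first token, FASTA-convention id
  if (any(!nzchar(nm))) stop("empty sequence name in ", path)
  if (anyDuplicated(nm))
    stop("duplicate sequence names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: record '", nm[which(lens != lens[1L])[1L]],
         "' has length ", lens[lens != lens[1L]][1L], " not ", lens[1L])
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- nm
  alignment_from_matrix(m)
}

#' Build an alignment object from a character matrix
#'
#' @param m Character matrix of single residues, rownames = taxon names.
#' @return An `aa_alignment`.
#' @export
alignment_from_matrix <- function(m) {
  alpha <- aa_alphabet()
  ok <- c(alpha$symbols, alpha$gap_symbol, alpha$missing_symbols)
  bad <- !(m %in% ok)
  if (any(bad)) {
    warning("mapping unknown residue character(s) to missing ('X'): ",
            paste(sort(unique(m[bad])), collapse = " "))
    m[bad] <- "X"
  }
  if (is.null(rownames(m))) stop("alignment matrix must have rownames")
  structure(list(names = rownames(m), matrix = m, n_sites = ncol(m)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", length(x$names), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (or named list).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- unlist(seqs)
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# taxa x sites integer matrix of state indices (NA = gap/missing)
encode_alignment <- function(alignment) {
  m <- alignment$matrix
  enc <- suppressWarnings(encode_states(as.vector(m)))
  matrix(enc, nrow = nrow(m), dimnames = dimnames(m))
}

# collapse identical site patterns; returns patterns (taxa x n_pattern),
# weights, and map site -> pattern index
compress_patterns <- function(enc) {
  key <- apply(enc, 2L, function(col) paste(ifelse(is.na(col), "-", col),
                                            collapse = ","))
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(patterns = enc[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       site_to_pattern = idx)
}
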