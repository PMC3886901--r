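split1 <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1L]] else as.character(x)
}

#' Map alignment columns to reference-sequence residue numbers
#'
#' Columns where the reference sequence is ungapped receive consecutive
#' residue numbers starting at `offset`; columns where the reference is
#' gapped get `NA` plus a nearest-anchor annotation such as `"415+2"`
#' (second inserted column after reference residue 415).
#'
#' @param alignment An alignment containing the reference taxon.
#' @param reference_taxon Name of the reference sequence (e.g. human ERα).
#' @param offset Residue number of the reference's first ungapped column.
#' @return Object of class `numbering_map`: list with `reference_name`,
#'   `number` (integer per column, `NA` where gapped) and `anchor`
#'   (character annotation per column).
#' @export
map_reference_numbering <- function(alignment, reference_taxon, offset = 1L) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (!reference_taxon %in% alignment$names)
    stop("reference taxon not in alignment: ", reference_taxon)
  alpha <- aa_alphabet()
  ref <- alignment$matrix[reference_taxon, ]
  ungapped <- ref %in% alpha$symbols
  number <- rep(NA_integer_, length(ref))
  number[ungapped] <- seq_len(sum(ungapped)) + offset - 1L
  anchor <- as.character(number)
  gap_cols <- which(!ungapped)
  if (length(gap_cols)) {
    last <- cummax(ifelse(ungapped, seq_along(ref), 0L))
    for (i in gap_cols) {
      if (last[i] == 0L) anchor[i] <- paste0("0+", i)
      else anchor[i] <- paste0(number[last[i]], "+", i - last[i])
    }
  }
  structure(list(reference_name = reference_taxon, number = number,
                 anchor = anchor),
            class = "numbering_map")
}

#' Enumerate amino-acid replacements between two aligned ancestors
#'
#' One substitution event per alignment column where both sequences carry
#' canonical amino acids and the states differ. Columns where either
#' sequence is gapped or missing are excluded from events and counted
#' separately.
#'
#' @param ancestor_a,ancestor_b Sequence strings (same alignment frame).
#' @param numbering Optional [map_reference_numbering()] result.
#' @return Object of class `substitution_events`: list with `events` (a
#'   data.frame: column, ancestral_state, derived_state, reference_number,
#'   reference_anchor, label) and `n_excluded_gap_columns`. The label uses
#'   the field's lower/UPPER convention: ancestral state in lower case,
#'   derived in upper, around the reference (or column) number.
#' @export
enumerate_substitutions <- function(ancestor_a, ancestor_b, numbering = NULL) {
  a <- toupper(split1(ancestor_a))
  b <- toupper(split1(ancestor_b))
  if (length(a) != length(b))
    stop("sequences have different lengths: ", length(a), " vs ", length(b))
  alpha <- aa_alphabet()
  canon_a <- a %in% alpha$symbols
  canon_b <- b %in% alpha$symbols
  diff <- canon_a & canon_b & a != b
  cols <- which(diff)
  refno <- rep(NA_integer_, length(cols))
  anchor <- rep(NA_character_, length(cols))
  if (!is.null(numbering)) {
    stopifnot(inherits(numbering, "numbering_map"))
    if (length(numbering$number) != length(a))
      stop("numbering map frame (", length(numbering$number),
           " columns) does not match sequences (", length(a), ")")
    refno <- numbering$number[cols]
    anchor <- numbering$anchor[cols]
  }
  label_no <- ifelse(is.na(refno),
                     if (is.null(numbering)) as.character(cols) else anchor,
                     as.character(refno))
  events <- data.frame(
    column = cols,
    ancestral_state = a[cols],
    derived_state = b[cols],
    reference_number = refno,
    reference_anchor = anchor,
    label = paste0(tolower(a[cols]), label_no, toupper(b[cols]))
  )
  structure(list(events = events,
                 n_excluded_gap_columns = sum(!canon_a | !canon_b),
                 n_events = nrow(events)),
            class = "substitution_events")
}

#' @export
print.substitution_events <- function(x, ...) {
  cat("substitution_events:", x$n_events, "replacements (",
      x$n_excluded_gap_columns, "gap/missing columns excluded )\n")
  invisible(x)
}

#' Filter substitutions by conservation among descendant sequences
#'
#' An event is retained iff the number of descendant sequences that carry a
#' canonical amino acid different from the derived state is at most
#' `max_exceptions`. Gapped/missing descendants are not counted as
#' exceptions (a missing residue is not evidence against conservation); the
#' per-event tallies expose the gap counts so the stricter reading can be
#' audited.
#'
#' @param substitutions An [enumerate_substitutions()] result.
#' @param descendant_alignment Alignment of the focal clade's extant
#'   members, in the same frame as the ancestors.
#' @param max_exceptions Maximum tolerated non-matching descendants
#'   (default 1, i.e. "conserved in all or all but one").
#' @return Object of class `conservation_report`: the events data.frame
#'   gains `conservation_count`, `n_mismatch`, `n_gapped`, `n_descendants`
#'   and `retained`; plus `n_retained` and the filter parameters.
#' @export
conservation_filter <- function(substitutions, descendant_alignment,
                                max_exceptions = 1L) {
  stopifnot(inherits(substitutions, "substitution_events"),
            inherits(descendant_alignment, "aa_alignment"))
  if (max_exceptions < 0L) stop("max_exceptions must be >= 0")
  ev <- substitutions$events
  m <- descendant_alignment$matrix
  alpha <- aa_alphabet()
  n_desc <- nrow(m)
  if (nrow(ev)) {
    if (max(ev$column) > ncol(m))
      stop("descendant alignment frame (", ncol(m),
           " columns) shorter than event columns")
    counts <- t(vapply(seq_len(nrow(ev)), function(i) {
      col <- m[, ev$column[i]]
      canon <- col %in% alpha$symbols
      match <- canon & col == ev$derived_state[i]
      c(match = sum(match), mismatch = sum(canon & !match),
        gapped = sum(!canon))
    }, numeric(3)))
    ev$conservation_count <- counts[, "match"]
    ev$n_mismatch <- counts[, "mismatch"]
    ev$n_gapped <- counts[, "gapped"]
    ev$n_descendants <- n_desc
    ev$retained <- ev$n_mismatch <= max_exceptions
  } else {
    ev$conservation_count <- ev$n_mismatch <- ev$n_gapped <-
      ev$n_descendants <- integer(0)
    ev$retained <- logical(0)
  }
  structure(list(events = ev,
                 n_events = nrow(ev),
                 n_retained = sum(ev$retained),
                 max_exceptions = as.integer(max_exceptions),
                 n_descendants = n_desc),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("conservation_report:", x$n_retained, "of", x$n_events,
      "events retained (max_exceptions =", x$max_exceptions, ")\n")
  invisible(x)
}

#' Percent identity between two aligned sequences
#'
#' Matching canonical positions over one of three denominators:
#' `"both-ungapped"` (columns where both sequences carry canonical residues;
#' the pipeline default), `"either-ungapped"` (columns where at least one
#' does), or `"alignment-length"` (all columns). The convention is returned
#' alongside the value so reports are unambiguous.
#'
#' @param seq_a,seq_b Sequence strings of equal length.
#' @param denominator One of the three conventions above.
#' @return List with `percent`, `n_matches`, `n_denominator`, `denominator`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              denominator = c("both-ungapped",
                                              "either-ungapped",
                                              "alignment-length")) {
  denominator <- match.arg(denominator)
  a <- toupper(split1(seq_a)); b <- toupper(split1(seq_b))
  if (length(a) != length(b)) stop("sequences have different lengths")
  alpha <- aa_alphabet()
  ca <- a %in% alpha$symbols; cb <- b %in% alpha$symbols
  matches <- sum(ca & cb & a == b)
  denom <- switch(denominator,
                  "both-ungapped" = sum(ca & cb),
                  "either-ungapped" = sum(ca | cb),
                  "alignment-length" = length(a))
  if (denom == 0L) stop("no comparable positions under denominator '",
                        denominator, "'")
  list(percent = 100 * matches / denom,
       n_matches = matches, n_denominator = denom,
       denominator = denominator)
}

#' Write a substitution-event table as TSV
#'
#' @param report A [conservation_filter()] (or [enumerate_substitutions()])
#'   result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(report, path) {
  ev <- report$events
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
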