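#' Van der Waals radius table
#'
#' Bondi-type heavy-atom radii in Angstroms. Crystal structures at typical
#' resolution lack hydrogens; radii are used as-is by default, with an
#' optional united-atom inflation added uniformly to compensate for the
#' missing hydrogens.
#'
#' @param inflation Value added to every radius (default 0).
#' @return Named numeric vector, element symbol -> radius.
#' @export
vdw_radii <- function(inflation = 0) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92)
  r + inflation
}

# radius per atom from element symbols; unknown elements error unless a
# default is supplied
atom_radii <- function(elements, inflation = 0, default_radius = NULL) {
  tab <- vdw_radii(inflation)
  r <- tab[toupper(elements)]
  if (anyNA(r)) {
    unknown <- sort(unique(toupper(elements)[is.na(r)]))
    if (is.null(default_radius))
      stop("element(s) not in radius table: ", paste(unknown, collapse = " "),
           " (supply default_radius to override)")
    r[is.na(r)] <- default_radius + inflation
  }
  unname(r)
}

#' Read an atomic structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]. Waters are always excluded; heteroatoms
#' (ligands, ions) are kept only when requested; when an atom has multiple
#' alternate locations, the highest-occupancy altloc is retained (ties keep
#' the first in file order).
#'
#' @param path PDB coordinate file.
#' @param chain Optional chain identifier(s) to keep.
#' @param keep_heteroatoms Keep HETATM records (default `FALSE`).
#' @return Object of class `protein_structure`: list with `atoms` (a
#'   data.frame: element, name, resid, resno, chain, x, y, z, occupancy,
#'   type) and `source`.
#' @export
read_structure <- function(path, chain = NULL, keep_heteroatoms = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L || !any(a$type == "ATOM"))
    stop("no ATOM records in ", path)
  keep <- a$type == "ATOM" | (keep_heteroatoms & a$type == "HETATM")
  keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left after filtering in ", path)
  # altloc resolution: highest occupancy per (chain, resno, insert, name)
  alt <- !is.na(a$alt) & nzchar(a$alt)
  if (any(alt)) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  element <- toupper(trimws(a$elesy))
  noel <- is.na(element) | !nzchar(element)
  if (any(noel))  # fall back to first letter of the atom name
    element[noel] <- toupper(substr(gsub("[0-9]", "", trimws(a$elety[noel])),
                                    1L, 1L))
  atoms <- data.frame(
    element = element, name = trimws(a$elety), resid = a$resid,
    resno = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o), type = a$type,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues [",
      x$source, "]\n")
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' @param structure A `protein_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = if (!is.null(a$type)) a$type else "ATOM",
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$name, o = a$occupancy, elesy = a$element)
  invisible(path)
}

atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# one-letter sequence + residue numbers of a chain, from CA atoms
chain_sequence <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  ca <- a[a$name == "CA" & a$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms found")
  list(sequence = paste(bio3d::aa321(ca$resid), collapse = ""),
       resno = ca$resno, chain = ca$chain)
}

#' Uniform random rotation matrices
#'
#' Uniform over SO(3) via random unit quaternions (Marsaglia method),
#' seeded. The first matrix is the identity, so the reference (input)
#' orientation is always included in an orientation ensemble.
#'
#' @param n Number of matrices.
#' @param seed Integer RNG seed.
#' @return List of `n` 3x3 proper rotation matrices; element 1 is identity.
#' @export
random_rotations <- function(n, seed = 1L) {
  out <- vector("list", n)
  out[[1L]] <- diag(3)
  if (n > 1L) withr::with_seed(seed, {
    for (i in 2:n) {
      q <- stats::rnorm(4)
      q <- q / sqrt(sum(q^2))
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      out[[i]] <- matrix(c(
        1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
        3, 3, byrow = TRUE)
    }
  })
  out
}

#' Least-squares rigid superposition of two structures
#'
#' Pairs residues by a global (affine-gap) sequence alignment of the two
#' chains, collects the requested atoms from each paired residue, and
#' computes the optimal proper rotation by the Kabsch/SVD method.
#'
#' @param structure_a Moving structure.
#' @param structure_b Target structure.
#' @param atom_scope `"CA"` (alpha carbons), `"backbone"` (N, CA, C, O), or
#'   `"all-common"` (all heavy atoms with matching names in both residues).
#' @param chain_a,chain_b Optional chain filters.
#' @return Object of class `superposition_result`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd`, `n_atom_pairs`, `atom_scope`, `residue_pairs`
#'   (data.frame of paired residue numbers) and `pairing` description.
#' @export
superpose <- function(structure_a, structure_b,
                      atom_scope = c("CA", "backbone", "all-common"),
                      chain_a = NULL, chain_b = NULL) {
  atom_scope <- match.arg(atom_scope)
  sa <- chain_sequence(structure_a, chain_a)
  sb <- chain_sequence(structure_b, chain_b)
  ali <- Biostrings::pairwiseAlignment(sa$sequence, sb$sequence,
                                       type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(ali)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(ali)), "")[[1L]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  residue_pairs <- data.frame(resno_a = sa$resno[ia[both]],
                              resno_b = sb$resno[ib[both]])

  pick <- function(structure, chain, resno) {
    a <- structure$atoms
    if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
    a <- a[a$type == "ATOM" & a$element != "H", , drop = FALSE]
    a[a$resno == resno, , drop = FALSE]
  }
  A <- list(); B <- list()
  for (i in seq_len(nrow(residue_pairs))) {
    ra <- pick(structure_a, chain_a, residue_pairs$resno_a[i])
    rb <- pick(structure_b, chain_b, residue_pairs$resno_b[i])
    names_use <- switch(atom_scope,
      "CA" = "CA",
      "backbone" = c("N", "CA", "C", "O"),
      "all-common" = intersect(ra$name, rb$name))
    common <- intersect(intersect(names_use, ra$name), rb$name)
    if (length(common) == 0L) next
    A[[length(A) + 1L]] <- as.matrix(ra[match(common, ra$name),
                                        c("x", "y", "z")])
    B[[length(B) + 1L]] <- as.matrix(rb[match(common, rb$name),
                                        c("x", "y", "z")])
  }
  P <- do.call(rbind, A); Q <- do.call(rbind, B)
  if (is.null(P) || nrow(P) < 3L)
    stop("fewer than 3 atom pairs; cannot superpose")
  kab <- kabsch(P, Q)
  structure(c(kab, list(n_atom_pairs = nrow(P), atom_scope = atom_scope,
                        residue_pairs = residue_pairs,
                        pairing = "global sequence alignment (BLOSUM62, affine gaps)")),
            class = "superposition_result")
}

# optimal proper rotation + translation mapping P onto Q; both n x 3
kabsch <- function(P, Q) {
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  sv_p <- svd(P0)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("degenerate (collinear) atom configuration")
  M <- t(P0) %*% Q0
  s <- svd(M)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' Apply a superposition (or any rigid transform) to a structure
#'
#' @param structure A `protein_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (default 0).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation, translation = c(0, 0, 0)) {
  xyz <- atom_coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2L, as.numeric(translation), "+")
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atom pairs (%s)\n",
              x$rmsd, x$n_atom_pairs, x$atom_scope))
  invisible(x)
}
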