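# Probe-occupied cavity volumes on a cubic grid.
#
# A voxel is probe-accessible when a probe sphere centred there overlaps no
# atom's van der Waals sphere. Accessibility is flood-filled from the grid
# boundary to define bulk solvent; interior accessible components are
# cavities. The "probe-occupied" convention then dilates the selected
# cavity's probe centres by the probe radius and clips by the vdW spheres,
# matching the way a water-sized probe physically fills a void; the
# "probe-center" convention counts accessible voxel volume directly.

#' Cavity-calculation parameters
#'
#' @param probe_radius Probe sphere radius in Angstroms (default 1.4, a
#'   water-sized probe).
#' @param grid_spacing Cubic grid spacing in Angstroms (default 0.5; must be
#'   in `(0, probe_radius]`).
#' @param n_orientations Number of grid orientations averaged (default 10);
#'   the first is always the input orientation, the rest uniform random
#'   rotations.
#' @param seed RNG seed for the random orientations.
#' @param radius_inflation United-atom inflation added to all vdW radii.
#' @param volume_convention `"probe-occupied"` (default) or `"probe-center"`.
#' @param seed_point Optional length-3 coordinate; the cavity containing (or
#'   nearest to) this point is selected instead of the largest one.
#' @param default_radius Radius for elements missing from the table
#'   (`NULL` = error on unknown elements).
#' @return A `cavity_params` list.
#' @export
cavity_params <- function(probe_radius = 1.4, grid_spacing = 0.5,
                          n_orientations = 10L, seed = 1L,
                          radius_inflation = 0,
                          volume_convention = c("probe-occupied",
                                                "probe-center"),
                          seed_point = NULL, default_radius = NULL) {
  volume_convention <- match.arg(volume_convention)
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (grid_spacing <= 0 || grid_spacing > probe_radius)
    stop("grid_spacing must be in (0, probe_radius]")
  if (n_orientations < 1L) stop("n_orientations must be >= 1")
  if (!is.null(seed_point) && length(seed_point) != 3L)
    stop("seed_point must be a length-3 coordinate")
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 n_orientations = as.integer(n_orientations),
                 seed = as.integer(seed),
                 radius_inflation = radius_inflation,
                 volume_convention = volume_convention,
                 seed_point = seed_point,
                 default_radius = default_radius),
            class = "cavity_params")
}

# --- grid primitives --------------------------------------------------------

make_grid <- function(coords, max_reach, spacing) {
  pad <- 2 * max_reach
  lo <- apply(coords, 2L, min) - pad
  hi <- apply(coords, 2L, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, spacing = spacing, dims = dims)
}

# logical array: voxel centre within radius r_i of atom i for any i
mark_spheres <- function(grid, coords, radii) {
  nx <- grid$dims[1L]; ny <- grid$dims[2L]; nz <- grid$dims[3L]
  h <- grid$spacing; o <- grid$origin
  inside <- array(FALSE, grid$dims)
  for (i in seq_len(nrow(coords))) {
    r <- radii[i]
    c1 <- coords[i, ]
    ilo <- pmax(1L, as.integer(floor((c1 - r - o) / h)) + 1L)
    ihi <- pmin(grid$dims, as.integer(ceiling((c1 + r - o) / h)) + 1L)
    if (any(ilo > ihi)) next
    xs <- o[1L] + (seq.int(ilo[1L], ihi[1L]) - 1L) * h - c1[1L]
    ys <- o[2L] + (seq.int(ilo[2L], ihi[2L]) - 1L) * h - c1[2L]
    zs <- o[3L] + (seq.int(ilo[3L], ihi[3L]) - 1L) * h - c1[3L]
    sub <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= r^2
    inside[seq.int(ilo[1L], ihi[1L]), seq.int(ilo[2L], ihi[2L]),
           seq.int(ilo[3L], ihi[3L])] <-
      inside[seq.int(ilo[1L], ihi[1L]), seq.int(ilo[2L], ihi[2L]),
             seq.int(ilo[3L], ihi[3L])] | sub
  }
  inside
}

# frontier BFS over the 6-connected grid restricted to `open`; returns a
# logical array of voxels reachable from `seeds` (linear indices)
flood_fill <- function(open, dims, seeds) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nxy <- nx * ny
  visited <- logical(length(open))
  frontier <- seeds[open[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% nx
    iy <- (i0 %/% nx) %% ny
    iz <- i0 %/% nxy
    nb <- c(frontier[ix > 0L] - 1L, frontier[ix < nx - 1L] + 1L,
            frontier[iy > 0L] - nx, frontier[iy < ny - 1L] + nx,
            frontier[iz > 0L] - nxy, frontier[iz < nz - 1L] + nxy)
    nb <- unique(nb)
    nb <- nb[open[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dims)
}

boundary_indices <- function(dims) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  idx <- array(seq_len(nx * ny * nz), dims)
  unique(c(idx[1L, , ], idx[nx, , ], idx[, 1L, ], idx[, ny, ],
           idx[, , 1L], idx[, , nz]))
}

# split a voxel set (linear indices) into 6-connected components
grid_components <- function(mask_idx, open, dims) {
  comps <- list()
  remaining <- logical(length(open))
  remaining[mask_idx] <- TRUE
  cav_open <- array(remaining, dims)
  while (any(remaining)) {
    seed <- which.max(remaining)
    comp <- flood_fill(cav_open, dims, seed)
    ci <- which(comp)
    comps[[length(comps) + 1L]] <- ci
    remaining[ci] <- FALSE
  }
  comps
}

voxel_centers <- function(grid, idx) {
  nx <- grid$dims[1L]; ny <- grid$dims[2L]
  i0 <- idx - 1L
  cbind(grid$origin[1L] + (i0 %% nx) * grid$spacing,
        grid$origin[2L] + ((i0 %/% nx) %% ny) * grid$spacing,
        grid$origin[3L] + (i0 %/% (nx * ny)) * grid$spacing)
}

# integer offsets within a sphere of `radius`, in voxel units
sphere_offsets <- function(radius, spacing, dims) {
  m <- as.integer(floor(radius / spacing))
  g <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  g <- g[(g$dx^2 + g$dy^2 + g$dz^2) * spacing^2 <= radius^2, ]
  as.integer(g$dx + g$dy * dims[1L] + g$dz * dims[1L] * dims[2L])
}

# Dilate cavity probe-centres by the probe radius and clip by the vdW
# spheres. The probe-accessible region is continuous but only sampled at
# voxel centres: around an accessible voxel whose whole neighbourhood is
# accessible, every point of the voxel is an admissible probe centre, so
# the dilation radius there is inflated by the half voxel diagonal; from
# boundary accessible voxels it is inflated by half a spacing (the true
# accessibility boundary lies on average halfway between the last
# accessible and the first blocked centre). The vdW clip then
# bounds the region at the atomic wall and the residual discretisation
# error vanishes with the grid spacing. Safe without index bounds checks
# because cavities sit >= padding away from the grid faces.
probe_occupied_indices <- function(cav_idx, grid, inside_vdw, probe_radius) {
  nx <- grid$dims[1L]; nxy <- nx * grid$dims[2L]
  in_cav <- logical(length(inside_vdw))
  in_cav[cav_idx] <- TRUE
  interior <- cav_idx[
    in_cav[cav_idx - 1L] & in_cav[cav_idx + 1L] &
    in_cav[cav_idx - nx] & in_cav[cav_idx + nx] &
    in_cav[cav_idx - nxy] & in_cav[cav_idx + nxy]]
  boundary <- setdiff(cav_idx, interior)
  occ <- c(
    if (length(interior))
      as.vector(outer(interior,
                      sphere_offsets(probe_radius +
                                     grid$spacing * sqrt(3) / 2,
                                     grid$spacing, grid$dims), "+")),
    if (length(boundary))
      as.vector(outer(boundary,
                      sphere_offsets(probe_radius + grid$spacing / 2,
                                     grid$spacing, grid$dims), "+")))
  occ <- unique(occ)
  occ <- occ[occ >= 1L & occ <= length(inside_vdw)]
  occ[!inside_vdw[occ]]
}

# --- single-orientation cavity computation ---------------------------------

cavity_one_orientation <- function(coords, radii, params, seed_point = NULL) {
  h <- params$grid_spacing
  grid <- make_grid(coords, max(radii) + params$probe_radius, h)
  blocked <- mark_spheres(grid, coords, radii + params$probe_radius)
  open <- !blocked
  exterior <- flood_fill(open, grid$dims, boundary_indices(grid$dims))
  cavity_mask <- which(open & !exterior)
  if (length(cavity_mask) == 0L)
    return(list(volume = 0, no_cavity = TRUE, cavity_idx = integer(0),
                grid = grid))
  comps <- grid_components(cavity_mask, open, grid$dims)
  if (!is.null(seed_point)) {
    # pick the component whose nearest voxel is closest to the seed point
    dmin <- vapply(comps, function(ci) {
      cc <- voxel_centers(grid, ci)
      min(colSums((t(cc) - seed_point)^2))
    }, numeric(1))
    sel <- comps[[which.min(dmin)]]
  } else {
    sel <- comps[[which.max(lengths(comps))]]
  }
  vol_idx <- if (params$volume_convention == "probe-center") sel else {
    inside_vdw <- mark_spheres(grid, coords, radii)
    probe_occupied_indices(sel, grid, inside_vdw, params$probe_radius)
  }
  list(volume = length(vol_idx) * h^3, no_cavity = FALSE,
       cavity_idx = sel, occupied_idx = vol_idx, grid = grid)
}

#' Probe-occupied cavity volume, averaged over randomized orientations
#'
#' For each orientation (the first is the input orientation, the rest
#' seeded uniform rotations about the centroid) the structure is regridded,
#' solvent is flood-filled from the box boundary, interior probe-accessible
#' components are identified, one cavity is selected (largest, or the one
#' containing `seed_point`), and its volume is measured under the configured
#' convention. The orientation scatter quantifies grid anisotropy.
#'
#' @param structure A `protein_structure` (or `toy_structure`).
#' @param params A [cavity_params()].
#' @return Object of class `cavity_result`: `volumes` (per orientation),
#'   `mean`, `sd`, `no_cavity` flag, `cavity_voxels` (voxel centres of the
#'   selected cavity in the reference orientation), `voxel_volume`, `params`.
#' @export
cavity_volume <- function(structure, params = cavity_params()) {
  stopifnot(inherits(params, "cavity_params"))
  if (inherits(structure, "toy_structure")) structure <- structure$structure
  coords <- atom_coords(structure)
  if (nrow(coords) == 0L) stop("empty structure")
  radii <- atom_radii(structure$atoms$element, params$radius_inflation,
                      params$default_radius)
  center <- colMeans(coords)
  rots <- random_rotations(params$n_orientations, params$seed)
  volumes <- numeric(params$n_orientations)
  cavity_voxels <- NULL
  any_cavity <- FALSE
  for (i in seq_along(rots)) {
    rc <- sweep(sweep(coords, 2L, center) %*% t(rots[[i]]), 2L, center, "+")
    sp <- params$seed_point
    if (!is.null(sp))
      sp <- as.numeric(rots[[i]] %*% (sp - center) + center)
    one <- cavity_one_orientation(rc, radii, params, sp)
    volumes[i] <- one$volume
    any_cavity <- any_cavity || !one$no_cavity
    if (i == 1L && !one$no_cavity)
      cavity_voxels <- voxel_centers(one$grid, one$cavity_idx)
  }
  structure(list(volumes = volumes, mean = mean(volumes),
                 sd = stats::sd(volumes),
                 no_cavity = !any_cavity,
                 cavity_voxels = cavity_voxels,
                 voxel_volume = params$grid_spacing^3,
                 params = params),
            class = "cavity_result")
}

#' @export
print.cavity_result <- function(x, ...) {
  if (x$no_cavity) cat("cavity_result: no interior cavity found\n")
  else cat(sprintf("cavity_result: %.1f +/- %.1f A^3 over %d orientations\n",
                   x$mean, ifelse(is.na(x$sd), 0, x$sd), length(x$volumes)))
  invisible(x)
}

#' Grid-integrated molecular volume of an atom set
#'
#' Volume of the union of atomic spheres (vdW radii, optionally inflated by
#' the probe radius), orientation-averaged like [cavity_volume()]. Used
#' e.g. for a ligand's volume when asking whether a pocket can house it.
#'
#' @param structure A `protein_structure`, or a data.frame/matrix of atoms.
#' @param params A [cavity_params()] (`n_orientations`, `grid_spacing`,
#'   `seed`, radius handling are honoured).
#' @param convention `"vdw"` (default) or `"probe-inflated"` (radii grown by
#'   `probe_radius`).
#' @return List with `mean`, `sd`, `volumes`, `convention`.
#' @export
molecular_volume <- function(structure, params = cavity_params(),
                             convention = c("vdw", "probe-inflated")) {
  convention <- match.arg(convention)
  if (inherits(structure, "toy_structure")) structure <- structure$structure
  coords <- atom_coords(structure)
  if (nrow(coords) == 0L) stop("empty atom set")
  radii <- atom_radii(structure$atoms$element, params$radius_inflation,
                      params$default_radius)
  if (convention == "probe-inflated") radii <- radii + params$probe_radius
  center <- colMeans(coords)
  rots <- random_rotations(params$n_orientations, params$seed)
  h <- params$grid_spacing
  volumes <- vapply(rots, function(R) {
    rc <- sweep(sweep(coords, 2L, center) %*% t(R), 2L, center, "+")
    grid <- make_grid(rc, max(radii), h)
    sum(mark_spheres(grid, rc, radii)) * h^3
  }, numeric(1))
  list(mean = mean(volumes), sd = stats::sd(volumes), volumes = volumes,
       convention = convention)
}

#' Residues lining a cavity
#'
#' Residues with at least one heavy side-chain atom within `cutoff` of any
#' cavity voxel centre (reference orientation), sorted by distance. Glycine
#' has no heavy side-chain atom and therefore never qualifies.
#'
#' @param structure The structure the cavity was computed on.
#' @param cavity A [cavity_volume()] result with `cavity_voxels`.
#' @param cutoff Distance cutoff in Angstroms.
#' @return data.frame: chain, resno, resid, min_distance; one row per
#'   qualifying residue.
#' @export
pocket_lining_residues <- function(structure, cavity, cutoff = 3.5) {
  stopifnot(inherits(cavity, "cavity_result"))
  if (inherits(structure, "toy_structure")) structure <- structure$structure
  if (is.null(cavity$cavity_voxels) || nrow(cavity$cavity_voxels) == 0L)
    stop("cavity result has no voxels (no cavity found?)")
  a <- structure$atoms
  side <- a[a$element != "H" & !(a$name %in% c("N", "CA", "C", "O")), ,
            drop = FALSE]
  if (nrow(side) == 0L) return(data.frame(chain = character(0),
                                          resno = integer(0),
                                          resid = character(0),
                                          min_distance = numeric(0)))
  d <- min_dist_to_points(as.matrix(side[, c("x", "y", "z")]),
                          cavity$cavity_voxels)
  key <- paste(side$chain, side$resno)
  agg <- tapply(d, key, min)
  first <- !duplicated(key)
  info <- side[first, c("chain", "resno", "resid")]
  info$min_distance <- as.numeric(agg[paste(info$chain, info$resno)])
  out <- info[info$min_distance <= cutoff, , drop = FALSE]
  out[order(out$min_distance), , drop = FALSE]
}

# rowwise min distance from points (n x 3) to a reference set (m x 3)
min_dist_to_points <- function(points, ref, chunk = 2000L) {
  n <- nrow(points)
  out <- numeric(n)
  r2 <- rowSums(ref^2)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), r2, "+") - 2 * p %*% t(ref)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

#' Structural context of candidate substitutions
#'
#' For each substitution event carrying a reference residue number, finds
#' the corresponding residue in the structure via `residue_map`, measures
#' the minimum heavy-atom distance to the cavity voxels (or to supplied
#' ligand atom coordinates), and flags events within `cutoff` as
#' pocket-proximal. Unresolvable residue numbers are reported as unmapped,
#' not fatal.
#'
#' @param events An [enumerate_substitutions()] or [conservation_filter()]
#'   result (or its `events` data.frame) with `reference_number`.
#' @param structure The structure to measure in.
#' @param residue_map Named integer vector mapping reference numbers (names)
#'   to structure residue numbers, or `NULL` when reference numbers already
#'   are structure numbering.
#' @param cavity A [cavity_volume()] result, or `NULL` if `ligand_coords`
#'   given.
#' @param ligand_coords Optional m x 3 matrix of ligand atom coordinates
#'   used instead of cavity voxels.
#' @param cutoff Proximity cutoff in Angstroms (default 5).
#' @return The events data.frame with `structure_resno`, `min_distance`,
#'   `pocket_proximal`, `unmapped` columns appended.
#' @export
candidate_structural_context <- function(events, structure,
                                         residue_map = NULL,
                                         cavity = NULL,
                                         ligand_coords = NULL,
                                         cutoff = 5) {
  ev <- if (is.data.frame(events)) events else events$events
  if (inherits(structure, "toy_structure")) structure <- structure$structure
  ref <- if (!is.null(cavity)) {
    stopifnot(inherits(cavity, "cavity_result"))
    if (is.null(cavity$cavity_voxels)) stop("cavity result has no voxels")
    cavity$cavity_voxels
  } else if (!is.null(ligand_coords)) {
    as.matrix(ligand_coords)
  } else stop("supply either a cavity result or ligand coordinates")

  a <- structure$atoms
  a <- a[a$element != "H", , drop = FALSE]
  ev$structure_resno <- if (is.null(residue_map)) ev$reference_number else {
    unname(residue_map[as.character(ev$reference_number)])
  }
  ev$min_distance <- NA_real_
  for (i in seq_len(nrow(ev))) {
    rn <- ev$structure_resno[i]
    if (is.na(rn)) next
    at <- a[a$resno == rn, , drop = FALSE]
    if (nrow(at) == 0L) { ev$structure_resno[i] <- NA; next }
    ev$min_distance[i] <- min(min_dist_to_points(
      as.matrix(at[, c("x", "y", "z")]), ref))
  }
  ev$unmapped <- is.na(ev$structure_resno)
  ev$pocket_proximal <- !is.na(ev$min_distance) & ev$min_distance <= cutoff
  ev
}
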