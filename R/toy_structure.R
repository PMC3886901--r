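fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Toy hollow-shell structure with analytically known cavity volume
#'
#' Places carbon-like pseudo-atoms on a sphere of radius
#' `r_cav + atom_radius`, so the probe-occupied interior cavity is exactly a
#' sphere of radius `r_cav` with analytic volume `4/3*pi*r_cav^3`. Optional
#' filler atoms are placed at seeded uniform positions fully inside the
#' cavity (shrinking it), and an optional distant compact decoy cluster
#' provides surface residues that must never be reported as pocket-lining.
#' Probe-tightness of the shell (no probe-accessible path from interior to
#' exterior) is verified at construction by running the cavity engine on the
#' reference orientation; if the shell leaks, the point density is raised
#' and construction retried before failing loudly.
#'
#' Every atom gets its own residue number (shell chain `A`, filler chain
#' `F`, decoys chain `D`) and the side-chain atom name `CB`, so
#' pocket-lining queries see one pseudo-residue per atom.
#'
#' @param r_cav Analytic cavity radius in Angstroms (> probe radius).
#' @param shell_thickness Extra shell layers are added until the shell is at
#'   least this thick (default 1, a single layer).
#' @param shell_density Points per square Angstrom on the shell sphere
#'   (default 3: probe-tight with a wide margin while keeping the discrete
#'   wall within about 1% of the ideal smooth sphere).
#' @param n_filler Number of interior filler atoms (default 0).
#' @param filler_radius vdW-style radius used to keep filler centres inside
#'   the cavity (atoms are written as carbon; default 1.7).
#' @param n_decoys Atoms in the distant decoy cluster (default 0).
#' @param seed Integer RNG seed (filler/decoy placement).
#' @param atom_radius Shell pseudo-atom radius (carbon, 1.7).
#' @param probe_radius Probe the shell must be tight against (default 1.4).
#' @return Object of class `toy_structure`: list with `structure` (a
#'   `protein_structure`), `r_cav`, `analytic_volume`, `filler_union_volume`
#'   (grid-estimated, 0 when no filler), `analytic_volume_bound`
#'   (`analytic_volume - filler_union_volume`; the cavity volume can be at
#'   most this), `n_shell_atoms`, `seed` and the construction parameters.
#' @export
make_toy_structure <- function(r_cav = 4, shell_thickness = 1,
                               shell_density = 3, n_filler = 0L,
                               filler_radius = 1.7, n_decoys = 0L,
                               seed = 1L, atom_radius = 1.7,
                               probe_radius = 1.4) {
  if (r_cav <= probe_radius)
    stop("r_cav must exceed the probe radius for a cavity to exist")
  r_shell <- r_cav + atom_radius
  n_layers <- max(1L, ceiling(shell_thickness / (2 * atom_radius)))

  build <- function(density) {
    pts <- NULL
    for (l in seq_len(n_layers)) {
      rl <- r_shell + (l - 1L) * atom_radius * 1.2
      n <- ceiling(4 * pi * rl^2 * density)
      pts <- rbind(pts, fibonacci_sphere(n, rl))
    }
    pts
  }

  filler <- NULL
  decoys <- NULL
  withr::with_seed(seed, {
    if (n_filler > 0L) {
      rmax <- max(r_cav - filler_radius, 0.2)
      u <- stats::runif(n_filler)^(1 / 3) * rmax
      dir <- matrix(stats::rnorm(3L * n_filler), ncol = 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      filler <- dir * u
    }
    if (n_decoys > 0L) {
      far <- c(4 * r_shell + 10, 0, 0)
      decoys <- sweep(matrix(stats::rnorm(3L * n_decoys, sd = 1.0),
                             ncol = 3L), 2L, far, "+")
    }
  })

  density <- shell_density
  for (attempt in 1:3) {
    shell <- build(density)
    atoms <- rbind(shell, filler, decoys)
    chain <- c(rep("A", nrow(shell)),
               if (!is.null(filler)) rep("F", nrow(filler)),
               if (!is.null(decoys)) rep("D", nrow(decoys)))
    resid <- c(rep("SHL", nrow(shell)),
               if (!is.null(filler)) rep("FIL", nrow(filler)),
               if (!is.null(decoys)) rep("DEC", nrow(decoys)))
    st <- structure(list(atoms = data.frame(
      element = "C", name = "CB", resid = resid,
      resno = seq_len(nrow(atoms)), chain = chain,
      x = atoms[, 1L], y = atoms[, 2L], z = atoms[, 3L],
      occupancy = 1, type = "ATOM", stringsAsFactors = FALSE),
      source = sprintf("synthetic shell r_cav=%g", r_cav)),
      class = "protein_structure")

    # probe-tightness check on the bare shell, reference orientation only
    shell_only <- st
    shell_only$atoms <- st$atoms[st$atoms$chain == "A", , drop = FALSE]
    chk <- cavity_one_orientation(
      as.matrix(shell_only$atoms[, c("x", "y", "z")]),
      rep(atom_radius, nrow(shell_only$atoms)),
      cavity_params(probe_radius = probe_radius, grid_spacing = 0.5,
                    n_orientations = 1L, volume_convention = "probe-center"))
    center_idx <- {
      g <- chk$grid
      ijk <- pmin(g$dims, pmax(1L, as.integer(round((c(0, 0, 0) - g$origin) /
                                                    g$spacing)) + 1L))
      ijk[1L] + (ijk[2L] - 1L) * g$dims[1L] +
        (ijk[3L] - 1L) * g$dims[1L] * g$dims[2L]
    }
    if (!chk$no_cavity && center_idx %in% chk$cavity_idx) break
    if (attempt == 3L)
      stop("shell is not probe-tight even at density ", density,
           " atoms/A^2; increase shell_density")
    density <- density * 1.5
  }

  filler_union <- 0
  if (!is.null(filler)) {
    fil_st <- structure(list(atoms = data.frame(
      element = "C", name = "CB", resid = "FIL",
      resno = seq_len(nrow(filler)), chain = "F",
      x = filler[, 1L], y = filler[, 2L], z = filler[, 3L],
      occupancy = 1, type = "ATOM"), source = "filler"),
      class = "protein_structure")
    filler_union <- molecular_volume(
      fil_st, cavity_params(grid_spacing = 0.25, n_orientations = 1L))$mean
  }

  analytic <- 4 / 3 * pi * r_cav^3
  structure(list(structure = st,
                 r_cav = r_cav,
                 analytic_volume = analytic,
                 filler_union_volume = filler_union,
                 analytic_volume_bound = analytic - filler_union,
                 n_shell_atoms = sum(st$atoms$chain == "A"),
                 n_filler = if (is.null(filler)) 0L else nrow(filler),
                 n_decoys = if (is.null(decoys)) 0L else nrow(decoys),
                 shell_density = density, atom_radius = atom_radius,
                 probe_radius = probe_radius, seed = seed),
            class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("toy_structure: shell of %d atoms, analytic cavity %.2f A^3",
              x$n_shell_atoms, x$analytic_volume))
  if (x$n_filler > 0)
    cat(sprintf(" (bound %.2f with %d filler atoms)",
                x$analytic_volume_bound, x$n_filler))
  cat("\n")
  invisible(x)
}
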