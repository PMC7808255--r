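# Solvent-accessible surface area (Shrake-Rupley) and solvent-accessible
# volume (grid fill). Hydrogens and waters are excluded by default (heavy-
# atom convention with implicit-hydrogen radii); metals are included.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral lattice: point k (k = 1..n) sits at
#' z = 1 - (2k - 1)/n, azimuth k times the golden angle. No randomness,
#' so every area computation is bit-reproducible.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, `n_sphere_points` quasi-uniform points are placed on the
#' sphere of radius r_vdw + probe; a point is exposed when it lies outside
#' every other atom's expanded sphere. The per-atom area is
#' (exposed / n) * 4 * pi * (r_vdw + probe)^2.
#'
#' @param structure a `tyr_structure` with at least one heavy atom.
#' @param probe_radius probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param n_sphere_points points per atom (default 960).
#' @param include_hydrogens,include_water override the default exclusion of
#'   hydrogens and water (HOH) residues.
#' @return object of class `sasa_report` with fields `total_area` (A^2),
#'   `per_atom_area`, `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960,
                 include_hydrogens = FALSE, include_water = FALSE) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 1) stop("n_sphere_points must be positive")
  a <- .geometry_atoms(structure, include_hydrogens, include_water)
  if (nrow(a) < 1L) stop("no heavy atoms to measure")
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element)
  pts <- sphere_points(n_sphere_points)
  exposed <- .sr_exposed(coords, radii, probe_radius, pts)
  per_atom <- exposed / n_sphere_points * 4 * pi * (radii + probe_radius)^2
  structure(list(total_area = sum(per_atom), per_atom_area = per_atom,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 serial = a$serial),
            class = "sasa_report")
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf(
    "<sasa_report> total area %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
    x$total_area, length(x$per_atom_area), x$probe_radius,
    x$n_sphere_points))
  invisible(x)
}

# Shared grid setup: origin, dims and voxel-center clearance field for the
# heavy atoms of a structure. `cap` bounds the stored clearance; values at
# the cap mean "at least cap".
.make_grid <- function(coords, radii, spacing, pad, cap,
                       max_voxels = 4e7) {
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  dims <- as.integer(floor((hi - lo) / spacing)) + 2L
  if (prod(as.numeric(dims)) > max_voxels)
    stop("grid of ", paste(dims, collapse = "x"),
         " voxels exceeds the budget; increase grid spacing")
  clearance <- .grid_clearance(lo, dims, spacing, coords, radii, cap)
  list(origin = lo, dims = dims, spacing = spacing, clearance = clearance)
}

# 0-based flat indices of the voxels on the six faces of the grid.
.boundary_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  on_face <- ix == 1L | ix == nx | iy == 1L | iy == ny | iz == 1L | iz == nz
  which(on_face) - 1L
}

#' Solvent-accessible volume (grid)
#'
#' Volume of the region enclosed by the solvent-accessible surface: grid
#' voxels whose centers lie within r_vdw + probe of any atom center, plus
#' interior voxels unreachable by a 6-connected flood fill from the grid
#' boundary. Volume = voxel count x spacing^3.
#'
#' @inheritParams sasa
#' @param grid_spacing voxel edge length in Angstrom, in (0, 2].
#' @param max_voxels guard on grid size; exceeded grids raise an error
#'   suggesting a larger spacing.
#' @return object of class `volume_report` with `total_volume` (A^3),
#'   `grid_spacing`, `probe_radius`.
#' @export
accessible_volume <- function(structure, probe_radius = 1.4,
                              grid_spacing = 0.5,
                              include_hydrogens = FALSE,
                              include_water = FALSE, max_voxels = 4e7) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (grid_spacing <= 0 || grid_spacing > 2)
    stop("grid_spacing must be in (0, 2] Angstrom")
  a <- .geometry_atoms(structure, include_hydrogens, include_water)
  if (nrow(a) < 1L) stop("no heavy atoms to measure")
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element)
  g <- .make_grid(coords, radii, grid_spacing,
                  pad = max(radii) + probe_radius + 2 * grid_spacing,
                  cap = probe_radius, max_voxels = max_voxels)
  # occupied: center within r_vdw + probe of an atom <=> clearance < probe
  occupied <- g$clearance < probe_radius
  exterior <- .grid_flood(!occupied, g$dims, .boundary_indices(g$dims))
  inside <- occupied | (!exterior)
  structure(list(total_volume = sum(inside) * grid_spacing^3,
                 grid_spacing = grid_spacing, probe_radius = probe_radius,
                 n_voxels = sum(inside)),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(
    "<volume_report> %.1f A^3 (probe %.2f A, grid %.2f A, %d voxels)\n",
    x$total_volume, x$probe_radius, x$grid_spacing, x$n_voxels))
  invisible(x)
}
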