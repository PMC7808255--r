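# Interior-cavity detection on a voxel grid.
#
# Semantics of the three scalar parameters: the probe radius is the size
# of exterior solvent (bulk water cannot enter clefts narrower than it);
# the interior threshold is the minimum clearance for a voxel to count as
# free interior space; the minimum depth discards shallow surface
# dimples. Exterior space is grown in two stages: a 6-connected flood
# fill from the grid boundary over voxels with clearance >= probe_radius,
# then expansion over connected voxels with clearance >=
# interior_threshold reachable from that set. Whatever free interior
# space remains unconnected to the exterior is a cavity.

#' Cavity-detection parameters
#'
#' Defaults follow the analysis convention for tyrosinase: probe radius
#' 3.00 A, interior threshold 1.25 A, minimum depth 5.00 A.
#'
#' @param probe_radius exterior solvent radius in Angstrom (> interior
#'   threshold).
#' @param interior_threshold minimum interior clearance in Angstrom (> 0).
#' @param min_depth burial filter in Angstrom (>= 0): cavities whose
#'   deepest voxel is closer than this to exterior space are discarded.
#' @param grid_spacing voxel edge length in Angstrom, in (0, 2].
#' @return object of class `cavity_params`.
#' @export
cavity_params <- function(probe_radius = 3.00, interior_threshold = 1.25,
                          min_depth = 5.00, grid_spacing = 0.6) {
  if (!(probe_radius > interior_threshold && interior_threshold > 0))
    stop("need probe_radius > interior_threshold > 0")
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (grid_spacing <= 0 || grid_spacing > 2)
    stop("grid_spacing must be in (0, 2] Angstrom")
  structure(list(probe_radius = probe_radius,
                 interior_threshold = interior_threshold,
                 min_depth = min_depth, grid_spacing = grid_spacing),
            class = "cavity_params")
}

#' Detect interior cavities
#'
#' Grid-based detection: free interior voxels (clearance >=
#' `interior_threshold`) that cannot be reached from the grid boundary
#' are clustered into 6-connected components; each component is a cavity
#' with volume = voxel count x spacing^3, depth = the largest Euclidean
#' distance from one of its voxels to the nearest exterior voxel, and a
#' set of lining residues (residues owning an atom within r_vdw +
#' interior_threshold + spacing of a cavity voxel). Components shallower
#' than `min_depth` are discarded. Hydrogens and waters are excluded;
#' metals are included.
#'
#' @param structure a `tyr_structure` with at least 4 heavy atoms.
#' @param params a [cavity_params] object.
#' @param max_voxels guard on grid size.
#' @return object of class `cavity_set`: list with `cavities` (list of
#'   `cavity` objects sorted by volume, largest first) and `parameters`.
#' @export
detect_cavities <- function(structure, params = cavity_params(),
                            max_voxels = 4e7) {
  stopifnot(inherits(params, "cavity_params"))
  a <- .geometry_atoms(structure)
  if (nrow(a) < 4L) stop("need at least 4 heavy atoms")
  coords <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element)
  sp <- params$grid_spacing
  g <- .make_grid(coords, radii, sp,
                  pad = max(radii) + params$probe_radius + 2 * sp,
                  cap = params$probe_radius, max_voxels = max_voxels)
  free_int <- g$clearance >= params$interior_threshold
  free_probe <- g$clearance >= params$probe_radius
  bnd <- .boundary_indices(g$dims)
  ext1 <- .grid_flood(free_probe, g$dims, bnd)
  exterior <- .grid_flood(free_int, g$dims, which(ext1) - 1L)
  cav_mask <- free_int & !exterior
  empty <- structure(list(cavities = list(), parameters = params,
                          grid = list(origin = g$origin, dims = g$dims,
                                      spacing = sp)),
                     class = "cavity_set")
  if (!any(cav_mask)) return(empty)
  labels <- .grid_components(cav_mask, g$dims)
  dist_ext <- .grid_edt(exterior, g$dims) * sp
  nx <- g$dims[1]; ny <- g$dims[2]
  cavities <- list()
  for (lab in seq_len(max(labels))) {
    vox <- which(labels == lab)
    depth <- max(dist_ext[vox])
    if (depth < params$min_depth) next
    idx0 <- vox - 1L
    iz <- idx0 %/% (nx * ny)
    iy <- (idx0 - iz * nx * ny) %/% nx
    ix <- idx0 - iz * nx * ny - iy * nx
    vc <- cbind(g$origin[1] + ix * sp, g$origin[2] + iy * sp,
                g$origin[3] + iz * sp)
    # lining residues: distance from each atom to its nearest cavity voxel,
    # read off a distance transform of the component mask
    comp_mask <- labels == lab
    dist_comp <- .grid_edt(comp_mask, g$dims) * sp
    ai <- pmin(pmax(round((coords - matrix(g$origin, nrow(coords), 3,
                                           byrow = TRUE)) / sp), 0),
               matrix(g$dims - 1L, nrow(coords), 3, byrow = TRUE))
    aidx <- ai[, 1] + nx * (ai[, 2] + ny * ai[, 3]) + 1
    near <- dist_comp[aidx] <= radii + params$interior_threshold + sp
    lining <- unique(a[near, c("chain", "resno"), drop = FALSE])
    rownames(lining) <- NULL
    cavities[[length(cavities) + 1L]] <- structure(
      list(volume = length(vox) * sp^3, voxel_count = length(vox),
           depth = depth, centroid = colMeans(vc),
           lining_residues = lining),
      class = "cavity")
  }
  if (!length(cavities)) return(empty)
  vols <- vapply(cavities, `[[`, numeric(1), "volume")
  cavities <- cavities[order(-vols)]
  structure(list(cavities = cavities, parameters = params,
                 grid = list(origin = g$origin, dims = g$dims,
                             spacing = sp)),
            class = "cavity_set")
}

#' Total volume of the largest cavities
#'
#' Sum of the `top_n` largest cavity volumes (all of them when fewer than
#' `top_n` are present; 0 for an empty set). The analysis convention sums
#' the three largest as an approximation of total interior cavity volume.
#'
#' @param cavity_set a `cavity_set`.
#' @param top_n how many of the largest cavities to sum (default 3).
#' @return total volume in A^3.
#' @export
total_cavity_volume <- function(cavity_set, top_n = 3) {
  stopifnot(inherits(cavity_set, "cavity_set"), top_n >= 1)
  vols <- vapply(cavity_set$cavities, `[[`, numeric(1), "volume")
  if (!length(vols)) return(0)
  sum(sort(vols, decreasing = TRUE)[seq_len(min(top_n, length(vols)))])
}

#' Residue numbers of the tyrosinase EGF-like domain
#'
#' The EGF-like domain occupies the first hundred residues of the mature
#' intra-melanosomal domain (which starts at residue 19), i.e. 19-118.
#' @export
egf_domain_residues <- 19:118

#' Aromatic residues lining the EGF-Tyr interface cavity
#'
#' Named default selection: F98, F105, F176, W210, F429, Y433, F438.
#' @export
egf_interface_residues <- c(98, 105, 176, 210, 429, 433, 438)

#' Identify the cavity at the interface of two domains
#'
#' Among cavities whose lining residues intersect BOTH residue sets,
#' returns the largest; `NULL` if none qualifies. Used to track the
#' hydrophobic pocket between the EGF-like domain and the catalytic
#' domain of tyrosinase.
#'
#' @param cavity_set a `cavity_set`.
#' @param domain_a,domain_b disjoint integer vectors of residue numbers
#'   (or data.frames with `chain` and `resno` columns).
#' @return a `cavity` or `NULL`.
#' @export
interface_cavity <- function(cavity_set, domain_a, domain_b) {
  stopifnot(inherits(cavity_set, "cavity_set"))
  resnos <- function(d) if (is.data.frame(d)) d$resno else as.integer(d)
  ra <- resnos(domain_a); rb <- resnos(domain_b)
  if (length(intersect(ra, rb)))
    stop("domain residue sets must be disjoint")
  touches <- function(cav, rs) any(cav$lining_residues$resno %in% rs)
  hits <- Filter(function(cv) touches(cv, ra) && touches(cv, rb),
                 cavity_set$cavities)
  if (!length(hits)) return(NULL)
  vols <- vapply(hits, `[[`, numeric(1), "volume")
  hits[[which.max(vols)]]
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf(
    "<cavity> %.1f A^3 (%d voxels), depth %.1f A, %d lining residues\n",
    x$volume, x$voxel_count, x$depth, nrow(x$lining_residues)))
  invisible(x)
}

#' @export
print.cavity_set <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<cavity_set> %d cavities (probe %.2f, interior %.2f, min depth %.2f, spacing %.2f A)\n",
    length(x$cavities), p$probe_radius, p$interior_threshold,
    p$min_depth, p$grid_spacing))
  for (cv in head(x$cavities, 5)) {
    cat(sprintf("  %.1f A^3, depth %.1f A\n", cv$volume, cv$depth))
  }
  if (length(x$cavities) > 5) cat("  ...\n")
  invisible(x)
}

#' Tabulate a cavity set
#'
#' One row per cavity: rank, volume, voxel count, depth, centroid and the
#' number of lining residues.
#'
#' @param x a `cavity_set`.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.cavity_set <- function(x, ...) {
  if (!length(x$cavities))
    return(data.frame(rank = integer(), volume = numeric(),
                      voxel_count = integer(), depth = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      n_lining = integer()))
  do.call(rbind, lapply(seq_along(x$cavities), function(i) {
    cv <- x$cavities[[i]]
    data.frame(rank = i, volume = cv$volume, voxel_count = cv$voxel_count,
               depth = cv$depth, cx = cv$centroid[1], cy = cv$centroid[2],
               cz = cv$centroid[3], n_lining = nrow(cv$lining_residues))
  }))
}
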