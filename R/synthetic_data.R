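# Deterministic synthetic-structure generators. Every generator returns
# its ground truth alongside the structure so downstream modules are
# tested against construction, not against themselves.

#' Hollow spherical shell with an analytically known interior cavity
#'
#' Atoms are placed quasi-uniformly (deterministic golden-spiral lattice)
#' on a sphere. The enclosed cavity detected with interior threshold t
#' has analytic volume (4/3) pi (shell_radius - r_vdw - t)^3. A positive
#' `aperture` removes the atoms inside a cone around +z to open a mouth
#' of that chord diameter.
#'
#' @param shell_radius sphere radius in Angstrom.
#' @param atom_spacing target nearest-neighbor spacing on the sphere in
#'   Angstrom; must be small enough to seal the shell.
#' @param element element symbol for the shell atoms (default "C").
#' @param aperture mouth chord diameter in Angstrom (0 = closed shell).
#' @param center shell center.
#' @param interior_threshold clearance threshold used for the analytic
#'   volume and the sealing check (default 1.25).
#' @param id structure identifier.
#' @param chain chain ID for the shell atoms.
#' @param resno_offset first residue number minus one (each atom gets its
#'   own residue number).
#' @return list with `structure` (a `tyr_structure`), `analytic_volume`
#'   (A^3), and `inner_radius` (A).
#' @export
make_hollow_shell <- function(shell_radius = 12, atom_spacing = 1.5,
                              element = "C", aperture = 0,
                              center = c(0, 0, 0),
                              interior_threshold = 1.25,
                              id = "shell", chain = "A",
                              resno_offset = 0) {
  stopifnot(shell_radius > atom_spacing, aperture >= 0)
  rv <- vdw_radius(.normalize_element(element))
  # largest opening between three neighboring atoms is about the
  # circumradius of their triangle, spacing/sqrt(3); the wall must block
  # clearance at the interior threshold there
  if (atom_spacing / sqrt(3) - rv >= interior_threshold)
    stop("atom_spacing too large to seal the shell at this threshold")
  n <- max(4L, round(4 * pi * shell_radius^2 /
                       (atom_spacing^2 * sqrt(3) / 2)))
  pts <- sphere_points(n)
  if (aperture > 0) {
    half_angle <- asin(min(1, (aperture / 2) / shell_radius))
    keep <- acos(pmin(1, pmax(-1, pts[, 3]))) > half_angle
    pts <- pts[keep, , drop = FALSE]
  }
  xyz <- sweep(pts * shell_radius, 2, center, `+`)
  k <- nrow(xyz)
  atoms <- data.frame(
    type = "ATOM", serial = seq_len(k) + resno_offset,
    name = toupper(element), alt = "", resid = "DUM", chain = chain,
    resno = seq_len(k) + resno_offset, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    element = .normalize_element(element), stringsAsFactors = FALSE)
  inner <- shell_radius - rv - interior_threshold
  list(structure = new_structure(atoms, id = id),
       analytic_volume = 4 / 3 * pi * inner^3,
       inner_radius = inner)
}

#' Two-domain assembly whose interface pocket opens by rigid drift
#'
#' A hollow shell is split at the x = 0 plane into domain A (x < 0,
#' chain A) and domain B (x >= 0, chain B); across frames, domain A
#' translates rigidly along -x by `drift_per_frame`, widening the sealed
#' interface pocket monotonically. Optionally a binuclear metal site
#' (two Cu plus His-like ND1/NE2 nitrogen ligands at 2.1 A) is embedded
#' with domain B. The returned ground truth is the analytic
#' sphere-plus-slab estimate of the pocket volume per frame,
#' (4/3) pi r_in^3 + pi r_in^2 d at separation d.
#'
#' @param shell_radius,atom_spacing,interior_threshold shell geometry
#'   (see [make_hollow_shell]).
#' @param n_frames number of frames (>= 1).
#' @param drift_per_frame rigid displacement of domain A along -x per
#'   frame step, in Angstrom (total separation stays well below the leak
#'   width so the pocket remains sealed).
#' @param times frame time labels in ns (default evenly spaced over
#'   0-100).
#' @param metal_pair `NULL`, or a list with `distance` (Cu-Cu separation,
#'   A) and `n_ligands` (His-like N per metal, default 3).
#' @param jitter_sd Gaussian positional jitter (A) applied once to the
#'   shell lattice (shared by all frames, so frames stay rigid copies).
#' @param seed RNG seed for the jitter.
#' @param id identifier prefix.
#' @return list with `trajectory` (a `tyr_trajectory`), `truth`
#'   (data.frame time, separation, analytic_interface_volume),
#'   `domain_a`, `domain_b` (residue-number vectors).
#' @export
make_two_domain_trajectory <- function(shell_radius = 10,
                                       atom_spacing = 1.4,
                                       interior_threshold = 1.25,
                                       n_frames = 2,
                                       drift_per_frame = 1.0,
                                       times = NULL,
                                       metal_pair = list(distance = 2.75,
                                                         n_ligands = 3),
                                       jitter_sd = 0, seed = 1,
                                       id = "twodomain") {
  stopifnot(n_frames >= 1)
  shell <- make_hollow_shell(shell_radius, atom_spacing,
                             interior_threshold = interior_threshold,
                             id = id)
  base <- shell$structure$atoms
  if (jitter_sd > 0) {
    set.seed(seed)
    jit <- matrix(rnorm(3 * nrow(base), 0, jitter_sd), ncol = 3)
    base$x <- base$x + jit[, 1]
    base$y <- base$y + jit[, 2]
    base$z <- base$z + jit[, 3]
  }
  in_a <- base$x < 0
  base$chain <- ifelse(in_a, "A", "B")
  domain_a <- base$resno[in_a]
  domain_b <- base$resno[!in_a]
  if (!is.null(metal_pair)) {
    nl <- if (is.null(metal_pair$n_ligands)) 3L else metal_pair$n_ligands
    dm <- metal_pair$distance
    c1 <- c(shell_radius + 5, 0, 0)
    c2 <- c1 + c(dm, 0, 0)
    mk_lig <- function(center, n, resno0) {
      ang <- 2 * pi * (seq_len(n) - 1) / n
      data.frame(
        type = "HETATM", serial = 0L,
        name = rep(c("ND1", "NE2"), length.out = n), alt = "",
        resid = "HIS", chain = "B",
        resno = resno0 + seq_len(n), insert = "",
        x = center[1], y = center[2] + 2.1 * cos(ang),
        z = center[3] + 2.1 * sin(ang), occ = 1, element = "N",
        stringsAsFactors = FALSE)
    }
    r0 <- max(base$resno)
    met <- data.frame(
      type = "HETATM", serial = 0L, name = "CU", alt = "",
      resid = "CU", chain = "B", resno = r0 + c(1L, 2L), insert = "",
      x = c(c1[1], c2[1]), y = c(c1[2], c2[2]), z = c(c1[3], c2[3]),
      occ = 1, element = "Cu", stringsAsFactors = FALSE)
    base <- rbind(base, met,
                  mk_lig(c1, nl, r0 + 2L),
                  mk_lig(c2, nl, r0 + 2L + nl))
    base$serial <- seq_len(nrow(base))
    domain_b <- c(domain_b, (r0 + 1):(r0 + 2 + 2 * nl))
  }
  if (is.null(times)) {
    times <- if (n_frames == 1) 0 else seq(0, 100, length.out = n_frames)
  }
  stopifnot(length(times) == n_frames)
  rv <- vdw_radius("C")
  r_in <- shell_radius - rv - interior_threshold
  frames <- vector("list", n_frames)
  truth <- data.frame(time = times, separation = NA_real_,
                      analytic_interface_volume = NA_real_)
  for (k in seq_len(n_frames)) {
    sep <- (k - 1) * drift_per_frame
    fa <- base
    shift <- fa$chain == "A" & fa$resno %in% domain_a
    fa$x[shift] <- fa$x[shift] - sep
    frames[[k]] <- new_structure(fa, id = sprintf("%s_f%d", id, k),
                                 time = times[k])
    truth$separation[k] <- sep
    truth$analytic_interface_volume[k] <-
      4 / 3 * pi * r_in^3 + pi * r_in^2 * sep
  }
  list(trajectory = as_trajectory(frames, times), truth = truth,
       domain_a = sort(domain_a), domain_b = sort(domain_b))
}

#' Synthetic ddG-vs-cavity-response table with known linear structure
#'
#' ddG values are drawn uniformly over `ddg_range`; the cavity response
#' is `slope * ddg + intercept + N(0, noise_sd)`. Fully reproducible per
#' seed. The noise sits on the structural response only: ddG values are
#' semi-empirical energy outputs and are treated as exact, while cavity
#' volumes carry measurement noise.
#'
#' @param n_mutants number of rows.
#' @param slope,intercept true regression coefficients (A^3 per kcal/mol
#'   and A^3).
#' @param noise_sd Gaussian noise SD on the response (A^3, >= 0).
#' @param ddg_range range (low < high) for the uniform ddG draw,
#'   kcal/mol.
#' @param seed RNG seed.
#' @return data.frame with columns mutation, ddg, dd_vcav.
#' @export
make_ddg_table <- function(n_mutants = 8, slope = 749.1,
                           intercept = 423.0, noise_sd = 0,
                           ddg_range = c(-2, 6), seed = 1) {
  stopifnot(noise_sd >= 0, ddg_range[1] < ddg_range[2], n_mutants >= 1)
  set.seed(seed)
  ddg <- sort(runif(n_mutants, ddg_range[1], ddg_range[2]))
  dd_vcav <- slope * ddg + intercept + rnorm(n_mutants, 0, noise_sd)
  data.frame(mutation = sprintf("M%03d", seq_len(n_mutants)),
             ddg = ddg, dd_vcav = dd_vcav, stringsAsFactors = FALSE)
}
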