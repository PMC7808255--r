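# Fixture builders shared by the tests. Everything is generated in code;
# no data files are read.

# One PDB v3.3 fixed-column ATOM/HETATM line.
pdb_line <- function(type = "ATOM", serial = 1, name = "CA", alt = "",
                     resid = "ALA", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, occ = 1, b = 0, element = "C") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, alt, resid, chain, resno,
          x, y, z, occ, b, toupper(element))
}

# Quick structure from bare coordinates (all carbon unless specified).
make_structure <- function(xyz, element = "C", name = toupper(element),
                           resid = "DUM", chain = "A", id = "fix") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  new_structure(data.frame(
    name = rep(name, length.out = n), resid = resid, chain = chain,
    resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(element, length.out = n), stringsAsFactors = FALSE),
    id = id)
}

# Random globular cluster of carbons (dense enough to have no interior).
make_cluster <- function(n = 50, radius = 4, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * runif(n)^(1 / 3)
  make_structure(pts, id = "cluster")
}

# Rigidly transform the coordinates of a structure.
rigid_transform <- function(s, angle = pi / 5, axis = c(0, 0, 1),
                            shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# Two-copper site with n His-like nitrogen ligands per copper at 2.1 A
# (n_ligands = 0 gives a bare metal pair).
make_metal_site <- function(separation = 2.75, n_ligands = 3,
                            ligand_dist = 2.1) {
  c1 <- c(0, 0, 0); c2 <- c(separation, 0, 0)
  ang <- 2 * pi * (seq_len(n_ligands) - 1) / max(1, n_ligands)
  lig <- function(center, resno0) data.frame(
    name = rep(c("ND1", "NE2"), length.out = n_ligands),
    resid = rep("HIS", n_ligands), chain = rep("A", n_ligands),
    resno = resno0 + seq_len(n_ligands),
    x = rep(center[1], n_ligands),
    y = center[2] + ligand_dist * cos(ang),
    z = center[3] + ligand_dist * sin(ang),
    element = rep("N", n_ligands), stringsAsFactors = FALSE)
  met <- data.frame(name = "CU", resid = "CU", chain = "A",
                    resno = 1:2, x = c(c1[1], c2[1]), y = 0, z = 0,
                    element = "Cu", stringsAsFactors = FALSE)
  new_structure(rbind(met, lig(c1, 10), lig(c2, 20)), id = "cusite")
}
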