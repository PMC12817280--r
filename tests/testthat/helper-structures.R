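# Programmatic construction of tiny peptide backbones with prescribed
# torsions (NeRF: place each atom from bond length, bond angle, dihedral)
# and plain-text PDB output, so omega-census tests need no stored fixtures.

# position atom D given A-B-C, |CD| = r, angle BCD = theta (deg),
# dihedral ABCD = chi (deg)
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone (N, CA, C per residue) with given per-bond omega angles;
# phi/psi fixed at extended-chain values
build_backbone <- function(n_res, omegas = rep(180, n_res - 1),
                           phi = -120, psi = 120) {
  stopifnot(length(omegas) == n_res - 1)
  coords <- list()
  coords[["N1"]] <- c(0, 0, 0)
  coords[["CA1"]] <- c(1.46, 0, 0)
  coords[["C1"]] <- coords[["CA1"]] +
    1.52 * c(cos(pi * (180 - 111) / 180), sin(pi * (180 - 111) / 180), 0)
  for (i in 2:n_res) {
    p_n <- coords[[paste0("N", i - 1)]]
    p_ca <- coords[[paste0("CA", i - 1)]]
    p_c <- coords[[paste0("C", i - 1)]]
    n_i <- nerf_place(p_n, p_ca, p_c, 1.33, 116.2, psi)
    ca_i <- nerf_place(p_ca, p_c, n_i, 1.46, 121.7, omegas[i - 1])
    c_i <- nerf_place(p_c, n_i, ca_i, 1.52, 111.0, phi)
    coords[[paste0("N", i)]] <- n_i
    coords[[paste0("CA", i)]] <- ca_i
    coords[[paste0("C", i)]] <- c_i
  }
  coords
}

write_backbone_pdb <- function(coords, n_res, path,
                               resnames = rep("GLY", n_res), chain = "A") {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1L
      xyz <- coords[[paste0(at, i)]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, at, resnames[i], chain, i, xyz[1], xyz[2], xyz[3],
        substr(at, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# rigid rotation of every coordinate (for the rotation-invariance property)
rotate_coords <- function(coords, angles = c(0.3, 1.1, -0.7)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% ry %*% rz
  lapply(coords, function(v) as.numeric(rot %*% v + c(5, -3, 2)))
}
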