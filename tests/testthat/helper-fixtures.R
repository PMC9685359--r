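# Minimal atom-table builder: one row per atom. `resno` groups atoms into
# residues; defaults give each atom its own glycine residue with a CA name.
make_atoms <- function(coords, element = "C", name = "CA", chain = "A",
                       resno = NULL, resname = "GLY", radius = NULL,
                       charge = 0L) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(n)
  element <- rep_len(element, n)
  if (is.null(radius)) {
    radius <- unname(default_vdw_radii()[element])
    radius[is.na(radius)] <- 1.7
  }
  tibble::tibble(
    serial = seq_len(n),
    name = rep_len(name, n),
    element = element,
    chain = rep_len(chain, n),
    resno = rep_len(resno, n),
    resname = rep_len(resname, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = rep_len(radius, n),
    charge = rep_len(as.integer(charge), n)
  )
}

# A chain of single-CA residues with the given residue names.
make_chain <- function(resnames, chain = "A", spacing = 3.8, y = 0, z = 0) {
  n <- length(resnames)
  make_atoms(cbind((seq_len(n) - 1) * spacing, y, z),
             element = "C", name = "CA", chain = chain,
             resno = seq_len(n), resname = resnames)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resno, x, y, z, element)
}

# Non-collinear chain of single-CA residues (helical path), suitable for
# superposition-based metrics.
make_helix_chain <- function(n, chain = "A", radius = 6, rise = 1.5) {
  th <- seq_len(n) * 2 * pi / 3.6
  make_atoms(cbind(radius * cos(th), radius * sin(th), rise * seq_len(n)),
             element = "C", name = "CA", chain = chain,
             resno = seq_len(n), resname = "GLY")
}

# Independent superposition oracle: Horn's quaternion method.
horn_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

rigid_transform <- function(coords, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(coords %*% t(R), 2, shift, "+")
}

# Small static replica set from a list of frames.
static_replicas <- function(topology, frames_per_rep, phase = "bulk",
                            times = NULL) {
  trs <- lapply(seq_along(frames_per_rep), function(r) {
    fr <- frames_per_rep[[r]]
    trajectory_ensemble(topology, fr,
                        times = if (is.null(times)) seq_along(fr) else times,
                        replica_id = paste0("r", r), phase = phase)
  })
  replica_set(trs)
}
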