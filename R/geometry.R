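#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic spherical point set used by the Shrake-Rupley SASA kernel
#' and the grid CCS oracle's orientation set.
#'
#' @param n Number of points (>= 1).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom accessible area by sphere-point sampling: each atom's sphere is
#' expanded by the probe radius and covered with a deterministic Fibonacci
#' lattice; the accessible area is `4*pi*(r+probe)^2` times the fraction of
#' points not buried inside any neighbouring expanded sphere.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Atom radii (Angstrom), positive.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere points per atom (>= 92; default 960).
#' @return Numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0), n_points >= 92)
  pts <- fibonacci_sphere(n_points)
  rex <- radii + probe
  # neighbour lists: atoms whose expanded spheres can overlap
  d2 <- as.matrix(stats::dist(coords))^2
  if (n > 1) {
    coincident <- which(d2[upper.tri(d2)] == 0)
    if (length(coincident) > 0) {
      warn("coincident atom centres detected; both treated normally")
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (rex[i] + rex)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rex[i]^2
      next
    }
    surf <- pts * rex[i]
    surf <- sweep(surf, 2, coords[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj <- sweep(surf, 2, coords[j, ], "-")
      buried <- buried | (rowSums(dj^2) < rex[j]^2)
      if (all(buried)) break
    }
    out[i] <- 4 * pi * rex[i]^2 * mean(!buried)
  }
  out
}

#' Total solvent accessible surface area of a structure
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere points per atom.
#' @return Total SASA in Angstrom^2.
#' @export
total_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  sum(shrake_rupley_sasa(atom_coords(atoms), atoms$radius,
                         probe = probe, n_points = n_points))
}

#' Grid-based van der Waals molecular volume
#'
#' Counts voxel centres lying inside at least one atomic sphere over a
#' bounding box padded by the largest radius.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Atom radii (Angstrom).
#' @param voxel Grid spacing in Angstrom (default 0.3).
#' @return Volume in Angstrom^3.
#' @export
molecular_volume <- function(coords, radii, voxel = 0.3) {
  coords <- as.matrix(coords)
  stopifnot(voxel > 0, nrow(coords) == length(radii))
  pad <- max(radii)
  lo <- apply(coords, 2, min) - pad - voxel
  hi <- apply(coords, 2, max) + pad + voxel
  nx <- ceiling((hi - lo) / voxel)
  gx <- lo[1] + (seq_len(nx[1]) - 0.5) * voxel
  gy <- lo[2] + (seq_len(nx[2]) - 0.5) * voxel
  gz <- lo[3] + (seq_len(nx[3]) - 0.5) * voxel
  inside <- array(FALSE, dim = nx)
  for (a in seq_len(nrow(coords))) {
    r <- radii[a]
    ix <- which(abs(gx - coords[a, 1]) <= r)
    iy <- which(abs(gy - coords[a, 2]) <= r)
    iz <- which(abs(gz - coords[a, 3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - coords[a, 1])^2
    dy2 <- (gy[iy] - coords[a, 2])^2
    dz2 <- (gz[iz] - coords[a, 3])^2
    # local cube, vectorised sphere test
    cube <- outer(dx2, dy2, "+")
    for (k in seq_along(iz)) {
      inside[ix, iy, iz[k]] <- inside[ix, iy, iz[k]] | (cube + dz2[k] <= r^2)
    }
  }
  sum(inside) * voxel^3
}

# Uniform random unit quaternions (Shoemake), returned as rotation matrices.
random_rotations <- function(n, seed) {
  set.seed(seed)
  u <- matrix(stats::runif(3 * n), ncol = 3)
  q <- cbind(
    sqrt(1 - u[, 1]) * sin(2 * pi * u[, 2]),
    sqrt(1 - u[, 1]) * cos(2 * pi * u[, 2]),
    sqrt(u[, 1]) * sin(2 * pi * u[, 3]),
    sqrt(u[, 1]) * cos(2 * pi * u[, 3])
  )
  lapply(seq_len(n), function(i) quat_to_rot(q[i, ]))
}

quat_to_rot <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Union area of discs (centres cxy, radii r) by pixel rasterization.
disc_union_area <- function(cxy, r, pixel) {
  lo <- c(min(cxy[, 1] - r), min(cxy[, 2] - r)) - pixel
  hi <- c(max(cxy[, 1] + r), max(cxy[, 2] + r)) + pixel
  nx <- ceiling((hi[1] - lo[1]) / pixel)
  ny <- ceiling((hi[2] - lo[2]) / pixel)
  gx <- lo[1] + (seq_len(nx) - 0.5) * pixel
  gy <- lo[2] + (seq_len(ny) - 0.5) * pixel
  covered <- matrix(FALSE, nx, ny)
  for (a in seq_len(nrow(cxy))) {
    ix <- which(abs(gx - cxy[a, 1]) <= r[a])
    iy <- which(abs(gy - cxy[a, 2]) <= r[a])
    if (!length(ix) || !length(iy)) next
    dx2 <- (gx[ix] - cxy[a, 1])^2
    dy2 <- (gy[iy] - cxy[a, 2])^2
    covered[ix, iy] <- covered[ix, iy] | (outer(dx2, dy2, "+") <= r[a]^2)
  }
  sum(covered) * pixel^2
}

#' Projection-approximation collision cross-section
#'
#' The PA collision cross-section is the union area of probe-expanded
#' atomic discs projected onto a plane, averaged over molecular
#' orientations. Orientations are drawn as seeded uniform random rotations
#' (quaternion method); the area of each projection is measured by
#' deterministic rasterization, so randomness enters only through the
#' orientation sample.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Atom radii (Angstrom).
#' @param probe Collision probe radius in Angstrom (default 1.0,
#'   helium-like).
#' @param n_orientations Number of random orientations (>= 1).
#' @param seed Integer seed for the orientation sample.
#' @param pixel Rasterization pixel size in Angstrom (default 0.5).
#' @param calibration Optional multiplicative calibration constant applied
#'   to the result (default 1, plain projection approximation).
#' @return A list of class `ccs_result` with fields `ccs` (Angstrom^2),
#'   `mc_standard_error`, `n_orientations`, `probe_radius`, `seed`.
#' @export
ccs_projection_approximation <- function(coords, radii, probe = 1.0,
                                         n_orientations = 100, seed = 1,
                                         pixel = 0.5, calibration = 1.0) {
  coords <- as.matrix(coords)
  stopifnot(n_orientations >= 1, nrow(coords) == length(radii))
  rex <- radii + probe
  ctr <- colMeans(coords)
  centred <- sweep(coords, 2, ctr)
  rots <- random_rotations(n_orientations, seed)
  areas <- vapply(rots, function(R) {
    xy <- centred %*% t(R)
    disc_union_area(xy[, 1:2, drop = FALSE], rex, pixel)
  }, numeric(1))
  ccs <- mean(areas) * calibration
  se <- if (n_orientations > 1) {
    stats::sd(areas) / sqrt(n_orientations) * calibration
  } else 0
  structure(
    list(ccs = ccs, mc_standard_error = se,
         n_orientations = n_orientations, probe_radius = probe, seed = seed),
    class = "ccs_result"
  )
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf("PA CCS: %.2f (+/- %.2f) A^2 over %d orientations (probe %.2f A)\n",
              x$ccs, x$mc_standard_error, x$n_orientations, x$probe_radius))
  invisible(x)
}

#' Deterministic grid oracle for the projection-approximation CCS
#'
#' Fine-pixel projected union area averaged over a fixed quasi-uniform
#' (Fibonacci) set of projection directions. Intended as a validation
#' oracle for small systems, so the atom count is guarded.
#'
#' @param coords `n x 3` coordinate matrix (<= 100 atoms).
#' @param radii Atom radii (Angstrom).
#' @param probe Probe radius (Angstrom).
#' @param grid Pixel size in Angstrom; must be below half the smallest
#'   expanded radius.
#' @param n_directions Number of quasi-uniform projection directions.
#' @return CCS estimate in Angstrom^2.
#' @export
ccs_grid_oracle <- function(coords, radii, probe = 1.0, grid = 0.2,
                            n_directions = 200) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("zero atoms: cannot compute a cross-section")
  if (nrow(coords) > 100) abort("grid oracle is limited to <= 100 atoms")
  rex <- radii + probe
  if (grid > min(rex) / 2) {
    abort(paste0("grid ", grid, " A too coarse for smallest expanded radius ",
                 round(min(rex), 3), " A"))
  }
  dirs <- fibonacci_sphere(n_directions)
  ctr <- colMeans(coords)
  centred <- sweep(coords, 2, ctr)
  areas <- vapply(seq_len(n_directions), function(k) {
    R <- rotation_to_z(dirs[k, ])
    xy <- centred %*% t(R)
    disc_union_area(xy[, 1:2, drop = FALSE], rex, grid)
  }, numeric(1))
  mean(areas)
}

# Rotation mapping unit vector v onto +z (projection plane normal).
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}
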