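test_that("Kabsch superposition removes rigid motion and matches the quaternion oracle", {
  set.seed(4)
  A <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(A, A)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  B <- rigid_transform(A, angle = pi / 2, axis = c(0, 0, 1), shift = c(1, 2, 3))
  fit <- kabsch_superpose(B, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # 4-point toy with one displaced point vs Horn's eigen-decomposition
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Q <- P; Q[4, ] <- Q[4, ] + c(0.3, -0.2, 0.5)
  expect_equal(kabsch_superpose(Q, P)$rmsd, horn_rmsd(Q, P),
               tolerance = 1e-10)
})

test_that("degenerate superpositions are rejected", {
  line <- cbind(0:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("RMSD series is zero for rigid-motion copies of the reference", {
  ref <- build_toy_dimer(12)
  X <- atom_coords(ref)
  frames <- lapply(seq(0.2, 1, by = 0.2), function(a) {
    rigid_transform(X, angle = a)
  })
  rs <- static_replicas(ref, list(frames, frames))
  ser <- rmsd_series(rs, ref)
  expect_true(all(ser$mean < 1e-8))
  expect_true(all(ser$spread < 1e-8))
})

test_that("RMSD of seeded Gaussian jitter matches the analytic expectation", {
  ref <- build_toy_dimer(16)
  X <- atom_coords(ref)
  sigma <- 0.5
  set.seed(31)
  frames <- lapply(1:60, function(k) X + matrix(rnorm(length(X), sd = sigma),
                                                nrow(X), 3))
  rs <- static_replicas(ref, list(frames), times = 1:60)
  ser <- rmsd_series(rs, ref, selection = "all")
  expect_equal(mean(ser$mean), sigma * sqrt(3), tolerance = 0.1)
})

test_that("misaligned replica frame times are rejected", {
  ref <- build_toy_dimer(10)
  X <- atom_coords(ref)
  t1 <- trajectory_ensemble(ref, list(X, X), times = c(1, 2), replica_id = "a")
  t2 <- trajectory_ensemble(ref, list(X, X), times = c(1, 3), replica_id = "b")
  rs <- replica_set(list(t1, t2))
  expect_error(rmsd_series(rs, ref), "misaligned")
})

test_that("average structure reproduces static and rigidly-moved ensembles", {
  ref <- build_toy_dimer(10)
  X <- atom_coords(ref)
  rs <- static_replicas(ref, list(list(X, X, X)))
  avg <- average_structure(rs)
  expect_equal(atom_coords(avg), X, tolerance = 1e-6)

  frames <- list(X, rigid_transform(X), rigid_transform(X, angle = 1.3))
  rs2 <- static_replicas(ref, list(frames))
  avg2 <- average_structure(rs2)
  expect_lt(kabsch_superpose(atom_coords(avg2), X)$rmsd, 1e-5)

  # frame-order invariance of the converged mean
  rs3 <- static_replicas(ref, list(rev(frames)))
  avg3 <- average_structure(rs3)
  expect_lt(kabsch_superpose(atom_coords(avg3), atom_coords(avg2))$rmsd, 1e-5)
})

test_that("RMSF recovers programmed per-atom fluctuations", {
  ch <- make_helix_chain(30)
  X <- atom_coords(ch)
  d <- 1.2
  frames <- lapply(1:40, function(k) {
    Y <- X
    Y[7, 1] <- Y[7, 1] + d * (-1)^k
    Y
  })
  rs <- static_replicas(ch, list(frames), times = 1:40)
  rmsf <- rmsf_per_residue(rs, selection = "calpha")
  # the least-squares fit absorbs ~1/n of the programmed displacement
  expect_equal(rmsf$rmsf[7], d, tolerance = 0.1)
  expect_lt(max(rmsf$rmsf[-7]), 0.15)
})

test_that("RMSF of Gaussian jitter converges to sigma*sqrt(3) at 200 frames", {
  ch <- make_helix_chain(40)
  X <- atom_coords(ch)
  sigma <- 0.4
  set.seed(77)
  frames <- lapply(1:200, function(k) X + matrix(rnorm(length(X), sd = sigma),
                                                 nrow(X), 3))
  rs <- static_replicas(ch, list(frames), times = 1:200)
  rmsf <- rmsf_per_residue(rs, selection = "calpha")
  expect_equal(mean(rmsf$rmsf), sigma * sqrt(3), tolerance = 0.1)
})

test_that("RMSF of pooled replicas equals RMSF of the concatenated frames", {
  ch <- make_helix_chain(12)
  X <- atom_coords(ch)
  set.seed(5)
  fr1 <- lapply(1:10, function(k) X + matrix(rnorm(length(X), sd = 0.3), nrow(X), 3))
  fr2 <- lapply(1:10, function(k) X + matrix(rnorm(length(X), sd = 0.3), nrow(X), 3))
  two <- static_replicas(ch, list(fr1, fr2), times = 1:10)
  one <- static_replicas(ch, list(c(fr1, fr2)), times = 1:20)
  avg <- average_structure(two)
  expect_equal(rmsf_per_residue(two, avg)$rmsf,
               rmsf_per_residue(one, avg)$rmsf, tolerance = 1e-9)
})

test_that("contact maps follow the minimum heavy-atom distance criterion", {
  two <- make_chain(rep("GLY", 2), spacing = 3.4)
  cm <- contact_map(atom_coords(two), two)
  expect_true(cm[1, 2])
  two_far <- make_chain(rep("GLY", 2), spacing = 3.6)
  expect_false(contact_map(atom_coords(two_far), two_far)[1, 2])

  # hydrogens are ignored
  hmix <- make_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(3.4, 0, 0)),
                     element = c("C", "H", "C"), name = c("CA", "H", "CA"),
                     resno = c(1, 1, 2))
  expect_true(contact_map(atom_coords(hmix), hmix)[1, 2])
  hmix2 <- make_atoms(rbind(c(0, 0, 0), c(2, 0, 0), c(5.4, 0, 0)),
                      element = c("C", "H", "C"), name = c("CA", "H", "CA"),
                      resno = c(1, 1, 2))
  expect_false(contact_map(atom_coords(hmix2), hmix2)[1, 2])
})

test_that("contact map equals the all-pairs brute-force oracle", {
  set.seed(13)
  top <- make_atoms(matrix(rnorm(36, sd = 3), 12, 3),
                    resno = rep(1:5, c(3, 2, 3, 2, 2)))
  X <- atom_coords(top)
  cm <- contact_map(X, top, cutoff = 3.5)
  oracle <- matrix(FALSE, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    di <- which(top$resno == i); dj <- which(top$resno == j)
    d2 <- outer(rowSums(X[di, , drop = FALSE]^2),
                rowSums(X[dj, , drop = FALSE]^2), "+") -
      2 * X[di, , drop = FALSE] %*% t(X[dj, , drop = FALSE])
    dmin <- min(sqrt(pmax(d2, 0)))
    oracle[i, j] <- dmin <= 3.5
  }
  diag(oracle) <- TRUE
  expect_equal(unclass(cm)[1:5, 1:5], oracle, ignore_attr = TRUE)
})

test_that("occupancy matrices are symmetric, unit-diagonal, monotone in cutoff", {
  ref <- build_toy_dimer(10)
  sp <- phase_spec("bulk", n_replicas = 2, n_frames = 5, jitter_sigma = 0.2,
                   seed = 3)
  rs <- generate_phase_ensemble(ref, sp)
  occ <- contact_occupancy(rs, cutoff = 3.5)
  expect_equal(unclass(occ), t(unclass(occ)), ignore_attr = TRUE)
  expect_true(all(diag(occ) == 1))
  expect_true(all(occ >= 0 & occ <= 1))
  occ_tight <- contact_occupancy(rs, cutoff = 3.0)
  expect_true(all(unclass(occ_tight) <= unclass(occ) + 1e-12))
  expect_error(contact_occupancy(rs, window = integer(0)), "window")
})

test_that("contact occupancy averages replicas and frames as programmed", {
  top <- make_chain(rep("GLY", 2), spacing = 3.0)
  near <- atom_coords(top)
  far <- near; far[2, 1] <- 10
  # contact in every frame of one replica, never in the other
  rs <- static_replicas(top, list(list(near, near), list(far, far)))
  occ <- contact_occupancy(rs)
  expect_equal(occ[1, 2], 0.5)

  set.seed(9)
  p <- 0.3
  frames <- lapply(1:300, function(k) if (runif(1) < p) near else far)
  rs2 <- static_replicas(top, list(frames), times = 1:300)
  occ2 <- contact_occupancy(rs2)
  expect_equal(occ2[1, 2], p, tolerance = 0.12)
})

test_that("hydrogen bonds require donor H, distance and angle gates", {
  # N-H...O collinear at 2.9 A
  top <- make_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)),
                    element = c("N", "H", "O"), name = c("N", "H", "O"),
                    resno = c(1, 1, 2))
  n <- hydrogen_bond_count(atom_coords(top), top)
  expect_equal(as.integer(n), 1L)
  expect_false(attr(n, "proxy"))

  far <- top; far$x[3] <- 4.0
  expect_equal(as.integer(hydrogen_bond_count(atom_coords(far), far)), 0L)

  # 45 degree H-D-A angle fails the 30 degree gate
  bent <- top
  bent$x[2] <- cos(pi / 4); bent$y[2] <- sin(pi / 4)
  expect_equal(as.integer(hydrogen_bond_count(atom_coords(bent), bent)), 0L)

  # heavy-atom-only input switches to the flagged distance-proxy mode
  heavy <- top[c(1, 3), ]
  np <- hydrogen_bond_count(atom_coords(heavy), heavy)
  expect_true(attr(np, "proxy"))
  expect_equal(as.integer(np), 1L)
})
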