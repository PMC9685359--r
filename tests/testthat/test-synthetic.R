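test_that("toy dimer construction is deterministic and homodimeric", {
  a <- build_toy_dimer(20, seed = 1)
  b <- build_toy_dimer(20, seed = 1)
  expect_identical(a, b)
  seqs <- chain_sequences(a)
  expect_identical(seqs$A, seqs$B)
  expect_error(build_toy_dimer(5), "at least 8")
})

test_that("toy dimer net charge equals the census-implied sum", {
  ref <- build_toy_dimer()
  seqs <- chain_sequences(ref)
  census <- table(seqs$A)
  oracle <- 2 * (sum(census[c("LYS", "ARG")], na.rm = TRUE) -
                   sum(census[c("ASP", "GLU")], na.rm = TRUE))
  # termini cancel per chain
  expect_equal(net_charge(ref), oracle)
  expect_equal(net_charge(ref), 2)
})

test_that("zero jitter and unit scale reproduce the reference exactly", {
  ref <- build_toy_dimer(12)
  sp <- phase_spec("bulk", n_replicas = 2, n_frames = 3, jitter_sigma = 0,
                   seed = 6)
  rs <- generate_phase_ensemble(ref, sp)
  for (tr in rs$trajectory) {
    for (fr in tr$frames) expect_equal(fr, atom_coords(ref), tolerance = 1e-12)
  }
})

test_that("ensembles are seed-reproducible with independent replicas", {
  ref <- build_toy_dimer(12)
  sp <- phase_spec("bulk", n_replicas = 2, n_frames = 3, jitter_sigma = 0.3,
                   seed = 6)
  r1 <- generate_phase_ensemble(ref, sp)
  r2 <- generate_phase_ensemble(ref, sp)
  expect_identical(r1$trajectory[[1]]$frames, r2$trajectory[[1]]$frames)
  expect_false(identical(r1$trajectory[[1]]$frames[[1]],
                         r1$trajectory[[2]]$frames[[1]]))
})

test_that("a shrunken ensemble has a smaller cross-section than the reference", {
  ref <- build_toy_dimer(12)
  sp <- phase_spec("vacuum", n_replicas = 1, n_frames = 1, jitter_sigma = 0,
                   scale_fun = function(t) 0.9, seed = 2)
  rs <- generate_phase_ensemble(ref, sp)
  ccs_ref <- ccs_projection_approximation(atom_coords(ref), ref$radius,
                                          n_orientations = 48, seed = 3)$ccs
  ccs_shr <- ccs_projection_approximation(rs$trajectory[[1]]$frames[[1]],
                                          ref$radius, n_orientations = 48,
                                          seed = 3)$ccs
  expect_lt(ccs_shr, ccs_ref)
})

test_that("loop jitter boost produces the programmed RMSF contrast", {
  ref <- build_toy_dimer()
  loop <- attr(ref, "loop_resnos")
  sp <- phase_spec("bulk", n_replicas = 1, n_frames = 200,
                   jitter_sigma = 0.3, loop_boost = 3, loop_resnos = loop,
                   seed = 11)
  rs <- generate_phase_ensemble(ref, sp)
  rmsf <- rmsf_per_residue(rs)
  in_loop <- rmsf$resno %in% loop
  ratio <- median(rmsf$rmsf[in_loop]) / median(rmsf$rmsf[!in_loop])
  expect_equal(ratio, 3, tolerance = 0.15)
  # body residues converge to sigma*sqrt(3)
  expect_equal(median(rmsf$rmsf[!in_loop]), 0.3 * sqrt(3), tolerance = 0.1)
})

test_that("toggled pairs hit their programmed contact occupancy", {
  ref <- build_toy_dimer()
  pairs <- pick_toggle_pairs(ref, loop_resnos = attr(ref, "loop_resnos"))
  expect_gt(nrow(pairs), 0)
  tp <- pairs[1, ]
  tp$prob <- 0.3
  sp <- phase_spec("bulk", n_replicas = 2, n_frames = 150,
                   jitter_sigma = 0.2, toggle_pairs = tp, seed = 19)
  rs <- generate_phase_ensemble(ref, sp)
  occ <- contact_occupancy(rs)
  rmap <- vacuform:::residue_index_map(ref)
  i <- rmap[paste(tp$chain_i, tp$resno_i)]
  j <- rmap[paste(tp$chain_j, tp$resno_j)]
  # binomial: 300 frames at p = 0.3 -> 3 sigma ~ 0.08
  expect_lt(abs(occ[i, j] - 0.3), 3 * sqrt(0.3 * 0.7 / 300) + 1e-9)
})

test_that("ground truth reports the programmed recovery identities", {
  sc <- default_scenario(n_replicas = 1, n_frames = 4)
  # epsilon = 0: rehydration relaxes fully back to the bulk scale
  sc$specs$rehydration$scale_fun <- function(t) {
    1 - (1 - 0.96) * exp(-t / 31.25)
  }
  gt <- ground_truth(sc$ref, sc$specs, n_orientations = 96)
  expect_equal(gt$scales[["rehydration"]], 1, tolerance = 1e-6)
  reh_pairs <- sc$specs$rehydration$toggle_pairs
  # with full relaxation, base geometry values match bulk up to toggles
  base_ccs <- gt$phase_values$value[gt$phase_values$metric == "ccs"]
  names(base_ccs) <- gt$phase_values$phase[gt$phase_values$metric == "ccs"]
  expect_equal(gt$recovery$recovery_pct[gt$recovery$metric == "ccs"], 100,
               tolerance = 0.01)
  # loop boost of 3 triples the expected RMSF on the hairpin
  loop <- attr(sc$ref, "loop_resnos")
  r <- gt$rmsf
  expect_equal(unique(r$expected_rmsf[r$resno %in% loop]) /
                 unique(r$expected_rmsf[!(r$resno %in% loop)]), 3)
})

test_that("measured compaction matches the scale-derived ground truth", {
  sc <- default_scenario(n_replicas = 3, n_frames = 10)
  vac <- generate_phase_ensemble(sc$ref, sc$specs$vacuum)
  bulk <- generate_phase_ensemble(sc$ref, sc$specs$bulk)
  ser_v <- frame_geometry_series(vac, n_orientations = 32, seed = 7,
                                 metrics = "ccs")
  ser_b <- frame_geometry_series(bulk, n_orientations = 32, seed = 7,
                                 metrics = "ccs")
  measured <- compaction_percent(tail_average(ser_b$ccs, 0.1)$mean,
                                 tail_average(ser_v$ccs, 0.1)$mean)
  gt <- ground_truth(sc$ref, sc$specs, n_orientations = 128)
  expected <- gt$compaction$compaction_pct[gt$compaction$metric == "ccs"]
  expect_lt(abs(measured - expected), 1)
})
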