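test_that("per-residue SASA reduces to the isolated-sphere closed form", {
  one <- make_atoms(matrix(0, 1, 3), element = "C", radius = 1.5)
  tr <- trajectory_ensemble(one, list(atom_coords(one)))
  tab <- per_residue_sasa(tr, probe = 1.4)
  expect_equal(tab$mean_sasa, 4 * pi * 2.9^2, tolerance = 1e-6)
  expect_equal(tab$sd_sasa, 0)
})

test_that("per-residue SASA averages frames with a per-frame oracle", {
  # residue 2 buried against residue 1 in frame 3 only
  top <- make_atoms(rbind(c(0, 0, 0), c(8, 0, 0)), radius = c(2.5, 1.5),
                    resno = c(1, 2))
  X <- atom_coords(top)
  X3 <- X; X3[2, 1] <- 0.4   # inside atom 1
  tr <- trajectory_ensemble(top, list(X, X, X3))
  tab <- per_residue_sasa(tr)
  per_frame <- sapply(list(X, X, X3), function(fr) {
    shrake_rupley_sasa(fr, top$radius)[2]
  })
  expect_equal(tab$mean_sasa[2], mean(per_frame), tolerance = 1e-9)
  expect_equal(tab$sd_sasa[2], sd(per_frame), tolerance = 1e-9)
  # two identical frames alone have zero spread
  tab2 <- per_residue_sasa(trajectory_ensemble(top, list(X, X)))
  expect_equal(tab2$sd_sasa, c(0, 0))
})

sasa_row <- function(chain, resno, resname, mean_sasa, sd_sasa = 1) {
  tibble::tibble(chain = chain, resno = resno, resname = resname,
                 mean_sasa = mean_sasa, sd_sasa = sd_sasa)
}

test_that("candidate selection applies the 50 A^2 threshold and GPB order", {
  tab <- dplyr::bind_rows(
    sasa_row("A", 11, "ASP", 87.63), sasa_row("A", 17, "ASP", 80.16),
    sasa_row("A", 76, "GLU", 115.58), sasa_row("A", 102, "GLU", 76.39),
    sasa_row("A", 30, "GLN", 49.9), sasa_row("A", 40, "SER", 200)
  )
  cand <- select_candidates(tab, threshold = 50)
  # the four exposed acidic residues survive; 49.9 and non-candidates drop
  expect_setequal(cand$resno, c(11, 17, 76, 102))
  # GPB ties (GLU vs GLU, ASP vs ASP) break by larger SASA
  expect_equal(cand$resno, c(76, 102, 11, 17))
})

test_that("equal GPB with unequal SASA ranks the larger area first", {
  tab <- dplyr::bind_rows(sasa_row("A", 2, "ASP", 80),
                          sasa_row("A", 1, "ASP", 90))
  cand <- select_candidates(tab)
  expect_equal(cand$resno, c(1, 2))
  # equal everything falls back to the lower residue number
  tab2 <- dplyr::bind_rows(sasa_row("A", 9, "GLU", 70),
                           sasa_row("A", 4, "GLU", 70))
  expect_equal(select_candidates(tab2)$resno, c(4, 9))
})

test_that("sequence-neighbor exclusion flags acidic residues beside +1 sites", {
  s <- assign_solution_charges(make_chain(c("GLY", "LYS", "ASP", "GLY",
                                            "ASP", "SER")))
  tab <- dplyr::bind_rows(sasa_row("A", 3, "ASP", 90),
                          sasa_row("A", 5, "ASP", 85))
  cand <- apply_neighbor_exclusion(select_candidates(tab), s)
  asp3 <- cand[cand$resno == 3, ]
  expect_true(asp3$excluded)
  expect_match(asp3$reason, "positive neighbor K at i-1")
  expect_false(cand[cand$resno == 5, ]$excluded)
})

test_that("spatial exclusion uses the charged-residue centroid distance", {
  coords <- rbind(c(0, 0, 0), c(4.9, 0, 0), c(50, 0, 0), c(55.1, 0, 0))
  s <- make_atoms(coords, resno = 1:4,
                  resname = c("ASP", "ARG", "ASP", "ARG"),
                  name = "CA")
  s <- assign_solution_charges(s, termini = FALSE)
  tab <- dplyr::bind_rows(sasa_row("A", 1, "ASP", 90),
                          sasa_row("A", 3, "ASP", 90))
  cand <- apply_neighbor_exclusion(select_candidates(tab), s,
                                   mode = "spatial", spatial_cutoff = 5)
  expect_true(cand[cand$resno == 1, ]$excluded)   # Arg at 4.9 A
  expect_false(cand[cand$resno == 3, ]$excluded)  # Arg at 5.1 A
  expect_error(apply_neighbor_exclusion(cand, s, mode = "spatial"),
               "spatial_cutoff")
})

# engineered dimer: known SASA table, GPB and neighbors
toy_plan_setup <- function() {
  ref <- build_toy_dimer()
  rs <- generate_phase_ensemble(
    ref, phase_spec("bulk", n_replicas = 1, n_frames = 2,
                    jitter_sigma = 0.05, seed = 8))
  sasa <- per_residue_sasa(rs, restrict = c("LYS", "ARG", "HIS", "GLN",
                                            "ASP", "GLU"), n_points = 240)
  cand <- apply_neighbor_exclusion(select_candidates(sasa), ref)
  list(ref = ref, sasa = sasa, cand = cand)
}

test_that("protonation plan reaches the target charge symmetrically", {
  st <- toy_plan_setup()
  plan <- build_protonation_plan(st$ref, st$cand, target_charge = 10)
  expect_equal(plan$initial_charge, 2)
  expect_equal(plan$resulting_charge, 10)
  # 8 protonations, 4 per chain, identical residue sets across chains
  expect_equal(nrow(plan$selected), 8)
  sel <- split(plan$selected$resno, plan$selected$chain)
  expect_identical(sort(sel$A), sort(sel$B))
  # every selected site passes the threshold and no exclusion
  expect_true(all(plan$selected$mean_sasa >= 50))
  expect_true(all(!plan$selected$excluded))
  # the engineered layout: His10, Gln15, Gln17, Glu8 by GPB rank
  expect_setequal(unique(plan$selected$resno), c(10, 15, 17, 8))
})

test_that("greedy plan matches the exhaustive ranking oracle", {
  st <- toy_plan_setup()
  plan <- build_protonation_plan(st$ref, st$cand, target_charge = 10)
  # oracle: full sort of all chain-A candidates, drop excluded and
  # already-protonated types, take the first k positions
  ca <- st$cand[st$cand$chain == "A", ]
  ca <- ca[order(-ca$gpb, -ca$mean_sasa, ca$resno), ]
  eligible <- ca[!ca$excluded & !(ca$resname %in% c("LYS", "ARG")), ]
  oracle <- eligible$resno[1:4]
  expect_setequal(unique(plan$selected$resno), oracle)
})

test_that("plan bookkeeping errors are informative", {
  st <- toy_plan_setup()
  # identity: target equals current charge
  empty <- build_protonation_plan(st$ref, st$cand, target_charge = 2)
  expect_equal(nrow(empty$selected), 0)
  expect_equal(empty$resulting_charge, 2)
  # candidates exhausted: 6 eligible positions per chain, 7 needed
  expect_error(build_protonation_plan(st$ref, st$cand, target_charge = 16),
               "insufficient sites.*shortfall 2")
  # parity: odd deficit over two chains
  expect_error(build_protonation_plan(st$ref, st$cand, target_charge = 9),
               "parity")
})

test_that("applying a plan updates charges once and only once", {
  st <- toy_plan_setup()
  plan <- build_protonation_plan(st$ref, st$cand, target_charge = 10)
  prot <- apply_plan(st$ref, plan)
  expect_equal(net_charge(prot), 10)
  expect_identical(apply_plan(st$ref, build_protonation_plan(
    st$ref, st$cand, target_charge = 2)), st$ref)  # empty plan
  expect_error(apply_plan(prot, plan), "double protonation")
})

test_that("plans are invariant under rigid motion of the trajectory", {
  ref <- build_toy_dimer()
  rs <- generate_phase_ensemble(
    ref, phase_spec("bulk", n_replicas = 1, n_frames = 2,
                    jitter_sigma = 0.05, seed = 8))
  moved <- rs
  moved$trajectory[[1]]$frames <- lapply(rs$trajectory[[1]]$frames,
                                         rigid_transform)
  restrict <- c("LYS", "ARG", "HIS", "GLN", "ASP", "GLU")
  s1 <- per_residue_sasa(rs, restrict = restrict, n_points = 240)
  s2 <- per_residue_sasa(moved, restrict = restrict, n_points = 240)
  p1 <- build_protonation_plan(ref, apply_neighbor_exclusion(
    select_candidates(s1), ref), 10)
  p2 <- build_protonation_plan(ref, apply_neighbor_exclusion(
    select_candidates(s2), ref), 10)
  sel1 <- split(sort(p1$selected$resno), p1$selected$chain)
  sel2 <- split(sort(p2$selected$resno), p2$selected$chain)
  expect_identical(sel1, sel2)
})

test_that("tidy and glance expose the Table-1-style plan summary", {
  st <- toy_plan_setup()
  plan <- build_protonation_plan(st$ref, st$cand, target_charge = 10)
  td <- tidy(plan)
  sel <- td[td$selected, ]
  expect_true(all(sel$vacuum_charge == sel$solution_charge + 1))
  gl <- glance(plan)
  expect_equal(gl$resulting_charge, 10)
  expect_equal(gl$n_selected, 8)
})
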