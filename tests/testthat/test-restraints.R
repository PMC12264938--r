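test_that("flat-bottom energy obeys the documented no-half convention", {
  expect_identical(flat_bottom_energy(12, 8, 16, 40), 0)
  expect_equal(flat_bottom_energy(17, 8, 16, 40), 40)   # 1 Å over, k = 40
  # symmetric violations cost the same
  expect_equal(flat_bottom_energy(6.5, 8, 16, 40),
               flat_bottom_energy(17.5, 8, 16, 40))
  # continuous with continuous first derivative at the band edges
  h <- 1e-7
  for (edge in c(8, 16)) {
    expect_lt(abs(flat_bottom_energy(edge + h, 8, 16, 40) -
                    flat_bottom_energy(edge - h, 8, 16, 40)), 1e-5)
  }
  expect_error(flat_bottom_energy(-0.1, 0, 1, 1), "non-negative")
  expect_error(restraint_set("protein_ligand", 1L, 2L, 5, 3, 10))
  expect_error(restraint_set("protein_ligand", 1L, 2L, 3, 5, -1))
})

test_that("pair statistics recover generator parameters and respect invariances", {
  fx <- make_distance_fixture(10000, tibble::tibble(
    ligand_atom = 1L, protein_atom = 2L, mean = 12, std = 0.5), seed = 17L)
  st <- compute_pair_stats(fx)
  expect_lt(abs(st$mean - 12), 0.05)
  expect_lt(abs(st$std - 0.5), 0.05)

  # coordinate-trajectory form: single frame has zero spread, and rigid
  # translation leaves distances untouched
  fr <- matrix(c(0, 0, 3, 4, 10, 0), ncol = 2, byrow = TRUE)
  st1 <- compute_pair_stats(list(fr), ligand_atoms = 1, protein_atoms = 2:3)
  expect_equal(st1$std, c(0, 0))
  expect_equal(st1$mean, c(5, 10))
  shifted <- lapply(list(fr, fr + 7), function(m) m)
  st2 <- compute_pair_stats(shifted, ligand_atoms = 1, protein_atoms = 2:3)
  expect_equal(st2$mean, c(5, 10))
  expect_error(compute_pair_stats(list(fr), ligand_atoms = integer(),
                                  protein_atoms = 2:3), "non-empty")
  expect_error(compute_pair_stats(list(), 1, 2), "at least one frame")
})

test_that("selection picks the minimum-spread pair and builds the band from the mean", {
  st <- tibble::tibble(ligand_atom = c(1L, 1L), protein_atom = c(10L, 11L),
                       mean = c(12.0, 12.5), std = c(1.0, 0.5),
                       n_frames = 100L)
  sel <- select_multiple_distance_restraints(st)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$atom_j, 11L)
  # r_min/r_max = mean -+ 4 Å around the average distance
  st2 <- tibble::tibble(ligand_atom = 1L, protein_atom = 10L,
                        mean = 12.0, std = 0.3, n_frames = 100L)
  sel2 <- select_multiple_distance_restraints(st2)
  expect_equal(sel2$r_min, 8.0)
  expect_equal(sel2$r_max, 16.0)
  expect_equal(sel2$k, 40)
  # out-of-band candidates produce an empty set with a warning, not an error
  st3 <- tibble::tibble(ligand_atom = 1L, protein_atom = 10L,
                        mean = 22, std = 0.3, n_frames = 100L)
  expect_warning(sel3 <- select_multiple_distance_restraints(st3), "empty")
  expect_equal(nrow(sel3), 0)
})

test_that("selection equals the brute-force oracle on randomized candidate sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n_lig <- 20; n_prot <- 50
    grid <- expand.grid(ligand_atom = seq_len(n_lig),
                        protein_atom = n_lig + seq_len(n_prot))
    st <- tibble::tibble(
      ligand_atom = as.integer(grid$ligand_atom),
      protein_atom = as.integer(grid$protein_atom),
      mean = stats::runif(nrow(grid), 5, 20),
      std = stats::runif(nrow(grid), 0.1, 3),
      n_frames = 500L)
    sel <- select_multiple_distance_restraints(st)
    bf <- brute_force_selection(st)
    sel <- sel[order(sel$atom_i), ]
    expect_equal(sel$atom_i, bf$ligand_atom)
    expect_equal(sel$atom_j, bf$protein_atom)
    expect_equal(sel$r_min, bf$r_min)
    expect_equal(sel$r_max, bf$r_max)
    # uniqueness and band invariants
    expect_false(any(duplicated(c(sel$atom_i, sel$atom_j))))
    mid <- (sel$r_min + sel$r_max) / 2
    expect_true(all(mid >= 10 & mid <= 15))
  }
})

test_that("single-frame statistics select by distance to the band center", {
  # all spreads are zero (degenerate min-sigma criterion): the documented
  # tie rule prefers the mean closest to the band center 12.5
  st <- tibble::tibble(ligand_atom = c(1L, 1L, 2L),
                       protein_atom = c(10L, 11L, 10L),
                       mean = c(14.9, 12.4, 12.6), std = 0,
                       n_frames = 1L)
  sel <- select_multiple_distance_restraints(st, single_frame = TRUE)
  sel <- sel[order(sel$atom_i), ]
  # ligand 1 takes protein 11 (12.4 beats 14.9); ligand 2 wants protein 10
  expect_equal(sel$atom_j, c(11L, 10L))
})

test_that("inter-pose tethers have the right cardinality and sanity checks", {
  te <- build_interpose_tethers(c(5L, 6L), c(7L, 8L), k = 120, width = 2)
  expect_equal(nrow(te), 2)
  expect_true(all(te$kind == "inter_pose"))
  expect_true(all(te$k == 120))
  expect_error(build_interpose_tethers(5L, 7L), "2-4")
  expect_error(build_interpose_tethers(c(5L, 6L), 7L), "one-to-one")
  expect_error(build_interpose_tethers(c(5L, 6L), c(7L, 8L), k = 2e4),
               "sane range")
  # identical pose coordinates start with zero tether energy
  spec <- toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = 1),
           list(type = "harmonic", center = 1, k = 1)),
      list(list(type = "harmonic", center = 0, k = 1),
           list(type = "harmonic", center = 1, k = 1))),
    env_coords = matrix(12.0, ncol = 1))
  sys <- make_dual_pose_toy(spec)
  te2 <- build_interpose_tethers(c(2L, 3L), c(4L, 5L), k = 100, width = 2)
  expect_identical(restraint_energy(sys, NULL, te2), 0)
})

test_that("restraint tables round-trip through the text format", {
  rs <- restraint_set(kind = c("inter_pose", "protein_ligand"),
                      atom_i = c(2L, 3L), atom_j = c(4L, 1L),
                      r_min = c(0, 8.25), r_max = c(2, 16.25), k = c(100, 40))
  f <- withr::local_tempfile(fileext = ".txt")
  write_restraint_table(rs, f)
  rs2 <- read_restraint_table(f)
  expect_equal(as.data.frame(rs2), as.data.frame(rs), tolerance = 1e-12)
})

test_that("tether contributions cancel between poses on a symmetric system", {
  # two tethered particles per pose, symmetric wells: the pose free-energy
  # difference is zero by symmetry, and the dual-topology end-state
  # difference with tethers present must also be zero (their contribution
  # cancels); checked with the exact dual-topology quadrature
  spec <- toy_system_spec(
    dim = 1,
    pose_wells = list(
      list(list(type = "harmonic", center = 0, k = 0.6),
           list(type = "harmonic", center = 1.5, k = 0.6)),
      list(list(type = "harmonic", center = 0, k = 0.6),
           list(type = "harmonic", center = 1.5, k = 0.6))),
    interactions = tibble::tibble(
      pose = c(1L, 2L), particle = c(1L, 1L), env_atom = c(1L, 1L),
      epsilon = c(0.3, 0.3), sigma = c(3, 3), alpha = c(0.5, 0.5)),
    env_coords = matrix(c(4.0, 12.0), ncol = 1))
  sys <- make_dual_pose_toy(spec)
  te <- build_interpose_tethers(c(3L, 4L), c(5L, 6L), k = 100, width = 2)
  with_te <- quadrature_free_energy(sys, c(0, 1), te) -
    quadrature_free_energy(sys, c(1, 0), te)
  without <- quadrature_free_energy(sys, c(0, 1)) -
    quadrature_free_energy(sys, c(1, 0))
  expect_lt(abs(with_te - without), 1e-8)
  expect_lt(abs(with_te), 1e-8)
})
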