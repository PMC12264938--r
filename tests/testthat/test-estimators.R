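test_that("population free energies follow the log-ratio formula", {
  expect_equal(deltaG_from_populations(0.4, 0.4)$value, 0)
  # ratio e^-1 at 298.15 K gives exactly +kBT
  expect_equal(deltaG_from_populations(0.5, 0.5 * exp(-1))$value, KBT_298,
               tolerance = 1e-12)
  a <- deltaG_from_populations(0.2, 0.7)$value
  b <- deltaG_from_populations(0.7, 0.2)$value
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(deltaG_from_populations(0, 0.5), "no endpoint sampling")
})

test_that("endpoint populations count dominant-pose frames", {
  mk <- function(l1) lambdapose:::new_lambda_trace(
    seq_along(l1) * 0.02, cbind(l1, 1 - l1))
  expect_equal(unname(endpoint_populations(mk(rep(0.9999, 10)))), c(1, 0))
  expect_equal(unname(endpoint_populations(mk(rep(0.5, 10)))), c(0, 0))
  l1 <- c(rep(0.9999, 3), rep(0.0001, 7))
  expect_equal(unname(endpoint_populations(mk(l1))), c(0.3, 0.7))
  # pooling across replicas
  expect_equal(unname(endpoint_populations(list(mk(rep(0.9999, 5)),
                                                mk(rep(0.0001, 5))))),
               c(0.5, 0.5))
})

test_that("reweighting with zero bias is exactly the population estimator", {
  set.seed(33)
  l1 <- ifelse(stats::runif(400) < 0.35, 0.999, 0.001)
  tr <- lambdapose:::new_lambda_trace(seq_along(l1) * 0.02, cbind(l1, 1 - l1))
  p <- endpoint_populations(tr)
  expect_equal(wham_deltaG(tr, bias_model())$value,
               deltaG_from_populations(p[1], p[2])$value, tolerance = 1e-12)
})

test_that("reweighting undoes a known analytic bias (hand-computed oracle)", {
  # ten frames, bias phi = (1, 0): applied energy -lambda_xray kcal/mol,
  # so each frame carries weight exp(-lambda_xray / kBT)
  l1 <- c(0.999, 0.001, 0.999, 0.001, 0.001, 0.999, 0.001, 0.001, 0.999,
          0.001)
  tr <- lambdapose:::new_lambda_trace(seq_along(l1) * 0.02, cbind(l1, 1 - l1))
  bias <- bias_model(phi = c(1, 0))
  w <- exp(-l1 / KBT_298)
  expected <- -KBT_298 * log(sum(w[l1 < 0.5]) / sum(w[l1 > 0.5]))
  expect_equal(wham_deltaG(tr, bias)$value, expected, tolerance = 1e-10)
  expect_error(wham_deltaG(lambdapose:::new_lambda_trace(
    c(0.02, 0.04), matrix(0.5, 2, 2)), bias_model()), "no endpoint sampling")
})

test_that("replica bootstrap matches its exhaustive enumeration limit", {
  expect_identical(bootstrap_uncertainty(c(1.7, 1.7, 1.7)), 0)
  # replicas {0, 2}: the four equally likely resamples have means
  # {0, 1, 1, 2}, whose standard deviation is sqrt(1/2)
  est <- bootstrap_uncertainty(c(0, 2), n_boot = 40000, seed = 2L)
  expect_equal(est, sqrt(0.5), tolerance = 0.02)
  expect_identical(bootstrap_uncertainty(c(0, 2), n_boot = 500, seed = 7L),
                   bootstrap_uncertainty(c(0, 2), n_boot = 500, seed = 7L))
})

test_that("the exponential averaging estimator matches closed forms", {
  expect_equal(zwanzig(rep(0, 50))$value, 0)
  expect_equal(zwanzig(rep(2.31, 50))$value, 2.31, tolerance = 1e-12)
  # Gaussian work distribution: dG = mu - sigma^2 / (2 kBT)
  set.seed(8)
  du <- stats::rnorm(1e5, 1.0, 0.5)
  est <- zwanzig(du)
  expect_within_sigma(est$value, 1.0 - 0.25 / (2 * KBT_298),
                      est$uncertainty)
  # no overflow for large inputs
  expect_true(is.finite(zwanzig(c(-500, -480, -490))$value))
})

test_that("the Gaussian-law bias of exponential averaging shrinks with n", {
  # average absolute deviation from the closed form over replicated draws
  dev_at <- function(n, reps = 40) {
    set.seed(123)
    mean(vapply(seq_len(reps), function(i) {
      du <- stats::rnorm(n, 1.0, 0.8)
      zwanzig(du)$value
    }, numeric(1))) - (1.0 - 0.64 / (2 * KBT_298))
  }
  expect_gt(abs(dev_at(100)), abs(dev_at(10000)))
})

test_that("multistate reweighting solves analytic harmonic windows", {
  expect_equal(fep_mbar_path(matrix(0, 2, 200), c(100, 100))$value, 0,
               tolerance = 1e-10)
  # windows U_w = (k0/2 + s_w k_r) x^2 sampled exactly from their
  # Gaussians: dG = kBT/2 ln((k0 + 2 k_r) / k0)
  k0 <- 0.8; kr <- 0.6
  scales <- seq(0, 1, length.out = 5)
  set.seed(77)
  n_w <- 400
  xs <- unlist(lapply(scales, function(s) {
    stats::rnorm(n_w, 0, sqrt(KBT_298 / (k0 + 2 * s * kr)))
  }))
  u_mat <- do.call(rbind, lapply(scales, function(s) {
    (k0 / 2 + s * kr) * xs^2
  }))
  est <- fep_mbar_path(u_mat, rep(n_w, 5), seed = 3L)
  exact <- KBT_298 / 2 * log((k0 + 2 * kr) / k0)
  expect_within_sigma(est$value, exact, est$uncertainty)
  expect_true(is.matrix(attr(est, "overlap")))
  expect_null(est$flag)
})

test_that("vanishing window overlap is flagged, not silent", {
  # two windows with essentially disjoint energy supports
  set.seed(5)
  x1 <- stats::rnorm(150, 0, 0.05)
  x2 <- stats::rnorm(150, 6, 0.05)
  xs <- c(x1, x2)
  u_mat <- rbind(2 * xs^2, 2 * (xs - 6)^2)
  expect_warning(est <- fep_mbar_path(u_mat, c(150, 150), n_boot = 5),
                 "overlap")
  expect_match(est$flag, "overlap")
})

test_that("one-step restraint corrections respect their exact contracts", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  wide <- restraint_set(
    kind = c("protein_ligand", "protein_ligand"),
    atom_i = c(8L, 9L), atom_j = c(2L, 4L),
    r_min = c(0, 0), r_max = c(60, 60), k = c(40, 40))
  ens <- run_reference_state(sys, wide, simulation_config(n_steps = 5000,
                                                          seed = 6L),
                             n_replicas = 2)
  # never-violated restraints cost exactly zero in both directions
  expect_identical(osp_restraint_correction(ens, "xray")$value, 0)
  expect_identical(osp_restraint_correction(ens, "flip")$value, 0)
  ens_bad <- ens; ens_bad$lam <- c(0.7, 0.3)
  expect_error(osp_restraint_correction(ens_bad, "xray"), "0.5")
})

test_that("one-step corrections match the oracle in their convergent regime", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  rs <- osp_test_restraints()
  gq <- function(lam, sc) quadrature_free_energy(sys, lam, rs,
                                                 restraint_scales = sc)
  add_x <- gq(c(1, 0), c(1, 1)) - gq(c(1, 0), c(0, 0))
  rem_f <- gq(c(0, 1), c(0, 0)) - gq(c(0, 1), c(1, 1))
  ens <- run_reference_state(sys, rs, simulation_config(n_steps = 60000,
                                                        seed = 31L),
                             n_replicas = 3)
  ox <- osp_restraint_correction(ens, "xray")
  of <- osp_restraint_correction(ens, "flip")
  expect_within_sigma(ox$value, add_x, ox$uncertainty)
  expect_within_sigma(of$value, rem_f, of$uncertainty)
})

test_that("adding and removing restraints are mirror images on a symmetric toy", {
  sys <- make_dual_pose_toy(toy_spec_symmetric())
  rs <- restraint_set(
    kind = c("protein_ligand", "protein_ligand"),
    atom_i = c(5L, 6L), atom_j = c(2L, 2L),
    r_min = c(10.5, 10.5), r_max = c(13.5, 13.5), k = c(0.5, 0.5))
  ens <- run_reference_state(sys, rs, simulation_config(n_steps = 40000,
                                                        seed = 19L),
                             n_replicas = 3)
  ox <- osp_restraint_correction(ens, "xray")
  of <- osp_restraint_correction(ens, "flip")
  expect_within_sigma(ox$value, -of$value,
                      sqrt(ox$uncertainty^2 + of$uncertainty^2))
})

test_that("cycle combination reproduces printed arithmetic and propagates errors", {
  # published cycle rows: components sum exactly to the printed total
  cyc1 <- combine_cycle(c(0.8, 0.4), c(-2.1, 0.8), c(-1.2, 0.8))
  expect_equal(cyc1$combined$value, -2.5, tolerance = 1e-12)
  expect_equal(round(cyc1$combined$uncertainty, 1), 1.2)
  cyc2 <- combine_cycle(c(0.8, 0.6), c(10.2, 0.1), c(-1.1, 0.2))
  expect_equal(cyc2$combined$value, 9.9, tolerance = 1e-12)
  cyc0 <- combine_cycle(0, 0, 0)
  expect_identical(cyc0$combined$value, 0)
  expect_identical(cyc0$combined$uncertainty, 0)
  # tidy/glance expose the four terms
  td <- tidy(cyc1)
  expect_equal(nrow(td), 4)
  expect_equal(td$estimate[td$term == "combined"], -2.5)
  expect_equal(glance(cyc1)$ddG, -2.5)
})

test_that("trace diagnostics count endpoint alternations", {
  mk <- function(l1, dt = 1) lambdapose:::new_lambda_trace(
    seq_along(l1) * dt, cbind(l1, 1 - l1))
  # never reaches an endpoint
  d0 <- trace_diagnostics(mk(rep(0.5, 100)))
  expect_equal(d0$transitions_per_ns, 0)
  expect_equal(d0$physical_fraction, 0)
  # alternating every frame, 1 ps apart: frames - 1 transitions
  alt <- rep(c(0.9999, 0.0001), 50)
  d1 <- trace_diagnostics(mk(alt))
  expect_equal(d1$transitions, 99)
  expect_equal(d1$transitions_per_ns, 99 / (99 / 1000))
  expect_equal(d1$physical_fraction, 1)
  # three planted alternations with dwell periods and excursions
  l1 <- c(rep(0.9999, 10), rep(0.5, 5), rep(0.0001, 10), rep(0.9999, 10),
          rep(0.3, 3), rep(0.0001, 10))
  d3 <- trace_diagnostics(mk(l1))
  expect_equal(d3$transitions, 3)
})

test_that("estimates negate under pose swap along analytic paths", {
  # population path: swapping the populations negates exactly
  a <- deltaG_from_populations(0.31, 0.54)$value
  b <- deltaG_from_populations(0.54, 0.31)$value
  expect_lt(abs(a + b), 1e-9)
  # reweighted path: swapping pose columns and bias coefficients negates
  set.seed(40)
  l1 <- ifelse(stats::runif(300) < 0.4, 0.999, 0.001)
  tr <- lambdapose:::new_lambda_trace(seq_along(l1) * 0.02,
                                      cbind(l1, 1 - l1))
  tr_sw <- lambdapose:::new_lambda_trace(seq_along(l1) * 0.02,
                                         cbind(1 - l1, l1))
  bias <- bias_model(phi = c(0.8, 0.1))
  bias_sw <- bias_model(phi = c(0.1, 0.8))
  expect_lt(abs(wham_deltaG(tr, bias)$value +
                  wham_deltaG(tr_sw, bias_sw)$value), 1e-9)
})
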