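test_that("runs are bit-reproducible for a fixed seed", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  cfg <- simulation_config(n_steps = 2000, seed = 99L)
  r1 <- run_lambda_dynamics(sys, bias_model(), NULL, cfg)
  r2 <- run_lambda_dynamics(sys, bias_model(), NULL, cfg)
  expect_identical(r1$trace$lambda_xray, r2$trace$lambda_xray)
  expect_identical(r1$final$x, r2$final$x)
  r3 <- run_lambda_dynamics(sys, bias_model(), NULL,
                            simulation_config(n_steps = 2000, seed = 100L))
  expect_false(identical(r1$trace$lambda_xray, r3$trace$lambda_xray))
})

test_that("the thermostat holds the kinetic temperature", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  run <- run_lambda_dynamics(sys, bias_model(), NULL,
                             simulation_config(n_steps = 100000, seed = 5L))
  expect_lt(abs(run$kinetic_temperature - 298.15) / 298.15, 0.02)
})

test_that("a symmetric system samples both endpoints equally", {
  sys <- make_dual_pose_toy(toy_spec_symmetric())
  run <- run_lambda_dynamics(sys, bias_model(), NULL,
                             simulation_config(n_steps = 60000, seed = 8L))
  p <- endpoint_populations(run$trace)
  n_end <- round(sum(p) * nrow(run$trace))
  # binomial 3-sigma band around 1/2 on endpoint frames
  se <- 0.5 / sqrt(n_end)
  expect_gt(n_end, 100)
  expect_lt(abs(p[1] / sum(p) - 0.5), 3 * se * 3)  # frames autocorrelated
})

test_that("non-finite energies abort with the step index", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  expect_error(
    run_lambda_dynamics(sys, bias_model(), NULL,
                        simulation_config(dt = 0.5, n_steps = 5000,
                                          seed = 2L)),
    "step")
})

test_that("a bias built from a known density flattens the sampled histogram", {
  sys <- make_dual_pose_toy(toy_spec_barrier())
  # unbiased run establishes P0 on the equal-measure bins; the matching
  # tabulated bias must then sample close to uniform on those bins
  edges <- lambdapose:::fnex_measure_quantile_edges(30)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cfg <- simulation_config(n_steps = 80000, seed = 12L,
                           lambda_save_stride = 2)
  r0 <- run_lambda_dynamics(sys, bias_model(), NULL, cfg)
  h0 <- tabulate(findInterval(r0$trace$lambda_xray, edges,
                              rightmost.closed = TRUE), length(mids))
  p0 <- pmax(h0, 0.5) / sum(h0)
  bias <- tabulated_bias(mids, -KBT_298 * log(p0))
  r1 <- run_lambda_dynamics(sys, bias, NULL,
                            simulation_config(n_steps = 80000, seed = 13L,
                                              lambda_save_stride = 2))
  h1 <- tabulate(findInterval(r1$trace$lambda_xray, edges,
                              rightmost.closed = TRUE), length(mids))
  p1 <- h1 / sum(h1)
  # occupied-bin ratio collapses by an order of magnitude
  ratio0 <- max(p0) / min(p0[p0 > 0])
  ratio1 <- max(p1) / min(p1[p1 > 0])
  expect_gt(ratio0, 30)
  expect_lt(ratio1, ratio0 / 5)
})

test_that("flattening reports convergence behavior across system types", {
  # already-flat (symmetric, zero barrier): one iteration, near-zero bias
  sysS <- make_dual_pose_toy(toy_spec_symmetric())
  flS <- flatten_alf(sysS, NULL, simulation_config(seed = 5L),
                     schedule = list(n_iterations = 6,
                                     steps_per_iteration = 15000))
  expect_true(flS$flattened)
  expect_equal(nrow(flS$diagnostics), 1)
  expect_lt(diff(range(flS$bias$table$value)), 0.5)

  # multi-kBT barrier: flattening restores endpoint transit
  sysB <- make_dual_pose_toy(toy_spec_barrier())
  flB <- flatten_alf(sysB, NULL, simulation_config(seed = 6L),
                     schedule = list(n_iterations = 12,
                                     steps_per_iteration = 20000))
  expect_true(flB$flattened)
  expect_gt(diff(range(flB$bias$table$value)), 1)
  rB <- run_lambda_dynamics(sysB, flB$bias, NULL,
                            simulation_config(n_steps = 100000, seed = 9L))
  expect_gt(trace_diagnostics(rB$trace)$transitions, 0)

  # an impossible schedule returns best-so-far flagged not flattened
  flX <- flatten_alf(sysB, NULL, simulation_config(seed = 7L),
                     schedule = list(n_iterations = 1,
                                     steps_per_iteration = 4000),
                     flatness_ratio = 1.01)
  expect_false(flX$flattened)
  expect_s3_class(flX$bias, "bias_model")
})

test_that("the replica protocol derives distinct seeds and discards the head", {
  sys <- make_dual_pose_toy(toy_spec_symmetric())
  cfg <- simulation_config(n_steps = 12000, seed = 3L)
  traces <- run_replica_protocol(sys, bias_model(), NULL, cfg,
                                 n_replicas = 5)
  expect_length(traces, 5)
  seeds <- vapply(traces, function(tr) attr(tr, "seed"), numeric(1))
  expect_length(unique(seeds), 5)
  expect_equal(nrow(traces[[1]]), 1000)  # 1200 frames minus 1/6
  expect_warning(run_replica_protocol(sys, bias_model(), NULL,
                                      simulation_config(n_steps = 1000,
                                                        seed = 3L),
                                      n_replicas = 1),
                 "bootstrap")
  # discard arithmetic: 6000-frame trace keeps 5000
  tr <- lambdapose:::new_lambda_trace(seq_len(6000) * 0.01,
                                      matrix(0.5, 6000, 2))
  expect_equal(nrow(discard_initial(tr, 1 / 6)), 5000)
})

test_that("the reference state stays pinned at lambda = (0.5, 0.5)", {
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  rs <- osp_test_restraints()
  ens <- run_reference_state(sys, rs, simulation_config(n_steps = 6000,
                                                        seed = 14L),
                             n_replicas = 3)
  expect_equal(ens$lam, c(0.5, 0.5))
  expect_length(unique(ens$replica_id), 3)
  # re-scoring at the reference definition itself gives exactly zero
  du_ref <- lambdapose:::ff_eval(
    lambdapose:::compile_ff(sys, rs),
    as.numeric(t(do.call(rbind, ens$frames[[1]]))), c(0.5, 0.5))$U -
    ens$energies[1]
  expect_equal(du_ref, 0, tolerance = 1e-10)
  # toggling a restraint that is never violated leaves the restraint part
  # of the re-scored differences untouched
  du_on <- rescore_frames(ens, list(lam = c(1, 0),
                                    restraint_scales = c(1, 1)))
  wide <- rs; wide$r_min <- c(0, 0); wide$r_max <- c(60, 60)
  ens_w <- ens; ens_w$restraints <- wide
  du_w_on <- rescore_frames(ens_w, list(lam = c(1, 0),
                                        restraint_scales = c(1, 1)))
  du_w_off <- rescore_frames(ens_w, list(lam = c(1, 0),
                                         restraint_scales = c(0, 0)))
  expect_equal(du_w_on$delta_u, du_w_off$delta_u, tolerance = 1e-10)
  expect_error(rescore_frames(ens, list(lam = c(0.7, 0.3))), "1, 0")
})

test_that("flattening biases do not distort endpoint-conditional configurations", {
  # coordinates collected while a pose dominates must match a plain
  # fixed-lambda simulation of that end state (bias acts only through
  # lambda); compared with a two-sample Kolmogorov-Smirnov test
  sys <- make_dual_pose_toy(toy_spec_asymmetric())
  fl <- flatten_alf(sys, NULL, simulation_config(seed = 4L),
                    schedule = list(n_iterations = 8,
                                    steps_per_iteration = 15000))
  cfg <- simulation_config(n_steps = 120000, seed = 15L,
                           lambda_save_stride = 40, coord_save_stride = 40)
  run <- run_lambda_dynamics(sys, fl$bias, NULL, cfg)
  sel <- run$trace$lambda_xray > 0.99
  x_biased <- vapply(run$frames[sel], function(fr) fr[[1]][1, 1],
                     numeric(1))
  ref <- run_lambda_dynamics(sys, NULL, NULL,
                             simulation_config(n_steps = 60000, seed = 16L,
                                               coord_save_stride = 40),
                             fixed_lambda = c(1, 0))
  x_ref <- vapply(ref$frames, function(fr) fr[[1]][1, 1], numeric(1))
  expect_gt(length(x_biased), 50)
  ks <- suppressWarnings(stats::ks.test(x_biased, x_ref))
  expect_gt(ks$p.value, 0.01)
})
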