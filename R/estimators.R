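logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Free-energy estimate container
#'
#' @param value Estimate in kcal/mol.
#' @param uncertainty One-sigma uncertainty in kcal/mol, `>= 0` (0 for exact
#'   values).
#' @param method One of `"population"`, `"WHAM"`, `"Zwanzig"`, `"MBAR"`,
#'   `"quadrature-oracle"`.
#' @param n_samples Number of samples behind the estimate.
#' @param flag Optional character note (e.g. `"not converged"`).
#' @return A `free_energy_estimate` object.
#' @export
free_energy_estimate <- function(value, uncertainty = 0,
                                 method = c("population", "WHAM", "Zwanzig",
                                            "MBAR", "quadrature-oracle"),
                                 n_samples = NA_integer_, flag = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(value), length(value) == 1,
            is.numeric(uncertainty), uncertainty >= 0)
  structure(list(value = value, uncertainty = uncertainty, method = method,
                 n_samples = n_samples, flag = flag),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> %.4f +- %.4f kcal/mol  [%s%s]\n",
              x$value, x$uncertainty, x$method,
              if (!is.null(x$flag)) paste0("; ", x$flag) else ""))
  invisible(x)
}

#' Free-energy difference from endpoint populations
#'
#' \deqn{\Delta G = -k_B T \ln(p_{flip} / p_{xray})}
#' Antisymmetric under swapping the two populations.
#'
#' @param p_xray,p_flip Endpoint probabilities, both `> 0`.
#' @param temperature Temperature in K.
#' @param uncertainty Optional pre-computed uncertainty (kcal/mol).
#' @param n_samples Optional sample count.
#' @return A [free_energy_estimate()] with method `"population"`.
#' @export
deltaG_from_populations <- function(p_xray, p_flip,
                                    temperature = DEFAULT_TEMPERATURE,
                                    uncertainty = 0, n_samples = NA_integer_) {
  if (p_xray <= 0 || p_flip <= 0) {
    stop("no endpoint sampling: both endpoint populations must be > 0 ",
         "(got p_xray = ", p_xray, ", p_flip = ", p_flip, ")")
  }
  free_energy_estimate(unname(-kBT(temperature) * log(p_flip / p_xray)),
                       uncertainty, method = "population",
                       n_samples = n_samples)
}

as_trace_list <- function(traces) {
  if (inherits(traces, "lambda_trace") || is.data.frame(traces)) {
    traces <- list(traces)
  }
  if (length(traces) == 0) stop("`traces` must be non-empty")
  traces
}

#' Endpoint populations of lambda traces
#'
#' Fraction of frames, pooled across replicas, in which a pose dominates
#' (its lambda exceeds `threshold`, default 0.99).
#'
#' @param traces A `lambda_trace` tibble or list of them.
#' @param threshold Dominance threshold on lambda.
#' @return Named numeric `c(p_xray =, p_flip =)`.
#' @export
endpoint_populations <- function(traces, threshold = 0.99) {
  traces <- as_trace_list(traces)
  n_x <- 0; n_f <- 0; n <- 0
  for (tr in traces) {
    n_x <- n_x + sum(tr$lambda_xray > threshold)
    n_f <- n_f + sum(tr$lambda_flip > threshold)
    n <- n + nrow(tr)
  }
  c(p_xray = n_x / n, p_flip = n_f / n)
}

wham_weights_log <- function(tr, bias, kT) {
  if (is.null(bias) || is_zero_bias(bias)) return(rep(0, nrow(tr)))
  vapply(seq_len(nrow(tr)), function(i) {
    bias_energy(c(tr$lambda_xray[i], tr$lambda_flip[i]), bias) / kT
  }, numeric(1))
}

wham_point <- function(traces, bias, kT, threshold) {
  lw_all <- numeric(0); x_all <- logical(0); f_all <- logical(0)
  for (tr in traces) {
    lw <- wham_weights_log(tr, bias, kT)
    lw_all <- c(lw_all, lw)
    x_all <- c(x_all, tr$lambda_xray > threshold)
    f_all <- c(f_all, tr$lambda_flip > threshold)
  }
  if (!any(x_all) || !any(f_all)) return(NA_real_)
  # DG = -kT ln(p_flip / p_xray); reweighted populations via log-sum-exp,
  # the common normalization cancels in the ratio
  kT * (logsumexp(lw_all[x_all]) - logsumexp(lw_all[f_all]))
}

#' WHAM-style reweighted free-energy difference
#'
#' Recovers unbiased endpoint populations from flattening-biased lambda
#' traces by weighting every frame with `exp(+U_bias(lambda)/kBT)` (the
#' inverse of the applied bias Boltzmann factor, computed via log-sum-exp)
#' and then applying the population formula. With a zero bias this is
#' identical to [endpoint_populations()] + [deltaG_from_populations()].
#' The uncertainty is a replica-level bootstrap over per-replica estimates
#' when two or more replicas sample both endpoints, otherwise a binomial
#' propagation on the pooled counts. Because a standard deviation estimated
#' from a handful of replicas is itself noisy, the bootstrap value is
#' floored by a binomial error over endpoint *visits* (contiguous dwell
#' segments, the effectively independent events in an autocorrelated
#' trace): `kBT * sqrt(1/v_xray + 1/v_flip)` with `v` the pooled visit
#' counts.
#'
#' @param traces A `lambda_trace` tibble or list of them (one per replica).
#' @param bias The [bias_model()] that was applied during sampling.
#' @param temperature Temperature in K.
#' @param threshold Endpoint dominance threshold.
#' @param n_boot Bootstrap resamples for the replica-level uncertainty.
#' @param seed Seed for the bootstrap.
#' @return A [free_energy_estimate()] with method `"WHAM"`.
#' @export
wham_deltaG <- function(traces, bias = NULL,
                        temperature = DEFAULT_TEMPERATURE,
                        threshold = 0.99, n_boot = 1000, seed = 1L) {
  traces <- as_trace_list(traces)
  kT <- kBT(temperature)
  value <- wham_point(traces, bias, kT, threshold)
  if (is.na(value)) {
    stop("no endpoint sampling: at least one pose never dominates ",
         "(lambda > ", threshold, ") in the pooled traces")
  }
  n <- sum(vapply(traces, nrow, numeric(1)))
  per_rep <- vapply(traces, function(tr) {
    wham_point(list(tr), bias, kT, threshold)
  }, numeric(1))
  per_rep <- per_rep[is.finite(per_rep)]
  if (length(per_rep) >= 2) {
    unc <- bootstrap_uncertainty(per_rep, n_boot = n_boot, seed = seed)
  } else {
    p <- endpoint_populations(traces, threshold)
    unc <- kT * sqrt((1 - p[1]) / (n * p[1]) + (1 - p[2]) / (n * p[2]))
  }
  # floor by the independent-visit binomial error (see Details)
  v_x <- 0; v_f <- 0
  for (tr in traces) {
    state <- ifelse(tr$lambda_xray > threshold, 1L,
                    ifelse(tr$lambda_flip > threshold, -1L, 0L))
    s <- state[state != 0L]
    if (length(s) > 0) {
      starts <- c(TRUE, diff(s) != 0L)
      v_x <- v_x + sum(s[starts] == 1L)
      v_f <- v_f + sum(s[starts] == -1L)
    }
  }
  floor_unc <- kT * sqrt(1 / max(v_x, 1) + 1 / max(v_f, 1))
  unc <- max(unname(unc), floor_unc)
  free_energy_estimate(value, unc, method = "WHAM", n_samples = n)
}

#' Replica-level bootstrap uncertainty
#'
#' Standard deviation of bootstrap means obtained by resampling the
#' *replica-level* estimates with replacement (frames within a replica are
#' autocorrelated; replicas are the independent unit).
#'
#' @param replica_estimates Numeric vector of per-replica estimates.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (deterministic for a fixed seed).
#' @return Bootstrap standard deviation (kcal/mol); exactly 0 when all
#'   replicas are identical.
#' @export
bootstrap_uncertainty <- function(replica_estimates, n_boot = 1000,
                                  seed = 1L) {
  x <- replica_estimates
  stopifnot(length(x) >= 1, n_boot >= 2)
  if (length(x) == 1 || stats::sd(x) == 0) return(0)
  with_local_seed(seed, {
    m <- matrix(sample(x, length(x) * n_boot, replace = TRUE),
                nrow = n_boot)
    stats::sd(rowMeans(m))
  })
}

#' Zwanzig one-step (exponential averaging) free-energy estimate
#'
#' \deqn{\Delta G = -k_B T \ln \langle e^{-\Delta U / k_B T} \rangle}
#' computed via log-sum-exp (overflow-safe for any `delta_u`). When
#' `replica_ids` are given, the uncertainty is a replica-level bootstrap of
#' per-replica estimates; otherwise it is a first-order delta-method
#' standard error over frames.
#'
#' @param delta_u Numeric series of energy differences
#'   `U_target - U_reference` in kcal/mol.
#' @param temperature Temperature in K.
#' @param replica_ids Optional integer vector assigning frames to replicas.
#' @param n_boot,seed Bootstrap controls.
#' @return A [free_energy_estimate()] with method `"Zwanzig"`.
#' @export
zwanzig <- function(delta_u, temperature = DEFAULT_TEMPERATURE,
                    replica_ids = NULL, n_boot = 1000, seed = 1L) {
  stopifnot(length(delta_u) >= 1, all(is.finite(delta_u)))
  kT <- kBT(temperature)
  point <- function(du) -kT * (logsumexp(-du / kT) - log(length(du)))
  value <- point(delta_u)
  if (!is.null(replica_ids)) {
    per_rep <- vapply(split(delta_u, replica_ids), point, numeric(1))
    unc <- bootstrap_uncertainty(per_rep, n_boot = n_boot, seed = seed)
  } else {
    # delta method on the exponential average, stabilized by the max weight
    a <- -delta_u / kT
    m <- max(a)
    w <- exp(a - m)
    mw <- mean(w)
    unc <- kT * stats::sd(w) / (mw * sqrt(length(w)))
  }
  free_energy_estimate(value, unc, method = "Zwanzig",
                       n_samples = length(delta_u))
}

#' One-step-perturbation restraint correction
#'
#' Computes the free-energy cost of adding the protein-ligand restraints to
#' the crystallographic ("xray") pose, or of removing them from the
#' alternative ("flip") pose, from a single reference ensemble sampled at
#' `lambda = (0.5, 0.5)` with full restraints on both poses
#' ([run_reference_state()]):
#'
#' * `pose = "xray"` (adding): `DG = DG_forward - DG_backward` with the
#'   forward target `lambda = (1, 0)` with restraints on and the backward
#'   target `lambda = (1, 0)` with restraints off;
#' * `pose = "flip"` (removing): forward target `lambda = (0, 1)` with
#'   restraints off, backward target `lambda = (0, 1)` with restraints on.
#'
#' With these signs the two corrections enter the thermodynamic cycle
#' ([combine_cycle()]) additively, and a restraint that is never violated in
#' any frame contributes exactly 0.
#'
#' @param ens A `reference_ensemble` from [run_reference_state()].
#' @param pose `"xray"` or `"flip"`.
#' @param n_boot,seed Bootstrap controls for the replica-level uncertainty.
#' @return A [free_energy_estimate()] with method `"Zwanzig"`.
#' @export
osp_restraint_correction <- function(ens, pose = c("xray", "flip"),
                                     n_boot = 1000, seed = 1L) {
  pose <- match.arg(pose)
  stopifnot(inherits(ens, "reference_ensemble"))
  if (any(abs(ens$lam - 0.5) > 1e-12)) {
    stop("reference ensemble must be sampled at lambda = (0.5, 0.5)")
  }
  lam_target <- if (pose == "xray") c(1, 0) else c(0, 1)
  du_on <- rescore_frames(ens, list(lam = lam_target,
                                    restraint_scales = c(1, 1)))
  du_off <- rescore_frames(ens, list(lam = lam_target,
                                     restraint_scales = c(0, 0)))
  ids <- ens$replica_id
  if (pose == "xray") {
    fwd <- zwanzig(du_on$delta_u, ens$temperature, ids, n_boot, seed)
    bwd <- zwanzig(du_off$delta_u, ens$temperature, ids, n_boot, seed + 1L)
  } else {
    fwd <- zwanzig(du_off$delta_u, ens$temperature, ids, n_boot, seed)
    bwd <- zwanzig(du_on$delta_u, ens$temperature, ids, n_boot, seed + 1L)
  }
  # replica-level bootstrap of the paired difference
  per_rep <- vapply(split(seq_along(ids), ids), function(ix) {
    kT <- kBT(ens$temperature)
    pt <- function(du) -kT * (logsumexp(-du / kT) - log(length(du)))
    if (pose == "xray") pt(du_on$delta_u[ix]) - pt(du_off$delta_u[ix])
    else pt(du_off$delta_u[ix]) - pt(du_on$delta_u[ix])
  }, numeric(1))
  unc <- bootstrap_uncertainty(per_rep, n_boot = n_boot, seed = seed)
  free_energy_estimate(fwd$value - bwd$value, unc, method = "Zwanzig",
                       n_samples = length(ids))
}

# ---------------------------------------------------------------------------
# MBAR

#' Multistate reweighting (MBAR) solver
#'
#' Solves the self-consistent multistate reweighting equations for the
#' relative free energies of K states given the reduced cross-evaluated
#' energies of all pooled samples, entirely in log space.
#'
#' @param u_kn K x N matrix of reduced energies `U_k(x_n)/kBT` where the N
#'   pooled samples comprise `n_k[k]` draws from each state k.
#' @param n_k Integer vector of per-state sample counts (`sum(n_k) == N`).
#' @param tol,max_iter Convergence controls on `max |delta f|`.
#' @return List with `f` (reduced free energies, `f[1] = 0`), `converged`,
#'   `overlap` (K x K overlap matrix whose row sums are 1) and `weights_log`.
#' @export
mbar_solve <- function(u_kn, n_k, tol = 1e-10, max_iter = 10000) {
  K <- nrow(u_kn); N <- ncol(u_kn)
  stopifnot(length(n_k) == K, sum(n_k) == N)
  f <- numeric(K)
  logN <- log(n_k)
  for (iter in seq_len(max_iter)) {
    # log denominator per sample: log sum_l N_l exp(f_l - u_ln)
    a <- logN + f - u_kn          # K x N (column-recycled: careful)
    # R recycles by column: logN + f is K-vector, u_kn K x N -> ok
    amax <- apply(a, 2, max)
    logden <- amax + log(colSums(exp(sweep(a, 2, amax))))
    fnew <- vapply(seq_len(K), function(k) {
      -logsumexp(-u_kn[k, ] - logden)
    }, numeric(1))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  converged <- delta < tol
  a <- logN + f - u_kn
  amax <- apply(a, 2, max)
  logden <- amax + log(colSums(exp(sweep(a, 2, amax))))
  # W[n, k] = exp(f_k - u_kn - logden_n); columns sum to 1 after * N... use:
  logW <- t(f - u_kn) - logden   # N x K
  W <- exp(logW)
  overlap <- t(W) %*% (W * rep(n_k, times = 1)[col(W)])
  # overlap_ij = sum_n W_ni N_j W_nj ; rows sum to ~1
  list(f = f, converged = converged, overlap = overlap, weights_log = logW)
}

#' Windowed restraint-coupling free energy via FEP/MBAR
#'
#' Estimates the free-energy difference between the first and last window of
#' a restraint-strength schedule from cross-evaluated window energies, using
#' the multistate reweighting solver, and exposes per-pair overlap
#' diagnostics so a vanishing-overlap failure between adjacent windows is
#' detectable rather than silent.
#'
#' @param u_mat K x N matrix of window potential energies (kcal/mol):
#'   `u_mat[k, n]` is window k's potential evaluated on pooled sample n.
#' @param n_k Per-window sample counts.
#' @param temperature Temperature in K.
#' @param n_boot,seed Sample-level bootstrap controls for the uncertainty.
#' @param overlap_warn Threshold on the adjacent-window overlap below which
#'   the estimate is flagged.
#' @return A [free_energy_estimate()] with method `"MBAR"`; the overlap
#'   matrix is attached as `attr(, "overlap")`, and `flag` is set when the
#'   solver fails to converge or adjacent overlap is poor.
#' @export
fep_mbar_path <- function(u_mat, n_k, temperature = DEFAULT_TEMPERATURE,
                          n_boot = 30, seed = 1L, overlap_warn = 0.03) {
  stopifnot(nrow(u_mat) >= 2)
  kT <- kBT(temperature)
  sol <- mbar_solve(u_mat / kT, n_k)
  K <- nrow(u_mat)
  value <- kT * (sol$f[K] - sol$f[1])
  adj <- vapply(seq_len(K - 1), function(k) {
    min(sol$overlap[k, k + 1], sol$overlap[k + 1, k])
  }, numeric(1))
  flag <- NULL
  if (!sol$converged) flag <- "not converged"
  if (min(adj) < overlap_warn) {
    flag <- paste(c(flag, sprintf("poor adjacent-window overlap (min %.3g)",
                                  min(adj))), collapse = "; ")
    warning("FEP/MBAR path has poor phase-space overlap between adjacent ",
            "windows (min pairwise overlap ", signif(min(adj), 3), ")")
  }
  # sample-level bootstrap within windows
  unc <- with_local_seed(seed, {
    idx_by_k <- split(seq_len(ncol(u_mat)), rep(seq_len(K), n_k))
    vals <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_k, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }))
      s <- mbar_solve(u_mat[, take, drop = FALSE] / kT, n_k,
                      tol = 1e-8, max_iter = 2000)
      kT * (s$f[K] - s$f[1])
    }, numeric(1))
    stats::sd(vals)
  })
  out <- free_energy_estimate(value, unc, method = "MBAR",
                              n_samples = ncol(u_mat), flag = flag)
  attr(out, "overlap") <- sol$overlap
  attr(out, "adjacent_overlap") <- adj
  out
}

# ---------------------------------------------------------------------------
# Cycle assembly and diagnostics

#' Assemble the pose-ranking thermodynamic cycle
#'
#' Combines the three legs of the restrained pose-ranking cycle — the cost
#' of adding restraints to the xray pose, the core restrained
#' lambda-dynamics free energy, and the cost of removing restraints from the
#' flip pose — into the final relative pose free energy:
#' \deqn{\Delta\Delta G_{xray \to flip} = \Delta G^{OSP}_{add,xray}
#'   + \Delta G^{MS\lambda D}_{core} + \Delta G^{OSP}_{remove,flip}}
#' The combined value is the exact sum of the component values and the
#' combined uncertainty is the quadrature (root-sum-square) of the component
#' uncertainties; rounding happens only at presentation.
#'
#' @param osp_add_xray,msld_core,osp_remove_flip [free_energy_estimate()]s
#'   (or plain numbers, taken as exact).
#' @return A `cycle_result` with the three components and the combined
#'   estimate.
#' @export
combine_cycle <- function(osp_add_xray, msld_core, osp_remove_flip) {
  as_est <- function(x, method = "Zwanzig") {
    if (inherits(x, "free_energy_estimate")) x
    else free_energy_estimate(as.numeric(x[1]),
                              if (length(x) > 1) x[2] else 0,
                              method = method)
  }
  a <- as_est(osp_add_xray); m <- as_est(msld_core, "WHAM")
  b <- as_est(osp_remove_flip)
  combined <- free_energy_estimate(
    a$value + m$value + b$value,
    sqrt(a$uncertainty^2 + m$uncertainty^2 + b$uncertainty^2),
    method = m$method, n_samples = m$n_samples)
  structure(list(osp_add_xray = a, msld_core = m, osp_remove_flip = b,
                 combined = combined),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result>  (kcal/mol)\n")
  cat(sprintf("  add restraints, xray : %7.3f +- %.3f\n",
              x$osp_add_xray$value, x$osp_add_xray$uncertainty))
  cat(sprintf("  restrained core      : %7.3f +- %.3f\n",
              x$msld_core$value, x$msld_core$uncertainty))
  cat(sprintf("  remove restraints, flip: %5.3f +- %.3f\n",
              x$osp_remove_flip$value, x$osp_remove_flip$uncertainty))
  cat(sprintf("  combined DDG(xray->flip): %7.3f +- %.3f\n",
              x$combined$value, x$combined$uncertainty))
  invisible(x)
}

#' Sampling diagnostics of lambda traces
#'
#' Counts endpoint-to-endpoint transitions (alternations between the two
#' dominant-pose states, ignoring intervening non-endpoint frames) per
#' nanosecond of pooled trace time, and the fraction of frames in which
#' either pose dominates (the "physical ligand" fraction).
#'
#' @param traces A `lambda_trace` tibble or list of them.
#' @param threshold Dominance threshold on lambda (default 0.99).
#' @return A tibble with `transitions`, `elapsed_ns`, `transitions_per_ns`
#'   and `physical_fraction`.
#' @export
trace_diagnostics <- function(traces, threshold = 0.99) {
  traces <- as_trace_list(traces)
  n_trans <- 0; elapsed_ps <- 0; n_phys <- 0; n <- 0
  for (tr in traces) {
    state <- ifelse(tr$lambda_xray > threshold, 1L,
                    ifelse(tr$lambda_flip > threshold, -1L, 0L))
    s <- state[state != 0L]
    if (length(s) > 1) n_trans <- n_trans + sum(diff(s) != 0L)
    elapsed_ps <- elapsed_ps + diff(range(tr$time_ps))
    n_phys <- n_phys + sum(state != 0L)
    n <- n + length(state)
  }
  tibble::tibble(
    transitions = n_trans,
    elapsed_ns = elapsed_ps / 1000,
    transitions_per_ns = if (elapsed_ps > 0) n_trans / (elapsed_ps / 1000)
                         else 0,
    physical_fraction = n_phys / n)
}
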