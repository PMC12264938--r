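#' Simulation configuration
#'
#' Settings for the Langevin samplers. Times are in ps, temperatures in K,
#' friction in 1/ps. The alchemical angles theta carry a fictitious mass
#' (amu Å²) and their own Langevin thermostat at the same temperature. The
#' default lambda save stride of 10 steps mirrors the convention of saving
#' lambda ten integration steps apart.
#'
#' @param dt Time step in ps.
#' @param n_steps Number of integration steps.
#' @param temperature Temperature in K.
#' @param friction Coordinate friction in 1/ps.
#' @param theta_friction Friction on theta in 1/ps.
#' @param theta_mass Fictitious theta mass in amu Å².
#' @param lambda_save_stride Save lambda every this many steps.
#' @param coord_save_stride Save coordinates every this many steps.
#' @param fnex_c FNEX exponent coefficient.
#' @param seed Integer seed; runs are bit-reproducible for a fixed seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.004, n_steps = 20000,
                              temperature = DEFAULT_TEMPERATURE,
                              friction = 5, theta_friction = 5,
                              theta_mass = 1,
                              lambda_save_stride = 10,
                              coord_save_stride = 50,
                              fnex_c = 5.5, seed = 1L) {
  stopifnot(dt > 0, n_steps >= 1, lambda_save_stride >= 1,
            coord_save_stride >= 1, temperature > 0, theta_mass > 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, friction = friction,
                 theta_friction = theta_friction, theta_mass = theta_mass,
                 lambda_save_stride = as.integer(lambda_save_stride),
                 coord_save_stride = as.integer(coord_save_stride),
                 fnex_c = fnex_c, seed = as.integer(seed)),
            class = "simulation_config")
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * offset) %% 2147483629 + 1)
}

new_lambda_trace <- function(time_ps, lam_mat, replica_id = 1L, seed = NA) {
  out <- tibble::tibble(time_ps = time_ps,
                        lambda_xray = lam_mat[, 1],
                        lambda_flip = lam_mat[, 2])
  attr(out, "replica_id") <- replica_id
  attr(out, "seed") <- seed
  class(out) <- c("lambda_trace", class(out))
  out
}

#' Discard the initial fraction of a lambda trace
#'
#' @param trace A `lambda_trace`.
#' @param fraction Fraction of leading frames to drop (default 1/6,
#'   mirroring discarding the first five of thirty production
#'   nanoseconds).
#' @return The truncated trace.
#' @export
discard_initial <- function(trace, fraction = 1 / 6) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nrow(trace)
  drop <- round(fraction * n)
  out <- trace[seq.int(drop + 1, n), ]
  attr(out, "replica_id") <- attr(trace, "replica_id")
  attr(out, "seed") <- attr(trace, "seed")
  class(out) <- unique(c("lambda_trace", class(out)))
  out
}

# --- flattened force field -------------------------------------------------
# Precompiled flat arrays so the inner loop avoids per-step list traversal.
compile_ff <- function(system, restraints = NULL, restraint_scales = c(1, 1)) {
  d <- system$dim
  n_env <- nrow(system$env_coords)
  n1 <- nrow(system$poses[[1]]$coords)
  n2 <- nrow(system$poses[[2]]$coords)
  n_mob <- n1 + n2
  slot_of_atom <- function(idx) {     # mobile slot (1-based) or NA for env
    if (idx <= n_env) NA_integer_ else as.integer(idx - n_env)
  }
  # wells
  wells <- list()
  k_harm <- numeric(n_mob * d); c_harm <- numeric(n_mob * d)
  quartic <- list()
  slot <- 0
  pose_of_slot <- integer(n_mob)
  mass <- numeric(n_mob)
  for (p in 1:2) {
    po <- system$poses[[p]]
    for (j in seq_len(nrow(po$coords))) {
      slot <- slot + 1
      pose_of_slot[slot] <- p
      mass[slot] <- system$masses[[p]][j]
      w <- po$wells[[j]]
      ix <- (slot - 1) * d + seq_len(d)
      if (w$type == "harmonic") {
        k_harm[ix] <- w$k; c_harm[ix] <- w$center
      } else {
        quartic[[length(quartic) + 1]] <- list(ix = ix[1], a = w$a, b = w$b,
                                               center = w$center)
      }
    }
  }
  # interactions
  # pose membership comes from structural position, not the stored column
  # (pose labels may have been swapped)
  ia_all <- dplyr::bind_rows(
    dplyr::mutate(system$poses[[1]]$interactions, .slot = .data$particle,
                  .pose = 1L),
    dplyr::mutate(system$poses[[2]]$interactions,
                  .slot = .data$particle + n1, .pose = 2L))
  ni <- nrow(ia_all)
  ia <- NULL
  if (ni > 0) {
    ia <- list(
      off = (ia_all$.slot - 1) * d,
      pose = ia_all$.pose,
      anchor = matrix(system$env_coords[ia_all$env_atom, ], ncol = d),
      eps4 = 4 * ia_all$epsilon,
      sig6 = ia_all$sigma^6,
      alpha = ia_all$alpha,
      idx = outer((ia_all$.slot - 1) * d, seq_len(d), "+")
    )
  }
  # restraints
  rs <- NULL
  if (!is.null(restraints) && nrow(restraints) > 0) {
    keep <- vapply(seq_len(nrow(restraints)), function(i) {
      restraint_scale_for(system, restraints, i, restraint_scales) > 0
    }, logical(1))
    rr <- restraints[keep, , drop = FALSE]
    if (nrow(rr) > 0) {
      sc <- vapply(seq_len(nrow(rr)), function(i) {
        restraint_scale_for(system, rr, i, restraint_scales)
      }, numeric(1))
      rs <- lapply(seq_len(nrow(rr)), function(i) {
        si <- slot_of_atom(rr$atom_i[i]); sj <- slot_of_atom(rr$atom_j[i])
        if (!is.na(si) && si > n_mob) stop("restraint references unknown atom ",
                                           rr$atom_i[i])
        if (!is.na(sj) && sj > n_mob) stop("restraint references unknown atom ",
                                           rr$atom_j[i])
        list(ix_i = if (!is.na(si)) (si - 1) * d + seq_len(d) else NULL,
             ix_j = if (!is.na(sj)) (sj - 1) * d + seq_len(d) else NULL,
             fix_i = if (is.na(si)) system$env_coords[rr$atom_i[i], ] else NULL,
             fix_j = if (is.na(sj)) system$env_coords[rr$atom_j[i], ] else NULL,
             r_min = rr$r_min[i], r_max = rr$r_max[i], k = sc[i] * rr$k[i])
      })
    }
  }
  x0 <- as.numeric(t(rbind(system$poses[[1]]$coords,
                           system$poses[[2]]$coords)))
  list(d = d, n_mob = n_mob, n1 = n1, x0 = x0, mass = mass,
       mass_per_coord = rep(mass, each = d),
       pose_of_slot = pose_of_slot, k_harm = k_harm, c_harm = c_harm,
       quartic = quartic, ia = ia, rs = rs)
}

# potential energy, gradient and dU/dlambda on the flat coordinate vector
ff_eval <- function(ff, x, lam, need_dlam = TRUE) {
  g <- ff$k_harm * (x - ff$c_harm)
  U <- 0.5 * sum(g * (x - ff$c_harm))
  for (q in ff$quartic) {
    dx <- x[q$ix] - q$center
    U <- U + q$a * (dx^2 - q$b^2)^2
    g[q$ix] <- g[q$ix] + 4 * q$a * dx * (dx^2 - q$b^2)
  }
  dUdlam <- c(0, 0)
  ia <- ff$ia
  if (!is.null(ia)) {
    Xi <- matrix(x[ia$idx], nrow = length(ia$off))
    dv <- Xi - ia$anchor
    r2 <- rowSums(dv * dv)
    s6 <- (r2 * r2 * r2) / ia$sig6
    lam_i <- lam[ia$pose]
    A <- 1 / (ia$alpha * (1 - lam_i) + s6)
    U <- U + sum(ia$eps4 * lam_i * (A * A - A))
    common <- ia$eps4 * lam_i * (2 * A - 1)
    coef <- common * (-(A * A) * 6 * (r2 * r2) / ia$sig6)
    gi <- dv * coef
    for (row in seq_along(ia$off)) {
      g[ia$idx[row, ]] <- g[ia$idx[row, ]] + gi[row, ]
    }
    if (need_dlam) {
      dl <- ia$eps4 * (A * A - A) + common * ia$alpha * (A * A)
      dUdlam[1] <- sum(dl[ia$pose == 1])
      dUdlam[2] <- sum(dl[ia$pose == 2])
    }
  }
  for (r in ff$rs) {
    xi <- if (is.null(r$ix_i)) r$fix_i else x[r$ix_i]
    xj <- if (is.null(r$ix_j)) r$fix_j else x[r$ix_j]
    dv <- xi - xj
    dd <- sqrt(sum(dv * dv))
    over <- dd - r$r_max; under <- r$r_min - dd
    if (over > 0) {
      U <- U + r$k * over * over
      if (dd > 0) {
        gr <- (2 * r$k * over / dd) * dv
        if (!is.null(r$ix_i)) g[r$ix_i] <- g[r$ix_i] + gr
        if (!is.null(r$ix_j)) g[r$ix_j] <- g[r$ix_j] - gr
      }
    } else if (under > 0) {
      U <- U + r$k * under * under
      if (dd > 0) {
        gr <- (-2 * r$k * under / dd) * dv
        if (!is.null(r$ix_i)) g[r$ix_i] <- g[r$ix_i] + gr
        if (!is.null(r$ix_j)) g[r$ix_j] <- g[r$ix_j] - gr
      }
    }
  }
  list(U = U, g = g, dUdlam = dUdlam)
}

flat_to_coords <- function(ff, x) {
  m <- matrix(x, ncol = ff$d, byrow = TRUE)
  list(m[seq_len(ff$n1), , drop = FALSE],
       m[seq.int(ff$n1 + 1, ff$n_mob), , drop = FALSE])
}

#' Run lambda-dynamics on a toy system
#'
#' BAOAB Langevin dynamics over the mobile pose coordinates and the two
#' alchemical angles theta, under the hybrid Hamiltonian with the supplied
#' flattening bias and restraints. Coordinates and theta have independent
#' thermostats at the same temperature. The run aborts with the step index
#' if the energy turns non-finite, and is bit-reproducible for a fixed
#' config seed.
#'
#' @param system A `particle_system`.
#' @param bias A [bias_model()] or `NULL`.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param cfg A [simulation_config()].
#' @param fixed_lambda Optional lambda vector: when given, theta is not
#'   propagated and lambda stays fixed (used for reference-state and
#'   windowed sampling).
#' @param init Optional list with elements `x` (flat coordinates) and
#'   `theta` to resume from.
#' @param replica_id Identifier stored on the trace.
#' @return List with `trace` (a `lambda_trace` tibble), `frames` (list of
#'   per-snapshot pose coordinate lists), `frame_energies` (potential energy
#'   of each stored frame, bias excluded), `final` (state to resume from)
#'   and `kinetic_temperature` (mean over steps, K).
#' @export
run_lambda_dynamics <- function(system, bias = NULL, restraints = NULL,
                                cfg = simulation_config(),
                                fixed_lambda = NULL, init = NULL,
                                replica_id = 1L) {
  ff <- compile_ff(system, restraints)
  d <- ff$d
  kT <- kBT(cfg$temperature)
  kT_mech <- kT * KCAL_TO_AKMA
  dt <- cfg$dt
  mpc <- ff$mass_per_coord
  fix_lam <- !is.null(fixed_lambda)
  with_local_seed(cfg$seed, {
    x <- if (!is.null(init)) init$x else ff$x0
    theta <- if (!is.null(init)) init$theta
             else if (fix_lam) c(0, 0)
             else c(0.4, -0.4)
    v <- stats::rnorm(length(x)) * sqrt(kT_mech / mpc)
    vth <- stats::rnorm(2) * sqrt(kT_mech / cfg$theta_mass)
    c1 <- exp(-cfg$friction * dt); c2 <- sqrt((1 - c1^2) * kT_mech / mpc)
    c1t <- exp(-cfg$theta_friction * dt)
    c2t <- sqrt((1 - c1t^2) * kT_mech / cfg$theta_mass)
    lam <- if (fix_lam) fixed_lambda else lambda_from_theta(theta, cfg$fnex_c)
    ev <- ff_eval(ff, x, lam, need_dlam = !fix_lam)
    grad_th <- if (fix_lam) c(0, 0) else {
      dUd <- ev$dUdlam + if (!is.null(bias)) bias_energy_dlam(lam, bias) else 0
      as.numeric(dUd %*% lambda_jacobian(theta, cfg$fnex_c))
    }
    n_save <- cfg$n_steps %/% cfg$lambda_save_stride
    t_out <- numeric(n_save); lam_out <- matrix(0, n_save, 2)
    frames <- list(); frame_E <- numeric(0)
    ksum <- 0
    isave <- 0
    half <- 0.5 * dt * KCAL_TO_AKMA
    for (step in seq_len(cfg$n_steps)) {
      # B
      v <- v - half * ev$g / mpc
      if (!fix_lam) vth <- vth - half * grad_th / cfg$theta_mass
      # A
      x <- x + 0.5 * dt * v
      if (!fix_lam) theta <- theta + 0.5 * dt * vth
      # O
      v <- c1 * v + c2 * stats::rnorm(length(v))
      if (!fix_lam) vth <- c1t * vth + c2t * stats::rnorm(2)
      # A
      x <- x + 0.5 * dt * v
      if (!fix_lam) theta <- theta + 0.5 * dt * vth
      # B
      if (!fix_lam) lam <- lambda_from_theta(theta, cfg$fnex_c)
      ev <- ff_eval(ff, x, lam, need_dlam = !fix_lam)
      if (!is.finite(ev$U)) {
        stop("non-finite potential energy at step ", step,
             " (U = ", ev$U, "); reduce dt or check the system")
      }
      if (!fix_lam) {
        dUd <- ev$dUdlam +
          if (!is.null(bias)) bias_energy_dlam(lam, bias) else 0
        grad_th <- as.numeric(dUd %*% lambda_jacobian(theta, cfg$fnex_c))
        vth <- vth - half * grad_th / cfg$theta_mass
      }
      v <- v - half * ev$g / mpc
      ksum <- ksum + sum(mpc * v * v) +
        if (!fix_lam) cfg$theta_mass * sum(vth * vth) else 0
      if (step %% cfg$lambda_save_stride == 0) {
        isave <- isave + 1
        t_out[isave] <- step * dt
        lam_out[isave, ] <- lam
      }
      if (step %% cfg$coord_save_stride == 0) {
        frames[[length(frames) + 1]] <- flat_to_coords(ff, x)
        # physical (bias-free) potential at the stored frame
        frame_E <- c(frame_E, ev$U)
      }
    }
    ndof <- length(x) + if (fix_lam) 0 else 2
    kin_T <- ksum / (cfg$n_steps * ndof * KB_KCAL * KCAL_TO_AKMA)
    list(trace = new_lambda_trace(t_out, lam_out, replica_id, cfg$seed),
         frames = frames, frame_energies = frame_E,
         final = list(x = x, theta = theta),
         kinetic_temperature = kin_T)
  })
}

#' Adaptive flattening of the lambda landscape
#'
#' Iteratively builds a tabulated bias on lambda from sampled histograms:
#' after each short run the profile is updated by
#' `b <- b - kBT ln P_hat(lambda)` (so over-sampled regions are pushed up),
#' until the occupied-bin probability ratio `max/min` drops below
#' `flatness_ratio` *and* both endpoints have been visited, or the schedule
#' is exhausted — in which case the best bias so far is returned flagged as
#' not flattened rather than failing.
#'
#' The theta-to-lambda map concentrates sampling near the endpoints even on
#' a perfectly flat landscape (the FNEX measure), so the histogram is taken
#' over *equal-measure* lambda bins: the 50 bins are quantiles of the exact
#' FNEX sampling measure (computed once from a deterministic theta grid).
#' On these bins a flat landscape gives a flat histogram with zero bias —
#' an already-flat system converges in one iteration with a near-zero
#' profile — and the learned profile only ever needs to represent the
#' (smooth) negative landscape itself, never the steep measure correction,
#' which keeps its forces well-resolved at the production time step.
#'
#' @param system A `particle_system`.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param cfg A [simulation_config()]; each iteration runs
#'   `schedule$steps_per_iteration` steps.
#' @param schedule List with `n_iterations` and `steps_per_iteration`.
#' @param n_bins Number of lambda bins (default 50).
#' @param flatness_ratio Occupied-bin max/min probability ratio defining
#'   "flat" (default 10).
#' @param gain Damping factor on each histogram update (default 0.7);
#'   full-strength updates amplify histogram noise.
#' @param init_bias Optional starting [bias_model()].
#' @return List with `bias` (a tabulated [bias_model()]), `flattened`
#'   (logical), and `diagnostics` (tibble, one row per iteration).
#' @export
flatten_alf <- function(system, restraints = NULL, cfg = simulation_config(),
                        schedule = list(n_iterations = 10,
                                        steps_per_iteration = 20000),
                        n_bins = 50, flatness_ratio = 10, gain = 0.7,
                        init_bias = NULL) {
  edges <- fnex_measure_quantile_edges(n_bins, cfg$fnex_c)
  n_bins <- length(edges) - 1
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  kT <- kBT(cfg$temperature)
  b <- if (!is.null(init_bias) && !is.null(init_bias$table)) {
    stats::approx(init_bias$table$mid, init_bias$table$value, xout = mids,
                  rule = 2)$y
  } else rep(0, n_bins)
  b <- b - min(b)
  diag_rows <- list()
  best <- NULL; best_ratio <- Inf
  flattened <- FALSE
  state <- NULL
  for (it in seq_len(schedule$n_iterations)) {
    bias <- tabulated_bias(mids, b)
    cfg_it <- cfg
    cfg_it$n_steps <- as.integer(schedule$steps_per_iteration)
    cfg_it$seed <- derive_seed(cfg$seed, 100 + it)
    cfg_it$lambda_save_stride <- min(cfg$lambda_save_stride, 2L)
    run <- run_lambda_dynamics(system, bias, restraints, cfg_it,
                               init = state)
    state <- run$final
    l1 <- run$trace$lambda_xray
    counts <- tabulate(pmin(pmax(findInterval(l1, edges,
                                              rightmost.closed = TRUE), 1),
                            n_bins), nbins = n_bins)
    occ <- counts > 0
    P <- counts / sum(counts)
    ratio <- if (sum(occ) > 1) max(P[occ]) / min(P[occ]) else Inf
    ends <- any(l1 > 0.99) && any(l1 < 0.01)
    coverage <- mean(occ)
    diag_rows[[it]] <- tibble::tibble(iteration = it, ratio = ratio,
                                      endpoints_visited = ends,
                                      bin_coverage = coverage)
    if (ratio <= flatness_ratio && ends && coverage == 1) {
      best <- b; flattened <- TRUE
      diag_rows[[it]]$flattened <- TRUE
      break
    }
    diag_rows[[it]]$flattened <- FALSE
    if (ratio < best_ratio && ends) { best_ratio <- ratio; best <- b }
    # update: floor empty bins at half a count so they attract sampling;
    # a light 3-bin smoothing and a damped gain keep histogram noise from
    # oscillating the profile
    Pfl <- pmax(counts, 0.5) / sum(counts)
    lp <- log(Pfl)
    lp_s <- lp
    if (n_bins >= 3) {
      lp_s[2:(n_bins - 1)] <- (lp[1:(n_bins - 2)] + lp[2:(n_bins - 1)] +
                                 lp[3:n_bins]) / 3
    }
    b <- b - gain * kT * lp_s
    b <- b - min(b)
  }
  if (is.null(best)) best <- b
  list(bias = tabulated_bias(mids, best), flattened = flattened,
       diagnostics = dplyr::bind_rows(diag_rows))
}

# lambda bin edges holding equal mass under the flat-landscape FNEX
# sampling measure
fnex_measure_quantile_edges <- function(n_bins = 50, fnex_c = 5.5) {
  n_fine <- 4000
  J <- fnex_lambda_measure(n_fine, fnex_c)
  cdf <- cumsum(J) / sum(J)
  fine_edges <- seq(0, 1, length.out = n_fine + 1)
  qs <- seq_len(n_bins - 1) / n_bins
  cut <- fine_edges[vapply(qs, function(q) which(cdf >= q)[1], integer(1)) + 1]
  unique(c(0, cut, 1))
}

#' Marginal sampling measure of lambda under the FNEX map
#'
#' Bin probabilities of `lambda[1]` when both theta angles are uniform on
#' the circle and the landscape is flat, computed by deterministic
#' integration on a theta grid. Used to seed [flatten_alf()].
#'
#' @param n_bins Number of lambda bins.
#' @param fnex_c FNEX exponent coefficient.
#' @param n_grid Grid points per theta dimension.
#' @return Numeric vector of bin probabilities (all positive).
#' @export
fnex_lambda_measure <- function(n_bins = 50, fnex_c = 5.5, n_grid = 1201) {
  th <- seq(-pi, pi, length.out = n_grid + 1)[seq_len(n_grid)]
  s <- outer(sin(th), sin(th), "-")
  l1 <- 1 / (1 + exp(-fnex_c * s))
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(l1, edges,
                                            rightmost.closed = TRUE), 1),
                          n_bins), nbins = n_bins)
  pmax(counts, 0.5) / sum(counts)
}

#' Replica production protocol
#'
#' Runs `n_replicas` independent lambda-dynamics production simulations with
#' seeds derived from the config seed, discarding the leading
#' `discard_fraction` of every trace before estimation (default 1/6).
#'
#' @inheritParams flatten_alf
#' @param bias The flattened [bias_model()].
#' @param n_replicas Number of replicas (default 5); fewer than 2 degrades
#'   the bootstrap and triggers a warning.
#' @param discard_fraction Leading fraction of frames to discard.
#' @return List of `lambda_trace` tibbles, one per replica.
#' @export
run_replica_protocol <- function(system, bias, restraints = NULL,
                                 cfg = simulation_config(), n_replicas = 5,
                                 discard_fraction = 1 / 6) {
  if (n_replicas < 2) {
    warning("fewer than 2 replicas: the replica-level bootstrap is degenerate")
  }
  lapply(seq_len(n_replicas), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, 1000 + r)
    run <- run_lambda_dynamics(system, bias, restraints, cfg_r,
                               replica_id = r)
    discard_initial(run$trace, discard_fraction)
  })
}

#' Sample the fixed-lambda reference state
#'
#' Samples the one-step-perturbation reference state: both poses held at
#' `lambda = (0.5, 0.5)` with the full restraints on, no bias, no theta
#' dynamics. Runs `n_replicas` independent simulations with distinct derived
#' seeds and stores frames plus their reference-state potential energies for
#' re-scoring.
#'
#' @param system A `particle_system`.
#' @param restraints_full The full-force-constant [restraint_set()].
#' @param cfg A [simulation_config()].
#' @param n_replicas Number of independent reference simulations (default 3).
#' @param equil_fraction Leading fraction of stored frames discarded as
#'   equilibration.
#' @return A `reference_ensemble` object.
#' @export
run_reference_state <- function(system, restraints_full,
                                cfg = simulation_config(), n_replicas = 3,
                                equil_fraction = 1 / 6) {
  frames <- list(); energies <- numeric(0); rep_id <- integer(0)
  for (r in seq_len(n_replicas)) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, 2000 + r)
    run <- run_lambda_dynamics(system, bias = NULL,
                               restraints = restraints_full, cfg_r,
                               fixed_lambda = c(0.5, 0.5), replica_id = r)
    nfr <- length(run$frames)
    keep <- seq.int(round(equil_fraction * nfr) + 1, nfr)
    frames <- c(frames, run$frames[keep])
    energies <- c(energies, run$frame_energies[keep])
    rep_id <- c(rep_id, rep(r, length(keep)))
  }
  structure(list(system = system, restraints = restraints_full,
                 frames = frames, energies = energies, replica_id = rep_id,
                 lam = c(0.5, 0.5), temperature = cfg$temperature),
            class = "reference_ensemble")
}

#' @export
print.reference_ensemble <- function(x, ...) {
  cat("<reference_ensemble>", length(x$frames), "frames from",
      length(unique(x$replica_id)), "replicas at lambda = (0.5, 0.5)\n")
  invisible(x)
}

#' Re-score reference-state frames at an end state
#'
#' Evaluates the per-frame energy difference `U_target - U_reference` on the
#' stored reference-ensemble frames without re-simulation. The target is an
#' end-state definition: a lambda vector (`(1, 0)` or `(0, 1)`) plus per-pose
#' restraint on/off toggles.
#'
#' @param ens A `reference_ensemble`.
#' @param endstate List with `lam` (lambda vector) and `restraint_scales`
#'   (length-2, 0 = restraints off for that pose, 1 = full force constant).
#' @return Tibble with `frame`, `replica_id` and `delta_u` (kcal/mol).
#' @export
rescore_frames <- function(ens, endstate) {
  stopifnot(inherits(ens, "reference_ensemble"))
  lam <- endstate$lam
  if (!isTRUE(all.equal(sort(lam), c(0, 1)))) {
    stop("endstate lambda must be (1, 0) or (0, 1)")
  }
  sc <- endstate$restraint_scales %||% c(1, 1)
  ff <- compile_ff(ens$system, ens$restraints, restraint_scales = sc)
  du <- vapply(seq_along(ens$frames), function(i) {
    x <- as.numeric(t(do.call(rbind, ens$frames[[i]])))
    ff_eval(ff, x, lam, need_dlam = FALSE)$U - ens$energies[i]
  }, numeric(1))
  tibble::tibble(frame = seq_along(du), replica_id = ens$replica_id,
                 delta_u = du)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a restraint-strength window schedule for FEP/MBAR
#'
#' Runs one fixed-lambda simulation per window, with the restraint force
#' constants multiplied by the window's coupling scale, and cross-evaluates
#' every stored frame's restraint energy so the full window-by-sample energy
#' matrix for [fep_mbar_path()] can be assembled. Because the windows differ
#' only in the restraint scaling, the cross-energy matrix is
#' `scale_k * U_restraint(frame_n)` up to a per-frame constant that drops
#' out of the multistate solve.
#'
#' @param system A `particle_system`.
#' @param restraints A [restraint_set()] (full force constants).
#' @param lam Fixed lambda vector for all windows (an end state, usually).
#' @param scales Increasing restraint coupling scales, e.g.
#'   `seq(0, 1, length.out = 6)`.
#' @param cfg A [simulation_config()]; each window runs `cfg$n_steps`.
#' @param equil_fraction Leading fraction of stored frames discarded.
#' @return List with `u_mat` (windows x pooled samples, kcal/mol), `n_k`
#'   (samples per window) and `scales`.
#' @export
sample_restraint_windows <- function(system, restraints, lam = c(1, 0),
                                     scales = seq(0, 1, length.out = 6),
                                     cfg = simulation_config(),
                                     equil_fraction = 1 / 6) {
  stopifnot(length(scales) >= 2, !is.unsorted(scales))
  ur <- numeric(0); n_k <- integer(0)
  for (w in seq_along(scales)) {
    s <- scales[w]
    rs_w <- if (s > 0) {
      r <- restraints; r$k <- r$k * s; r
    } else NULL
    cfg_w <- cfg
    cfg_w$seed <- derive_seed(cfg$seed, 3000 + w)
    run <- run_lambda_dynamics(system, NULL, rs_w, cfg_w,
                               fixed_lambda = lam, replica_id = w)
    nfr <- length(run$frames)
    keep <- seq.int(round(equil_fraction * nfr) + 1, nfr)
    ur_w <- vapply(run$frames[keep], function(fr) {
      restraint_energy(system, fr, restraints)
    }, numeric(1))
    ur <- c(ur, ur_w)
    n_k <- c(n_k, length(keep))
  }
  list(u_mat = outer(scales, ur), n_k = n_k, scales = scales)
}
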