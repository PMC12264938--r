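#' @importFrom rlang .data
NULL

well_energy_one <- function(w, x) {
  if (w$type == "harmonic") {
    0.5 * w$k * sum((x - w$center)^2)
  } else { # quartic, 1D
    dx <- x[1] - w$center
    w$a * (dx^2 - w$b^2)^2
  }
}

well_grad_one <- function(w, x) {
  if (w$type == "harmonic") {
    w$k * (x - w$center)
  } else {
    dx <- x[1] - w$center
    4 * w$a * dx * (dx^2 - w$b^2)
  }
}

atom_pose <- function(system, idx) {
  n_env <- nrow(system$env_coords)
  n1 <- nrow(system$poses[[1]]$coords)
  n2 <- nrow(system$poses[[2]]$coords)
  if (idx <= n_env) 0L
  else if (idx <= n_env + n1) 1L
  else if (idx <= n_env + n1 + n2) 2L
  else stop("restraint references unknown atom index ", idx)
}

restraint_scale_for <- function(system, restraints, i, restraint_scales) {
  p_i <- atom_pose(system, restraints$atom_i[i])
  p_j <- atom_pose(system, restraints$atom_j[i])
  ps <- setdiff(unique(c(p_i, p_j)), 0L)
  if (length(ps) == 0) 1 else restraint_scales[ps[1]]
}

#' Hybrid dual-topology potential energy
#'
#' Evaluates the full hybrid Hamiltonian of a dual-pose system:
#' \deqn{U = U_{env} + \sum_i u_{sc}(r; \lambda_i) + U_{wells}
#'       + U_{restraints} + U_{bias}(\lambda)}
#' where the alchemically scaled part is only the soft-core nonbonded
#' coupling of each pose to the environment ([softcore_pair_energy()], which
#' carries the lambda scaling internally); within-pose well ("bonded") terms
#' and all restraints are *not* scaled by lambda, and no interaction term
#' couples the two poses. The environment is rigid, so `U_env = 0`.
#'
#' @param system A `particle_system`.
#' @param coords List of two matrices of current pose coordinates
#'   (`n_particles x dim` each); defaults to the starting coordinates.
#' @param lam A [lambda_state()] or a numeric lambda vector summing to 1.
#' @param bias A [bias_model()] or `NULL`.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param restraint_scales Length-2 multiplier on the force constants of the
#'   restraints attached to each pose (used when re-scoring end states with
#'   restraints toggled); an inter-pose restraint uses the first pose's
#'   scale.
#' @return Potential energy in kcal/mol.
#' @export
hybrid_energy <- function(system, coords = NULL, lam = c(0.5, 0.5),
                          bias = NULL, restraints = NULL,
                          restraint_scales = c(1, 1)) {
  stopifnot(inherits(system, "particle_system"))
  if (inherits(lam, "lambda_state")) lam <- lam$lam
  stopifnot(length(lam) == 2, abs(sum(lam) - 1) < 1e-9)
  if (is.null(coords)) {
    coords <- list(system$poses[[1]]$coords, system$poses[[2]]$coords)
  }
  U <- 0
  for (p in 1:2) {
    po <- system$poses[[p]]
    for (j in seq_along(po$wells)) {
      U <- U + well_energy_one(po$wells[[j]], coords[[p]][j, ])
    }
    ia <- po$interactions
    for (i in seq_len(nrow(ia))) {
      x <- coords[[p]][ia$particle[i], ]
      a <- system$env_coords[ia$env_atom[i], ]
      r <- sqrt(sum((x - a)^2))
      U <- U + softcore_pair_energy(r, lam[p], ia$epsilon[i], ia$sigma[i],
                                    ia$alpha[i])
    }
  }
  if (!is.null(restraints) && nrow(restraints) > 0) {
    for (i in seq_len(nrow(restraints))) {
      sc <- restraint_scale_for(system, restraints, i, restraint_scales)
      if (sc == 0) next
      xi <- atom_position(system, restraints$atom_i[i], coords)
      xj <- atom_position(system, restraints$atom_j[i], coords)
      d <- sqrt(sum((xi - xj)^2))
      U <- U + flat_bottom_energy(d, restraints$r_min[i], restraints$r_max[i],
                                  sc * restraints$k[i])
    }
  }
  if (!is.null(bias)) U <- U + bias_energy(lam, bias)
  U
}

#' Energy, coordinate gradients and theta gradients of the hybrid Hamiltonian
#'
#' Internal workhorse of the Langevin sampler: returns the potential energy
#' together with analytic gradients with respect to every mobile coordinate
#' and, when `theta` is supplied, with respect to the alchemical angles (via
#' the FNEX chain rule).
#'
#' @return List with `U` (kcal/mol), `grad` (list of two matrices,
#'   kcal/mol/Å) and `grad_theta` (length-2 vector or NULL).
#' @keywords internal
hybrid_gradients <- function(system, coords, lam = NULL, theta = NULL,
                             fnex_c = 5.5, bias = NULL, restraints = NULL,
                             restraint_scales = c(1, 1)) {
  if (!is.null(theta)) lam <- lambda_from_theta(theta, fnex_c)
  if (inherits(lam, "lambda_state")) lam <- lam$lam
  U <- 0
  grad <- lapply(coords, function(m) m * 0)
  dU_dlam <- c(0, 0)
  for (p in 1:2) {
    po <- system$poses[[p]]
    for (j in seq_along(po$wells)) {
      U <- U + well_energy_one(po$wells[[j]], coords[[p]][j, ])
      grad[[p]][j, ] <- grad[[p]][j, ] + well_grad_one(po$wells[[j]],
                                                       coords[[p]][j, ])
    }
    ia <- po$interactions
    for (i in seq_len(nrow(ia))) {
      x <- coords[[p]][ia$particle[i], ]
      a <- system$env_coords[ia$env_atom[i], ]
      dv <- x - a
      r <- sqrt(sum(dv^2))
      U <- U + softcore_pair_energy(r, lam[p], ia$epsilon[i], ia$sigma[i],
                                    ia$alpha[i])
      dd <- softcore_pair_deriv(r, lam[p], ia$epsilon[i], ia$sigma[i],
                                ia$alpha[i])
      if (r > 0) {
        grad[[p]][ia$particle[i], ] <- grad[[p]][ia$particle[i], ] +
          dd$du_dr * dv / r
      }
      dU_dlam[p] <- dU_dlam[p] + dd$du_dlam
    }
  }
  if (!is.null(restraints) && nrow(restraints) > 0) {
    n_env <- nrow(system$env_coords)
    n1 <- nrow(system$poses[[1]]$coords)
    for (i in seq_len(nrow(restraints))) {
      sc <- restraint_scale_for(system, restraints, i, restraint_scales)
      if (sc == 0) next
      ii <- restraints$atom_i[i]; jj <- restraints$atom_j[i]
      xi <- atom_position(system, ii, coords)
      xj <- atom_position(system, jj, coords)
      dv <- xi - xj
      d <- sqrt(sum(dv^2))
      U <- U + flat_bottom_energy(d, restraints$r_min[i], restraints$r_max[i],
                                  sc * restraints$k[i])
      if (d > 0) {
        g <- flat_bottom_deriv(d, restraints$r_min[i], restraints$r_max[i],
                               sc * restraints$k[i]) * dv / d
        add_to <- function(idx, val) {
          if (idx > n_env) {
            if (idx <= n_env + n1) grad[[1]][idx - n_env, ] <<-
                grad[[1]][idx - n_env, ] + val
            else grad[[2]][idx - n_env - n1, ] <<-
                grad[[2]][idx - n_env - n1, ] + val
          }
        }
        add_to(ii, g)
        add_to(jj, -g)
      }
    }
  }
  grad_theta <- NULL
  if (!is.null(bias)) {
    U <- U + bias_energy(lam, bias)
    dU_dlam <- dU_dlam + bias_energy_dlam(lam, bias)
  }
  if (!is.null(theta)) {
    J <- lambda_jacobian(theta, fnex_c)
    grad_theta <- as.numeric(dU_dlam %*% J)
  }
  list(U = U, grad = grad, grad_theta = grad_theta)
}
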