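#' Soft-core Lennard-Jones pair interaction
#'
#' Alchemically scaled pair potential that remains finite at zero separation
#' for partially coupled states, avoiding the end-point singularity of a bare
#' Lennard-Jones term. The package uses the separation-shifted (Beutler-style)
#' form, frozen as this package's convention:
#' \deqn{u(r; \lambda) = 4 \epsilon \lambda \left[ A^2 - A \right], \quad
#'       A = \frac{1}{\alpha (1 - \lambda) + (r/\sigma)^6}}
#' with dimensionless softness `alpha` (default 0.5). At `lambda = 1` this is
#' exactly the plain Lennard-Jones potential; for `lambda < 1` it is finite
#' everywhere (for example `u(0, 0.5) = 24 epsilon` at the default `alpha`).
#' The alchemical scaling lives entirely inside this form: callers sum
#' `softcore_pair_energy()` terms directly, without an extra lambda prefactor.
#'
#' @param r Distance in Å, `>= 0` (vectorized).
#' @param lam_i Coupling fraction of the owning pose, in `[0, 1]`.
#' @param epsilon Well depth in kcal/mol.
#' @param sigma Zero-crossing distance in Å.
#' @param alpha Soft-core softness parameter, `> 0`.
#' @return Energy in kcal/mol.
#' @examples
#' softcore_pair_energy(2^(1 / 6) * 3.0, 1, epsilon = 0.5, sigma = 3.0) # -0.5
#' @export
softcore_pair_energy <- function(r, lam_i, epsilon, sigma, alpha = 0.5) {
  if (any(r < 0)) stop("`r` must be non-negative")
  stopifnot(lam_i >= 0, lam_i <= 1, alpha > 0, sigma > 0)
  A <- 1 / (alpha * (1 - lam_i) + (r / sigma)^6)
  4 * epsilon * lam_i * (A^2 - A)
}

#' Derivatives of the soft-core pair energy
#'
#' Returns `du/dr` and `du/dlambda` for the force and theta-force evaluation.
#'
#' @inheritParams softcore_pair_energy
#' @return List with vectors `du_dr` (kcal/mol/Å) and `du_dlam` (kcal/mol).
#' @keywords internal
softcore_pair_deriv <- function(r, lam_i, epsilon, sigma, alpha = 0.5) {
  s6 <- (r / sigma)^6
  denom <- alpha * (1 - lam_i) + s6
  A <- 1 / denom
  # dA/dr = -A^2 * 6 r^5 / sigma^6 ; dA/dlam = alpha A^2
  dA_dr <- -A^2 * 6 * r^5 / sigma^6
  dA_dlam <- alpha * A^2
  common <- 4 * epsilon * lam_i * (2 * A - 1)
  list(
    du_dr = common * dA_dr,
    du_dlam = 4 * epsilon * (A^2 - A) + common * dA_dlam
  )
}
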