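#' FNEX parameterization of the alchemical variable
#'
#' The alchemical coupling of each pose is driven by an unbounded dynamical
#' variable theta through the implicit-constraint ("FNEX") functional form
#' \deqn{\lambda_i = \frac{\exp(c \sin\theta_i)}{\sum_j \exp(c \sin\theta_j)}}
#' with exponent coefficient `fnex_c` (default 5.5). The lambdas are smooth in
#' theta, strictly inside (0, 1), and sum to one exactly, so a two-pose system
#' is fully described by `(lambda_xray, lambda_flip)` with
#' `lambda_flip = 1 - lambda_xray`.
#'
#' @param theta Numeric vector of alchemical angles (one per pose), finite.
#' @param fnex_c Dimensionless exponent coefficient; default 5.5.
#' @return Numeric vector of coupling fractions summing to 1.
#' @examples
#' lambda_from_theta(c(pi / 2, -pi / 2))
#' @export
lambda_from_theta <- function(theta, fnex_c = 5.5) {
  if (!is.numeric(theta) || length(theta) < 2 || any(!is.finite(theta))) {
    stop("`theta` must be a finite numeric vector with one entry per pose")
  }
  g <- fnex_c * sin(theta)
  g <- g - max(g)
  e <- exp(g)
  e / sum(e)
}

#' Jacobian of lambda with respect to theta
#'
#' Returns the matrix `J[j, i] = d lambda_j / d theta_i` used by the sampler's
#' chain rule. For the FNEX form this is
#' `lambda_j (delta_ij - lambda_i) c cos(theta_i)`.
#'
#' @inheritParams lambda_from_theta
#' @return A length(theta) x length(theta) matrix.
#' @keywords internal
lambda_jacobian <- function(theta, fnex_c = 5.5) {
  lam <- lambda_from_theta(theta, fnex_c)
  n <- length(lam)
  gp <- fnex_c * cos(theta)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    J[, i] <- lam * (-lam[i]) * gp[i]
    J[i, i] <- J[i, i] + lam[i] * gp[i]
  }
  J
}

#' Construct a lambda state
#'
#' A light container pairing theta with its induced lambda vector. Index 1 is
#' the "xray" pose, index 2 the "flip" pose, by package-wide convention.
#'
#' @inheritParams lambda_from_theta
#' @return A `lambda_state` list with elements `theta`, `lam`, `fnex_c`.
#' @export
lambda_state <- function(theta, fnex_c = 5.5) {
  lam <- lambda_from_theta(theta, fnex_c)
  structure(list(theta = theta, lam = lam, fnex_c = fnex_c),
            class = "lambda_state")
}

#' @export
print.lambda_state <- function(x, ...) {
  cat("<lambda_state>  lambda = (",
      paste(signif(x$lam, 6), collapse = ", "),
      "),  fnex_c = ", x$fnex_c, "\n", sep = "")
  invisible(x)
}
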