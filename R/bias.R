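#' Biasing potentials on the alchemical variable
#'
#' Adaptive landscape flattening (ALF) biases are represented by a
#' `bias_model`, which stores an estimate `b(lambda)` of the free-energy
#' landscape along lambda. The energy the bias contributes to the hybrid
#' Hamiltonian is the *negative* of the stored profile,
#' `U_bias(lambda) = -b(lambda)`, so that when `b` equals the true landscape
#' the sampled lambda density is flat. Two forms are supported:
#'
#' * a coefficient form, this package's own convention:
#'   `b(lambda) = sum_i phi_i lambda_i + psi_i lambda_i^2 +
#'    omega_i lambda_i / (lambda_i + chi_i)`,
#'   with linear (`phi`), quadratic (`psi`) and end-point-shaping
#'   (`omega`, `chi`) terms per pose;
#' * a model-free tabulated form: a piecewise-linear profile over bins of
#'   `lambda[1]` (sufficient for two poses since the lambdas sum to 1).
#'
#' A zero-coefficient model contributes exactly 0, and adding a constant to
#' all `phi` shifts the bias by a lambda-independent constant (lambda
#' populations are unaffected because `sum(lambda) = 1`).
#'
#' @param phi,psi Numeric vectors (kcal/mol), one entry per pose.
#' @param omega Numeric vector (kcal/mol) of end-point-shaping amplitudes.
#' @param chi Numeric vector (dimensionless, > 0) of end-point-shaping widths.
#' @param table Optional tabulated profile: a list with `mid` (bin midpoints
#'   of lambda 1 in `[0, 1]`) and `value` (kcal/mol).
#' @return A `bias_model` object.
#' @export
bias_model <- function(phi = c(0, 0), psi = c(0, 0),
                       omega = c(0, 0), chi = c(1, 1), table = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(omega) == n, length(chi) == n,
            all(chi > 0))
  if (!is.null(table)) {
    stopifnot(is.list(table), length(table$mid) == length(table$value),
              all(is.finite(table$value)))
  }
  structure(list(phi = phi, psi = psi, omega = omega, chi = chi,
                 table = table),
            class = "bias_model")
}

#' Tabulated flattening bias from a lambda histogram
#'
#' Builds a `bias_model` whose profile over `lambda[1]` is given on `n_bins`
#' equal bins. Used by [flatten_alf()] and directly in tests.
#'
#' @param mid Bin midpoints in `[0, 1]`.
#' @param value Profile values in kcal/mol (the landscape estimate `b`).
#' @export
tabulated_bias <- function(mid, value) {
  bias_model(table = list(mid = as.numeric(mid), value = as.numeric(value)))
}

bias_profile_interp <- function(bias, lam1, deriv = FALSE) {
  tb <- bias$table
  if (is.null(tb) || length(tb$mid) == 0) {
    return(rep(0, length(lam1)))
  }
  if (length(tb$mid) == 1) {
    return(if (deriv) rep(0, length(lam1)) else rep(tb$value, length(lam1)))
  }
  if (deriv) {
    idx <- findInterval(lam1, tb$mid, all.inside = TRUE)
    slope <- (tb$value[idx + 1] - tb$value[idx]) /
      (tb$mid[idx + 1] - tb$mid[idx])
    # energy is clamped outside [mid_1, mid_n] (rule = 2): zero force there
    slope[lam1 < tb$mid[1] | lam1 > tb$mid[length(tb$mid)]] <- 0
    slope
  } else {
    stats::approx(tb$mid, tb$value, xout = lam1, rule = 2)$y
  }
}

#' Bias energy contribution to the hybrid Hamiltonian
#'
#' Evaluates `U_bias(lambda) = -b(lambda)` (see [bias_model()] for the sign
#' convention; with `phi = (1, 0)` and `lambda = (1, 0)` the result is
#' `-1` kcal/mol). Finite for all lambda in `[0, 1]`.
#'
#' @param lam Numeric lambda vector (fractions summing to 1) or a
#'   [lambda_state()].
#' @param bias A [bias_model()].
#' @return Energy in kcal/mol.
#' @export
bias_energy <- function(lam, bias) {
  if (inherits(lam, "lambda_state")) lam <- lam$lam
  stopifnot(inherits(bias, "bias_model"))
  b <- sum(bias$phi * lam + bias$psi * lam^2 +
             bias$omega * lam / (lam + bias$chi))
  b <- b + bias_profile_interp(bias, lam[1])
  -b
}

#' Gradient of the bias energy with respect to lambda
#' @keywords internal
bias_energy_dlam <- function(lam, bias) {
  d <- bias$phi + 2 * bias$psi * lam +
    bias$omega * bias$chi / (lam + bias$chi)^2
  d[1] <- d[1] + bias_profile_interp(bias, lam[1], deriv = TRUE)
  -d
}

#' Is this a zero (empty) bias?
#' @keywords internal
is_zero_bias <- function(bias) {
  all(bias$phi == 0) && all(bias$psi == 0) && all(bias$omega == 0) &&
    (is.null(bias$table) || all(bias$table$value == 0))
}

#' Serialize / deserialize a bias model as JSON
#'
#' @param bias A [bias_model()].
#' @param path File path.
#' @return `read_bias_json()` returns a [bias_model()].
#' @export
write_bias_json <- function(bias, path) {
  stopifnot(inherits(bias, "bias_model"))
  jsonlite::write_json(unclass(bias), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_bias_json
#' @export
read_bias_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- x$table
  if (!is.null(tb) && length(tb) == 0) tb <- NULL
  bias_model(phi = x$phi, psi = x$psi, omega = x$omega, chi = x$chi,
             table = tb)
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model>\n  phi: ", paste(signif(x$phi, 4), collapse = ", "),
      "\n  psi: ", paste(signif(x$psi, 4), collapse = ", "), "\n", sep = "")
  if (!is.null(x$table)) {
    cat("  tabulated profile over", length(x$table$mid), "bins, range",
        paste(signif(range(x$table$value), 4), collapse = " .. "),
        "kcal/mol\n")
  }
  invisible(x)
}
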