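# Stability criteria and the constructive energy certificate -------------

#' Spectral analysis of the well-mixed system
#'
#' Eigenvalues of the homogeneous reaction matrix in closed form:
#' \eqn{\lambda_1 = -k_5} and
#' \eqn{\lambda_{2,3} = (-(k_1 + k_4) \mp \sqrt{(k_1-k_4)^2 + 4 k_2 k_3})/2}.
#' With \eqn{k_2, k_3 > 0} the discriminant is a sum of squares plus
#' \eqn{4 k_2 k_3 > 0}, so all eigenvalues are real; with \eqn{k_3 < 0} a
#' complex pair can occur, in which case real parts are reported and used
#' for the stability flag.  The system is stable iff all eigenvalues (real
#' parts) are strictly negative, which is algebraically equivalent to
#' \eqn{k_1 k_4 > k_2 k_3}.
#'
#' @param lc A `ps_lincoef`.
#' @return An object of class `ps_spectral` with the 3x3 `jacobian`,
#'   eigenvalues `lambda1`, `lambda2`, `lambda3` (real parts if complex),
#'   logicals `stable` and `complex_pair`, and `k1k4_minus_k2k3`.
#' @export
spectral_analysis <- function(lc) {
  if (!inherits(lc, "ps_lincoef"))
    stop_ps("plaquestab_config_error", "'lc' is not a ps_lincoef")
  A <- reaction_matrix(lc)
  disc <- (lc$k1 - lc$k4)^2 + 4 * lc$k2 * lc$k3
  lambda1 <- -lc$k5
  if (disc >= 0) {
    r <- sqrt(disc)
    lambda2 <- (-(lc$k1 + lc$k4) - r) / 2
    lambda3 <- (-(lc$k1 + lc$k4) + r) / 2
    complex_pair <- FALSE
  } else {
    # complex-conjugate pair: common real part
    lambda2 <- lambda3 <- -(lc$k1 + lc$k4) / 2
    complex_pair <- TRUE
  }
  structure(list(
    jacobian = A,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    complex_pair = complex_pair,
    k1k4_minus_k2k3 = lc$k1 * lc$k4 - lc$k2 * lc$k3,
    stable = max(lambda1, lambda2, lambda3) < 0
  ), class = "ps_spectral")
}

#' @export
print.ps_spectral <- function(x, ...) {
  cat(sprintf("<ps_spectral> lambda = (%.6g, %.6g, %.6g)%s  stable: %s\n",
              x$lambda1, x$lambda2, x$lambda3,
              if (x$complex_pair) " [real parts of complex pair]" else "",
              x$stable))
  invisible(x)
}

#' Check the two sufficient PDE stability criteria
#'
#' Criterion 1: \eqn{f'(L_e) > 0} (the immune response strengthens when
#' ox-LDL rises) -- equivalent to the spectral condition
#' \eqn{k_1 k_4 > k_2 k_3}.
#' Criterion 2: \eqn{\chi_a^2 < 4 D_b D_a k_3 / k_2} (diffusion dominates
#' chemotactic aggregation).  Both inequalities are strict; equality is
#' classified not stable.  When both hold (which forces \eqn{k_3 > 0}) an
#' explicit energy certificate is constructed.
#'
#' @param lc A `ps_lincoef`.
#' @return An object of class `ps_stability` with logical fields
#'   `criterion1`, `criterion2`, `ode_stable`, the embedded `spectral`
#'   report and, when both criteria hold, the `certificate`
#'   (see [construct_certificate()]), else `NULL`.
#' @export
check_criteria <- function(lc) {
  if (!inherits(lc, "ps_lincoef"))
    stop_ps("plaquestab_config_error", "'lc' is not a ps_lincoef")
  if (lc$k2 <= 0)
    stop_ps("plaquestab_invalid_coefficients", "k2 must be positive")
  sp <- spectral_analysis(lc)
  criterion1 <- lc$fprime_at_Le > 0
  criterion2 <- lc$chi_a^2 < 4 * lc$D_b * lc$D_a * lc$k3 / lc$k2
  cert <- NULL
  if (criterion1 && criterion2 && lc$k3 > 0)
    cert <- construct_certificate(lc)
  structure(list(
    criterion1 = criterion1,
    criterion2 = criterion2,
    ode_stable = sp$stable,
    spectral = sp,
    certificate = cert
  ), class = "ps_stability")
}

#' @export
print.ps_stability <- function(x, ...) {
  cat("<ps_stability>\n")
  cat("  criterion 1 (f'(L_e) > 0):          ", x$criterion1, "\n")
  cat("  criterion 2 (chi_a^2 < 4DbDak3/k2): ", x$criterion2, "\n")
  cat("  ODE spectrum stable:                ", x$ode_stable, "\n")
  cat("  energy certificate:                 ",
      if (is.null(x$certificate)) "absent" else
        sprintf("present (decay rate bound %.6g)",
                x$certificate$decay_rate_bound), "\n")
  invisible(x)
}

# The five bracketed right-hand-side coefficients of the energy identity
#   (1/2) d/dt Int(x a^2 + y b^2 + z c^2) <=
#       coeff_a Int a^2 + coeff_b Int b^2 + coeff_c Int c^2
#     + coeff_grad_a Int |grad a|^2 + coeff_grad_b Int |grad b|^2
# obtained from the weighted, Cauchy-bounded energy identities.
certificate_coefficients <- function(cert, lc) {
  e <- cert
  ga <- if (lc$chi_a > 0) lc$chi_a * e$eps3 * e$y - lc$D_a * e$x
        else -lc$D_a * e$x
  gb <- if (lc$chi_a > 0) (lc$chi_a / (4 * e$eps3) - lc$D_b) * e$y
        else -lc$D_b * e$y
  list(
    coeff_a = lc$k6 * e$eps1 * e$z + lc$k3 * e$eps4 * e$y +
      (lc$k2 * e$eps5 - lc$k1) * e$x,
    coeff_b = lc$k4 * e$eps2 * e$z +
      (lc$k3 / (4 * e$eps4) - lc$k4) * e$y +
      lc$k2 / (4 * e$eps5) * e$x,
    coeff_c = (lc$k6 / (4 * e$eps1) + lc$k4 / (4 * e$eps2) - lc$k5) * e$z,
    coeff_grad_a = ga,
    coeff_grad_b = gb
  )
}

#' Construct the energy-estimate certificate
#'
#' Builds explicit positive weights \eqn{x, y, z} and Cauchy weights
#' \eqn{\epsilon_1..\epsilon_5} under which all five right-hand-side
#' coefficients of the weighted energy identity are strictly negative,
#' certifying exponential decay of
#' \eqn{\phi(t) = \tfrac12 \int x a^2 + y b^2 + z c^2}.
#'
#' The construction follows the constructive existence proof:
#' \eqn{\epsilon_1 = k_6/k_5}, \eqn{\epsilon_2 = k_4/k_5},
#' \eqn{\epsilon_4 = \epsilon_5 = k_1/(2 k_2)}; \eqn{x = 1} (only ratios
#' matter); \eqn{y} is the geometric mean of the open admissible interval
#' for \eqn{y/x},
#' \eqn{\big(k_2 / (4\epsilon_5 (k_4 - k_3/(4\epsilon_4))),\;
#'       (k_1 - k_2\epsilon_5)/(k_3 \epsilon_4)\big)},
#' which is non-empty exactly when \eqn{k_1 k_4 > k_2 k_3};
#' \eqn{z} is half the smaller of its two upper bounds; and, when
#' \eqn{\chi_a > 0}, \eqn{\epsilon_3} is the geometric mean of
#' \eqn{(\chi_a/(4 D_b),\, D_a k_3/(\chi_a k_2))}, non-empty exactly under
#' criterion 2.  The decay-rate bound is the weight-normalised
#' \eqn{M = 2\min(|c_a|/x, |c_b|/y, |c_c|/z)} so that
#' \eqn{d\phi/dt \le -M\phi}.
#'
#' @param lc A `ps_lincoef` satisfying both criteria with \eqn{k_3 > 0}.
#' @return An object of class `ps_certificate` with fields `x`, `y`, `z`,
#'   `eps1`..`eps5` (`eps3 = NA` when `chi_a == 0`), the five coefficients
#'   `coeff_a`, `coeff_b`, `coeff_c`, `coeff_grad_a`, `coeff_grad_b` and
#'   `decay_rate_bound`.
#' @export
construct_certificate <- function(lc) {
  if (!inherits(lc, "ps_lincoef"))
    stop_ps("plaquestab_config_error", "'lc' is not a ps_lincoef")
  if (lc$k1 * lc$k4 <= lc$k2 * lc$k3 || lc$fprime_at_Le <= 0)
    stop_ps("plaquestab_certificate_unavailable",
            "criterion 1 fails: f'(L_e) > 0 (equivalently k1 k4 > k2 k3) is required")
  if (lc$k3 <= 0)
    stop_ps("plaquestab_certificate_unavailable",
            "k3 <= 0: certification requires k3 > 0")
  if (!(lc$chi_a^2 < 4 * lc$D_b * lc$D_a * lc$k3 / lc$k2))
    stop_ps("plaquestab_certificate_unavailable",
            "criterion 2 fails: chi_a^2 < 4 D_b D_a k3 / k2 is required")

  eps1 <- lc$k6 / lc$k5
  eps2 <- lc$k4 / lc$k5
  eps4 <- eps5 <- lc$k1 / (2 * lc$k2)

  x <- 1
  y_hi <- (lc$k1 - lc$k2 * eps5) / (lc$k3 * eps4)
  y_lo <- lc$k2 / (4 * eps5 * (lc$k4 - lc$k3 / (4 * eps4)))
  if (!(y_lo < y_hi))                       # cannot happen if k1k4 > k2k3
    stop_ps("plaquestab_certificate_unavailable",
            "empty admissible interval for y/x (%g, %g)", y_lo, y_hi)
  y <- x * sqrt(y_lo * y_hi)

  z_hi1 <- ((lc$k1 - lc$k2 * eps5) * x - lc$k3 * eps4 * y) / (lc$k6 * eps1)
  z_hi2 <- ((lc$k4 - lc$k3 / (4 * eps4)) * y - lc$k2 / (4 * eps5) * x) /
    (lc$k4 * eps2)
  z <- 0.5 * min(z_hi1, z_hi2)

  eps3 <- NA_real_
  if (lc$chi_a > 0) {
    e3_lo <- lc$chi_a / (4 * lc$D_b)
    e3_hi <- lc$D_a * lc$k3 / (lc$chi_a * lc$k2)
    eps3 <- sqrt(e3_lo * e3_hi)
  }

  cert <- structure(list(
    x = x, y = y, z = z,
    eps1 = eps1, eps2 = eps2, eps3 = eps3, eps4 = eps4, eps5 = eps5
  ), class = "ps_certificate")
  cf <- certificate_coefficients(cert, lc)
  cert[names(cf)] <- cf
  if (!all(unlist(cf) < 0))
    stop_ps("plaquestab_certificate_unavailable",
            "internal: constructed coefficients not all negative")
  cert$decay_rate_bound <- 2 * min(abs(cf$coeff_a) / x,
                                   abs(cf$coeff_b) / y,
                                   abs(cf$coeff_c) / z)
  cert
}

#' @export
print.ps_certificate <- function(x, ...) {
  cat("<ps_certificate>\n")
  cat(sprintf("  weights: x=%g y=%g z=%g\n", x$x, x$y, x$z))
  cat(sprintf("  eps: %g %g %s %g %g\n", x$eps1, x$eps2,
              ifelse(is.na(x$eps3), "NA", format(x$eps3)), x$eps4, x$eps5))
  cat(sprintf("  coefficients: a=%g b=%g c=%g grad_a=%g grad_b=%g\n",
              x$coeff_a, x$coeff_b, x$coeff_c, x$coeff_grad_a,
              x$coeff_grad_b))
  cat(sprintf("  decay rate bound M = %g\n", x$decay_rate_bound))
  invisible(x)
}

#' Verify an energy certificate against coefficients
#'
#' Recomputes the five energy-identity coefficients from the certificate's
#' weights and the supplied linearised coefficients and returns `TRUE` iff
#' all weights (`x`, `y`, `z` and the relevant `eps_i`) are strictly
#' positive and all five coefficients strictly negative.  Never throws on a
#' bad certificate -- it simply returns `FALSE` -- so it can be used as an
#' independent audit of [construct_certificate()] or of a certificate
#' loaded from a file.
#'
#' @param cert A `ps_certificate` (or a bare list with the same weight
#'   fields).
#' @param lc A `ps_lincoef`.
#' @return `TRUE` or `FALSE`.
#' @export
verify_certificate <- function(cert, lc) {
  w <- c(cert$x, cert$y, cert$z, cert$eps1, cert$eps2, cert$eps4, cert$eps5)
  if (lc$chi_a > 0) w <- c(w, cert$eps3)
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) return(FALSE)
  cf <- certificate_coefficients(cert, lc)
  all(unlist(cf) < 0)
}
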