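# Bipolar-coordinate eccentric annulus -----------------------------------
#
# (tau, sigma) with x = d sinh(tau)/(cosh tau - cos sigma),
#                   y = d sin(sigma)/(cosh tau - cos sigma).
# Constant-tau curves are nested non-concentric circles of radius
# d/sinh(tau) centred at (d coth(tau), 0); larger tau means smaller radius.
# The computational domain tau_ext < tau < tau_int is an off-centre annulus
# (a thin intima with intimal thickening on one side).  The metric scale
# factor is h = d/(cosh tau - cos sigma); it is the unique choice for which
# (1/h^2)(d^2/dtau^2 + d^2/dsigma^2) is the Laplacian.

#' Map bipolar to Cartesian coordinates
#'
#' @param tau,sigma Bipolar coordinates (vectors recycled to a common
#'   length).  The map is singular at `tau == 0, sigma == 0 (mod 2*pi)`.
#' @param d Focal half-distance (positive).
#' @return A list with numeric vectors `x` and `y`.
#' @examples
#' bipolar_to_cartesian(1, pi / 2, 1)  # (tanh 1, 1/cosh 1)
#' @export
bipolar_to_cartesian <- function(tau, sigma, d) {
  check_scalar(d, "d", positive = TRUE)
  denom <- cosh(tau) - cos(sigma)
  if (any(denom < .Machine$double.eps))
    stop_ps("plaquestab_domain_error",
            "bipolar map singular at (tau, sigma) = (0, 0) mod 2*pi")
  list(x = d * sinh(tau) / denom, y = d * sin(sigma) / denom)
}

#' Construct a bipolar grid on the eccentric annulus
#'
#' Grid points \eqn{(\tau_i, \sigma_j)} with
#' \eqn{\Delta\tau = (\tau_{int} - \tau_{ext})/(m-1)} (boundary rows on the
#' two circles) and \eqn{\Delta\sigma = 2\pi/n} with periodic wrap
#' \eqn{\sigma_{n+k} = \sigma_k}.  The scale factor
#' \eqn{h_{ij} = d/(\cosh\tau_i - \cos\sigma_j)} is precomputed.
#'
#' @param tau_ext,tau_int Outer and inner coordinate bounds,
#'   `tau_ext < tau_int` (larger tau = smaller circle, so `tau_int` is the
#'   inner boundary).
#' @param m,n Numbers of tau and sigma levels (both at least 4).
#' @param d Focal half-distance (positive).
#' @return An object of class `ps_grid` with fields `d`, `tau_ext`,
#'   `tau_int`, `m`, `n`, `dtau`, `dsigma`, `tau_values`, `sigma_values`
#'   and the `m x n` matrix `h`.
#' @export
bipolar_grid <- function(tau_ext = 1, tau_int = 2, m = 32, n = 32, d = 1) {
  check_scalar(tau_ext, "tau_ext")
  check_scalar(tau_int, "tau_int")
  check_scalar(d, "d", positive = TRUE)
  if (!(tau_ext < tau_int))
    stop_ps("plaquestab_config_error",
            "need tau_ext < tau_int (got %g >= %g)", tau_ext, tau_int)
  if (m < 4 || n < 4)
    stop_ps("plaquestab_config_error", "need m >= 4 and n >= 4")
  m <- as.integer(m); n <- as.integer(n)
  dtau <- (tau_int - tau_ext) / (m - 1)
  dsigma <- 2 * pi / n
  tau_values <- tau_ext + dtau * (seq_len(m) - 1)
  sigma_values <- -pi + dsigma * (seq_len(n) - 1)
  h <- d / (outer(cosh(tau_values), cos(sigma_values), `-`))
  structure(list(d = d, tau_ext = tau_ext, tau_int = tau_int,
                 m = m, n = n, dtau = dtau, dsigma = dsigma,
                 tau_values = tau_values, sigma_values = sigma_values,
                 h = h),
            class = "ps_grid")
}

#' @export
print.ps_grid <- function(x, ...) {
  cat(sprintf(
    "<ps_grid> %d x %d, tau in [%g, %g], d=%g (circles r=%.4g and r=%.4g)\n",
    x$m, x$n, x$tau_ext, x$tau_int, x$d,
    x$d / sinh(x$tau_ext), x$d / sinh(x$tau_int)))
  invisible(x)
}

#' Quadrature weights for grid integrals
#'
#' Metric-weighted cell areas \eqn{h_{ij}^2 \Delta\tau \Delta\sigma} with
#' trapezoid half-weights on the two boundary tau rows (sigma is periodic,
#' so all sigma columns carry full weight).  Their sum converges to the
#' analytic annulus area
#' \eqn{\pi d^2 (1/\sinh^2\tau_{ext} - 1/\sinh^2\tau_{int})}.
#' With `metric = FALSE` the bare coordinate weights
#' \eqn{\Delta\tau \Delta\sigma} are returned instead (the literal
#' "Riemann sum over grid points" reading).
#'
#' @param grid A `ps_grid`.
#' @param metric Include the `h^2` metric factor (default `TRUE`).
#' @return An `m x n` matrix of positive weights.
#' @export
area_weights <- function(grid, metric = TRUE) {
  if (!inherits(grid, "ps_grid"))
    stop_ps("plaquestab_config_error", "'grid' is not a ps_grid")
  w <- if (metric) grid$h^2 * grid$dtau * grid$dsigma
       else matrix(grid$dtau * grid$dsigma, grid$m, grid$n)
  w[1, ] <- w[1, ] / 2
  w[grid$m, ] <- w[grid$m, ] / 2
  w
}

#' Analytic area of the eccentric annulus
#'
#' \eqn{\pi d^2 (1/\sinh^2\tau_{ext} - 1/\sinh^2\tau_{int})}: the area
#' between the two nested circles of radii \eqn{d/\sinh\tau}.
#'
#' @param grid A `ps_grid` (only its bounds and `d` are used).
#' @return Positive scalar area.
#' @export
annulus_area <- function(grid) {
  pi * grid$d^2 * (1 / sinh(grid$tau_ext)^2 - 1 / sinh(grid$tau_int)^2)
}
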