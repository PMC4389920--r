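# Energy diagnostics and validation experiments --------------------------

#' Perturbation specifications
#'
#' Deterministic initial-perturbation generators compatible with the
#' no-flux boundary (zero normal derivative at the two tau rows):
#'
#' * `perturbation_fourier(k_tau, k_sigma)`:
#'   \eqn{\cos(k_\tau \pi (\tau - \tau_{ext})/(\tau_{int}-\tau_{ext}))
#'   \cos(k_\sigma \sigma)}; the cosine tau profile has zero slope at both
#'   walls for any integer mode.
#' * `perturbation_bump(center_tau, center_sigma, width)`: a Gaussian bump
#'   whose tau argument passes through a smoothstep reparameterisation
#'   \eqn{\psi(\tau)} with \eqn{\psi' = 0} at the walls, killing the normal
#'   derivative exactly.
#' * `perturbation_random(seed, k_max)`: a seeded random combination of the
#'   Fourier modes \eqn{0 \le k_\tau, k_\sigma \le k_{max}} (the (0,0) mean
#'   mode included, which is the one excited in the homogeneous-instability
#'   experiments); reproducible from its seed and independent of the
#'   caller's RNG state.
#'
#' @param amplitude Concentration scale of the perturbation.
#' @param k_tau,k_sigma Non-negative integer mode numbers.
#' @param center_tau,center_sigma,width Bump centre and width (width > 0).
#' @param seed Integer seed.
#' @param k_max Highest mode number in the random combination.
#' @param species_mask Logical length-3 vector: which of the three species
#'   are perturbed.
#' @return A `ps_perturbation` specification.
#' @name perturbation
NULL

new_perturbation <- function(pattern, amplitude, params, species_mask) {
  if (!is.logical(species_mask) || length(species_mask) != 3L)
    stop_ps("plaquestab_config_error",
            "species_mask must be logical of length 3")
  structure(list(pattern = pattern,
                 amplitude = check_scalar(amplitude, "amplitude",
                                          nonneg = TRUE),
                 params = params, species_mask = species_mask),
            class = "ps_perturbation")
}

#' @rdname perturbation
#' @export
perturbation_fourier <- function(amplitude, k_tau = 0, k_sigma = 2,
                                 species_mask = c(TRUE, TRUE, TRUE)) {
  if (k_tau < 0 || k_sigma < 0 || k_tau != round(k_tau) ||
        k_sigma != round(k_sigma))
    stop_ps("plaquestab_config_error",
            "mode numbers must be non-negative integers")
  new_perturbation("fourier", amplitude,
                   list(k_tau = as.integer(k_tau),
                        k_sigma = as.integer(k_sigma)), species_mask)
}

#' @rdname perturbation
#' @export
perturbation_bump <- function(amplitude, center_tau, center_sigma,
                              width, species_mask = c(TRUE, TRUE, TRUE)) {
  new_perturbation("bump", amplitude,
                   list(center_tau = check_scalar(center_tau, "center_tau"),
                        center_sigma = check_scalar(center_sigma,
                                                    "center_sigma"),
                        width = check_scalar(width, "width",
                                             positive = TRUE)),
                   species_mask)
}

#' @rdname perturbation
#' @export
perturbation_random <- function(amplitude, seed, k_max = 3,
                                species_mask = c(TRUE, TRUE, TRUE)) {
  new_perturbation("random", amplitude,
                   list(seed = as.integer(seed), k_max = as.integer(k_max)),
                   species_mask)
}

# one boundary-compatible unit pattern on the grid
pattern_matrix <- function(spec, grid) {
  tau <- grid$tau_values; sig <- grid$sigma_values
  s_tau <- (tau - grid$tau_ext) / (grid$tau_int - grid$tau_ext)
  mode_mat <- function(kt, ks)
    outer(cos(kt * pi * s_tau), cos(ks * sig))
  switch(spec$pattern,
    fourier = mode_mat(spec$params$k_tau, spec$params$k_sigma),
    bump = {
      # smoothstep psi has psi'(0) = psi'(1) = 0 => zero normal derivative
      psi <- grid$tau_ext + (grid$tau_int - grid$tau_ext) *
        (3 * s_tau^2 - 2 * s_tau^3)
      dtau2 <- outer((psi - spec$params$center_tau)^2, rep(1, grid$n))
      dsig <- (sig - spec$params$center_sigma + pi) %% (2 * pi) - pi
      dsig2 <- outer(rep(1, grid$m), dsig^2)
      exp(-(dtau2 + dsig2) / (2 * spec$params$width^2))
    },
    random = with_private_seed(spec$params$seed, {
      km <- spec$params$k_max
      P <- matrix(0, grid$m, grid$n)
      for (kt in 0:km) for (ks in 0:km)
        P <- P + rnorm(1) / (1 + kt + ks) * mode_mat(kt, ks)
      P / max(abs(P))
    }),
    stop_ps("plaquestab_config_error", "unknown pattern '%s'", spec$pattern)
  )
}

#' Realise a perturbation on a grid
#'
#' Builds the initial `ps_state` for an experiment.  In linearized mode the
#' perturbation fields themselves are returned; in nonlinear mode they are
#' added to the equilibrium, with a warning when the amplitude exceeds 10%
#' of the smallest equilibrium concentration (the linear-regime guard).
#'
#' @param spec A [perturbation] specification.
#' @param grid A `ps_grid`.
#' @param eq A `ps_equilibrium` (required in nonlinear mode; used only
#'   for the amplitude guard in linearized mode when supplied).
#' @param mode `"linearized"` or `"nonlinear"`.
#' @return A `ps_state`.
#' @export
make_perturbation <- function(spec, grid, eq = NULL,
                              mode = c("linearized", "nonlinear")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "ps_perturbation"))
    stop_ps("plaquestab_config_error", "'spec' is not a ps_perturbation")
  P <- pattern_matrix(spec, grid) * spec$amplitude
  fields <- lapply(1:3, function(s)
    if (spec$species_mask[s]) P else matrix(0, grid$m, grid$n))
  if (mode == "nonlinear") {
    if (is.null(eq))
      stop_ps("plaquestab_config_error",
              "nonlinear perturbations need the equilibrium")
    if (spec$amplitude > 0.1 * min(eq$L_e, eq$M_e, eq$N_e))
      warning("perturbation amplitude exceeds 10% of the equilibrium; ",
              "outside the linear regime")
    state_field(grid, eq$L_e + fields[[1]], eq$M_e + fields[[2]],
                eq$N_e + fields[[3]], mode = "nonlinear")
  } else {
    state_field(grid, fields[[1]], fields[[2]], fields[[3]],
                mode = "linearized")
  }
}

#' Energy integral of a state
#'
#' The squared-perturbation integral
#' \eqn{I = \int (a^2 + b^2 + c^2)\, dA} approximated as a Riemann sum with
#' the metric quadrature weights of [area_weights()].  Nonlinear-mode
#' states are converted to perturbations by subtracting the equilibrium.
#'
#' @param state A `ps_state`.
#' @param eq A `ps_equilibrium` (required for nonlinear-mode states).
#' @param metric Use metric-weighted quadrature (default) or bare
#'   coordinate weights.
#' @return Non-negative scalar.
#' @export
energy_integral <- function(state, eq = NULL, metric = TRUE) {
  p <- perturbation_fields(state, eq)
  w <- area_weights(state$grid, metric = metric)
  sum((p[[1]]^2 + p[[2]]^2 + p[[3]]^2) * w)
}

perturbation_fields <- function(state, eq) {
  if (state$mode == "nonlinear") {
    if (is.null(eq))
      stop_ps("plaquestab_config_error",
              "nonlinear-mode energy needs the equilibrium")
    list(state$L - eq$L_e, state$M - eq$M_e, state$N - eq$N_e)
  } else list(state$a, state$b, state$c)
}

#' Weighted energy functional of a certificate
#'
#' \eqn{\phi = \tfrac12 \int (x a^2 + y b^2 + z c^2)\, dA} with the
#' certificate's species weights; the quantity whose exponential decay the
#' certificate guarantees.
#'
#' @inheritParams energy_integral
#' @param cert A `ps_certificate`.
#' @return Non-negative scalar.
#' @export
weighted_functional <- function(state, cert, eq = NULL, metric = TRUE) {
  p <- perturbation_fields(state, eq)
  w <- area_weights(state$grid, metric = metric)
  0.5 * sum((cert$x * p[[1]]^2 + cert$y * p[[2]]^2 + cert$z * p[[3]]^2) * w)
}

classify_energy <- function(times, I) {
  if (I[1] <= 0) return("stable")          # nothing to decay
  nI <- length(I)
  if (I[nI] > 10 * I[1]) return("unstable")
  if (I[nI] < 1e-3 * I[1]) return("stable")
  tail_ix <- which(times >= times[nI] - 0.1 * (times[nI] - times[1]))
  if (length(tail_ix) >= 2) {
    tail_vals <- I[tail_ix]
    rel_change <- (max(tail_vals) - min(tail_vals)) /
      max(max(abs(tail_vals)), 1e-300)
    if (rel_change < 1e-4 && all(I <= 2 * I[1])) return("stable")
  }
  "inconclusive"
}

#' Run a perturbation experiment
#'
#' End-to-end driver: equilibrium, linearisation, stability report,
#' initial perturbation, time integration, and energy time series with a
#' stable/unstable classification.  This is the numerical replication of
#' the criteria: runs satisfying both stability criteria decay
#' (\eqn{I(t_{end}) < 10^{-3} I(0)} or plateau), runs with a negative
#' response slope grow (\eqn{I(t_{end}) > 10 I(0)}).
#'
#' @param params A `ps_model`.
#' @param spec A [perturbation] specification.
#' @param t_end Final time.
#' @param grid A `ps_grid`.
#' @param mode `"linearized"` or `"nonlinear"`.
#' @param output_times Optional output times (default 25 equispaced).
#' @param rtol,atol Solver tolerances.
#' @param div_mode Boundary divergence form.
#' @param metric Quadrature choice for the energy integrals.
#' @return An object of class `ps_energy_series`: `times`, `I_values`,
#'   `phi_values` (`NA` when no certificate exists), `classification`,
#'   plus the `stability` report, `equilibrium` and the `trajectory`.
#' @export
run_experiment <- function(params, spec, t_end, grid,
                           mode = c("linearized", "nonlinear"),
                           output_times = NULL, rtol = 1e-8, atol = 1e-10,
                           div_mode = "faithful", metric = TRUE) {
  mode <- match.arg(mode)
  eq <- compute_equilibrium(params)
  lc <- linearize(params, eq)
  report <- check_criteria(lc)
  if (is.null(output_times))
    output_times <- seq(0, t_end, length.out = 25)
  state0 <- make_perturbation(spec, grid, eq, mode = mode)
  model <- if (mode == "linearized") lc else params
  traj <- mol_integrate(state0, model, t_end, output_times,
                        rtol = rtol, atol = atol, div_mode = div_mode)
  I <- vapply(traj$states, energy_integral, 0, eq = eq, metric = metric)
  phi <- if (!is.null(report$certificate))
    vapply(traj$states, weighted_functional, 0, cert = report$certificate,
           eq = eq, metric = metric)
  else rep(NA_real_, length(I))
  structure(list(times = traj$times, I_values = I, phi_values = phi,
                 classification = classify_energy(traj$times, I),
                 stability = report, equilibrium = eq, lincoef = lc,
                 trajectory = traj),
            class = "ps_energy_series")
}

#' @export
print.ps_energy_series <- function(x, ...) {
  cat(sprintf(
    "<ps_energy_series> %d points, I(0)=%.4g, I(end)=%.4g -> %s\n",
    length(x$times), x$I_values[1], x$I_values[length(x$I_values)],
    x$classification))
  invisible(x)
}

#' Check the certified exponential decay bound on a simulation
#'
#' Returns `TRUE` iff
#' \eqn{\phi(t) \le 1.05\, \phi(0) e^{-M t}} at every output time, where
#' `M` is the certificate's decay-rate bound.  The 5% slack absorbs
#' quadrature and integration error; the bound itself is analytic.
#'
#' @param series A `ps_energy_series` with `phi_values` present.
#' @param cert The `ps_certificate` (defaults to the one embedded in the
#'   series' stability report).
#' @return `TRUE` or `FALSE`.
#' @export
check_decay_bound <- function(series, cert = series$stability$certificate) {
  if (is.null(cert) || anyNA(series$phi_values))
    stop_ps("plaquestab_config_error",
            "series has no weighted functional values")
  phi0 <- series$phi_values[1]
  if (!(phi0 > 0)) return(all(series$phi_values <= 0 + 1e-300))
  M <- cert$decay_rate_bound
  all(series$phi_values <=
        1.05 * phi0 * exp(-M * (series$times - series$times[1])))
}
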