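# Physical model: parameters, homogeneous equilibrium, linearisation -----
#
# Species: L = oxidised LDL, M = macrophages, N = necrotic lipids.
# Fluxes:  J_L = -D_L grad L,  J_M = mu M grad L - D_M grad M,  J_N = 0
# (macrophages are the only chemotactic species; necrotic lipids immobile).
# Reactions: L + M -> N first order in each reactant; constant LDL influx
# L0; macrophage influx f(L); necrotic clearance at rate k_N.

#' Model parameters for the plaque inflammation system
#'
#' Bundles the physical constants of the three-species
#' reaction--diffusion--chemotaxis system
#' \deqn{L_t = D_L \nabla^2 L - k_L L M + L_0,}
#' \deqn{M_t = D_M \nabla^2 M - \nabla\cdot(\mu M \nabla L) - k_M L M + f(L),}
#' \deqn{N_t = k_M L M - k_N N.}
#'
#' The per-species structure is fixed: only macrophages are chemotactic
#' (\eqn{\mu_L = \mu_N = 0}) and necrotic lipids do not diffuse
#' (\eqn{D_N = 0}); these are not parameters.
#'
#' @param D_L,D_M Diffusion coefficients of ox-LDL and macrophages
#'   (length^2/time), strictly positive.
#' @param mu Chemotactic sensitivity of macrophages toward ox-LDL
#'   (length^2/(time * concentration)), non-negative.
#' @param k_L,k_M Second-order reaction rates removing ox-LDL and macrophages
#'   (1/(time * concentration)), strictly positive.
#' @param k_N Necrotic-lipid clearance rate (1/time), strictly positive.
#' @param L0 Constant ox-LDL influx (concentration/time), strictly positive.
#' @param response A [response] object giving the macrophage influx
#'   \eqn{f(L)}.
#' @return An object of class `ps_model`.
#' @examples
#' mp <- model_parameters(k_L = 1, k_M = 1, k_N = 1, L0 = 1,
#'                        response = response_identity())
#' compute_equilibrium(mp)
#' @export
model_parameters <- function(D_L = 1, D_M = 1, mu = 0,
                             k_L = 1, k_M = 1, k_N = 1, L0 = 1,
                             response = response_logistic(a = 0, b = 2)) {
  if (!inherits(response, "ps_response"))
    stop_ps("plaquestab_config_error", "'response' is not a ps_response")
  obj <- list(
    D_L = check_scalar(D_L, "D_L", positive = TRUE),
    D_M = check_scalar(D_M, "D_M", positive = TRUE),
    mu  = check_scalar(mu, "mu", nonneg = TRUE),
    # zero switches the process off entirely (pure-diffusion configurations);
    # equilibrium computation re-checks strict positivity where it needs it
    k_L = check_scalar(k_L, "k_L", nonneg = TRUE),
    k_M = check_scalar(k_M, "k_M", nonneg = TRUE),
    k_N = check_scalar(k_N, "k_N", nonneg = TRUE),
    L0  = check_scalar(L0, "L0", nonneg = TRUE),
    response = response
  )
  structure(obj, class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat("<ps_model>\n")
  cat(sprintf("  D_L=%g D_M=%g mu=%g | k_L=%g k_M=%g k_N=%g | L0=%g\n",
              x$D_L, x$D_M, x$mu, x$k_L, x$k_M, x$k_N, x$L0))
  cat("  response family:", x$response$family, "\n")
  invisible(x)
}

#' Build a model pinned at a prescribed equilibrium
#'
#' Convenience constructor used throughout the validation experiments: given
#' a target equilibrium \eqn{(L_e, M_e)} and a response slope
#' \eqn{f'(L_e)} of either sign, it sets \eqn{L_0 = k_L L_e M_e} and a
#' pinned response with \eqn{f(L_e) = k_M L_e M_e}, so that
#' [compute_equilibrium()] recovers exactly the requested state.
#'
#' @inheritParams model_parameters
#' @param L_e,M_e Target equilibrium concentrations (positive).
#' @param fprime Target response slope \eqn{f'(L_e)}, any sign.
#' @return A `ps_model`.
#' @export
model_pinned <- function(L_e, M_e, fprime, D_L = 1, D_M = 1, mu = 0,
                         k_L = 1, k_M = 1, k_N = 1) {
  check_scalar(L_e, "L_e", positive = TRUE)
  check_scalar(M_e, "M_e", positive = TRUE)
  L0 <- k_L * L_e * M_e
  rf <- response_pinned(L_star = L_e, value = k_M * L_e * M_e, slope = fprime)
  model_parameters(D_L = D_L, D_M = D_M, mu = mu, k_L = k_L, k_M = k_M,
                   k_N = k_N, L0 = L0, response = rf)
}

#' Spatially homogeneous right-hand side
#'
#' The reaction/source part of the system evaluated at a spatially uniform
#' state; this is the 3-variable ODE system obtained when all gradients
#' vanish.  Used by the equilibrium residual checks and as the reduction
#' target of the homogeneous-initial-data simulator tests.
#'
#' @param params A `ps_model`.
#' @param state Numeric vector `c(L, M, N)` (or a 3-column matrix).
#' @return Numeric vector (or matrix) of time derivatives `c(dL, dM, dN)`.
#' @export
homogeneous_rhs <- function(params, state) {
  if (is.matrix(state)) {
    L <- state[, 1]; M <- state[, 2]; N <- state[, 3]
  } else {
    L <- state[1]; M <- state[2]; N <- state[3]
  }
  fL <- evaluate_response(params$response, L)$value
  dL <- -params$k_L * L * M + params$L0
  dM <- -params$k_M * L * M + fL
  dN <- params$k_M * L * M - params$k_N * N
  if (is.matrix(state)) cbind(dL, dM, dN) else c(dL, dM, dN)
}

# Expanding-bracket + bisection root finder for f(L) = target.
# Derivative-free on purpose: the pinned family need not be monotone
# increasing, and the first bracketed root (scanning upward from ~0) is
# taken.  Bisection is iterated to an interval width of `tol`.
find_response_root <- function(rf, target, tol = 1e-12) {
  g <- function(L) evaluate_response(rf, L)$value - target
  lo <- max(rf$domain[1], .Machine$double.eps)
  glo <- g(lo)
  if (abs(glo) < tol) return(lo)
  # scan upward on a geometric grid to find the first sign change
  hi <- NA_real_
  Lprev <- lo; gprev <- glo
  Lcur <- max(1e-8, lo * 2)
  for (i in 1:220) {
    gcur <- g(Lcur)
    if (is.finite(gcur) && gprev * gcur <= 0) { lo <- Lprev; glo <- gprev; hi <- Lcur; break }
    Lprev <- Lcur; gprev <- gcur
    Lcur <- Lcur * 1.25
    if (Lcur > 1e12) break
  }
  if (is.na(hi))
    stop_ps("plaquestab_equilibrium_error",
            "no root of f(L) = %g found with positive L: the response never
crosses the required macrophage influx (check k_M*L0/k_L against the range of f)",
            target)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    gm <- g(mid)
    if (gm == 0) { lo <- hi <- mid; break }
    if (glo * gm < 0) hi <- mid else { lo <- mid; glo <- gm }
    if ((hi - lo) < tol * max(1, abs(mid))) break
  }
  0.5 * (lo + hi)
}

#' Spatially homogeneous equilibrium
#'
#' Solves \eqn{f(L_e) = k_M L_0 / k_L} for the equilibrium ox-LDL
#' concentration (bracketing search plus bisection; for the pinned family
#' the root is the pin point) and sets
#' \eqn{M_e = L_0/(k_L L_e)}, \eqn{N_e = k_M L_0/(k_L k_N)} -- the unique
#' values making the homogeneous system stationary.
#'
#' @param params A `ps_model`.
#' @param tol Bisection interval tolerance.
#' @return An object of class `ps_equilibrium` with fields `L_e`, `M_e`,
#'   `N_e` (all positive).
#' @export
compute_equilibrium <- function(params, tol = 1e-12) {
  if (!inherits(params, "ps_model"))
    stop_ps("plaquestab_config_error", "'params' is not a ps_model")
  for (nm in c("k_L", "k_M", "k_N", "L0"))
    if (params[[nm]] <= 0)
      stop_ps("plaquestab_equilibrium_error",
              "a positive equilibrium requires %s > 0", nm)
  target <- params$k_M * params$L0 / params$k_L
  rf <- params$response
  if (rf$family == "pinned" && abs(rf$parameters$value - target) <=
        1e-9 * max(1, abs(target))) {
    L_e <- rf$parameters$L_star
  } else {
    L_e <- find_response_root(rf, target, tol = tol)
  }
  if (!is.finite(L_e) || L_e <= 0)
    stop_ps("plaquestab_equilibrium_error",
            "equilibrium root found at non-positive L (%g)", L_e)
  eq <- structure(list(L_e = L_e,
                       M_e = params$L0 / (params$k_L * L_e),
                       N_e = params$k_M * params$L0 / (params$k_L * params$k_N)),
                  class = "ps_equilibrium")
  eq
}

#' @export
print.ps_equilibrium <- function(x, ...) {
  cat(sprintf("<ps_equilibrium> L_e=%.8g M_e=%.8g N_e=%.8g\n",
              x$L_e, x$M_e, x$N_e))
  invisible(x)
}

#' Linearise the system about its homogeneous equilibrium
#'
#' Writing \eqn{L = L_e + a}, \eqn{M = M_e + b}, \eqn{N = N_e + c} and
#' keeping first-order terms yields
#' \deqn{a_t = D_a \nabla^2 a - k_1 a - k_2 b,}
#' \deqn{b_t = D_b \nabla^2 b - \chi_a \nabla^2 a - k_3 a - k_4 b,}
#' \deqn{c_t = k_6 a + k_4 b - k_5 c,}
#' with \eqn{k_1 = k_L M_e}, \eqn{k_2 = k_L L_e},
#' \eqn{k_3 = k_M M_e - f'(L_e)}, \eqn{k_4 = k_M L_e}, \eqn{k_5 = k_N},
#' \eqn{k_6 = k_M M_e}, \eqn{\chi_a = \mu M_e}, \eqn{D_a = D_L},
#' \eqn{D_b = D_M}.  The algebraic identity
#' \eqn{k_1 k_4 - k_2 k_3 = k_L L_e f'(L_e)} ties the ODE spectral
#' criterion to the sign of the response slope.
#'
#' @param params A `ps_model`.
#' @param eq A `ps_equilibrium` consistent with `params`; computed if
#'   missing.
#' @return An object of class `ps_lincoef` with fields `k1`..`k6`, `chi_a`,
#'   `D_a`, `D_b` and `fprime_at_Le`.
#' @export
linearize <- function(params, eq = compute_equilibrium(params)) {
  if (!inherits(eq, "ps_equilibrium"))
    stop_ps("plaquestab_config_error", "'eq' is not a ps_equilibrium")
  fp <- evaluate_response(params$response, eq$L_e)$derivative
  lc <- lin_coefficients(
    k1 = params$k_L * eq$M_e,
    k2 = params$k_L * eq$L_e,
    k3 = params$k_M * eq$M_e - fp,
    k4 = params$k_M * eq$L_e,
    k5 = params$k_N,
    k6 = params$k_M * eq$M_e,
    chi_a = params$mu * eq$M_e,
    D_a = params$D_L,
    D_b = params$D_M,
    fprime_at_Le = fp
  )
  lc
}

#' Linearised coefficient set
#'
#' Direct constructor for the linearised coefficients, used when sweeping
#' coefficient space without an underlying nonlinear model.  `k3` may be of
#' either sign (a very steep response makes it negative); certification
#' rejects non-positive `k3` downstream.
#'
#' @param k1,k2,k4,k5,k6 Positive linearised reaction constants.
#' @param k3 Linearised cross-reaction constant, any sign.
#' @param chi_a Linearised chemotaxis coefficient, non-negative.
#' @param D_a,D_b Positive diffusion coefficients.
#' @param fprime_at_Le Response slope at equilibrium; when omitted it is
#'   recovered from the identity \eqn{f'(L_e) = (k_1 k_4 - k_2 k_3)/k_2}.
#' @return A `ps_lincoef` object.
#' @export
lin_coefficients <- function(k1, k2, k3, k4, k5, k6 = k4, chi_a = 0,
                             D_a = 1, D_b = 1, fprime_at_Le = NULL) {
  lc <- list(
    k1 = check_scalar(k1, "k1", positive = TRUE),
    k2 = check_scalar(k2, "k2", positive = TRUE),
    k3 = check_scalar(k3, "k3"),
    k4 = check_scalar(k4, "k4", positive = TRUE),
    k5 = check_scalar(k5, "k5", positive = TRUE),
    k6 = check_scalar(k6, "k6", positive = TRUE),
    chi_a = check_scalar(chi_a, "chi_a", nonneg = TRUE),
    D_a = check_scalar(D_a, "D_a", positive = TRUE),
    D_b = check_scalar(D_b, "D_b", positive = TRUE)
  )
  lc$fprime_at_Le <- if (is.null(fprime_at_Le))
    (lc$k1 * lc$k4 - lc$k2 * lc$k3) / lc$k2
  else check_scalar(fprime_at_Le, "fprime_at_Le")
  structure(lc, class = "ps_lincoef")
}

#' @export
print.ps_lincoef <- function(x, ...) {
  cat(sprintf(
    "<ps_lincoef> k1=%g k2=%g k3=%g k4=%g k5=%g k6=%g\n  chi_a=%g D_a=%g D_b=%g f'(L_e)=%g\n",
    x$k1, x$k2, x$k3, x$k4, x$k5, x$k6, x$chi_a, x$D_a, x$D_b,
    x$fprime_at_Le))
  invisible(x)
}

#' Reaction Jacobian of the homogeneous (well-mixed) system
#'
#' The 3x3 matrix governing spatially uniform perturbations,
#' \eqn{d(a,b,c)/dt = A (a,b,c)^T}.
#'
#' @param lc A `ps_lincoef`.
#' @return A 3x3 numeric matrix.
#' @export
reaction_matrix <- function(lc) {
  matrix(c(-lc$k1, -lc$k2, 0,
           -lc$k3, -lc$k4, 0,
            lc$k6,  lc$k4, -lc$k5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
}
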