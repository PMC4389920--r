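# Method-of-lines spatial discretisation on the bipolar grid -------------
#
# Interior tau rows (i = 2..m-1) use the centred 5-point Laplacian
#   (1/h^2) [ (f[i+1,j] - 2 f[i,j] + f[i-1,j]) / dtau^2
#           + (f[i,j+1] - 2 f[i,j] + f[i,j-1]) / dsigma^2 ]
# with sigma periodic (index modulo n).  The boundary tau rows use the
# one-sided 3-point divergence of the flux components F (tau) and G
# (sigma), with F = 0 on the boundary row itself encoding no-flux:
#   (1/h) [ (-3 F1 + 4 F2 - F3) / (2 dtau) + (G[j+1] - G[j-1]) / (2 dsigma) ]
# mirrored at row m.  F and G are full flux components (diffusion
# coefficient included; minus the chemotactic part for macrophages).
# div_mode = "consistent" swaps in the full curvilinear divergence
# (1/h^2)(d(hF)/dtau + d(hG)/dsigma); the one-sided form above is the
# default ("faithful").

shift_sig <- function(X, k) {
  n <- ncol(X)
  X[, ((seq_len(n) - 1 + k) %% n) + 1, drop = FALSE]
}

#' Grid fields of the three species
#'
#' Container for the species values on a bipolar grid.  In `"nonlinear"`
#' mode the fields are the concentrations `L`, `M`, `N` (non-negative at
#' t = 0); in `"linearized"` mode they are the perturbations `a`, `b`, `c`
#' about the equilibrium (any sign).
#'
#' @param grid A `ps_grid`.
#' @param f1,f2,f3 `m x n` matrices (scalars are recycled).
#' @param mode `"nonlinear"` or `"linearized"`.
#' @return An object of class `ps_state` with the three matrices under
#'   mode-appropriate names (`L`,`M`,`N` or `a`,`b`,`c`), plus `grid` and
#'   `mode`.
#' @export
state_field <- function(grid, f1 = 0, f2 = 0, f3 = 0,
                        mode = c("nonlinear", "linearized")) {
  mode <- match.arg(mode)
  if (!inherits(grid, "ps_grid"))
    stop_ps("plaquestab_config_error", "'grid' is not a ps_grid")
  as_field <- function(f, nm) {
    if (length(f) == 1L) f <- matrix(f, grid$m, grid$n)
    if (!is.matrix(f) || nrow(f) != grid$m || ncol(f) != grid$n)
      stop_ps("plaquestab_shape_error",
              "field '%s' must be a %d x %d matrix", nm, grid$m, grid$n)
    if (!all(is.finite(f)))
      stop_ps("plaquestab_shape_error", "field '%s' has non-finite values", nm)
    f
  }
  fl <- list(as_field(f1, "f1"), as_field(f2, "f2"), as_field(f3, "f3"))
  nms <- if (mode == "nonlinear") c("L", "M", "N") else c("a", "b", "c")
  if (mode == "nonlinear" && any(vapply(fl, min, 0) < 0))
    warning("nonlinear-mode state has negative concentrations")
  st <- setNames(fl, nms)
  st$grid <- grid
  st$mode <- mode
  structure(st, class = "ps_state")
}

#' @export
print.ps_state <- function(x, ...) {
  nms <- state_names(x)
  rng <- vapply(nms, function(nm) range(x[[nm]]), numeric(2))
  cat(sprintf("<ps_state> %s, %d x %d\n", x$mode, x$grid$m, x$grid$n))
  for (nm in nms)
    cat(sprintf("  %s in [%.4g, %.4g]\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}

state_names <- function(state) {
  if (state$mode == "nonlinear") c("L", "M", "N") else c("a", "b", "c")
}

# stack the three fields into one vector (species-major, column-major grids)
pack_state <- function(state) {
  nms <- state_names(state)
  c(as.vector(state[[nms[1]]]), as.vector(state[[nms[2]]]),
    as.vector(state[[nms[3]]]))
}

unpack_state <- function(u, grid, mode) {
  mn <- grid$m * grid$n
  state_field(grid,
              matrix(u[seq_len(mn)], grid$m, grid$n),
              matrix(u[mn + seq_len(mn)], grid$m, grid$n),
              matrix(u[2 * mn + seq_len(mn)], grid$m, grid$n),
              mode = mode)
}

check_field <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$m || ncol(field) != grid$n)
    stop_ps("plaquestab_shape_error",
            "field must be a %d x %d matrix", grid$m, grid$n)
}

#' Discrete Laplacian on interior tau rows
#'
#' Centred second differences in tau and (periodic) sigma scaled by
#' \eqn{1/h^2}.  Boundary rows are not produced by this operator (they are
#' handled by the one-sided flux scheme, see [boundary_rhs()]) and are
#' returned as `NA`.
#'
#' @param field `m x n` matrix.
#' @param grid A `ps_grid`.
#' @return `m x n` matrix; rows 1 and m are `NA`.
#' @export
laplacian <- function(field, grid) {
  check_field(field, grid)
  m <- grid$m
  out <- matrix(NA_real_, m, grid$n)
  i <- 2:(m - 1)
  d2tau <- (field[i + 1, , drop = FALSE] - 2 * field[i, , drop = FALSE] +
              field[i - 1, , drop = FALSE]) / grid$dtau^2
  fsig <- (shift_sig(field, 1) - 2 * field + shift_sig(field, -1)) /
    grid$dsigma^2
  out[i, ] <- (d2tau + fsig[i, , drop = FALSE]) / grid$h[i, , drop = FALSE]^2
  out
}

#' Dot product of two gradients
#'
#' \eqn{(1/h^2)(\partial_\tau A\, \partial_\tau B +
#' \partial_\sigma A\, \partial_\sigma B)} with centred differences,
#' periodic in sigma; used for the expanded chemotaxis product
#' \eqn{\mu \nabla M \cdot \nabla L}.  Boundary rows are `NA`.
#'
#' @param fieldA,fieldB `m x n` matrices.
#' @param grid A `ps_grid`.
#' @return `m x n` matrix; rows 1 and m are `NA`.
#' @export
gradient_dot <- function(fieldA, fieldB, grid) {
  check_field(fieldA, grid); check_field(fieldB, grid)
  m <- grid$m
  out <- matrix(NA_real_, m, grid$n)
  i <- 2:(m - 1)
  dA_tau <- (fieldA[i + 1, , drop = FALSE] - fieldA[i - 1, , drop = FALSE]) /
    (2 * grid$dtau)
  dB_tau <- (fieldB[i + 1, , drop = FALSE] - fieldB[i - 1, , drop = FALSE]) /
    (2 * grid$dtau)
  dA_sig <- (shift_sig(fieldA, 1) - shift_sig(fieldA, -1)) / (2 * grid$dsigma)
  dB_sig <- (shift_sig(fieldB, 1) - shift_sig(fieldB, -1)) / (2 * grid$dsigma)
  out[i, ] <- (dA_tau * dB_tau +
                 dA_sig[i, , drop = FALSE] * dB_sig[i, , drop = FALSE]) /
    grid$h[i, , drop = FALSE]^2
  out
}

# tau-component of the gradient flux of a scalar potential w:
#   F[i,j] = (w[i+1,j] - w[i-1,j]) / (2 h[i,j] dtau), F = 0 on rows 1, m.
flux_tau <- function(w, grid) {
  m <- grid$m
  F <- matrix(0, m, grid$n)
  i <- 2:(m - 1)
  F[i, ] <- (w[i + 1, , drop = FALSE] - w[i - 1, , drop = FALSE]) /
    (2 * grid$dtau * grid$h[i, , drop = FALSE])
  F
}

# sigma-component (periodic), defined on all rows
flux_sigma <- function(w, grid) {
  (shift_sig(w, 1) - shift_sig(w, -1)) / (2 * grid$dsigma * grid$h)
}

# one-sided boundary divergence of flux components (F, G); returns the two
# boundary rows as a list.  F must already be 0 on rows 1 and m.
divergence_boundary <- function(F, G, grid, div_mode = "faithful") {
  m <- grid$m
  if (div_mode == "consistent") { F <- grid$h * F; G <- grid$h * G }
  scale <- if (div_mode == "consistent") grid$h^2 else grid$h
  dG <- (shift_sig(G, 1) - shift_sig(G, -1)) / (2 * grid$dsigma)
  r1 <- ((-3 * F[1, ] + 4 * F[2, ] - F[3, ]) / (2 * grid$dtau) + dG[1, ]) /
    scale[1, ]
  rm <- ((3 * F[m, ] - 4 * F[m - 1, ] + F[m - 2, ]) / (2 * grid$dtau) +
           dG[m, ]) / scale[m, ]
  list(row1 = r1, rowm = rm)
}

# species flux components for the current state; list of (F, G) per species
species_fluxes <- function(state, model) {
  grid <- state$grid
  if (state$mode == "nonlinear") {
    L <- state$L; M <- state$M
    FL <- model$D_L * flux_tau(L, grid)
    GL <- model$D_L * flux_sigma(L, grid)
    FM <- model$D_M * flux_tau(M, grid) - model$mu * M * flux_tau(L, grid)
    GM <- model$D_M * flux_sigma(M, grid) - model$mu * M * flux_sigma(L, grid)
    FM[c(1, grid$m), ] <- 0                 # total no-flux at the walls
    list(list(F = FL, G = GL), list(F = FM, G = GM),
         list(F = matrix(0, grid$m, grid$n), G = matrix(0, grid$m, grid$n)))
  } else {
    a <- state$a; b <- state$b
    wa <- model$D_a * a
    wb <- model$D_b * b - model$chi_a * a
    list(list(F = flux_tau(wa, grid), G = flux_sigma(wa, grid)),
         list(F = flux_tau(wb, grid), G = flux_sigma(wb, grid)),
         list(F = matrix(0, grid$m, grid$n), G = matrix(0, grid$m, grid$n)))
  }
}

# pointwise reaction/source terms, valid on every row
reaction_terms <- function(state, model) {
  if (state$mode == "nonlinear") {
    L <- state$L; M <- state$M; N <- state$N
    fL <- matrix(evaluate_response(model$response, as.vector(L))$value,
                 state$grid$m, state$grid$n)
    list(-model$k_L * L * M + model$L0,
         -model$k_M * L * M + fL,
         model$k_M * L * M - model$k_N * N)
  } else {
    a <- state$a; b <- state$b; cc <- state$c
    list(-model$k1 * a - model$k2 * b,
         -model$k3 * a - model$k4 * b,
         model$k6 * a + model$k4 * b - model$k5 * cc)
  }
}

#' Boundary rows of the time derivative
#'
#' Applies the one-sided 3-point flux-divergence scheme at the two tau
#' boundary rows (with the flux zero on the boundary row itself) and adds
#' the pointwise reaction and source terms.
#'
#' @param state A `ps_state`.
#' @param model A `ps_model` (nonlinear mode) or `ps_lincoef` (linearized
#'   mode), matching `state$mode`.
#' @param div_mode `"faithful"` (the one-sided form, default) or
#'   `"consistent"` (full curvilinear divergence).
#' @return A list per species, each with vectors `row1` and `rowm` of
#'   length n.
#' @export
boundary_rhs <- function(state, model, div_mode = c("faithful", "consistent")) {
  div_mode <- match.arg(div_mode)
  fluxes <- species_fluxes(state, model)
  reac <- reaction_terms(state, model)
  grid <- state$grid
  out <- vector("list", 3L)
  for (s in 1:3) {
    if (s == 3L) {
      # immobile species: purely pointwise
      out[[s]] <- list(row1 = reac[[s]][1, ], rowm = reac[[s]][grid$m, ])
    } else {
      dv <- divergence_boundary(fluxes[[s]]$F, fluxes[[s]]$G, grid, div_mode)
      out[[s]] <- list(row1 = dv$row1 + reac[[s]][1, ],
                       rowm = dv$rowm + reac[[s]][grid$m, ])
    }
  }
  names(out) <- state_names(state)
  out
}

#' Time derivative of the nonlinear system
#'
#' Interior rows: \eqn{dL/dt = D_L \nabla^2 L - k_L L M + L_0};
#' \eqn{dM/dt = D_M \nabla^2 M - \mu \nabla M \cdot \nabla L -
#' \mu M \nabla^2 L - k_M L M + f(L)} (the expanded chemotaxis product);
#' \eqn{dN/dt = k_M L M - k_N N} pointwise everywhere.  Boundary rows use
#' [boundary_rhs()].
#'
#' @param state A nonlinear-mode `ps_state`.
#' @param params A `ps_model`.
#' @inheritParams boundary_rhs
#' @return A `ps_state`-shaped derivative (same class and mode).
#' @export
rhs_nonlinear <- function(state, params,
                          div_mode = c("faithful", "consistent")) {
  div_mode <- match.arg(div_mode)
  if (state$mode != "nonlinear")
    stop_ps("plaquestab_config_error", "state is not in nonlinear mode")
  if (min(state$L, state$M, state$N) < -1e-8)
    warning("state has concentrations below -1e-8; model leaving its regime")
  grid <- state$grid
  reac <- reaction_terms(state, params)
  lapL <- laplacian(state$L, grid)
  lapM <- laplacian(state$M, grid)
  dL <- params$D_L * lapL + reac[[1]]
  dM <- params$D_M * lapM -
    params$mu * gradient_dot(state$M, state$L, grid) -
    params$mu * state$M * lapL + reac[[2]]
  dN <- reac[[3]]
  bd <- boundary_rhs(state, params, div_mode)
  dL[1, ] <- bd[[1]]$row1; dL[grid$m, ] <- bd[[1]]$rowm
  dM[1, ] <- bd[[2]]$row1; dM[grid$m, ] <- bd[[2]]$rowm
  derivative_field(grid, dL, dM, dN, mode = "nonlinear")
}

# like state_field but for time derivatives: no sign warning
derivative_field <- function(grid, d1, d2, d3, mode) {
  nms <- if (mode == "nonlinear") c("L", "M", "N") else c("a", "b", "c")
  st <- setNames(list(d1, d2, d3), nms)
  st$grid <- grid
  st$mode <- mode
  structure(st, class = "ps_state")
}

#' Time derivative of the linearised system
#'
#' Interior rows follow the linearised equations (see [linearize()]);
#' boundary rows use the same one-sided flux scheme with the linearised
#' fluxes \eqn{F_a = D_a \partial_\tau a / h},
#' \eqn{F_b = (D_b \partial_\tau b - \chi_a \partial_\tau a)/h}.
#'
#' @param state A linearized-mode `ps_state`.
#' @param lc A `ps_lincoef`.
#' @inheritParams boundary_rhs
#' @return A `ps_state`-shaped derivative.
#' @export
rhs_linearized <- function(state, lc,
                           div_mode = c("faithful", "consistent")) {
  div_mode <- match.arg(div_mode)
  if (state$mode != "linearized")
    stop_ps("plaquestab_config_error", "state is not in linearized mode")
  grid <- state$grid
  reac <- reaction_terms(state, lc)
  wa <- lc$D_a * state$a
  wb <- lc$D_b * state$b - lc$chi_a * state$a
  da <- laplacian(wa, grid) + reac[[1]]
  db <- laplacian(wb, grid) + reac[[2]]
  dc <- reac[[3]]
  bd <- boundary_rhs(state, lc, div_mode)
  da[1, ] <- bd[[1]]$row1; da[grid$m, ] <- bd[[1]]$rowm
  db[1, ] <- bd[[2]]$row1; db[grid$m, ] <- bd[[2]]$rowm
  derivative_field(grid, da, db, dc, mode = "linearized")
}
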