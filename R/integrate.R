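# Time integration -------------------------------------------------------
#
# The semi-discrete method-of-lines system is stiff (the diffusion spectrum
# scales like 1/(h dtau)^2), so the workhorse is TR-BDF2: the one-step,
# L-stable composite of a trapezoidal half-step and a BDF2 step
# (gamma = 2 - sqrt(2)), with the classical embedded error estimate passed
# through (I - d*dt*J)^{-1} for stiff damping, and a step-size controller
# that quantises dt changes so sparse LU factorisations are reused.  For
# the linearised system the stage equations are solved exactly (one sparse
# solve); for the nonlinear system a simplified Newton iteration with a
# coloured finite-difference Jacobian is used.
#
# An independently coded explicit Dormand-Prince RK45 (reference_rk45) is
# shipped for small non-stiff oracle problems, e.g. the homogeneous
# 3-variable reduction; it shares no code with the implicit path.

TRBDF2_GAMMA <- 2 - sqrt(2)
TRBDF2_D <- 1 - sqrt(2) / 2              # gamma / 2
TRBDF2_W <- sqrt(2) / 4
# b - bhat for the embedded 1st-order error estimate
TRBDF2_E <- c((sqrt(2) - 1) / 3, -1 / 3, (2 - sqrt(2)) / 3)

# adaptive TR-BDF2 on u' = f(u); returns matrix of states at output_times.
# f:     function(u) -> du
# jfun:  function(u) -> sparse Jacobian (constant matrix allowed via
#        linear = TRUE, in which case jfun IS the matrix and stages are
#        solved without Newton)
trbdf2 <- function(f, u0, output_times, jfun, linear = FALSE,
                   rtol = 1e-8, atol = 1e-10, dt0 = NULL,
                   max_steps = 200000L) {
  stopifnot(all(diff(output_times) > 0), output_times[1] >= 0)
  nu <- length(u0)
  out <- matrix(NA_real_, nrow = nu, ncol = length(output_times))
  t <- 0
  u <- u0
  if (output_times[1] == 0) out[, 1] <- u
  next_out <- if (output_times[1] == 0) 2L else 1L
  t_final <- output_times[length(output_times)]
  if (next_out > length(output_times)) return(out)

  J <- if (linear) jfun else jfun(u)
  fac_env <- new.env(parent = emptyenv())
  fac_env$dt <- NA_real_
  get_fact <- function(dt) {
    if (!identical(fac_env$dt, dt)) {
      n <- nrow(J)
      fac_env$fact <- Matrix::lu(Matrix::Diagonal(n) - (TRBDF2_D * dt) * J)
      fac_env$dt <- dt
    }
    fac_env$fact
  }
  stage_solve <- function(rhs, dt, pred) {
    fct <- get_fact(dt)
    if (linear) return(list(u = as.numeric(Matrix::solve(fct, rhs)), ok = TRUE))
    v <- pred
    for (it in 1:12) {
      res <- rhs + TRBDF2_D * dt * f(v) - v
      dv <- as.numeric(Matrix::solve(fct, res))
      v <- v + dv
      nrm <- sqrt(mean((dv / (atol + rtol * pmax(abs(v), abs(u))))^2))
      if (!is.finite(nrm)) return(list(ok = FALSE))
      if (nrm < 0.03) return(list(u = v, ok = TRUE))
    }
    list(ok = FALSE)
  }

  fu <- f(u)
  dt <- dt0 %||% min(1e-4, t_final / 10)
  steps <- 0L; rejects <- 0L; jac_age <- 0L
  while (t < t_final - 1e-14 * max(1, t_final)) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop_ps("plaquestab_solver_error",
              "TR-BDF2 exceeded %d steps at t = %g (dt = %g)",
              max_steps, t, dt)
    dt_eff <- min(dt, output_times[next_out] - t)
    s2 <- stage_solve(u + TRBDF2_D * dt_eff * fu, dt_eff,
                      u + TRBDF2_GAMMA * dt_eff * fu)
    if (s2$ok) {
      f2 <- f(s2$u)
      s3 <- stage_solve(u + dt_eff * TRBDF2_W * (fu + f2), dt_eff, s2$u)
    }
    if (!s2$ok || !s3$ok) {
      # Newton failure: refresh Jacobian once, then shrink the step
      if (!linear && jac_age > 0L) {
        J <- jfun(u); jac_age <- 0L; fac_env$dt <- NA_real_
      } else {
        dt <- dt / 4
        if (dt < 1e-14 * max(1, t_final))
          stop_ps("plaquestab_solver_error",
                  "step size underflow at t = %g", t)
      }
      rejects <- rejects + 1L
      next
    }
    f3 <- f(s3$u)
    est <- dt_eff * (TRBDF2_E[1] * fu + TRBDF2_E[2] * f2 + TRBDF2_E[3] * f3)
    est <- as.numeric(Matrix::solve(get_fact(dt_eff), est))
    errnorm <- sqrt(mean((est / (atol + rtol *
                                   pmax(abs(u), abs(s3$u))))^2))
    if (!is.finite(errnorm)) errnorm <- 2
    if (errnorm <= 1) {
      t <- t + dt_eff
      u <- s3$u
      fu <- f3
      jac_age <- jac_age + 1L
      while (next_out <= length(output_times) &&
             t >= output_times[next_out] - 1e-12 * max(1, t_final)) {
        out[, next_out] <- u
        next_out <- next_out + 1L
      }
      if (next_out > length(output_times)) break
      fac <- min(4, max(0.25, 0.9 * errnorm^(-1/3)))
      if (fac > 1.3 || fac < 0.9) dt <- dt * fac   # quantised: reuse LU
    } else {
      rejects <- rejects + 1L
      dt <- dt * max(0.2, min(0.9, 0.9 * errnorm^(-1/3)))
      if (!linear && jac_age > 3L) {
        J <- jfun(u); jac_age <- 0L; fac_env$dt <- NA_real_
      }
    }
  }
  attr(out, "stats") <- list(steps = steps, rejects = rejects)
  out
}

#' Reference explicit Runge-Kutta integrator (Dormand-Prince 5(4))
#'
#' A small, self-contained adaptive explicit integrator for non-stiff
#' oracle problems such as the homogeneous 3-variable reduction of the
#' model.  It deliberately shares no code with the implicit
#' method-of-lines path so the two can cross-validate each other.
#'
#' @param f Function `f(t, y)` returning `dy`.
#' @param y0 Initial state vector.
#' @param times Increasing output times, starting at the initial time.
#' @param rtol,atol Relative/absolute tolerances.
#' @return Matrix with `length(y0)` rows, one column per output time.
#' @export
reference_rk45 <- function(f, y0, times, rtol = 1e-9, atol = 1e-12) {
  A <- list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
  )
  cs <- c(1/5, 3/10, 4/5, 8/9, 1, 1)
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  t <- times[1]; y <- y0
  out <- matrix(NA_real_, length(y0), length(times))
  out[, 1] <- y0
  k <- vector("list", 7)
  dt <- diff(range(times)) / 100
  for (m in 2:length(times)) {
    t_target <- times[m]
    while (t < t_target - 1e-14 * max(1, abs(t_target))) {
      dt_eff <- min(dt, t_target - t)
      k[[1]] <- f(t, y)
      for (s in 1:6) {
        ys <- y + dt_eff * Reduce(`+`, Map(`*`, A[[s]], k[seq_len(s)]))
        k[[s + 1]] <- f(t + cs[s] * dt_eff, ys)
      }
      y5 <- y + dt_eff * Reduce(`+`, Map(`*`, b5, k))
      y4 <- y + dt_eff * Reduce(`+`, Map(`*`, b4, k))
      err <- sqrt(mean(((y5 - y4) /
                          (atol + rtol * pmax(abs(y), abs(y5))))^2))
      if (!is.finite(err)) err <- 2
      if (err <= 1) {
        t <- t + dt_eff; y <- y5
        dt <- dt_eff * min(5, max(0.2, 0.9 * err^(-1/5)))
      } else {
        dt <- dt_eff * max(0.1, 0.9 * err^(-1/5))
        if (dt < 1e-14 * max(1, abs(t_target)))
          stop_ps("plaquestab_solver_error", "RK45 step underflow")
      }
    }
    out[, m] <- y
  }
  out
}

#' Integrate the method-of-lines system
#'
#' Advances a spatial state in time with the adaptive L-stable TR-BDF2
#' integrator.  In linearized mode the stacked system `u' = A u` is built
#' once as a sparse matrix and each implicit stage is a cached sparse LU
#' solve; in nonlinear mode a simplified Newton iteration with a coloured
#' finite-difference Jacobian is used.  The result is deterministic for
#' given inputs (no randomness enters the solver).
#'
#' @param state0 Initial `ps_state` (mode decides the equations).
#' @param model A `ps_model` (nonlinear) or `ps_lincoef` (linearized),
#'   matching `state0$mode`.
#' @param t_end Final time (positive).
#' @param output_times Increasing times in `[0, t_end]` at which to store
#'   states; defaults to 11 equispaced times including 0 and `t_end`.
#' @param rtol,atol Solver tolerances.
#' @param div_mode Boundary divergence form, see [boundary_rhs()].
#' @return An object of class `ps_trajectory`: list with `times`, `states`
#'   (list of `ps_state`), `mode` and solver `stats`.
#' @export
mol_integrate <- function(state0, model, t_end, output_times = NULL,
                          rtol = 1e-8, atol = 1e-10,
                          div_mode = c("faithful", "consistent")) {
  div_mode <- match.arg(div_mode)
  if (!inherits(state0, "ps_state"))
    stop_ps("plaquestab_config_error", "'state0' is not a ps_state")
  check_scalar(t_end, "t_end", positive = TRUE)
  if (is.null(output_times))
    output_times <- seq(0, t_end, length.out = 11)
  output_times <- sort(unique(c(output_times)))
  if (output_times[1] < 0 || output_times[length(output_times)] > t_end + 1e-12)
    stop_ps("plaquestab_config_error", "output_times must lie in [0, t_end]")
  grid <- state0$grid
  u0 <- pack_state(state0)
  linear <- state0$mode == "linearized"
  if (linear) {
    if (!inherits(model, "ps_lincoef"))
      stop_ps("plaquestab_config_error",
              "linearized state needs a ps_lincoef model")
    A <- linearized_system_matrix(model, grid, div_mode)
    fvec <- function(u) as.numeric(A %*% u)
    sol <- trbdf2(fvec, u0, output_times, jfun = A, linear = TRUE,
                  rtol = rtol, atol = atol)
  } else {
    if (!inherits(model, "ps_model"))
      stop_ps("plaquestab_config_error",
              "nonlinear state needs a ps_model")
    fvec <- function(u) {
      st <- unpack_state(u, grid, "nonlinear")
      pack_state(rhs_nonlinear(st, model, div_mode))
    }
    jfun <- function(u) nonlinear_jacobian(fvec, u, fvec(u), grid$m, grid$n)
    sol <- trbdf2(fvec, u0, output_times, jfun = jfun, linear = FALSE,
                  rtol = rtol, atol = atol)
  }
  states <- lapply(seq_along(output_times), function(k)
    unpack_state(sol[, k], grid, state0$mode))
  structure(list(times = output_times, states = states, mode = state0$mode,
                 stats = attr(sol, "stats")),
            class = "ps_trajectory")
}

#' @export
print.ps_trajectory <- function(x, ...) {
  cat(sprintf("<ps_trajectory> %s mode, %d snapshots, t in [%g, %g]\n",
              x$mode, length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$stats))
    cat(sprintf("  solver: %d steps, %d rejects\n",
                x$stats$steps, x$stats$rejects))
  invisible(x)
}
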