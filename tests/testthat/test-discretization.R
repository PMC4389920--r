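# discretization: stencils, fluxes, boundary scheme, right-hand sides

test_that("laplacian stencil is exact on its algebraic special cases", {
  g <- small_grid(10, 12)
  i <- 2:(g$m - 1)
  # constants are annihilated
  L <- laplacian(matrix(3.7, g$m, g$n), g)
  expect_close(L[i, ], 0, 1e-13)
  # f = tau^2: centred difference exact on quadratics -> 2/h^2
  L <- laplacian(outer(g$tau_values^2, rep(1, g$n)), g)
  expect_close(L[i, ], 2 / g$h[i, ]^2, 1e-10)
  # f = cos sigma: discrete symbol cos(sigma) (2 cos(dsigma) - 2)/dsigma^2
  f <- outer(rep(1, g$m), cos(g$sigma_values))
  L <- laplacian(f, g)
  sym <- (2 * cos(g$dsigma) - 2) / g$dsigma^2
  expect_close(L[i, ], f[i, ] * sym / g$h[i, ]^2, 1e-10)
  expect_true(all(is.na(L[c(1, g$m), ])))
  expect_error(laplacian(matrix(0, 3, 3), g),
               class = "plaquestab_shape_error")
})

test_that("gradient_dot matches its stencil algebra", {
  g <- small_grid(10, 12)
  i <- 2:(g$m - 1)
  set.seed(5)
  A <- matrix(rnorm(g$m * g$n), g$m)
  # constant second factor -> zero
  expect_close(gradient_dot(A, matrix(2, g$m, g$n), g)[i, ], 0, 1e-13)
  # A = B -> squared gradient norm, non-negative
  expect_true(all(gradient_dot(A, A, g)[i, ] >= 0))
  # A = B = tau: exact centred derivative 1 -> 1/h^2
  Tau <- outer(g$tau_values, rep(1, g$n))
  expect_close(gradient_dot(Tau, Tau, g)[i, ], 1 / g$h[i, ]^2, 1e-12)
})

test_that("observed laplacian convergence order lies in [1.8, 2.2]", {
  errs <- vapply(c(16, 32, 64), function(mm) {
    g <- bipolar_grid(1, 2, mm, mm, 1)
    u <- outer(sin(g$tau_values), cos(2 * g$sigma_values))
    truth <- (outer(-sin(g$tau_values), cos(2 * g$sigma_values)) +
                outer(sin(g$tau_values), -4 * cos(2 * g$sigma_values))) /
      g$h^2
    i <- 2:(mm - 1)
    max(abs(laplacian(u, g)[i, ] - truth[i, ]))
  }, 0)
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders > 1.8 & orders < 2.2))
})

test_that("boundary scheme: no-flux rows, stencil exactness, conservation", {
  g <- small_grid(10, 12)
  set.seed(6)
  w <- matrix(rnorm(g$m * g$n), g$m)
  # flux tau-component is identically zero on both boundary rows
  F <- plaquestab:::flux_tau(w, g)
  expect_true(all(F[c(1, g$m), ] == 0))

  # one-sided 3-point formula is exact for flux quadratic in tau
  alpha <- 0.7; beta <- -0.4
  Fq <- outer((g$tau_values - g$tau_ext) *
                (alpha + beta * g$tau_values), rep(1, g$n))
  Fq[g$m, ] <- 0   # formal: row m not used for the row-1 check
  dv <- plaquestab:::divergence_boundary(Fq, matrix(0, g$m, g$n), g)
  exact_row1 <- (alpha + beta * g$tau_ext) / g$h[1, ]
  expect_close(dv$row1, exact_row1, 1e-10)

  # uniform equilibrium state: boundary derivative vanishes
  m <- model_pinned(L_e = 1.2, M_e = 0.9, fprime = 0.3, mu = 0.4)
  eq <- compute_equilibrium(m)
  st <- state_field(g, eq$L_e, eq$M_e, eq$N_e, mode = "nonlinear")
  bd <- boundary_rhs(st, m)
  for (s in 1:3)
    expect_close(c(bd[[s]]$row1, bd[[s]]$rowm), 0, 1e-10)

  # pure diffusion, tau-symmetric bump: metric-weighted mass drift per unit
  # time < 1e-6 of total mass at m = n = 64, and shrinks under refinement
  drift <- vapply(c(32, 64), function(mm) {
    gg <- bipolar_grid(1, 2, mm, mm, 1)
    m0 <- model_parameters(D_L = 1, D_M = 1, mu = 0, k_L = 0, k_M = 0,
                           k_N = 0, L0 = 0, response = response_identity())
    prof <- outer(1 + cos(pi * (gg$tau_values - gg$tau_ext) /
                            (gg$tau_int - gg$tau_ext)), rep(1, gg$n))
    stt <- state_field(gg, prof, prof, 0 * prof, mode = "nonlinear")
    d <- rhs_nonlinear(stt, m0)
    ww <- area_weights(gg)
    abs(sum(d$L * ww)) / sum(stt$L * ww)
  }, 0)
  expect_lt(drift[2], 1e-6)
  expect_lt(drift[2], drift[1])
})

test_that("nonlinear rhs reduces to the homogeneous ODE on uniform states", {
  g <- small_grid()
  m <- model_pinned(L_e = 1, M_e = 1, fprime = 0.5, mu = 0.3)
  eq <- compute_equilibrium(m)
  st <- state_field(g, eq$L_e, eq$M_e, eq$N_e, mode = "nonlinear")
  d <- rhs_nonlinear(st, m)
  expect_close(c(d$L, d$M, d$N), 0, 1e-10)
  # off-equilibrium uniform state: identical across grid points and equal
  # to the homogeneous right-hand side
  st2 <- state_field(g, 2 * eq$L_e, eq$M_e, eq$N_e, mode = "nonlinear")
  d2 <- rhs_nonlinear(st2, m)
  hom <- homogeneous_rhs(m, c(2 * eq$L_e, eq$M_e, eq$N_e))
  expect_close(d2$L, hom[1], 1e-11)
  expect_close(d2$M, hom[2], 1e-11)
  expect_close(d2$N, hom[3], 1e-11)
})

test_that("linearised rhs: homogeneous reduction and structure", {
  g <- small_grid()
  lc <- lin_coefficients(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
                         chi_a = 0.5, D_a = 1, D_b = 1, fprime_at_Le = 1)
  st <- state_field(g, 0.3, -0.2, 0.1, mode = "linearized")
  d <- rhs_linearized(st, lc)
  expected <- as.numeric(reaction_matrix(lc) %*% c(0.3, -0.2, 0.1))
  expect_close(d$a, expected[1], 1e-11)
  expect_close(d$b, expected[2], 1e-11)
  expect_close(d$c, expected[3], 1e-11)
  # a == 0 kills chemotaxis and k3 coupling in the b equation
  set.seed(7)
  b <- matrix(rnorm(g$m * g$n), g$m)
  st0 <- state_field(g, 0, b, 0, mode = "linearized")
  d0 <- rhs_linearized(st0, lc)
  lc_nochem <- lc; lc_nochem$chi_a <- 0; lc_nochem$k3 <- 1e-9
  d0b <- rhs_linearized(st0, lc_nochem)
  expect_close(d0$b, d0b$b, 1e-12)
})

test_that("linearised rhs is the Frechet derivative of the nonlinear rhs", {
  set.seed(42)
  for (mm in c(8, 12, 16)) {
    g <- bipolar_grid(1, 2, mm, mm, 1)
    m <- model_pinned(L_e = 1.3, M_e = 0.8, fprime = 0.4,
                      D_L = 1.2, D_M = 0.9, mu = 0.5)
    eq <- compute_equilibrium(m)
    lc <- linearize(m, eq)
    p <- state_field(g, matrix(rnorm(mm * mm), mm), matrix(rnorm(mm * mm), mm),
                     matrix(rnorm(mm * mm), mm), mode = "linearized")
    lin <- rhs_linearized(p, lc)
    err <- vapply(c(1e-4, 1e-5), function(eps) {
      stp <- state_field(g, eq$L_e + eps * p$a, eq$M_e + eps * p$b,
                         eq$N_e + eps * p$c, mode = "nonlinear")
      nl <- rhs_nonlinear(stp, m)
      max(abs(nl$L / eps - lin$a), abs(nl$M / eps - lin$b),
          abs(nl$N / eps - lin$c))
    }, 0)
    # error is O(eps): one decade of eps gains one decade of accuracy
    expect_lt(err[2], err[1] / 5)
    expect_lt(err[2], 1e-3 * max(abs(lin$a), abs(lin$b)))
  }
})

test_that("sparse operator assembly agrees with the field-level rhs", {
  g <- small_grid(9, 10)
  lc <- lin_coefficients(k1 = 1.5, k2 = 0.8, k3 = 0.6, k4 = 2, k5 = 1.1,
                         k6 = 2, chi_a = 0.7, D_a = 1.3, D_b = 0.9,
                         fprime_at_Le = 1)
  for (dm in c("faithful", "consistent")) {
    A <- linearized_system_matrix(lc, g, div_mode = dm)
    set.seed(8)
    u <- rnorm(3 * g$m * g$n)
    st <- plaquestab:::unpack_state(u, g, "linearized")
    r <- plaquestab:::pack_state(rhs_linearized(st, lc, div_mode = dm))
    expect_close(as.numeric(A %*% u), r, 1e-10)
  }
})
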