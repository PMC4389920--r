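# diagnostics: perturbations, energy integrals, classification, decay bound

test_that("perturbation patterns are boundary-compatible and reproducible", {
  g <- small_grid(16, 16)
  # fourier(0, 2): tau-uniform, proportional to cos(2 sigma)
  st <- make_perturbation(perturbation_fourier(0.5, 0, 2), g)
  expect_close(st$a, 0.5 * outer(rep(1, g$m), cos(2 * g$sigma_values)),
               1e-13)
  expect_close(st$a[1, ] - st$a[2, ], 0, 1e-13)     # zero normal derivative
  # every pattern family: one-sided derivative at both walls -> 0 as the
  # grid refines (the patterns are built with exactly zero normal slope)
  for (spec in list(perturbation_fourier(1, 2, 1),
                    perturbation_bump(1, 1.4, 0.5, 0.3),
                    perturbation_random(1, seed = 9))) {
    P <- plaquestab:::pattern_matrix(spec, bipolar_grid(1, 2, 128, 16, 1))
    slope1 <- max(abs(-3 * P[1, ] + 4 * P[2, ] - P[3, ]))
    slopem <- max(abs(3 * P[128, ] - 4 * P[127, ] + P[126, ]))
    expect_lt(max(slope1, slopem) / max(abs(P)), 1e-3)
  }
  # reproducibility and RNG hygiene
  s1 <- make_perturbation(perturbation_random(0.3, seed = 4), g)
  set.seed(999); before <- rnorm(1)
  s2 <- make_perturbation(perturbation_random(0.3, seed = 4), g)
  expect_identical(s1$a, s2$a)
  # amplitude 0 -> equilibrium exactly (nonlinear mode)
  eq <- compute_equilibrium(model_pinned(1, 1, 0.5))
  s0 <- make_perturbation(perturbation_fourier(0, 0, 2), g, eq,
                          mode = "nonlinear")
  expect_true(all(s0$L == eq$L_e) && all(s0$M == eq$M_e))
  # amplitude guard in nonlinear mode
  expect_warning(
    make_perturbation(perturbation_fourier(0.5, 0, 2), g, eq,
                      mode = "nonlinear"),
    "amplitude")
})

test_that("energy integral is the metric-weighted quadratic form", {
  g <- small_grid(24, 24)
  zero <- state_field(g, 0, 0, 0, mode = "linearized")
  expect_equal(energy_integral(zero), 0)
  # a == 1 -> domain area (converging to the analytic value)
  one <- state_field(g, 1, 0, 0, mode = "linearized")
  expect_lt(abs(energy_integral(one) - annulus_area(g)) / annulus_area(g),
            5e-3)
  # quadratic scaling
  set.seed(10)
  st <- make_perturbation(perturbation_random(0.2, seed = 12), g)
  st2 <- state_field(g, 2 * st$a, 2 * st$b, 2 * st$c, mode = "linearized")
  expect_lt(abs(energy_integral(st2) - 4 * energy_integral(st)), 1e-12)
  # weighted functional: x = y = z = 2 on unit fields -> 3 * area;
  # phi = x I / 2 when all weights equal and all species perturbed equally
  cert <- structure(list(x = 2, y = 2, z = 2), class = "ps_certificate")
  ones <- state_field(g, 1, 1, 1, mode = "linearized")
  expect_equal(weighted_functional(ones, cert),
               3 * sum(area_weights(g)))
  expect_equal(weighted_functional(st, cert), 0.5 * 2 * energy_integral(st))
  # nonlinear states are measured as deviations from equilibrium
  eq <- compute_equilibrium(model_pinned(1, 1, 0.5))
  stn <- state_field(g, eq$L_e + st$a, eq$M_e + st$b, eq$N_e + st$c,
                     mode = "nonlinear")
  expect_lt(abs(energy_integral(stn, eq) - energy_integral(st)), 1e-12)
})

test_that("experiments classify by criteria and honor the decay bound", {
  g <- bipolar_grid(1, 2, 16, 16, 1)
  set.seed(21)
  sm <- sample_model_with_rate(stable = TRUE, mu_frac = 0.5)
  m <- sm$model
  series <- run_experiment(m, perturbation_random(0.01, seed = 2),
                           t_end = min(7 / sm$rate, 60), grid = g,
                           rtol = 1e-6, atol = 1e-9)
  expect_true(series$stability$criterion1 && series$stability$criterion2)
  expect_equal(series$classification, "stable")
  expect_true(check_decay_bound(series))
  # certificate soundness across distinct perturbation shapes
  for (spec in list(perturbation_fourier(0.01, 0, 0),
                    perturbation_fourier(0.01, 1, 3),
                    perturbation_bump(0.01, 1.5, 1, 0.4),
                    perturbation_random(0.01, seed = 5),
                    perturbation_random(0.01, seed = 6,
                                        species_mask = c(TRUE, FALSE, TRUE)))) {
    s <- run_experiment(m, spec, t_end = 6, grid = g,
                        output_times = seq(0, 6, length.out = 7),
                        rtol = 1e-6, atol = 1e-9)
    expect_true(check_decay_bound(s))
  }
  # unstable side: pinned negative slope grows
  un <- sample_model_with_rate(stable = FALSE, min_rate = 0.15)
  s_un <- run_experiment(un$model, perturbation_bump(0.01, 1.5, 0, 0.5),
                         t_end = 10 + 4 / un$rate, grid = g,
                         rtol = 1e-6, atol = 1e-9)
  expect_false(s_un$stability$criterion1)
  expect_equal(s_un$classification, "unstable")
  # amplitude zero -> I identically 0, classified stable
  s0 <- run_experiment(m, perturbation_fourier(0, 0, 2), t_end = 1, grid = g,
                       output_times = c(0, 1), rtol = 1e-6, atol = 1e-9)
  expect_true(all(s0$I_values == 0))
  expect_equal(s0$classification, "stable")
})

test_that("check_decay_bound flags violations and degenerate cases", {
  cert <- structure(list(decay_rate_bound = 1), class = "ps_certificate")
  mk <- function(times, phi) {
    structure(list(times = times, phi_values = phi,
                   stability = list(certificate = cert)),
              class = "ps_energy_series")
  }
  # constant phi with M > 0 fails once exp(-Mt) < 1/1.05
  expect_false(check_decay_bound(mk(c(0, 1, 5), c(1, 1, 1)), cert))
  # M = 0: any non-increasing phi passes trivially
  cert0 <- structure(list(decay_rate_bound = 0), class = "ps_certificate")
  expect_true(check_decay_bound(mk(c(0, 1, 5), c(1, 0.9, 0.5)), cert0))
  # honest decay passes
  expect_true(check_decay_bound(mk(c(0, 1, 2), exp(-1.2 * c(0, 1, 2))),
                                cert))
})

test_that("nonlinear I(t) tracks linearized I(t) for small amplitudes", {
  g <- bipolar_grid(1, 2, 12, 12, 1)
  set.seed(33)
  m <- sample_model_with_rate(stable = TRUE, mu_frac = 0.4)$model
  eq <- compute_equilibrium(m)
  amp <- 0.01 * min(eq$L_e, eq$M_e, eq$N_e)
  spec <- perturbation_bump(amp, 1.5, 0, 0.5)
  ts <- seq(0, 4, length.out = 9)
  lin <- run_experiment(m, spec, t_end = 4, grid = g, mode = "linearized",
                        output_times = ts, rtol = 1e-7, atol = 1e-10)
  nl <- run_experiment(m, spec, t_end = 4, grid = g, mode = "nonlinear",
                       output_times = ts, rtol = 1e-7, atol = 1e-10)
  keep <- lin$I_values >= lin$I_values[1] / 10   # before 10x decay
  expect_true(all(abs(nl$I_values[keep] - lin$I_values[keep]) <=
                    0.1 * lin$I_values[keep]))
})
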