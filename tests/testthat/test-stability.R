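# stability: spectral criterion, the two PDE criteria, energy certificate

test_that("spectral analysis matches closed forms and the eigen oracle", {
  lc <- lin_coefficients(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
                         fprime_at_Le = NULL)
  sp <- spectral_analysis(lc)
  expect_equal(sp$lambda1, -5)
  expect_lt(abs(sp$lambda2 - (-5 - sqrt(5)) / 2), 1e-12)
  expect_lt(abs(sp$lambda3 - (-5 + sqrt(5)) / 2), 1e-12)
  expect_true(sp$stable)
  ev <- sort(eigen_oracle(lc))
  expect_close(sort(c(sp$lambda1, sp$lambda2, sp$lambda3)), ev, 1e-10)

  # k1 = k4 = k2 = k3 = 1: lambda3 = 0 -> not stable (strict)
  sp0 <- spectral_analysis(lin_coefficients(1, 1, 1, 1, 1, 1))
  expect_equal(sp0$lambda3, 0)
  expect_false(sp0$stable)

  # k3 < 0 with small discriminant -> complex pair, real parts used
  lcc <- lin_coefficients(k1 = 1, k2 = 1, k3 = -5, k4 = 1, k5 = 1,
                          fprime_at_Le = 6)
  spc <- spectral_analysis(lcc)
  expect_true(spc$complex_pair)
  expect_equal(spc$lambda2, -1)
  expect_true(spc$stable)
  expect_close(sort(Re(eigen_oracle(lcc))),
               sort(c(spc$lambda1, spc$lambda2, spc$lambda3)), 1e-10)
})

test_that("criteria checks are strict and mutually consistent", {
  base <- list(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
               D_a = 1, D_b = 1, fprime_at_Le = 1)
  rep1 <- check_criteria(do.call(lin_coefficients, c(base, chi_a = 1)))
  expect_true(rep1$criterion1 && rep1$criterion2 && rep1$ode_stable)
  expect_false(is.null(rep1$certificate))

  # boundary case 4 < 4 fails (strict)
  rep2 <- check_criteria(do.call(lin_coefficients, c(base, chi_a = 2)))
  expect_false(rep2$criterion2)
  expect_null(rep2$certificate)
  expect_true(rep2$criterion1)

  # criterion1 <-> ode_stable across a seeded model sweep
  set.seed(77)
  for (i in 1:50) {
    m <- sample_pinned_model(stable = runif(1) < 0.5, mu_frac = runif(1))
    lc <- linearize(m)
    rep <- check_criteria(lc)
    expect_identical(rep$criterion1, rep$ode_stable)
    expect_identical(!is.null(rep$certificate),
                     rep$criterion1 && rep$criterion2 && lc$k3 > 0)
  }
})

test_that("certificate construction follows the constructive proof", {
  lc <- lin_coefficients(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
                         chi_a = 1, D_a = 1, D_b = 1, fprime_at_Le = 1)
  cert <- construct_certificate(lc)
  expect_equal(cert$eps4, 1)
  expect_equal(cert$eps5, 1)
  expect_equal(cert$eps1, 0.2)
  expect_equal(cert$eps2, 0.6)
  expect_equal(cert$x, 1)
  # y/x interval is (1/11, 1); geometric mean
  expect_lt(abs(cert$y - sqrt(1 / 11)), 1e-12)
  # eps3 interval (0.25, 1); geometric mean
  expect_lt(abs(cert$eps3 - 0.5), 1e-12)
  expect_true(all(c(cert$coeff_a, cert$coeff_b, cert$coeff_c,
                    cert$coeff_grad_a, cert$coeff_grad_b) < 0))
  expect_gt(cert$decay_rate_bound, 0)
  expect_equal(cert$decay_rate_bound,
               2 * min(abs(cert$coeff_a) / cert$x, abs(cert$coeff_b) / cert$y,
                       abs(cert$coeff_c) / cert$z))
  expect_true(verify_certificate(cert, lc))

  # no chemotaxis: gradient coefficients reduce to -D_a x and -D_b y
  lc0 <- lin_coefficients(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
                          chi_a = 0, D_a = 1.3, D_b = 0.7, fprime_at_Le = 1)
  cert0 <- construct_certificate(lc0)
  expect_equal(cert0$coeff_grad_a, -1.3 * cert0$x)
  expect_equal(cert0$coeff_grad_b, -0.7 * cert0$y)

  # Theorem-2 violation -> certificate-unavailable
  bad <- lin_coefficients(k1 = 1, k2 = 2, k3 = 2, k4 = 1, k5 = 1,
                          fprime_at_Le = -1)
  expect_error(construct_certificate(bad),
               class = "plaquestab_certificate_unavailable")
})

test_that("verify_certificate audits coefficients and weights", {
  lc <- lin_coefficients(k1 = 2, k2 = 1, k3 = 1, k4 = 3, k5 = 5, k6 = 1,
                         chi_a = 1, D_a = 1, D_b = 1, fprime_at_Le = 1)
  # all-ones certificate: coefficient on Int a^2 is 1+1+1-2 = 1 > 0 -> FALSE
  ones <- structure(list(x = 1, y = 1, z = 1, eps1 = 1, eps2 = 1, eps3 = 1,
                         eps4 = 1, eps5 = 1), class = "ps_certificate")
  expect_false(verify_certificate(ones, lc))
  cf <- plaquestab:::certificate_coefficients(ones, lc)
  expect_equal(cf$coeff_a, 1)
  # non-positive weight -> FALSE regardless
  cert <- construct_certificate(lc)
  bad <- cert; bad$z <- -bad$z
  expect_false(verify_certificate(bad, lc))
})

test_that("certificates exist and verify across a seeded admissible sweep", {
  set.seed(303)
  for (i in 1:100) {
    m <- sample_pinned_model(stable = TRUE, mu_frac = runif(1, 0, 0.9))
    lc <- linearize(m)
    cert <- construct_certificate(lc)
    expect_true(verify_certificate(cert, lc))
    expect_gt(cert$decay_rate_bound, 0)
  }
})

test_that("criterion 2 is monotone in the diffusion product", {
  set.seed(404)
  for (i in 1:50) {
    m <- sample_pinned_model(stable = TRUE, mu_frac = runif(1, 0, 1.5))
    lc <- linearize(m)
    c2 <- function(s) {
      lc2 <- lc; lc2$D_a <- s * lc$D_a; lc2$D_b <- s * lc$D_b
      check_criteria(lc2)$criterion2
    }
    if (c2(1)) expect_true(c2(2.5))   # enlarging Da*Db never breaks it
  }
})
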