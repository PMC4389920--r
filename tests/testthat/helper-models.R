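# Seeded samplers for parameter sweeps.  All sampling happens inside the
# calling test's set.seed(), so sweeps are reproducible.

# A pinned-response model with O(1) rates.  stable = TRUE keeps
# 0 < f'(L_e) < k_M * M_e (so k3 > 0); stable = FALSE gives f'(L_e) < 0.
# mu_frac scales the chemotaxis coefficient relative to the criterion-2
# boundary chi_max = sqrt(4 D_a D_b k3 / k2): mu_frac < 1 satisfies
# criterion 2, mu_frac > 1 violates it.
sample_pinned_model <- function(stable = TRUE, mu_frac = 0) {
  L_e <- runif(1, 0.5, 2); M_e <- runif(1, 0.5, 2)
  k_L <- runif(1, 0.5, 2); k_M <- runif(1, 0.5, 2); k_N <- runif(1, 0.5, 2)
  D_L <- runif(1, 0.5, 2); D_M <- runif(1, 0.5, 2)
  fprime <- if (stable) runif(1, 0.05, 0.8) * k_M * M_e
            else -runif(1, 0.3, 1.5)
  k3 <- k_M * M_e - fprime
  chi_max <- if (k3 > 0) sqrt(4 * D_L * D_M * k3 / (k_L * L_e)) else 0
  mu <- if (chi_max > 0) mu_frac * chi_max / M_e else 0
  model_pinned(L_e, M_e, fprime, D_L = D_L, D_M = D_M, mu = mu,
               k_L = k_L, k_M = k_M, k_N = k_N)
}

# rejection-sample a model whose slowest homogeneous rate is >= min_rate,
# so experiment horizons t ~ 1/min_rate stay bounded
sample_model_with_rate <- function(stable, mu_frac = 0, min_rate = 0.12) {
  for (i in 1:200) {
    m <- sample_pinned_model(stable = stable, mu_frac = mu_frac)
    sp <- spectral_analysis(linearize(m))
    lam <- max(sp$lambda1, sp$lambda2, sp$lambda3)
    if (stable && lam <= -min_rate) return(list(model = m, rate = -lam))
    if (!stable && lam >= min_rate) return(list(model = m, rate = lam))
  }
  stop("rejection sampler failed (should not happen at these ranges)")
}

# numeric eigen oracle for the 3x3 reaction matrix
eigen_oracle <- function(lc) eigen(reaction_matrix(lc))$values

expect_close <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}

small_grid <- function(m = 12, n = 12) bipolar_grid(1, 2, m, n, 1)
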