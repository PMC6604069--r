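test_that("the relation evaluates to its closed-form anchor values", {
  # hand arithmetic: (1/2) * ln(10) / ln(100) = 0.25
  expect_equal(as.numeric(ryabov_beta(100e-12, 1, 1e11, 1e-12)), 0.25,
               tolerance = 1e-12)
  # numerator zero at tau = 1/omega_s, for any D and tau0
  for (D in c(0.3, 1, 1.8))
    expect_identical(as.numeric(ryabov_beta(1e-11, D, 1e11, 1e-12)), 0)
  # beta -> D/2 asymptotically when the time and space cutoffs are
  # reciprocal (tau0 = 1/omega_s)
  b <- as.numeric(ryabov_beta(1, 1.8, 1e12, 1e-12))
  expect_lt(abs(b - 0.9), 0.02)
  expect_error(ryabov_beta(1e-12, 1, 1e11, 1e-12), "singular")
  expect_error(ryabov_beta(-1e-12, 1, 1e11, 1e-12), "positive")
})

test_that("unphysical branch values are flagged, not clamped", {
  # just above the time cutoff on the descending branch beta blows up past 1
  b <- ryabov_beta(c(5e-12, 100e-12), 1.9, 1e12, 4e-12)
  expect_true(any(!attr(b, "physical")))
  expect_true(any(as.numeric(b) > 1))
  expect_true(all(attr(ryabov_beta(1e-10, 1, 1e11, 1e-12), "physical")))
})

test_that("omega_s follows the self-diffusion formula", {
  # unit inputs with G = 1: exponent is irrelevant, omega_s = 2 * d_E
  for (D in c(0.5, 1, 2)) expect_equal(self_diffusion_omega(3, 1, 1, D), 6)
  expect_equal(self_diffusion_omega(1, 1, 1, D = 2, g = 2), 4)
  expect_equal(self_diffusion_omega(2, 3e-9, 1e-9, D = 1.5, g = 1) /
                 self_diffusion_omega(2, 3e-9, 2e-9, D = 1.5, g = 1), 4)
  expect_error(self_diffusion_omega(4, 1, 1, 1), "d_e")
})

test_that("noise-free trajectories round-trip the fractal dimension", {
  for (D in c(0.4, 1.44)) {
    fit <- fit_trajectory(synth_trajectory(D, n = 10))
    expect_lt(abs(fit$D - D), 0.05)
    expect_lt(fit$D_uncertainty, 1e-3)
    expect_true(fit$converged)
  }
})

test_that("degenerate trajectories are rejected", {
  p3 <- synth_trajectory(1.4, n = 10)[1:3, ]
  expect_error(fit_trajectory(p3), "at least 4")
  same_tau <- tau_beta_points(rep(2e-11, 5), seq(0.5, 0.9, length.out = 5))
  expect_error(fit_trajectory(same_tau), "distinct tau")
})

test_that("near-vertical dispersion arcs carry much larger D uncertainty", {
  u <- t(vapply(1:20, function(s) {
    c(sol = fit_trajectory(solution_trajectory(seed = s))$D_uncertainty,
      disp = fit_trajectory(dispersion_trajectory(seed = s))$D_uncertainty)
  }, numeric(2)))
  expect_gt(stats::median(u[, "disp"]), stats::median(u[, "sol"]))
  expect_gt(mean(u[, "disp"] > u[, "sol"]), 0.7)
})

test_that("classification respects the uncertainty band around D = 1", {
  expect_identical(classify_water_structure(1.74, 0.04), "solution")
  expect_identical(classify_water_structure(0.16, 0.05), "dispersion")
  # with its printed uncertainty the same value is indeterminate
  expect_identical(classify_water_structure(0.16, 1.49), "indeterminate")
  expect_identical(classify_water_structure(1.0, 0), "indeterminate")
  expect_identical(classify_water_structure(1.05, 0.4), "indeterminate")
  expect_error(classify_water_structure(-0.2), "non-negative")
})

test_that("fitted low-noise solution trajectories classify as solution", {
  fit <- fit_trajectory(synth_trajectory(1.5, beta_noise = 0.005, seed = 4))
  expect_identical(classify_water_structure(fit$D, fit$D_uncertainty), "solution")
})

test_that("bulk normalization is the identity for matching trajectories", {
  comp <- seq(0.1, 0.9, by = 0.1)
  bulk <- tau_beta_points(2e-11 * (1 + comp), 0.9 - 0.3 * comp, composition = comp)
  gel <- bulk
  out <- normalize_by_bulk(gel, bulk)
  expect_equal(out$tau_normalized, rep(1, length(comp)), tolerance = 1e-12)
  gel2 <- bulk; gel2$tau_s <- 2 * bulk$tau_s
  expect_equal(normalize_by_bulk(gel2, bulk)$tau_normalized,
               rep(2, length(comp)), tolerance = 1e-12)
})

test_that("normalization straightens a reentrant bulk trajectory", {
  comp <- seq(0, 1, length.out = 11)
  # bulk tau non-monotone in composition (reentrant mixed solvent)
  tau_bulk <- 1e-11 * (1 + 2 * sin(pi * comp))
  restriction <- 1 + 3 * comp            # what the shrinking gel adds
  gel <- tau_beta_points(tau_bulk * restriction, seq(0.95, 0.55, length.out = 11),
                         composition = comp)
  bulk <- tau_beta_points(tau_bulk, seq(0.97, 0.6, length.out = 11),
                          composition = comp)
  expect_true(is.unsorted(gel$tau_s))    # raw trajectory is reentrant
  out <- normalize_by_bulk(gel, bulk)
  expect_false(is.unsorted(out$tau_normalized))  # normalized one is monotone
  expect_equal(out$beta, gel$beta)               # beta passes through
})

test_that("compositions outside the bulk range error per point, not globally", {
  bulk <- tau_beta_points(c(1e-11, 2e-11), c(0.9, 0.8), composition = c(0.2, 0.8))
  gel <- tau_beta_points(c(1e-11, 2e-11, 3e-11), c(0.9, 0.8, 0.7),
                         composition = c(0.3, 0.5, 0.95))
  out <- normalize_by_bulk(gel, bulk)
  expect_true(is.na(out$tau_normalized[3]))
  expect_false(anyNA(out$tau_normalized[1:2]))
  expect_length(attr(out, "errors"), 1)
})

test_that("tau normalization uses the 8.3 ps diagram constant by default", {
  expect_equal(normalize_tau(8.3e-12), 1)
  expect_equal(normalize_tau(8.2e-12, "peak"), 1)
  expect_equal(unname(tau_water_25C), c(8.3e-12, 8.2e-12))
})
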