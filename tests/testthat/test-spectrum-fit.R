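test_that("initial guess lands within a factor of 2 of the true tau", {
  sp <- synthesize_spectrum(water_model(), 1e8, 6.5e10, 100)
  g <- initial_guess(sp, fit_config())
  tau0 <- g$processes[[1]]$tau
  expect_gt(tau0, 8.3e-12 / 2)
  expect_lt(tau0, 8.3e-12 * 2)
})

test_that("flat spectra take the fallback path with a recorded warning", {
  flat <- dielectric_spectrum(10^seq(8, 10, length.out = 40),
                              rep(5, 40), rep(0, 40))
  g <- initial_guess(flat, fit_config())
  expect_true(any(grepl("no interior loss maximum", attr(g, "warnings"))))
})

test_that("two well-separated processes seed two tau guesses a decade apart", {
  m <- spectrum_model(4, list(relaxation_process(60, 8e-12),
                              relaxation_process(20, 1e-8, beta_sym = 0.9)))
  sp <- synthesize_spectrum(m, 1e6, 1e11, 120)
  g <- initial_guess(sp, fit_config(n_processes = 2))
  taus <- sort(vapply(g$processes, `[[`, numeric(1), "tau"))
  expect_gte(log10(taus[2] / taus[1]), 1)
})

test_that("noise-free self-consistency: all four special cases recover to 1e-6", {
  cases <- list(
    debye = list(p = relaxation_process(73.2, 8.3e-12),
                 cfg = fit_config(fix_alpha_to_one = TRUE, fix_beta_to_one = TRUE)),
    cole_cole = list(p = relaxation_process(70, 2e-11, beta_sym = 0.8),
                     cfg = fit_config(fix_alpha_to_one = TRUE)),
    cole_davidson = list(p = relaxation_process(65, 5e-11, alpha_asym = 0.7),
                         cfg = fit_config(fix_beta_to_one = TRUE)),
    havriliak_negami = list(p = relaxation_process(60, 3e-11, beta_sym = 0.85,
                                                   alpha_asym = 0.75),
                            cfg = fit_config()))
  for (nm in names(cases)) {
    true_p <- cases[[nm]]$p
    m <- spectrum_model(5, true_p)
    sp <- synthesize_spectrum(m, 1e8, 6.5e10, 100)
    fit <- fit_spectrum(sp, cases[[nm]]$cfg)
    expect_true(fit$converged, info = nm)
    p <- fit$model$processes[[1]]
    expect_equal(p$tau, true_p$tau, tolerance = 1e-6)
    expect_equal(p$delta_eps, true_p$delta_eps, tolerance = 1e-6)
    expect_equal(p$beta_sym, true_p$beta_sym, tolerance = 1e-6)
    expect_equal(p$alpha_asym, true_p$alpha_asym, tolerance = 1e-6)
    expect_equal(fit$model$eps_inf, 5, tolerance = 1e-5)
  }
})

test_that("uncertainties collapse to the numerical floor for an exact fit", {
  sp <- synthesize_spectrum(water_model(), 1e8, 6.5e10, 100)
  fit <- fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE))
  expect_true(all(fit$parameter_uncertainties < 1e-8, na.rm = TRUE))
})

test_that("fitting Debye data with beta free pins beta at 1 within 1e-3", {
  sp <- synthesize_spectrum(water_model(), 1e8, 6.5e10, 100)
  fit <- fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE))
  expect_equal(fit$model$processes[[1]]$beta_sym, 1, tolerance = 1e-3)
})

test_that("1% noise leaves tau and beta recoverable within 5% across seeds", {
  m <- spectrum_model(5, relaxation_process(70, 2e-11, beta_sym = 0.8))
  errs <- t(vapply(1:20, function(s) {
    sp <- synthesize_spectrum(m, 1e8, 6.5e10, 100, noise_rel = 0.01, seed = s)
    fit <- fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE))
    p <- fit$model$processes[[1]]
    c(abs(p$tau - 2e-11) / 2e-11, abs(p$beta_sym - 0.8) / 0.8)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)
})

test_that("parameter RMSE shrinks when the noise level halves", {
  m <- spectrum_model(5, relaxation_process(70, 2e-11, beta_sym = 0.8))
  rmse_tau <- function(noise) {
    e <- vapply(1:20, function(s) {
      sp <- synthesize_spectrum(m, 1e8, 6.5e10, 100, noise_rel = noise, seed = s)
      fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE))$model$processes[[1]]$tau - 2e-11
    }, numeric(1))
    sqrt(mean(e^2))
  }
  expect_lt(rmse_tau(0.005), rmse_tau(0.01))
})

test_that("the GHz process is selected by proximity to 8.3 ps when unindexed", {
  m <- spectrum_model(4, list(relaxation_process(60, 8e-12),
                              relaxation_process(20, 1e-8, beta_sym = 0.9)))
  sp <- synthesize_spectrum(m, 1e6, 1e11, 140)
  fit <- fit_spectrum(sp, fit_config(n_processes = 2))
  tb <- extract_tau_beta(fit)
  expect_equal(tb$tau, 8e-12, tolerance = 1e-3)
  expect_equal(tb$process_index, 1L)
  expect_error(extract_tau_beta(fit, 3), "out of range")
})

test_that("processes are reported sorted by ascending tau", {
  m <- spectrum_model(4, list(relaxation_process(20, 1e-8, beta_sym = 0.9),
                              relaxation_process(60, 8e-12)))
  sp <- synthesize_spectrum(m, 1e6, 1e11, 140)
  fit <- fit_spectrum(sp, fit_config(n_processes = 2))
  taus <- vapply(fit$model$processes, `[[`, numeric(1), "tau")
  expect_true(all(diff(taus) > 0))
})

test_that("NA data are rejected; non-convergence is flagged, not thrown", {
  sp <- synthesize_spectrum(water_model(), 1e8, 6.5e10, 100)
  bad <- sp; bad$eps_real[3] <- NA
  expect_error(fit_spectrum(bad, fit_config()), "NA")
  cramped <- suppressWarnings(
    fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE, max_iterations = 1)))
  expect_s3_class(cramped, "fit_result")
  expect_false(cramped$converged)
})
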