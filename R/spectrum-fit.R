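# Weighted complex nonlinear least-squares estimation of relaxation
# parameters from permittivity spectra.
#
# Parameterization: tau and delta_eps are fitted on log10 scale, broadening
# exponents and eps_inf on their natural scale, all under box constraints
# enforced by the Levenberg-Marquardt solver (minpack.lm). Bounds:
# log10(tau) in [-14, -6], exponents in (0, 1], eps_inf in [1, 1e4].

#' Configure a spectrum fit
#'
#' @param n_processes Number of relaxation processes (>= 1).
#' @param fix_alpha_to_one Cole-Cole mode: hold every asymmetric exponent at 1.
#' @param fix_beta_to_one Cole-Davidson mode: hold every symmetric exponent
#'   at 1.
#' @param include_conductivity Add a dc-conductivity term to the model.
#' @param weighting `"relative"` (default; weights `1/|eps*_data|^2`, suited
#'   to spectra whose loss spans decades) or `"uniform"`.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param tolerance Relative convergence tolerance on the residual norm.
#' @param diagram_exponent Which broadening exponent [extract_tau_beta()]
#'   reports for the tau-beta diagram: `"symmetric"` (default; Cole-Cole
#'   beta) or `"asymmetric"` (Cole-Davidson alpha, used when a process is
#'   asymmetric and its alpha plays the role of the distribution parameter).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_processes = 1,
                       fix_alpha_to_one = FALSE,
                       fix_beta_to_one = FALSE,
                       include_conductivity = FALSE,
                       weighting = c("relative", "uniform"),
                       max_iterations = 500,
                       tolerance = 1e-12,
                       diagram_exponent = c("symmetric", "asymmetric")) {
  stopifnot(n_processes >= 1)
  weighting <- match.arg(weighting)
  diagram_exponent <- match.arg(diagram_exponent)
  structure(list(n_processes = as.integer(n_processes),
                 fix_alpha_to_one = isTRUE(fix_alpha_to_one),
                 fix_beta_to_one = isTRUE(fix_beta_to_one),
                 include_conductivity = isTRUE(include_conductivity),
                 weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 diagram_exponent = diagram_exponent),
            class = "fit_config")
}

# locate interior maxima of the loss curve, tallest first
loss_maxima <- function(spectrum) {
  y <- spectrum$eps_imag
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i[order(y[i], decreasing = TRUE)]
}

#' Initial parameter guess for a spectrum fit
#'
#' tau for each process is seeded from interior loss maxima
#' (`tau = 1/(2 pi f_peak)`), eps_inf from the highest-frequency real
#' permittivity, and the total dielectric decrement across the band is split
#' between processes in proportion to their peak losses. Exponents start
#' near 1. When no interior loss maximum exists (flat or truncated spectra)
#' the geometric band center is used and a warning is recorded in
#' `attr(, "warnings")`.
#'
#' @param spectrum A [dielectric_spectrum()].
#' @param config A [fit_config()].
#' @return A [spectrum_model()] carrying a `warnings` attribute.
#' @export
initial_guess <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"), inherits(config, "fit_config"))
  k <- config$n_processes
  n_free <- k * (2L + (!config$fix_beta_to_one) + (!config$fix_alpha_to_one)) +
    1L + config$include_conductivity
  if (nrow(spectrum) < 4L * n_free)
    stop(sprintf("spectrum too short: %d points for %d free parameters",
                 nrow(spectrum), n_free))
  warnings <- character(0)
  f <- spectrum$frequency_hz
  eps_inf <- mean(utils::tail(spectrum$eps_real, 3))
  eps_inf <- max(eps_inf, 1)
  d_total <- max(mean(utils::head(spectrum$eps_real, 3)) - eps_inf, 1e-3)

  peaks <- loss_maxima(spectrum)
  if (length(peaks) == 0L) {
    warnings <- c(warnings, "no interior loss maximum; tau seeded from band center")
    f_pk <- sqrt(f[1] * f[length(f)])
    h_pk <- 1
  } else {
    use <- peaks[seq_len(min(k, length(peaks)))]
    f_pk <- f[use]
    h_pk <- pmax(spectrum$eps_imag[use], 1e-6)
    while (length(f_pk) < k) {       # pad with decade-spaced extra guesses
      f_pk <- c(f_pk, utils::tail(f_pk, 1) / 10)
      h_pk <- c(h_pk, utils::tail(h_pk, 1))
      warnings <- c(warnings, "fewer loss maxima than processes; padded tau guesses")
    }
  }
  d_each <- d_total * h_pk / sum(h_pk)
  ord <- order(1 / f_pk)             # ascending tau
  procs <- lapply(ord, function(i) {
    relaxation_process(delta_eps = d_each[i],
                       tau = min(max(1 / (2 * pi * f_pk[i]), 1e-14), 1e-6),
                       beta_sym = if (config$fix_beta_to_one) 1 else 0.98,
                       alpha_asym = if (config$fix_alpha_to_one) 1 else 0.98)
  })
  m <- spectrum_model(eps_inf, procs,
                      sigma_dc = if (config$include_conductivity) 1e-6 else 0)
  attr(m, "warnings") <- warnings
  m
}

# ---- parameter packing ------------------------------------------------------

pack_par <- function(model, config) {
  par <- c(); lo <- c(); hi <- c()
  add <- function(par, lo, hi, v, l, h, nm) {
    par <- c(par, stats::setNames(v, nm)); c(list(par), list(c(lo, l)), list(c(hi, h)))
  }
  for (i in seq_along(model$processes)) {
    p <- model$processes[[i]]
    par <- c(par, stats::setNames(log10(p$tau), paste0("log_tau", i)))
    lo <- c(lo, -14); hi <- c(hi, -6)
    par <- c(par, stats::setNames(log10(max(p$delta_eps, 1e-6)), paste0("log_deps", i)))
    lo <- c(lo, -6); hi <- c(hi, 6)
    if (!config$fix_beta_to_one) {
      par <- c(par, stats::setNames(p$beta_sym, paste0("beta", i)))
      lo <- c(lo, 1e-3); hi <- c(hi, 1)
    }
    if (!config$fix_alpha_to_one) {
      par <- c(par, stats::setNames(p$alpha_asym, paste0("alpha", i)))
      lo <- c(lo, 1e-3); hi <- c(hi, 1)
    }
  }
  par <- c(par, eps_inf = model$eps_inf); lo <- c(lo, 1); hi <- c(hi, 1e4)
  if (config$include_conductivity) {
    par <- c(par, log_sigma = log10(max(model$sigma_dc, 1e-12)))
    lo <- c(lo, -12); hi <- c(hi, 2)
  }
  list(par = par, lower = lo, upper = hi)
}

unpack_par <- function(par, config) {
  k <- config$n_processes
  procs <- vector("list", k)
  for (i in seq_len(k)) {
    procs[[i]] <- relaxation_process(
      delta_eps = 10^par[[paste0("log_deps", i)]],
      tau = 10^par[[paste0("log_tau", i)]],
      beta_sym = if (config$fix_beta_to_one) 1 else par[[paste0("beta", i)]],
      alpha_asym = if (config$fix_alpha_to_one) 1 else par[[paste0("alpha", i)]])
  }
  spectrum_model(par[["eps_inf"]], procs,
                 sigma_dc = if (config$include_conductivity) 10^par[["log_sigma"]] else 0)
}

#' Fit a relaxation model to a spectrum
#'
#' Minimizes \eqn{\sum_i w_i |\epsilon^*_{model}(f_i) -
#' \epsilon^*_{data}(f_i)|^2} by bounded Levenberg-Marquardt, with the
#' weights set by the configuration. Non-convergence is reported through
#' `converged = FALSE`, never as an error. Parameter uncertainties are
#' 1-sigma values from the local curvature (Gauss-Newton covariance) at the
#' optimum, delta-mapped back to the natural scale.
#'
#' @param spectrum A [dielectric_spectrum()].
#' @param config A [fit_config()].
#' @param start Optional [spectrum_model()] overriding [initial_guess()].
#' @return A list of class `fit_result`: `model` (processes sorted by
#'   ascending tau), `residual_norm`, `parameter_uncertainties` (named, on
#'   the natural scale), `converged`, `config`, `n_obs`, `warnings`.
#' @examples
#' m <- spectrum_model(5, relaxation_process(70, 2e-11, beta_sym = 0.8))
#' sp <- synthesize_spectrum(m, 1e8, 6.5e10, 100)
#' fit <- fit_spectrum(sp, fit_config(fix_alpha_to_one = TRUE))
#' fit$model
#' @export
fit_spectrum <- function(spectrum, config = fit_config(), start = NULL) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"), inherits(config, "fit_config"))
  if (anyNA(spectrum)) stop("NA in spectrum data")
  if (is.null(start)) start <- initial_guess(spectrum, config)
  warnings <- attr(start, "warnings") %||% character(0)

  data_c <- complex(real = spectrum$eps_real, imaginary = -spectrum$eps_imag)
  w <- 2 * pi * spectrum$frequency_hz
  sw <- if (config$weighting == "relative") 1 / pmax(Mod(data_c), 1e-12) else
    rep(1, length(data_c))

  resid_fn <- function(par) {
    par <- stats::setNames(par, names(pk$par))
    m <- unpack_par(par, config)
    d <- hn_eval(m, w) - data_c
    c(Re(d) * sw, Im(d) * sw)
  }
  pk <- pack_par(start, config)
  res <- minpack.lm::nls.lm(
    par = pk$par, lower = pk$lower, upper = pk$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(config$max_iterations, 1024L),
      ftol = config$tolerance, ptol = config$tolerance, gtol = 0))

  par <- stats::setNames(res$par, names(pk$par))
  model <- unpack_par(par, config)
  converged <- res$info %in% 1:4
  if (!converged)
    warnings <- c(warnings, paste0("solver did not converge: ", res$message))

  # curvature-based uncertainties on the natural scale
  n_obs <- 2L * nrow(spectrum)
  dof <- max(n_obs - length(par), 1L)
  sigma2 <- res$deviance / dof
  vc <- tryCatch(sigma2 * solve(res$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(par)) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(par)
  nat <- se
  for (nm in names(se)) {
    if (startsWith(nm, "log_tau") || startsWith(nm, "log_deps") || nm == "log_sigma")
      nat[nm] <- log(10) * 10^par[[nm]] * se[nm]
  }
  names(nat) <- sub("^log_", "", names(nat))

  # report processes sorted by ascending tau; ties broken by larger delta_eps
  taus <- vapply(model$processes, `[[`, numeric(1), "tau")
  deps <- vapply(model$processes, `[[`, numeric(1), "delta_eps")
  ord <- order(taus, -deps)
  model$processes <- model$processes[ord]
  uncert <- relabel_process_uncertainties(nat, ord)

  structure(list(model = model,
                 residual_norm = sqrt(res$deviance),
                 parameter_uncertainties = uncert,
                 converged = converged,
                 config = config,
                 n_obs = n_obs,
                 warnings = warnings),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rename per-process uncertainty entries after sorting processes by tau
relabel_process_uncertainties <- function(nat, ord) {
  out <- nat
  for (new_i in seq_along(ord)) {
    old_i <- ord[new_i]
    for (stem in c("tau", "deps", "beta", "alpha")) {
      old_nm <- paste0(stem, old_i)
      new_nm <- paste0(stem, new_i)
      if (old_nm %in% names(nat)) out[new_nm] <- nat[[old_nm]]
    }
  }
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> converged = %s, residual_norm = %.4g\n",
              x$converged, x$residual_norm))
  print(x$model)
  invisible(x)
}

#' Extract (tau, beta) for the tau-beta diagram from a fit
#'
#' Returns the relaxation time and distribution parameter of one fitted
#' process together with their 1-sigma uncertainties. When
#' `process_index` is `NULL` the GHz water process is selected as the one
#' with tau closest (in log distance) to 8.3 ps. Which exponent is reported
#' as "beta" follows `config$diagram_exponent`: the symmetric exponent by
#' default, or the asymmetric one for Cole-Davidson-type analyses where the
#' asymmetric shape parameter plays the role of the distribution parameter.
#'
#' @param result A `fit_result` from [fit_spectrum()].
#' @param process_index Index into the tau-sorted process list, or `NULL`.
#' @return A list: `tau`, `beta`, `tau_err`, `beta_err`, `process_index`.
#' @export
extract_tau_beta <- function(result, process_index = NULL) {
  stopifnot(inherits(result, "fit_result"))
  k <- length(result$model$processes)
  taus <- vapply(result$model$processes, `[[`, numeric(1), "tau")
  if (is.null(process_index))
    process_index <- which.min(abs(log(taus) - log(tau_water_25C[["diagram"]])))
  if (process_index < 1 || process_index > k) stop("process_index out of range")
  if (!result$converged)
    warning("extracting parameters from a non-converged fit")
  p <- result$model$processes[[process_index]]
  u <- result$parameter_uncertainties
  exp_stem <- if (result$config$diagram_exponent == "symmetric") "beta" else "alpha"
  beta <- if (exp_stem == "beta") p$beta_sym else p$alpha_asym
  get_u <- function(nm) if (nm %in% names(u)) unname(u[[nm]]) else 0
  list(tau = p$tau, beta = beta,
       tau_err = get_u(paste0("tau", process_index)),
       beta_err = get_u(paste0(exp_stem, process_index)),
       process_index = process_index)
}
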