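# Havriliak-Negami relaxation family: forward models and synthetic spectra.
#
# Convention note. The relaxation function is written
#   (eps* - eps_inf) / delta_eps = 1 / [1 + (j w tau)^beta]^alpha
# with beta the *symmetric* and alpha the *asymmetric* broadening exponent.
# This is the reverse of the most common literature placement of the two
# exponents; field names (`beta_sym`, `alpha_asym`) pin the convention used
# throughout this package so the two cannot be swapped silently.
# Debye: alpha = beta = 1.  Cole-Cole: alpha = 1.  Cole-Davidson: beta = 1.

#' Vacuum permittivity (F/m)
#' @keywords internal
EPS_VACUUM <- 8.8541878128e-12

#' Relaxation times of pure water at 25 degrees C
#'
#' The principal GHz dielectric relaxation of bulk water at 25 degrees C has a
#' relaxation time quoted in the literature as either 8.2 ps (loss peak near
#' 20 GHz) or 8.3 ps. Both constants are exposed; the tau-beta diagram
#' normalization defaults to the 8.3 ps value (see [normalize_tau()]).
#'
#' @format Named numeric vector with elements `diagram` (8.3e-12 s) and
#'   `peak` (8.2e-12 s).
#' @export
tau_water_25C <- c(diagram = 8.3e-12, peak = 8.2e-12)

#' Define a single relaxation process
#'
#' A single term of the Havriliak-Negami family,
#' \deqn{\Delta\epsilon / [1 + (j\omega\tau)^\beta]^\alpha,}
#' with `beta_sym` the symmetric and `alpha_asym` the asymmetric broadening
#' exponent (both in (0, 1]).
#'
#' @param delta_eps Relaxation strength (dimensionless, > 0).
#' @param tau Relaxation time in seconds (> 0).
#' @param beta_sym Symmetric broadening exponent in (0, 1]; 1 = no symmetric
#'   broadening. The Cole-Cole function has `alpha_asym = 1` and
#'   `beta_sym < 1`.
#' @param alpha_asym Asymmetric broadening exponent in (0, 1]; 1 = no
#'   asymmetric skew. The Cole-Davidson function has `beta_sym = 1` and
#'   `alpha_asym < 1`.
#' @return An object of class `relaxation_process`.
#' @examples
#' # the GHz process of pure water at 25 C
#' relaxation_process(delta_eps = 73.2, tau = 8.3e-12)
#' @export
relaxation_process <- function(delta_eps, tau, beta_sym = 1, alpha_asym = 1) {
  stopifnot(is.numeric(delta_eps), length(delta_eps) == 1L,
            is.numeric(tau), length(tau) == 1L)
  if (!is.finite(delta_eps) || delta_eps < 0)
    stop("`delta_eps` must be finite and >= 0")
  if (!is.finite(tau) || tau <= 0)
    stop("`tau` must be finite and > 0")
  check_exponent(beta_sym, "beta_sym")
  check_exponent(alpha_asym, "alpha_asym")
  structure(list(delta_eps = delta_eps, tau = tau,
                 beta_sym = beta_sym, alpha_asym = alpha_asym),
            class = "relaxation_process")
}

check_exponent <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
    stop(sprintf("`%s` must lie in (0, 1]", name))
  invisible(x)
}

#' @export
print.relaxation_process <- function(x, ...) {
  cat(sprintf(
    "<relaxation_process> delta_eps = %.4g, tau = %.4g s, beta_sym = %.4g, alpha_asym = %.4g\n",
    x$delta_eps, x$tau, x$beta_sym, x$alpha_asym))
  invisible(x)
}

#' Define a dielectric spectrum model
#'
#' A sum of relaxation processes on a common high-frequency limit, with an
#' optional dc-conductivity term \eqn{\sigma_{dc}/(j\omega\epsilon_v)} to
#' represent unresolved low-frequency contributions.
#'
#' @param eps_inf High-frequency limit of the real permittivity (>= 1).
#' @param processes A single [relaxation_process()] or a list of them,
#'   ordered by ascending relaxation time by convention.
#' @param sigma_dc DC conductivity in S/m (>= 0, default 0).
#' @return An object of class `spectrum_model`.
#' @seealso [evaluate_model()], [synthesize_spectrum()]
#' @export
spectrum_model <- function(eps_inf, processes, sigma_dc = 0) {
  if (inherits(processes, "relaxation_process")) processes <- list(processes)
  stopifnot(is.list(processes), length(processes) >= 1L)
  if (!all(vapply(processes, inherits, logical(1), "relaxation_process")))
    stop("`processes` must be relaxation_process objects")
  if (!is.numeric(eps_inf) || length(eps_inf) != 1L || !is.finite(eps_inf) || eps_inf < 1)
    stop("`eps_inf` must be >= 1")
  if (!is.numeric(sigma_dc) || length(sigma_dc) != 1L || !is.finite(sigma_dc) || sigma_dc < 0)
    stop("`sigma_dc` must be >= 0")
  structure(list(eps_inf = eps_inf, processes = processes, sigma_dc = sigma_dc),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> eps_inf = %.4g, sigma_dc = %.4g S/m, %d process(es)\n",
              x$eps_inf, x$sigma_dc, length(x$processes)))
  for (p in x$processes) print(p)
  cat(sprintf("  static permittivity eps_0 = %.4g\n", static_permittivity(x)))
  invisible(x)
}

#' Static (zero-frequency) permittivity of a model
#'
#' `eps_0 = eps_inf + sum(delta_eps)`.
#'
#' @param model A [spectrum_model()].
#' @return Numeric scalar.
#' @export
static_permittivity <- function(model) {
  stopifnot(inherits(model, "spectrum_model"))
  model$eps_inf + sum(vapply(model$processes, `[[`, numeric(1), "delta_eps"))
}

#' Construct a dielectric spectrum container
#'
#' Frequencies must be strictly increasing and positive; the loss `eps_imag`
#' is stored as a positive number under the physics sign convention
#' \eqn{\epsilon^* = \epsilon' - j\epsilon''}.
#'
#' @param frequency_hz Strictly increasing positive frequencies in Hz
#'   (length >= 2).
#' @param eps_real Real permittivity at each frequency.
#' @param eps_imag Dielectric loss (positive) at each frequency.
#' @return A data frame of class `dielectric_spectrum` with columns
#'   `frequency_hz`, `eps_real`, `eps_imag`.
#' @export
dielectric_spectrum <- function(frequency_hz, eps_real, eps_imag) {
  n <- length(frequency_hz)
  if (n < 2L) stop("a spectrum needs at least 2 frequency points")
  if (length(eps_real) != n || length(eps_imag) != n)
    stop("frequency_hz, eps_real and eps_imag must have equal length")
  if (anyNA(frequency_hz) || anyNA(eps_real) || anyNA(eps_imag))
    stop("NA values are not allowed in a spectrum")
  if (any(frequency_hz <= 0)) stop("frequencies must be positive")
  if (any(diff(frequency_hz) <= 0)) stop("frequencies must be strictly increasing")
  structure(data.frame(frequency_hz = as.numeric(frequency_hz),
                       eps_real = as.numeric(eps_real),
                       eps_imag = as.numeric(eps_imag)),
            class = c("dielectric_spectrum", "data.frame"))
}

#' Complex permittivity of a spectrum
#'
#' Returns `eps_real - 1i * eps_imag` (physics convention with positive
#' stored loss).
#'
#' @param spectrum A [dielectric_spectrum()].
#' @return Complex vector.
#' @export
eps_complex <- function(spectrum) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  complex(real = spectrum$eps_real, imaginary = -spectrum$eps_imag)
}

# complex permittivity of a model at angular frequency w (rad/s)
hn_eval <- function(model, w) {
  e <- rep(complex(real = model$eps_inf, imaginary = 0), length(w))
  for (p in model$processes) {
    e <- e + p$delta_eps / (1 + (1i * w * p$tau)^p$beta_sym)^p$alpha_asym
  }
  if (model$sigma_dc > 0) e <- e + model$sigma_dc / (1i * w * EPS_VACUUM)
  e
}

#' Evaluate a relaxation model on a frequency grid
#'
#' Computes \eqn{\epsilon^*(\omega) = \epsilon_\infty + \sum_k
#' \Delta\epsilon_k / [1 + (j\omega\tau_k)^{\beta_k}]^{\alpha_k} +
#' \sigma_{dc}/(j\omega\epsilon_v)} with the principal branch of the complex
#' power, and returns it as a [dielectric_spectrum()] with positive loss.
#'
#' @param model A [spectrum_model()].
#' @param frequency_hz Strictly positive, strictly increasing frequencies (Hz).
#' @return A [dielectric_spectrum()].
#' @examples
#' m <- spectrum_model(5.2, relaxation_process(73.2, 8.3e-12))
#' sp <- evaluate_model(m, 10^seq(8, 10.8, length.out = 50))
#' head(sp)
#' @export
evaluate_model <- function(model, frequency_hz) {
  stopifnot(inherits(model, "spectrum_model"))
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0))
    stop("frequencies must be finite and positive")
  e <- hn_eval(model, 2 * pi * frequency_hz)
  dielectric_spectrum(frequency_hz, Re(e), pmax(-Im(e), 0))
}

#' Loss-peak frequency of a single relaxation process
#'
#' For `alpha_asym = 1` (Debye/Cole-Cole) the loss peak sits exactly at
#' \eqn{f = 1/(2\pi\tau)}; symmetric broadening does not move it. For
#' `alpha_asym < 1` the peak is found numerically (coarse log-frequency grid
#' followed by golden-section refinement); asymmetric skew pushes it above
#' \eqn{1/(2\pi\tau)}.
#'
#' @param process A [relaxation_process()].
#' @return Peak frequency in Hz.
#' @examples
#' loss_peak_frequency(relaxation_process(73, 8.2e-12)) # ~1.94e10 Hz
#' @export
loss_peak_frequency <- function(process) {
  stopifnot(inherits(process, "relaxation_process"))
  f0 <- 1 / (2 * pi * process$tau)
  if (process$alpha_asym == 1) return(f0)
  m <- spectrum_model(1, process)
  loss <- function(lf) -Im(hn_eval(m, 2 * pi * 10^lf))
  lf_grid <- seq(log10(f0) - 3, log10(f0) + 3, length.out = 400)
  i <- which.max(loss(lf_grid))
  lo <- lf_grid[max(i - 1L, 1L)]
  hi <- lf_grid[min(i + 1L, length(lf_grid))]
  opt <- stats::optimize(loss, lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  10^opt$maximum
}

#' Generate a synthetic spectrum with optional noise
#'
#' Evaluates `model` on a log-spaced grid and adds independent Gaussian noise
#' to the real and imaginary parts, with standard deviation
#' `noise_rel * |eps*(f)|` at each frequency. Reproducible via `seed`.
#' The loss is not clipped, so noisy spectra can carry small negative
#' `eps_imag` values where the true loss is near zero.
#'
#' @param model A [spectrum_model()].
#' @param f_min,f_max Band edges in Hz (`f_min < f_max`).
#' @param n_points Number of log-spaced points (>= 8).
#' @param noise_rel Relative noise magnitude (>= 0; 0 reproduces
#'   [evaluate_model()] exactly).
#' @param seed Optional integer seed; the generator state is restored on exit.
#' @return A [dielectric_spectrum()].
#' @export
synthesize_spectrum <- function(model, f_min = 1e8, f_max = 6.5e10,
                                n_points = 100, noise_rel = 0, seed = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  if (!is.numeric(noise_rel) || noise_rel < 0) stop("`noise_rel` must be >= 0")
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  if (n_points < 8) stop("`n_points` must be >= 8")
  f <- 10^seq(log10(f_min), log10(f_max), length.out = n_points)
  e <- hn_eval(model, 2 * pi * f)
  re <- Re(e); im <- -Im(e)
  if (noise_rel > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    s <- noise_rel * Mod(e)
    re <- re + stats::rnorm(n_points, 0, s)
    im <- im + stats::rnorm(n_points, 0, s)
  }
  structure(data.frame(frequency_hz = f, eps_real = re, eps_imag = im),
            class = c("dielectric_spectrum", "data.frame"))
}
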