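# The Ryabov relation between the Cole-Cole distribution parameter and the
# mean relaxation time, and fractal characterization of tau-beta
# trajectories.
#
#   beta(tau) = (D/2) * ln(tau * omega_S) / ln(tau / tau0_s)
#
# D is the fractal dimension of the set of relaxing units interacting with
# the statistical reservoir, omega_S the characteristic frequency of
# self-diffusion, tau0_s the cutoff time of the time-domain scaling.
# tau0_s is deliberately named apart from the pure-water normalization
# constant of the tau-beta diagram (tau_water_25C), which the source
# literature also writes as "tau0".

#' Cole-Cole parameter from the Ryabov fractal relation
#'
#' \deqn{\beta(\tau) = \frac{D}{2}\,\frac{\ln(\tau\,\omega_S)}{\ln(\tau/\tau_{0s})}}
#'
#' Values are returned unclamped: a `physical` attribute flags, per point,
#' whether the result lies in the physical branch (0, 1]. The horizontal
#' asymptote for large tau is `D/2`; the curve crosses zero exactly at
#' `tau = 1/omega_s`.
#'
#' @param tau Relaxation time(s) in seconds (> 0, != `tau0_s`).
#' @param D Fractal dimension (>= 0).
#' @param omega_s Characteristic self-diffusion angular frequency (rad/s, > 0).
#' @param tau0_s Cutoff time of the time-domain scaling (s, > 0).
#' @return Numeric vector of beta values with logical attribute `physical`.
#' @examples
#' ryabov_beta(100e-12, D = 1, omega_s = 1e11, tau0_s = 1e-12)  # 0.25
#' @export
ryabov_beta <- function(tau, D, omega_s, tau0_s) {
  stopifnot(is.numeric(tau), is.numeric(D), is.numeric(omega_s), is.numeric(tau0_s))
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (D < 0) stop("`D` must be >= 0")
  if (omega_s <= 0 || tau0_s <= 0) stop("`omega_s` and `tau0_s` must be positive")
  if (any(tau == tau0_s)) stop("`tau` equal to `tau0_s`: the relation is singular there")
  num <- log(tau * omega_s)
  num[tau == 1 / omega_s] <- 0        # exact zero at the representable crossing
  b <- (D / 2) * num / log(tau / tau0_s)
  attr(b, "physical") <- b > 0 & b <= 1
  b
}

#' Characteristic self-diffusion frequency from physical parameters
#'
#' \deqn{\omega_S = 2\, d_E\, G^{2/D}\, D_s / R_0^2}
#'
#' @param d_e Euclidean dimension (1, 2 or 3).
#' @param d_s Self-diffusion coefficient (length^2 / time).
#' @param r0 Cutoff size of the spatial scaling (length).
#' @param D Fractal dimension (> 0).
#' @param g Geometrical coefficient, approximately 1 (default).
#' @return omega_S in rad/s (for `d_s`, `r0` in SI units).
#' @export
self_diffusion_omega <- function(d_e, d_s, r0, D, g = 1) {
  if (!d_e %in% 1:3) stop("`d_e` must be 1, 2 or 3")
  if (d_s <= 0 || r0 <= 0 || g <= 0) stop("`d_s`, `r0`, `g` must be positive")
  if (!is.numeric(D) || D <= 0) stop("`D` must be > 0")
  2 * d_e * g^(2 / D) * d_s / r0^2
}

#' Build a table of tau-beta points
#'
#' @param tau Relaxation times (s).
#' @param beta Distribution parameters in (0, 1].
#' @param label Optional point labels (composition/condition).
#' @param tau_err,beta_err Optional 1-sigma uncertainties (default 0).
#' @param composition Optional numeric composition coordinate (e.g. water
#'   weight fraction), required by [normalize_by_bulk()].
#' @param tau_ref Normalization constant for `tau_normalized` (default the
#'   8.3 ps pure-water value).
#' @return Data frame of class `tau_beta_points` with a `tau_normalized`
#'   column (`tau / tau_ref`).
#' @export
tau_beta_points <- function(tau, beta, label = "", tau_err = 0, beta_err = 0,
                            composition = NA_real_,
                            tau_ref = tau_water_25C[["diagram"]]) {
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (any(beta <= 0 | beta > 1)) stop("`beta` must lie in (0, 1]")
  structure(data.frame(label = label, tau_s = tau, beta = beta,
                       tau_err = tau_err, beta_err = beta_err,
                       composition = composition,
                       tau_normalized = tau / tau_ref),
            class = c("tau_beta_points", "data.frame"))
}

#' Normalize relaxation times by the pure-water value
#'
#' @param tau Relaxation times (s).
#' @param variant `"diagram"` (8.3 ps, default) or `"peak"` (8.2 ps).
#' @return `tau / tau_water`.
#' @export
normalize_tau <- function(tau, variant = c("diagram", "peak")) {
  variant <- match.arg(variant)
  tau / tau_water_25C[[variant]]
}

# sum of squared residuals of the relation at parameters th = (D, log10 wS,
# log10 tau0), for points (tau, beta)
ryabov_rss <- function(th, tau, beta) {
  b <- (th[1] / 2) * log(tau * 10^th[2]) / log(tau / 10^th[3])
  sum((b - beta)^2)
}

#' Fit the Ryabov relation to a tau-beta trajectory
#'
#' Least-squares fit of the relation in (ln tau, beta) space over the three
#' parameters (D, omega_S, tau0_s). The three parameters are weakly
#' identifiable from the short trajectory arcs that real water data provide,
#' so omega_S and tau0_s are kept inside data-driven boxes:
#' `1/omega_s` in `[min(tau)/10, min(tau)]` and `tau0_s` in
#' `[0.01, 1] * min(tau)`. The reported `D_uncertainty` is a
#' profile-likelihood-style standard error: the curvature of the residual
#' sum of squares profiled over (omega_S, tau0_s) as D varies — this is what
#' makes near-vertical (dispersion-type) trajectories report much larger D
#' errors than solution-type ones.
#'
#' @param points A [tau_beta_points()] data frame (or any data frame with
#'   `tau_s` and `beta` columns); at least 4 points with distinct tau.
#' @param n_starts Number of deterministic multi-starts (default 5).
#' @return List of class `fractal_fit`: `D`, `omega_s`, `tau0_s`,
#'   `D_uncertainty`, `fit_residual` (RSS), `converged`, `tau_range`.
#' @export
fit_trajectory <- function(points, n_starts = 5) {
  if (!is.data.frame(points) || !all(c("tau_s", "beta") %in% names(points)))
    stop("`points` needs columns tau_s and beta")
  tau <- points$tau_s; beta <- points$beta
  if (length(tau) < 4L) stop("at least 4 points are required")
  if (length(unique(tau)) < 4L) stop("at least 4 distinct tau values are required")
  if (any(beta <= 0 | beta > 1)) stop("`beta` must lie in (0, 1]")
  tmin <- min(tau)

  lo <- c(0, log10(1 / tmin), log10(0.01 * tmin))
  hi <- c(3, log10(10 / tmin), log10(1 * tmin) - 1e-9)
  # deterministic multi-starts across the identifiability box
  d0 <- min(max(2 * max(beta), 0.05), 3)
  starts <- list(c(d0, mean(c(lo[2], hi[2])), mean(c(lo[3], hi[3]))))
  grid <- expand.grid(w = c(0.25, 0.75), t0 = c(0.25, 0.75))
  for (i in seq_len(nrow(grid)))
    starts[[i + 1]] <- c(d0, lo[2] + grid$w[i] * (hi[2] - lo[2]),
                         lo[3] + grid$t0[i] * (hi[3] - lo[3]))
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lo, upper = hi,
      fn = function(th) (th[1] / 2) * log(tau * 10^th[2]) / log(tau / 10^th[3]) - beta,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("trajectory fit failed from every start")
  th <- best$par
  converged <- best$info %in% 1:4

  ci <- profile_D_interval(th, lo, hi, tau, beta, best$deviance)
  structure(list(D = th[1], omega_s = 10^th[2], tau0_s = 10^th[3],
                 D_uncertainty = unname((ci[2] - ci[1]) / 2),
                 D_interval = ci,
                 fit_residual = best$deviance,
                 converged = converged,
                 tau_range = range(tau)),
            class = "fractal_fit")
}

# profile-likelihood 1-sigma interval for D: walk a D grid away from the
# optimum, refitting the nuisance pair (wS, tau0) from several starts at
# each step, until the profiled RSS crosses the F-based threshold; the
# crossing is located by linear interpolation. Flat or multimodal valleys
# (near-vertical dispersion-type arcs) produce wide intervals; intervals
# hitting the D in [0, 3] box are truncated there.
profile_D_interval <- function(th, lo, hi, tau, beta, rss0,
                               step = 0.025, max_steps = 120L) {
  n <- length(tau)
  dof <- max(n - 3, 1)
  thr <- rss0 * (1 + stats::qf(0.683, 1, dof) / dof)
  if (!is.finite(thr) || thr <= 0) thr <- rss0 + .Machine$double.eps
  starts <- list(th[2:3],
                 c(mean(c(lo[2], hi[2])), mean(c(lo[3], hi[3]))),
                 c(lo[2] + 0.25 * (hi[2] - lo[2]), lo[3] + 0.75 * (hi[3] - lo[3])),
                 c(lo[2] + 0.75 * (hi[2] - lo[2]), lo[3] + 0.25 * (hi[3] - lo[3])))
  prof <- function(D) {
    devs <- vapply(starts, function(s) {
      fit <- try(minpack.lm::nls.lm(
        par = s, lower = lo[2:3], upper = hi[2:3],
        fn = function(p) (D / 2) * log(tau * 10^p[1]) / log(tau / 10^p[2]) - beta,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) Inf else fit$deviance
    }, numeric(1))
    min(devs)
  }
  walk <- function(dir) {
    d_prev <- th[1]; r_prev <- rss0
    for (k in seq_len(max_steps)) {
      d2 <- th[1] + dir * k * step
      if (d2 < lo[1] || d2 > hi[1]) return(max(min(d2, hi[1]), lo[1]))
      r2 <- prof(d2)
      if (r2 > thr) {
        frac <- if (is.finite(r2) && r2 > r_prev) (thr - r_prev) / (r2 - r_prev) else 0
        return(d_prev + dir * step * max(min(frac, 1), 0))
      }
      d_prev <- d2; r_prev <- r2
    }
    max(min(th[1] + dir * max_steps * step, hi[1]), lo[1])
  }
  c(lower = walk(-1), upper = walk(1))
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D = %.3f +/- %.3f, omega_s = %.3g rad/s, tau0_s = %.3g s\n",
              x$D, x$D_uncertainty, x$omega_s, x$tau0_s))
  cat(sprintf("  RSS = %.3g over tau in [%.3g, %.3g] s (fit-range dependent: D is\n",
              x$fit_residual, x$tau_range[1], x$tau_range[2]))
  cat("  an observation-scale quantity; report it together with this range)\n")
  invisible(x)
}

#' Classify water structure from a fractal dimension
#'
#' Solution systems (mutually penetrating solute and hydrogen-bond
#' networks) have `1 <= D <= 2`; dispersion systems (network fragmented by
#' dispersed particles) have `0 <= D <= 1`. The call is made only when the
#' uncertainty band clears the boundary: solution iff `D - u >= 1`,
#' dispersion iff `D + u <= 1`, otherwise indeterminate (the two regimes
#' genuinely overlap near D = 1).
#'
#' @param D Fractal dimension (>= 0).
#' @param uncertainty 1-sigma uncertainty on D (>= 0).
#' @return `"solution"`, `"dispersion"` or `"indeterminate"`.
#' @examples
#' classify_water_structure(1.74, 0.04)  # solution (collagen-like)
#' classify_water_structure(0.16, 0.05)  # dispersion (globular-protein-like)
#' @export
classify_water_structure <- function(D, uncertainty = 0) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop("`D` must be a finite non-negative scalar")
  u <- if (is.na(uncertainty)) Inf else max(uncertainty, 0)
  sol <- D - u >= 1
  disp <- D + u <= 1
  if (sol && disp) "indeterminate"    # boundary tie (D = 1, u = 0)
  else if (sol) "solution"
  else if (disp) "dispersion"
  else "indeterminate"
}

#' Normalize a gel trajectory by the bulk-solvent trajectory
#'
#' For mixed-solvent gels the bulk solvent mixture itself moves in the
#' tau-beta diagram (sometimes reentrantly) as composition changes.
#' Normalizing the gel relaxation time by the bulk-solvent value at the same
#' composition removes the solvent-mixture contribution, leaving only the
#' restriction exerted by the polymer network; reentrant raw trajectories
#' straighten into ordinary solution-like ones.
#'
#' @param system_points [tau_beta_points()] for the solvent inside the gel;
#'   must carry a numeric `composition` column.
#' @param bulk_points [tau_beta_points()] for the bulk solvent, with
#'   `composition` covering the system compositions (bulk tau is linearly
#'   interpolated in composition; no extrapolation).
#' @return `system_points` with `tau_normalized = tau_gel / tau_bulk`;
#'   compositions outside the bulk range get `NA` and an entry in
#'   `attr(, "errors")`.
#' @export
normalize_by_bulk <- function(system_points, bulk_points) {
  for (nm in c("system_points", "bulk_points")) {
    p <- get(nm)
    if (!is.data.frame(p) || !all(c("tau_s", "beta", "composition") %in% names(p)))
      stop(sprintf("`%s` needs columns tau_s, beta, composition", nm))
  }
  if (anyNA(bulk_points$composition) || anyNA(system_points$composition))
    stop("compositions must be non-missing")
  if (any(bulk_points$tau_s <= 0)) stop("bulk tau must be positive")
  rng <- range(bulk_points$composition)
  out <- system_points
  errors <- character(0)
  inside <- system_points$composition >= rng[1] & system_points$composition <= rng[2]
  tau_bulk <- rep(NA_real_, nrow(system_points))
  if (any(inside)) {
    ord <- order(bulk_points$composition)
    tau_bulk[inside] <- stats::approx(bulk_points$composition[ord],
                                      bulk_points$tau_s[ord],
                                      xout = system_points$composition[inside],
                                      ties = mean)$y
  }
  if (any(!inside))
    errors <- sprintf("composition %.4g outside bulk range [%.4g, %.4g]; not extrapolated",
                      system_points$composition[!inside], rng[1], rng[2])
  out$tau_normalized <- system_points$tau_s / tau_bulk
  attr(out, "errors") <- errors
  out
}

#' Generate a synthetic tau-beta trajectory
#'
#' Draws `n` log-spaced relaxation times in `tau_range`, computes beta from
#' the Ryabov relation at the given (D, omega_s, tau0_s) and optionally adds
#' Gaussian noise to beta (results clipped to (0, 1]). Two branch layouts
#' are provided:
#'
#' * `"rising"` (default): `tau0_s < 1/omega_s`, so beta grows from 0
#'   toward the `D/2` asymptote (tau from 12 ps to 1.2 ns,
#'   `1/omega_s` = 10 ps, `tau0_s` = 1 ps). Never clips for any
#'   `D <= 2`, which makes it the clean layout for recovery studies.
#' * `"descending"`: `tau0_s > 1/omega_s` (`tau0_s` = 4 ps,
#'   `1/omega_s` = 2.5 ps), so beta falls from near 1 toward `D/2` —
#'   the plasticizer-effect trajectory of real aqueous systems, which
#'   starts at the pure-water point and descends with decreasing water
#'   content. Restricting `tau_range` to a narrow window just above
#'   `tau0_s` yields the near-vertical arcs characteristic of dispersion
#'   systems.
#'
#' @param D Fractal dimension of the generated trajectory.
#' @param n Number of points (default 12, a typical concentration series).
#' @param branch `"rising"` or `"descending"` (sets the defaults below).
#' @param omega_s,tau0_s Relation parameters; `NULL` picks the branch
#'   default.
#' @param tau_range Range of tau in seconds (default `c(1.2e-11, 1.2e-9)`).
#' @param beta_noise Gaussian s.d. added to beta (default 0).
#' @param seed Optional integer seed.
#' @return A [tau_beta_points()] data frame.
#' @export
synth_trajectory <- function(D, n = 12, branch = c("rising", "descending"),
                             omega_s = NULL, tau0_s = NULL,
                             tau_range = c(1.2e-11, 1.2e-9),
                             beta_noise = 0, seed = NULL) {
  branch <- match.arg(branch)
  if (is.null(omega_s)) omega_s <- if (branch == "rising") 1e11 else 4e11
  if (is.null(tau0_s)) tau0_s <- if (branch == "rising") 1e-12 else 4e-12
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  tau <- 10^seq(log10(tau_range[1]), log10(tau_range[2]), length.out = n)
  b <- as.numeric(ryabov_beta(tau, D, omega_s, tau0_s))
  if (beta_noise > 0) b <- b + stats::rnorm(n, 0, beta_noise)
  b <- pmin(pmax(b, 1e-4), 1)
  tau_beta_points(tau, b)
}
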