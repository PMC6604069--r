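# Simplified electrostatic model of an open-ended coaxial electrode pressed
# against a sample half-space.
#
# The quasi-static fringing field is obtained by solving
#   div( eps(r,z) grad V ) = 0
# in cylindrical (r, z) coordinates with azimuthal symmetry, on a uniform
# grid: finite-volume 5-point stencil with radial face weights r +/- h/2,
# assembled as a sparse symmetric system and solved directly. Dirichlet
# conditions: inner conductor at `v_inner` (0.2 V), outer conductor and
# ground flange at `v_outer` (0 V), far boundaries 0 V, analytic coax
# profile at the cable mouth; Neumann symmetry at r = 0. This replaces a
# full-wave treatment: adequate for the static fringing potential pattern
# and penetration depth, not for radiation or frequency-dependent probe
# admittance.

#' Build an open-ended coaxial electrode geometry
#'
#' The conductor radius ratio follows from the characteristic impedance of
#' a coaxial line, `Z = (59.96 / sqrt(eps_ins)) * ln(b/a)`, so
#' `b/a = exp(Z * sqrt(eps_ins) / 59.96)`; `b` is set from the outer
#' diameter minus the outer-conductor wall thickness.
#'
#' @param outer_diameter Outer diameter of the outer conductor in meters
#'   (probes of 2.2, 3.6 and 6.3 mm are typical).
#' @param impedance Line impedance in ohms (default 50).
#' @param insulator_eps Relative permittivity of the insulator (default
#'   2.1, PTFE).
#' @param sample_eps Relative permittivity of the sample half-space
#'   (default 78.4, water at 25 C).
#' @param wall_thickness Outer-conductor wall thickness in meters (default
#'   0.3 mm).
#' @param v_inner,v_outer Conductor potentials in volts (defaults 0.2 and 0).
#' @return List of class `coax_geometry` with `inner_radius` (a),
#'   `outer_conductor_inner_radius` (b), `outer_radius`, permittivities and
#'   potentials.
#' @examples
#' g <- coax_geometry(3.6e-3)
#' c(a = g$inner_radius, b = g$outer_conductor_inner_radius)
#' @export
coax_geometry <- function(outer_diameter, impedance = 50, insulator_eps = 2.1,
                          sample_eps = 78.4, wall_thickness = 0.3e-3,
                          v_inner = 0.2, v_outer = 0) {
  stopifnot(outer_diameter > 0, impedance > 0, insulator_eps >= 1, sample_eps >= 1)
  b <- outer_diameter / 2 - wall_thickness
  if (b <= 0) stop("wall thickness leaves no room for the insulator")
  ratio <- exp(impedance * sqrt(insulator_eps) / 59.96)
  a <- b / ratio
  if (a <= 0 || a >= b) stop("infeasible geometry")
  structure(list(outer_diameter = outer_diameter,
                 inner_radius = a,
                 outer_conductor_inner_radius = b,
                 outer_radius = outer_diameter / 2,
                 impedance = impedance,
                 insulator_eps = insulator_eps,
                 sample_eps = sample_eps,
                 v_inner = v_inner, v_outer = v_outer),
            class = "coax_geometry")
}

#' @export
print.coax_geometry <- function(x, ...) {
  cat(sprintf("<coax_geometry> od = %.3g mm, a = %.4g mm, b = %.4g mm (Z = %g ohm)\n",
              1e3 * x$outer_diameter, 1e3 * x$inner_radius,
              1e3 * x$outer_conductor_inner_radius, x$impedance))
  cat(sprintf("  insulator eps = %.3g, sample eps = %.3g, V = %.3g / %.3g V\n",
              x$insulator_eps, x$sample_eps, x$v_inner, x$v_outer))
  invisible(x)
}

#' Solve the axisymmetric electrostatic potential of a coaxial probe
#'
#' @param geometry A [coax_geometry()].
#' @param grid_resolution Grid spacing in meters; default `inner_radius/10`.
#'   Must resolve the inner radius by at least 8 cells.
#' @param domain_size Extent of the sample region beyond the aperture plane
#'   (z > 0) and beyond the outer conductor radially, in meters; default
#'   `3 * outer_diameter` (at least 3 outer radii, as the fringing field
#'   requires).
#' @param cable_length Modeled cable depth below the aperture (default
#'   `3 * b`), deep enough that the field at the mouth is the ideal coax
#'   field.
#' @return List of class `potential_field`: `r`, `z` (coordinate vectors,
#'   m), `potential` (matrix `length(r) x length(z)`, V), `dirichlet`
#'   (logical mask), `geometry`, `residual` (relative algebraic residual of
#'   the solve).
#' @export
solve_potential <- function(geometry, grid_resolution = NULL,
                            domain_size = NULL, cable_length = NULL) {
  stopifnot(inherits(geometry, "coax_geometry"))
  a <- geometry$inner_radius
  b <- geometry$outer_conductor_inner_radius
  r_out <- geometry$outer_radius
  h <- grid_resolution %||% (a / 10)
  if (a / h < 8) stop("grid_resolution must resolve the inner radius by >= 8 cells")
  L_dom <- domain_size %||% (3 * geometry$outer_diameter)
  if (L_dom < 3 * r_out) stop("domain must extend >= 3 outer radii beyond the aperture")
  L_cab <- cable_length %||% (3 * b)

  r <- seq(0, r_out + L_dom, by = h)
  z <- seq(-L_cab, L_dom, by = h)
  nr <- length(r); nz <- length(z)

  # node permittivity: insulator below the aperture plane, sample above
  eps <- matrix(geometry$sample_eps, nr, nz)
  eps[, z <= 0] <- geometry$insulator_eps

  # Dirichlet mask and values
  mask <- matrix(FALSE, nr, nz)
  val <- matrix(0, nr, nz)
  in_cable <- outer(rep(TRUE, nr), z <= 0)
  inner_cond <- in_cable & outer(r <= a + 1e-12, rep(TRUE, nz))
  outer_cond <- in_cable & outer(r >= b - 1e-12, rep(TRUE, nz))
  mask[inner_cond] <- TRUE; val[inner_cond] <- geometry$v_inner
  mask[outer_cond] <- TRUE; val[outer_cond] <- geometry$v_outer
  mask[, nz] <- TRUE                       # far field above
  mask[nr, ] <- TRUE                       # far field radially
  # cable mouth: analytic coax profile
  ins <- which(r > a & r < b)
  mask[ins, 1] <- TRUE
  val[ins, 1] <- geometry$v_outer + (geometry$v_inner - geometry$v_outer) *
    log(b / r[ins]) / log(b / a)

  sol <- solve_var_eps(r, z, eps, mask, val)
  structure(list(r = r, z = z, potential = sol$V, dirichlet = mask,
                 geometry = geometry, residual = sol$residual),
            class = "potential_field")
}

# finite-volume assembly and sparse direct solve of div(eps grad V) = 0 on a
# uniform (r, z) grid with Dirichlet mask/values; returns V and the relative
# residual of the linear solve
solve_var_eps <- function(r, z, eps, mask, val) {
  nr <- length(r); nz <- length(z); h <- r[2] - r[1]
  idx <- matrix(seq_len(nr * nz), nr, nz)
  unk <- which(!mask)
  uid <- rep(NA_integer_, nr * nz)
  uid[unk] <- seq_along(unk)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(length(unk))
  diag_acc <- numeric(length(unk))

  # vectorized face lists: for each unknown node, neighbors E/W/N/S
  ij <- arrayInd(unk, c(nr, nz))
  ri <- ij[, 1]; zi <- ij[, 2]
  rr <- r[ri]
  epsn <- eps[cbind(ri, zi)]

  neigh <- function(dri, dzi, w_face) {
    ok <- ri + dri >= 1 & ri + dri <= nr & zi + dzi >= 1 & zi + dzi <= nz
    p <- idx[cbind(ri[ok], zi[ok])]
    q <- idx[cbind(ri[ok] + dri, zi[ok] + dzi)]
    w <- w_face[ok]
    list(p = p, q = q, w = w, ok = ok)
  }
  eps_at <- function(dri, dzi) {
    i2 <- pmin(pmax(ri + dri, 1), nr); j2 <- pmin(pmax(zi + dzi, 1), nz)
    (epsn + eps[cbind(i2, j2)]) / 2
  }

  # radial faces carry weight r +/- h/2 (finite-volume ring areas); the
  # z-faces of the cell at node r carry weight r (h/8 for the axis cell)
  w_e <- eps_at(1, 0) * (rr + h / 2)
  w_w <- eps_at(-1, 0) * (rr - h / 2)
  w_w[ri == 1] <- 0                         # axis: no inner face
  rz <- ifelse(ri == 1, h / 8, rr)
  w_n <- eps_at(0, 1) * rz
  w_s <- eps_at(0, -1) * rz

  faces <- list(neigh(1, 0, w_e), neigh(-1, 0, w_w),
                neigh(0, 1, w_n), neigh(0, -1, w_s))
  for (f in faces) {
    keep <- f$w > 0
    p <- f$p[keep]; q <- f$q[keep]; w <- f$w[keep]
    up <- uid[p]
    acc <- tapply(w, up, sum)
    diag_acc[as.integer(names(acc))] <- diag_acc[as.integer(names(acc))] + acc
    bdry <- mask[q]
    if (any(bdry)) {
      racc <- tapply(w[bdry] * val[q[bdry]], uid[p[bdry]], sum)
      rhs[as.integer(names(racc))] <- rhs[as.integer(names(racc))] + racc
    }
    if (any(!bdry)) {
      ii <- c(ii, uid[p[!bdry]]); jj <- c(jj, uid[q[!bdry]]); xx <- c(xx, -w[!bdry])
    }
  }
  ii <- c(ii, seq_along(unk)); jj <- c(jj, seq_along(unk)); xx <- c(xx, diag_acc)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(unk), length(unk)))
  v_unk <- as.numeric(Matrix::solve(A, rhs))
  resid <- as.numeric(sqrt(sum((A %*% v_unk - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300))

  V <- val
  V[unk] <- v_unk
  list(V = V, residual = resid)
}

#' Penetration depth of the fringing field
#'
#' Extracts the potential along the symmetry axis above the aperture
#' (`r = 0`, `z >= 0`) and reports two penetration depths:
#' `depth_exponential`, the decay length of a single-exponential fit
#' `V(z) = V_s exp(-z/delta)` over the near region (down to 10% of the
#' surface potential), and `depth_54pct`, the distance at which the
#' potential first falls to 54% of the surface potential on the inner
#' conductor (linearly interpolated between grid points). For an exact
#' exponential profile `depth_54pct = -ln(0.54) * delta ~= 0.616 delta`.
#'
#' @param field A [solve_potential()] result, or a data frame with columns
#'   `z` and `v` giving an axial profile directly.
#' @return List of class `penetration_result`: `depth_exponential`,
#'   `depth_54pct` (m), `surface_potential`, `profile` (data frame `z`, `v`).
#' @export
penetration_depth <- function(field) {
  if (inherits(field, "potential_field")) {
    iz <- which(field$z >= 0)
    profile <- data.frame(z = field$z[iz], v = field$potential[1, iz])
  } else if (is.data.frame(field) && all(c("z", "v") %in% names(field))) {
    profile <- field[order(field$z), ]
  } else stop("`field` must be a potential_field or a data frame with z, v")
  v_s <- profile$v[1]
  if (v_s <= 0) stop("non-positive surface potential on the axis")
  dec <- diff(profile$v)
  if (any(dec > 1e-9 * v_s))
    stop("axial potential is not monotonically decreasing (numerical artifact)")

  # 54% criterion; the crossing is interpolated log-linearly between grid
  # points (exact for an exponential decay, and much less sensitive to the
  # grid spacing than linear interpolation)
  v54 <- 0.54 * v_s
  k <- which(profile$v <= v54)[1]
  if (is.na(k)) stop("potential never falls to 54% inside the domain; enlarge it")
  d54 <- if (k == 1L) 0 else {
    z0 <- profile$z[k - 1]; z1 <- profile$z[k]
    v0 <- profile$v[k - 1]; v1 <- max(profile$v[k], 1e-12 * v_s)
    z0 + (log(v0) - log(v54)) / (log(v0) - log(v1)) * (z1 - z0)
  }

  # single-exponential fit over the near region (V >= 10% of surface)
  near <- profile$v >= 0.1 * v_s & profile$v > 0
  f <- stats::lm(log(v) ~ z, data = profile[near, ])
  delta <- -1 / unname(stats::coef(f)[2])
  if (delta <= 0) stop("exponential fit produced a non-positive decay length")

  structure(list(depth_exponential = delta, depth_54pct = d54,
                 surface_potential = v_s, profile = profile),
            class = "penetration_result")
}

#' @export
print.penetration_result <- function(x, ...) {
  cat(sprintf("<penetration_result> exp-fit depth = %.4g mm, 54%% depth = %.4g mm\n",
              1e3 * x$depth_exponential, 1e3 * x$depth_54pct))
  invisible(x)
}
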