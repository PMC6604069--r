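# Geometric validation models rasterized to binary images / voxel grids:
# the 100-sphere chain, filled / half-filled boxes and straight lines, and
# grayscale binarization for micrographs.

#' Specification of a sphere chain
#'
#' `n_spheres` spheres of radius `radius_r` with centers spaced `spacing_d`
#' apart along one axis, rasterized at `voxel_size` model units per voxel.
#' For `radius_r >> spacing_d` the union is a solid rod; for
#' `radius_r << spacing_d` it is a dotted line.
#'
#' @param n_spheres Number of spheres (>= 1).
#' @param spacing_d Center spacing in model units (> 0).
#' @param radius_r Sphere radius in model units (0.05 to 20 supported).
#' @param voxel_size Voxel edge in model units (> 0).
#' @return An object of class `sphere_chain_spec`.
#' @export
sphere_chain_spec <- function(n_spheres = 100, spacing_d = 1.5,
                              radius_r = 20, voxel_size = 0.5) {
  stopifnot(n_spheres >= 1, spacing_d > 0, voxel_size > 0)
  if (radius_r < 0.05 || radius_r > 20)
    stop("`radius_r` outside the supported range [0.05, 20]")
  structure(list(n_spheres = as.integer(n_spheres), spacing_d = spacing_d,
                 radius_r = radius_r, voxel_size = voxel_size),
            class = "sphere_chain_spec")
}

#' Rasterize a sphere chain to a 3-D voxel grid
#'
#' Centers sit at `i * spacing_d` (i = 0..n-1) on the axis midline; a voxel
#' is occupied iff its center lies within `radius_r` of any sphere center
#' (center-inclusion rasterization: deterministic, no partial-volume
#' weighting). The grid is padded by one radius beyond the occupied extent
#' on every side.
#'
#' @param spec A [sphere_chain_spec()] (or arguments passed to it).
#' @param ... Passed to [sphere_chain_spec()] when `spec` is missing.
#' @return A logical 3-D array of class `voxel_grid` with attributes
#'   `cell_size` (model units) and `spec`.
#' @examples
#' g <- make_sphere_chain(sphere_chain_spec(3, 1.5, 0.6, 0.2))
#' sum(g)  # occupied voxels
#' @export
make_sphere_chain <- function(spec, ...) {
  if (missing(spec)) spec <- sphere_chain_spec(...)
  stopifnot(inherits(spec, "sphere_chain_spec"))
  n <- spec$n_spheres; d <- spec$spacing_d; R <- spec$radius_r
  vox <- spec$voxel_size
  if (vox > R / 2)
    warning("voxel_size > radius_r/2: spheres are under-resolved")
  # occupied extent: axis [-R, (n-1)d + R], cross [-R, R]; pad by R
  ax_lo <- -2 * R; ax_hi <- (n - 1) * d + 2 * R
  nx <- ceiling((ax_hi - ax_lo) / vox)
  nyz <- ceiling(4 * R / vox)
  if (as.double(nx) * nyz * nyz > 1e8)
    stop(sprintf("grid of %d x %d x %d voxels exceeds the 1e8 memory guard",
                 nx, nyz, nyz))
  xc <- ax_lo + (seq_len(nx) - 0.5) * vox        # axis coords of voxel centers
  cr <- -2 * R + (seq_len(nyz) - 0.5) * vox      # cross coords
  # axial distance to the nearest sphere center (guard the rounding midpoint)
  idx <- pmin(pmax(round(xc / d), 0), n - 1)
  dxm <- pmin(abs(xc - idx * d),
              abs(xc - pmin(idx + 1, n - 1) * d),
              abs(xc - pmax(idx - 1, 0) * d))
  d2cross <- outer(cr^2, cr^2, "+")
  occ <- array(FALSE, c(nx, nyz, nyz))
  R2 <- R^2
  for (i in seq_len(nx)) {
    rem <- R2 - dxm[i]^2
    if (rem > 0) occ[i, , ] <- d2cross <= rem
  }
  structure(occ, class = "voxel_grid", cell_size = vox, spec = spec)
}

#' Generate the 2-D box-model validation images
#'
#' * `"full"`: every pixel occupied (dimension 2 at all scales).
#' * `"half"`: left half occupied (same slope, shifted intercept).
#' * `"line"`: solid axis-aligned line of width `line_width` through the
#'   image center, spanning the full extent. The line edge is placed on the
#'   `size/2` pixel boundary so that dyadic box tilings anchored at the
#'   origin see a single box row at every size >= `line_width` — the regime
#'   change at the line width is then exactly the rasterized ideal.
#'
#' @param kind `"full"`, `"half"` or `"line"`.
#' @param size Image edge in pixels (>= 64).
#' @param line_width Line width in pixels (for `kind = "line"`).
#' @param orientation `"horizontal"` (default) or `"vertical"` line.
#' @return A logical matrix of class `binary_image` (TRUE = foreground).
#' @examples
#' img <- make_box_model("line", 512, 2)
#' sum(img)  # 1024 pixels
#' @export
make_box_model <- function(kind = c("full", "half", "line"), size = 512,
                           line_width = 2,
                           orientation = c("horizontal", "vertical")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (size < 64) stop("`size` must be >= 64")
  img <- matrix(FALSE, size, size)
  if (kind == "full") {
    img[] <- TRUE
  } else if (kind == "half") {
    img[, seq_len(size %/% 2)] <- TRUE
  } else {
    if (line_width < 1 || line_width >= size)
      stop("`line_width` must satisfy 1 <= line_width < size")
    rows <- size %/% 2 + seq_len(line_width)
    if (orientation == "horizontal") img[rows, ] <- TRUE else img[, rows] <- TRUE
  }
  structure(img, class = "binary_image")
}

#' Binarize a grayscale image
#'
#' @param img Numeric matrix (single channel); any range.
#' @param threshold Numeric cut, or `"auto"` for the histogram-valley
#'   (maximum between-class variance, Otsu) threshold.
#' @param dark_foreground If `TRUE` (default, matching dark-stained
#'   structures on a light background) pixels with intensity `<= threshold`
#'   become foreground; `FALSE` inverts the polarity.
#' @return A logical matrix of class `binary_image` with attribute
#'   `threshold` recording the cut used.
#' @export
binarize <- function(img, threshold = "auto", dark_foreground = TRUE) {
  if (!is.matrix(img) || !is.numeric(img)) stop("`img` must be a numeric matrix")
  if (identical(threshold, "auto")) {
    if (diff(range(img)) == 0)
      stop("constant image: automatic threshold is undefined")
    threshold <- otsu_threshold(img)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  occ <- if (dark_foreground) img <= threshold else img > threshold
  structure(occ, class = "binary_image", threshold = threshold)
}

#' Histogram-valley (maximum between-class variance) threshold
#'
#' Picks, over a 256-bin histogram, the cut maximizing the between-class
#' variance of the two resulting intensity classes.
#'
#' @param x Numeric vector or matrix of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) stop("constant input: threshold undefined")
  br <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

#' Read / write binary images as PNG
#'
#' Foreground is written as white (255), background as black (0). On read,
#' any pixel above 0.5 (of the 0..1 PNG scale) is foreground; multi-channel
#' files are collapsed by their first channel.
#'
#' @param path File path.
#' @param img A `binary_image` logical matrix (for writing).
#' @return `read_binary_image` returns a `binary_image`;
#'   `write_binary_image` returns `path` invisibly.
#' @export
read_binary_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  structure(a > 0.5, class = "binary_image")
}

#' @rdname read_binary_image
#' @export
write_binary_image <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(matrix(as.numeric(img), nrow(img), ncol(img)), path)
  invisible(path)
}

#' Read / write voxel grids as plain text
#'
#' Plain-text raster: a header (`aquafrac-voxel-grid 1`, dimensions, cell
#' size) followed by one line of 0/1 characters per (row, slice) pair —
#' a human-inspectable flat bitstream.
#'
#' @param grid A `voxel_grid` logical 3-D array (for writing).
#' @param path File path.
#' @return `read_voxel_grid` returns a `voxel_grid`; `write_voxel_grid`
#'   returns `path` invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  dm <- dim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("aquafrac-voxel-grid 1",
               paste("dim", dm[1], dm[2], dm[3]),
               paste("cell_size", format(attr(grid, "cell_size") %||% 1, digits = 17))),
             con)
  for (k in seq_len(dm[3]))
    writeLines(apply(grid[, , k, drop = FALSE], 2,
                     function(col) paste(as.integer(col), collapse = "")), con)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "aquafrac-voxel-grid"))
    stop("not an aquafrac voxel grid file")
  dm <- as.integer(strsplit(lines[2], " ")[[1]][-1])
  cell <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  body <- lines[-(1:3)]
  if (length(body) != dm[2] * dm[3]) stop("corrupt voxel grid: wrong line count")
  occ <- array(FALSE, dm)
  idx <- 1L
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) {
    occ[, j, k] <- strsplit(body[idx], "")[[1]] == "1"
    idx <- idx + 1L
  }
  structure(occ, class = "voxel_grid", cell_size = cell)
}

#' Dump occupied voxel coordinates as xyz text
#'
#' Debug helper: one `x y z` line (voxel indices) per occupied voxel.
#'
#' @param grid A `voxel_grid`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_voxel_xyz <- function(grid, path) {
  ai <- arrayInd(which(grid), dim(grid))
  utils::write.table(ai, path, row.names = FALSE, col.names = c("x", "y", "z"),
                     quote = FALSE)
  invisible(path)
}
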