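test_that("exact tiling counts on a full image", {
  img <- make_box_model("full", 256)
  bc <- box_count(img, c(1, 4, 64, 256))
  expect_equal(bc$n_boxes, c(65536, 4096, 16, 1))
})

test_that("N(1) equals the number of occupied cells", {
  set.seed(5)
  img <- structure(matrix(runif(128^2) < 0.1, 128), class = "binary_image")
  bc <- box_count(img, 1)
  expect_equal(bc$n_boxes, sum(img))
})

test_that("optimized counting equals the brute-force oracle in 2-D and 3-D", {
  set.seed(31)
  for (rep in 1:3) {
    img <- matrix(runif(48 * 64) < runif(1, 0.02, 0.3), 48, 64)
    img[1] <- TRUE
    sizes <- c(1, 2, 3, 4, 8, 16, 32, 48)
    expect_equal(box_count(img, sizes)$n_boxes, naive_box_count(img, sizes))
  }
  arr <- array(runif(32^3) < 0.05, c(32, 32, 32)); arr[1] <- TRUE
  sizes <- c(1, 2, 4, 8, 16, 32)
  expect_equal(box_count(arr, sizes)$n_boxes, naive_box_count(arr, sizes))
})

test_that("counts nest: N(s) <= N(s/2) <= 2^dim N(s) for dyadic sizes", {
  set.seed(77)
  img <- matrix(runif(64^2) < 0.2, 64, 64); img[1] <- TRUE
  bc <- box_count(img)
  expect_true(all(diff(bc$n_boxes) <= 0))
  expect_true(all(bc$n_boxes[-nrow(bc)] <= 4 * bc$n_boxes[-1]))
  arr <- array(runif(32^3) < 0.1, c(32, 32, 32)); arr[1] <- TRUE
  bc3 <- box_count(arr)
  expect_true(all(bc3$n_boxes[-nrow(bc3)] <= 8 * bc3$n_boxes[-1]))
})

test_that("non-dyadic sizes use ceiling tiling", {
  img <- make_box_model("full", 512)
  bc <- box_count(img, c(100, 200))
  expect_equal(bc$n_boxes, c(ceiling(512 / 100)^2, ceiling(512 / 200)^2))
})

test_that("degenerate inputs are rejected", {
  img <- matrix(FALSE, 32, 32)
  expect_error(box_count(img), "no occupied")
  img[5, 5] <- TRUE
  expect_error(box_count(img, 0), ">= 1")
  expect_error(box_count(img, 64), "exceed")
})

test_that("flat sets give their Euclidean dimensions exactly", {
  expect_equal(fit_dimension(box_count(make_box_model("full", 256)))$dimension,
               2, tolerance = 1e-10)
  row1 <- matrix(FALSE, 512, 512); row1[256, ] <- TRUE
  expect_equal(fit_dimension(box_count(row1))$dimension, 1, tolerance = 1e-10)
  expect_error(fit_dimension(box_count(make_box_model("full", 256), c(1, 2))),
               "3 box sizes")
})

test_that("a half-filled box shifts the intercept but not the slope", {
  fd_full <- fit_dimension(box_count(make_box_model("full", 512)))
  fd_half <- fit_dimension(box_count(make_box_model("half", 512)))
  expect_lt(abs(fd_half$dimension - 2), 0.1)
  expect_lt(abs(fd_half$dimension - fd_full$dimension), 0.01)
})

test_that("the width-2 line splits into slopes 2 and 1 at breakpoint 2", {
  seg <- segment_regimes(box_count(make_box_model("line", 512, 2)))
  expect_false(seg$single_regime)
  expect_identical(seg$breakpoint_size, 2L)
  expect_equal(seg$slope_small, 2, tolerance = 1e-10)
  expect_equal(seg$slope_large, 1, tolerance = 1e-10)
})

test_that("a full box is one regime; too-few sizes are rejected", {
  seg <- segment_regimes(box_count(make_box_model("full", 512)))
  expect_true(seg$single_regime)
  expect_equal(seg$single_dimension, 2, tolerance = 1e-10)
  bc <- box_count(make_box_model("full", 512), c(1, 2, 4, 8))
  expect_error(segment_regimes(bc), "at least 6")
})

test_that("scale direction contrasts: thin line vs sparse blobs", {
  # thin line: dimension is higher below the breakpoint than above
  seg_line <- segment_regimes(box_count(make_box_model("line", 512, 2)))
  expect_gt(seg_line$slope_small, seg_line$slope_large)
  # sparse speckle field (micrograph-like): at small boxes the sparse
  # structure gives a dimension below 2, while at large boxes every box is
  # hit and the slope approaches 2
  set.seed(12)
  img <- matrix(FALSE, 512, 512)
  cx <- runif(400, 4, 508); cy <- runif(400, 4, 508)
  xs <- col(img); ys <- row(img)
  for (i in seq_along(cx))
    img[(xs - cx[i])^2 + (ys - cy[i])^2 <= 1.5^2] <- TRUE
  seg_blob <- segment_regimes(box_count(img))
  expect_lt(seg_blob$slope_small, seg_blob$slope_large)
})

test_that("offset averaging keeps counts within the origin-anchored bracket", {
  set.seed(3)
  img <- matrix(runif(128^2) < 0.15, 128, 128); img[1] <- TRUE
  a <- box_count(img, c(4, 8, 16), offsets = "origin")
  b <- box_count(img, c(4, 8, 16), offsets = "average")
  expect_true(all(b$n_boxes > 0))
  expect_true(all(abs(log(b$n_boxes / a$n_boxes)) < log(2)))
  expect_identical(attr(b, "grid_origin_policy"), "average")
})
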