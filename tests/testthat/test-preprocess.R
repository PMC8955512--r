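test_that("common FOV is the source box, clipped with a warning when needed", {
  mr <- volume(array(1:1000, c(10, 10, 10)), spacing = c(10, 10, 10),
               origin = c(5, 5, 5))                      # extent [0,100]^3
  ct <- volume(array(rnorm(14^3), c(14, 14, 14)), spacing = c(10, 10, 10),
               origin = c(-15, -15, -15))                # extent [-20,120]^3
  box <- common_fov(mr, ct)
  expect_equal(box$lower, c(0, 0, 0))
  expect_equal(box$upper, c(100, 100, 100))
  expect_equal(common_fov(mr, mr)$upper, c(100, 100, 100))

  # source exceeding target on one axis: interval intersection per axis
  mr2 <- volume(mr$data, spacing = c(10, 10, 10), origin = c(-25, 5, 5))
  expect_warning(box2 <- common_fov(mr2, ct), "clipping")
  ex <- vol_extent(mr2); ec <- vol_extent(ct)
  expect_equal(box2$lower, pmax(ex$lower, ec$lower))
  expect_equal(box2$upper, pmin(ex$upper, ec$upper))
})

test_that("cropping keeps exactly the voxels whose centres fall in the box", {
  v <- rand_volume(c(10, 10, 10), seed = 2)              # spacing 1, origin 0
  full <- do.call(fov_box, vol_extent(v))
  expect_identical(crop_to_fov(v, full)$data, v$data)

  half <- fov_box(c(-0.5, -0.5, -0.5), c(4.5, 9.5, 9.5))
  cropped <- crop_to_fov(v, half)
  # brute-force oracle: count centres inside the half-open box
  centers <- expand.grid(x = 0:9, y = 0:9, z = 0:9)
  inside <- with(centers, x >= -0.5 & x < 4.5 & y >= -0.5 & y < 9.5 &
                   z >= -0.5 & z < 9.5)
  expect_identical(as.integer(prod(dim(cropped$data))), sum(inside))
  expect_identical(dim(cropped$data), c(5L, 10L, 10L))
  expect_identical(cropped$data, v$data[1:5, , ])

  expect_error(crop_to_fov(v, fov_box(c(100, 100, 100), c(110, 110, 110))),
               "intersect")
})

test_that("resampling at the identity grid reproduces the samples", {
  v <- rand_volume(c(12, 10, 8), seed = 7, spacing = c(2, 1, 3))
  r <- resample(v, dim(v))
  expect_lt(max(abs(r$data - v$data)), 1e-5)
  expect_equal(r$spacing, v$spacing)
  expect_error(resample(v, c(1, 10, 10)), ">= 2")
})

test_that("a linear intensity ramp survives resampling to double resolution", {
  shape <- c(10, 8, 6)
  ramp <- function(p) 2 * p[, 1] - 0.5 * p[, 2] + 0.25 * p[, 3] + 1
  centers <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1,
                                   y = seq_len(shape[2]) - 1,
                                   z = seq_len(shape[3]) - 1))
  v <- volume(array(ramp(centers), shape))
  r <- resample(v, 2 * shape)
  new_centers <- as.matrix(expand.grid(
    x = r$origin[1] + (seq_len(2 * shape[1]) - 1) * r$spacing[1],
    y = r$origin[2] + (seq_len(2 * shape[2]) - 1) * r$spacing[2],
    z = r$origin[3] + (seq_len(2 * shape[3]) - 1) * r$spacing[3]))
  expect_lt(max(abs(r$data - array(ramp(new_centers), 2 * shape))), 1e-10)
})

test_that("normalization maps extremes to -1/+1 and inverts exactly", {
  v <- volume(array(c(0, 5, 10, 5, 5, 5, 5, 5), c(2, 2, 2)))
  n <- normalize_intensity(v)
  expect_equal(sort(unique(round(as.numeric(n$vol$data), 12))), c(-1, 0, 1))

  w <- rand_volume(c(8, 8, 8), seed = 9)
  nw <- normalize_intensity(w)
  expect_equal(min(nw$vol$data), -1, tolerance = 1e-12)
  expect_equal(max(nw$vol$data), 1, tolerance = 1e-12)
  back <- denormalize_intensity(nw$vol, nw$record)
  expect_lt(max(abs(back$data - w$data)), 1e-6)

  expect_error(normalize_intensity(volume(array(3, c(4, 4, 4)))), "constant")
})

test_that("preprocess_pair yields an identical grid in [-1,1] and is geometry-idempotent", {
  raw <- phantom_pair(phantom_spec(), 77)
  pp <- preprocess_pair(raw$mr, raw$ct, target_shape = c(64, 64, 32))
  expect_identical(dim(pp$mr$data), c(64L, 64L, 32L))
  expect_identical(dim(pp$mr$data), dim(pp$ct$data))
  expect_equal(pp$mr$spacing, pp$ct$spacing)
  expect_equal(pp$mr$origin, pp$ct$origin)
  for (vv in list(pp$mr, pp$ct)) {
    expect_equal(min(vv$data), -1, tolerance = 1e-6)
    expect_equal(max(vv$data), 1, tolerance = 1e-6)
  }
  # applying the pipeline to an already-matched pair leaves the grid fixed
  pp2 <- preprocess_pair(pp$mr, pp$ct, target_shape = c(64, 64, 32))
  expect_equal(pp2$mr$spacing, pp$mr$spacing, tolerance = 1e-12)
  expect_equal(pp2$mr$origin, pp$mr$origin, tolerance = 1e-12)
})
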