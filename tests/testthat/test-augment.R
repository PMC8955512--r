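test_that("the schedule enumerates all 512 fixed triples in the printed order", {
  triples <- vapply(0:511, fixed_triple, numeric(3))
  expect_identical(ncol(unique(t(triples))), 3L)
  expect_identical(nrow(unique(t(triples))), 512L)
  expect_equal(fixed_triple(0), c(1, 1, 1))
  expect_equal(fixed_triple(1), c(1, 1, -1))
  expect_equal(fixed_triple(2), c(1, 1, 3))
  expect_equal(fixed_triple(8), c(1, -1, 1))      # y advances after 8 z-steps
  expect_equal(fixed_triple(64), c(-1, 1, 1))     # x advances after 64 steps
  expect_equal(fixed_triple(511), c(-7, -7, -7))
  # cycle of length 512
  for (e in c(0, 17, 300)) expect_equal(fixed_triple(e), fixed_triple(e + 512))
  expect_true(all(abs(triples) %in% c(1, 3, 5, 7)))
})

test_that("one augmentation period is 512 epochs of n subjects", {
  expect_identical(augmentation_period(26), 13312L)
  expect_identical(augmentation_period(4), 2048L)
})

test_that("angle draws are jittered within (-1,1), reproducible, and centred", {
  s <- rotation_schedule(seed = 5)
  s2 <- rotation_schedule(seed = 5)
  for (e in c(0, 3, 511, 512)) {
    a <- draw_angles(s, e)
    expect_true(all(abs(a - fixed_triple(e)) < 1))
    expect_identical(a, draw_angles(s2, e))       # same seed, same draws
  }
  expect_false(identical(draw_angles(rotation_schedule(1), 0),
                         draw_angles(rotation_schedule(2), 0)))
  # Monte-Carlo mean of the uniform(-1,1) jitter
  jit <- vapply(0:3332, function(e) draw_angles(s, e) - fixed_triple(e),
                numeric(3))
  expect_lt(abs(mean(jit)), 0.02)
})

test_that("rotation is the identity at zero angles and equivariant on pairs", {
  v <- blob_volume(c(24, 24, 16), spacing = c(2, 2, 3))
  r0 <- rotate_volume(v, c(0, 0, 0))
  expect_lt(max(abs(r0$data - v$data)), 1e-6)

  pair <- paired_sample(v, v)                      # CT == MR
  rot <- rotate_pair(pair, c(4.4, -2.2, 6.1))
  expect_identical(rot$mr$data, rot$ct$data)       # identical transforms
  expect_identical(dim(rot$mr$data), dim(v$data))
})

test_that("rotating forward then inverse restores a smooth phantom", {
  v <- blob_volume(c(28, 28, 20))
  ang <- c(5, 7, -3)
  back <- rotate_volume(rotate_volume(v, ang, fill = 0), ang,
                        inverse = TRUE, fill = 0)
  expect_gt(mssim(back, v, ssim_params(window = 7)), 0.98)
})

test_that("rotation preserves the intensity range up to interpolation overshoot", {
  pp <- tiny_phantom_pairs(2)[[1]]
  rot <- rotate_pair(pp, c(6.5, -4.2, 7.9))
  for (vv in list(rot$mr$data, rot$ct$data)) {
    expect_gte(min(vv), -1 - 0.02 * 2)             # trilinear cannot overshoot,
    expect_lte(max(vv), 1 + 0.02 * 2)              # bound kept for safety
  }
})
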