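test_that("kernel mixing is the exact 1:1:1 mean with convex bounds", {
  a <- rand_volume(c(8, 8, 8), seed = 1)
  expect_identical(merge_kernels(a, a, a)$data, a$data)
  consts <- lapply(c(0, 0.3, 0.6), function(v) array(v, c(4, 4, 4)))
  expect_true(all(merge_kernels(consts[[1]], consts[[2]], consts[[3]])$data == 0.3))
  b <- rand_volume(c(8, 8, 8), seed = 2)
  c3 <- rand_volume(c(8, 8, 8), seed = 3)
  mix <- merge_kernels(a, b, c3)$data
  expect_true(all(mix <= pmax(a$data, b$data, c3$data) + 1e-15))
  expect_true(all(mix >= pmin(a$data, b$data, c3$data) - 1e-15))
  expect_error(merge_kernels(a, rand_volume(c(4, 4, 4))), "share one shape")
})

test_that("range alignment maps endpoints, midpoints and self consistently", {
  p <- volume(array(seq(-0.8, 0.9, length.out = 64), c(4, 4, 4)))
  ref <- structure(list(min = -1, max = 1), class = "range_stats")
  out <- align_range(p, ref)
  expect_equal(min(out$data), -1, tolerance = 1e-12)
  expect_equal(max(out$data), 1, tolerance = 1e-12)
  # midpoint maps to midpoint
  mid_in <- (min(p$data) + max(p$data)) / 2
  mid_idx <- which.min(abs(p$data - mid_in))
  expect_equal(out$data[mid_idx],
               -1 + (p$data[mid_idx] - min(p$data)) * 2 / (max(p$data) - min(p$data)),
               tolerance = 1e-12)
  # aligning to one's own range is the exact identity
  expect_identical(align_range(p, range_stats(p))$data, p$data)
  expect_warning(align_range(volume(array(1, c(4, 4, 4))), ref), "constant")
})

test_that("synthesis with identity generators is the exact identity", {
  # every 32^3 patch of this periodic volume holds the full value range,
  # so p3-range alignment is an exact pass-through everywhere
  x <- sin(2 * pi * (0:63) / 16)
  arr <- outer(outer(x, x, `+`), rep(0, 32), `+`)
  v <- volume(array(arr, c(64, 64, 32)), spacing = c(3, 3, 4))
  lay <- default_layout(c(64, 64, 32), c(32, 32, 32))

  id_model <- structure(list(generator = structure(list(), class = "idgen"),
                             cfg = generator_config(k = 4, f = 4, depth = 2),
                             out_range = c(min = -1, max = 1),
                             history = tibble::tibble(iteration = 1L)),
                        class = "vox_model")
  registerS3method("predict", "idgen", function(object, newdata, ...) newdata,
                   envir = asNamespace("voxsynth"))
  models <- setNames(rep(list(id_model), 5), sprintf("p%d_k4_f4", 1:5))
  bundle <- model_bundle(models, lay, "k4_f4")
  out <- synthesize(v, bundle)
  expect_identical(out$data, v$data)
  expect_identical(dim(out$data), c(64L, 64L, 32L))
})

test_that("an incomplete bundle is rejected with the missing keys named", {
  lay <- default_layout(c(64, 64, 32), c(32, 32, 32))
  id_model <- structure(list(), class = "vox_model")
  models <- setNames(rep(list(id_model), 4), sprintf("p%d_k4_f4", 1:4))
  bundle <- model_bundle(models, lay, "k4_f4")
  expect_error(synthesize(volume(array(0.5, c(64, 64, 32))), bundle),
               "p5_k4_f4")
})
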