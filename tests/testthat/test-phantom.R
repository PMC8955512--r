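test_that("phantom pairs are deterministic given their seeds", {
  spec <- phantom_spec(noise_sd = 0)
  a <- phantom_pair(spec, 123)
  b <- phantom_pair(spec, 123)
  expect_identical(a$mr$data, b$mr$data)
  expect_identical(a$ct$data, b$ct$data)
  c <- phantom_pair(spec, 124)
  expect_false(identical(a$ct$data, c$ct$data))
  # noisy generation is equally reproducible
  spec_n <- phantom_spec(noise_sd = 0.01)
  expect_identical(phantom_pair(spec_n, 9)$mr$data,
                   phantom_pair(spec_n, 9)$mr$data)
})

test_that("tissue classes partition the grid", {
  p <- phantom_pair(phantom_spec(), 55)
  counts <- tabulate(p$mr_classes + 1L, nbins = 5)
  expect_identical(sum(counts), length(p$mr_classes))
  expect_true(counts[1] > 0)                 # air background present
  expect_true(counts[2] > 0 && counts[3] > 0)  # skull and brain present
})

test_that("the generated target equals the class-map oracle at zero noise", {
  spec <- phantom_spec(noise_sd = 0)
  p <- phantom_pair(spec, 321)
  expect_identical(p$ct$data, phantom_ct_intensity(p$ct_classes, p$ct_tex))
  expect_identical(p$mr$data, phantom_mr_intensity(p$mr_classes, p$mr_tex))
})

test_that("the source grid is finer and smaller than the target grid", {
  p <- phantom_pair(phantom_spec(), 7)
  em <- vol_extent(p$mr); ec <- vol_extent(p$ct)
  expect_true(all(em$lower > ec$lower) && all(em$upper < ec$upper))
  expect_true(all(p$mr$spacing < p$ct$spacing))
})

test_that("subjects are distinct and the split yields 26 train / 5 test", {
  pairs <- phantom_dataset(phantom_spec(), 31, seed = 3)
  expect_length(pairs, 31)
  # the configured fraction of subjects are outliers with extreme pathology
  outs <- vapply(pairs, function(p) isTRUE(p$outlier), TRUE)
  expect_identical(sum(outs), 2L)
  expect_true(all(vapply(pairs[outs], function(p)
    nrow(p$geometry$lesions) >= 4, TRUE)))
  sp <- split_phantoms(pairs, n_test = 5)
  expect_length(sp$train, 26)
  expect_length(sp$test, 5)
  expect_identical(sum(vapply(sp$test, function(p) isTRUE(p$outlier), TRUE)), 2L)
  expect_identical(sum(vapply(sp$train, function(p) isTRUE(p$outlier), TRUE)), 0L)

  # inter-subject variation: different subjects' targets are not near-identical
  subs <- pairs[c(1, 8, 15)]
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(mssim(subs[[i]]$ct, subs[[j]]$ct), 0.99)
})

test_that("the do-nothing baseline leaves headroom for translation", {
  pp <- tiny_phantom_pairs(3)
  for (p in pp) expect_lt(mssim(p$mr, p$ct), 0.9)
})
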