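test_that("all five indices take their identity values on identical volumes", {
  A <- rand_volume(c(32, 32, 32), seed = 21)
  expect_equal(cad(A, A), 1, tolerance = 1e-12)
  expect_equal(l2_distance(A, A), 0)
  expect_equal(mse(A, A), 0)
  expect_identical(psnr(A, A), Inf)
  expect_equal(mssim(A, A), 1, tolerance = 1e-12)
  rep <- evaluate_pair(A, A)
  expect_equal(unlist(rep[c("cad", "l2", "mse", "mssim")]),
               c(cad = 1, l2 = 0, mse = 0, mssim = 1), tolerance = 1e-12)
  expect_identical(rep$psnr, Inf)
})

test_that("cad matches hand-computed cosines and flags degenerate input", {
  A <- array(0, c(2, 2, 2)); A[1] <- 1
  B <- array(0, c(2, 2, 2)); B[1] <- 1; B[2] <- 1
  expect_equal(cad(A, B), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cad(A, -1 * A), -1)
  expect_error(cad(A, array(0, c(2, 2, 2))), "all-zero")
  expect_error(cad(A, array(1, c(2, 2, 1))), "identical shapes")
})

test_that("l2 is the rooted Euclidean distance and a metric", {
  A <- array(0, c(2, 2, 1)); B <- array(3, c(2, 2, 1))
  expect_equal(l2_distance(A, B), 6)                 # sqrt(4 * 9)
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- array(rnorm(64), c(4, 4, 4)); y <- array(rnorm(64), c(4, 4, 4))
      z <- array(rnorm(64), c(4, 4, 4))
      expect_lte(l2_distance(x, z),
                 l2_distance(x, y) + l2_distance(y, z) + 1e-12)
      expect_equal(l2_distance(x, y), l2_distance(y, x))
    }
  })
})

test_that("mse/psnr follow their closed forms and the range scaling law", {
  A <- array(0.5, c(4, 4, 4)); B <- A + 0.1
  expect_equal(mse(A, B), 0.01, tolerance = 1e-12)
  expect_equal(psnr(A, B, L = 1), 20, tolerance = 1e-9)
  expect_equal(psnr(A, B, L = 1) - psnr(A, B, L = 0.5), 20 * log10(2),
               tolerance = 1e-9)
})

test_that("mssim agrees with a brute-force per-window oracle", {
  A <- rand_volume(c(16, 16, 16), seed = 41)
  B <- volume(A$data * 0.8 + array(rnorm(16^3, 0, 0.3), c(16, 16, 16)))
  pars <- ssim_params()                              # Gaussian 11^3
  expect_equal(mssim(A, B, pars), mssim_bruteforce(A, B, pars),
               tolerance = 1e-8)
  up <- ssim_params(window_type = "uniform")         # uniform 7^3 alternative
  expect_equal(mssim(A, B, up), mssim_bruteforce(A, B, up), tolerance = 1e-8)
})

test_that("mssim is symmetric and degrades monotonically with disruption", {
  A <- rand_volume(c(16, 16, 16), seed = 43)
  B <- rand_volume(c(16, 16, 16), seed = 44)
  expect_equal(mssim(A, B), mssim(B, A), tolerance = 1e-12)
  noisy <- volume(A$data + array(rnorm(16^3, 0, 0.05), c(16, 16, 16)))
  inverted <- volume(1 - A$data)                     # structural disruption
  expect_lt(mssim(A, inverted), mssim(A, noisy))
  expect_error(mssim(rand_volume(c(8, 8, 8)), rand_volume(c(8, 8, 8))),
               "window")
})

test_that("evaluate_pair reports finite indices and the reporting format", {
  pairs <- tiny_phantom_pairs(4)
  reports <- do.call(rbind, lapply(pairs, function(p)
    evaluate_pair(p$ct, p$mr)))
  expect_true(all(is.finite(unlist(reports))))
  # mean +/- sd summary over a small test set, one value per index
  summ <- vapply(reports, function(col) c(mean(col), sd(col)), numeric(2))
  expect_identical(dim(summ), c(2L, 5L))
  expect_true(all(is.finite(summ)))
})
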