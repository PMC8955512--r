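test_that("a random-weight generator maps shape to shape inside (-1,1)", {
  cfg <- generator_config(k = 4, f = 4, depth = 2)
  G <- build_generator(cfg, c(32, 32, 32), seed = 2)
  x <- withr::with_seed(3, array(runif(32^3, -1, 1), c(32, 32, 32)))
  y <- predict(G, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y > -1 & y < 1))
  expect_identical(y, predict(G, x))                   # inference determinism
  expect_error(build_generator(cfg, c(30, 30, 30)), "divisible")
  # non-cubic patches work as long as each side divides
  G2 <- build_generator(generator_config(k = 4, f = 4, depth = 3),
                        c(32, 32, 16), seed = 2)
  x2 <- array(0.1, c(32, 32, 16))
  expect_identical(dim(predict(G2, x2)), c(32L, 32L, 16L))
})

test_that("full-size presets have parameter counts in the hundreds of millions", {
  n46 <- generator_n_params(preset_config("k6_f60"), c(128, 128, 128))
  n48 <- generator_n_params(preset_config("k4_f80"), c(128, 128, 128))
  n83 <- generator_n_params(preset_config("k8_f30"), c(128, 128, 128))
  for (n in c(n46, n48, n83)) {
    expect_gt(n, 1e8)
    expect_lt(n, 1e9)
  }
})

test_that("the discriminator emits a smaller score grid in (0,1)", {
  cfg <- generator_config(k = 4, f = 4, depth = 2)
  D <- build_discriminator(cfg, c(16, 16, 16), depth = 2, seed = 5)
  cond <- withr::with_seed(6, array(runif(16^3, -1, 1), c(16, 16, 16)))
  cand <- withr::with_seed(7, array(runif(16^3, -1, 1), c(16, 16, 16)))
  sc <- discriminator_scores(D, cond, cand)
  expect_true(all(dim(sc) < 16))
  expect_true(all(sc > 0 & sc < 1))
  expect_error(discriminator_scores(D, cond, array(0, c(8, 8, 8))), "match")
})

test_that("scores outside an element's receptive field never move", {
  cfg <- generator_config(k = 4, f = 4, depth = 2)
  D <- build_discriminator(cfg, c(16, 16, 16), depth = 1, seed = 9)
  rf <- discriminator_receptive_field(D)
  expect_identical(rf, 10)                             # 4 then 4 at jump 2
  cond <- withr::with_seed(8, array(runif(16^3, -1, 1), c(16, 16, 16)))
  cand <- withr::with_seed(9, array(runif(16^3, -1, 1), c(16, 16, 16)))
  base <- discriminator_scores(D, cond, cand)
  # corner score element: its receptive field cannot reach the far corner
  pert <- cand; pert[16, 16, 16] <- pert[16, 16, 16] + 5
  moved <- discriminator_scores(D, cond, pert)
  expect_identical(moved[1, 1, 1], base[1, 1, 1])
  # but a perturbation inside the field does move it
  pert2 <- cand; pert2[2, 2, 2] <- pert2[2, 2, 2] + 5
  expect_false(discriminator_scores(D, cond, pert2)[1, 1, 1] == base[1, 1, 1])
})

test_that("losses hit their closed forms at the textbook equilibrium", {
  x <- withr::with_seed(10, array(runif(4^3, -1, 1), c(4, 4, 4)))
  half <- array(0.5, c(2, 2, 2))
  eq <- cgan_losses(half, half, x, x)
  expect_equal(eq$loss_d, 2 * log(2), tolerance = 1e-6)
  expect_equal(eq$loss_g, log(2), tolerance = 1e-6)    # lambda term is zero
  # constant deviation 0.1 with lambda 100 adds exactly 10 to loss_g
  shifted <- cgan_losses(half, half, x, x + 0.1)
  expect_equal(shifted$loss_g - eq$loss_g, 10, tolerance = 1e-9)
  # lambda = 0 leaves the pure adversarial term
  expect_equal(cgan_losses(half, half, x, x + 0.1, lambda = 0)$loss_g,
               log(2), tolerance = 1e-6)
  expect_error(cgan_losses(half, half, x, array(0, c(2, 2, 2))), "match")
})

test_that("training bookkeeping, determinism, and loss improvement hold", {
  # identity task: target equals source on tiny 8^3 patches
  pairs <- withr::with_seed(12, lapply(1:3, function(i) {
    v <- volume(array(runif(8^3, -1, 1), c(8, 8, 8)))
    paired_sample(v, v)
  }))
  cfg <- generator_config(k = 4, f = 4, depth = 2)
  m <- train_model(pairs, cfg, iterations = 50, eval_every = 10, seed = 31,
                   disc_depth = 1, ssim_window = 5)
  expect_identical(nrow(m$history), 5L)                # 50 / eval_every
  expect_identical(m$history$iteration, seq(10L, 50L, 10L))
  expect_lt(m$history$l1[5], m$history$l1[1])          # learning happened
  expect_true(is.finite(m$out_range[["min"]]) &&
              m$out_range[["min"]] < m$out_range[["max"]])

  m2 <- train_model(pairs, cfg, iterations = 50, eval_every = 10, seed = 31,
                    disc_depth = 1, ssim_window = 5)
  expect_identical(m$history, m2$history)              # reproducible
  expect_identical(m$generator$params, m2$generator$params)

  m3 <- train_model(pairs, cfg, iterations = 50, eval_every = 10, seed = 32,
                    disc_depth = 1, ssim_window = 5)
  expect_false(identical(m$history, m3$history))
})

test_that("an augmented run differs from an unaugmented one only via the schedule", {
  pairs <- withr::with_seed(14, lapply(1:2, function(i) {
    v <- volume(array(runif(16^3, -1, 1), c(16, 16, 16)))
    paired_sample(v, volume(-v$data))
  }))
  cfg <- generator_config(k = 4, f = 4, depth = 2)
  m_off <- train_model(pairs, cfg, iterations = 6, eval_every = 6, seed = 1,
                       disc_depth = 1, ssim_window = 5)
  m_on <- train_model(pairs, cfg, iterations = 6, eval_every = 6, seed = 1,
                      schedule = rotation_schedule(4), disc_depth = 1,
                      ssim_window = 5)
  expect_false(identical(m_off$history, m_on$history))
})
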