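# Shared fixtures, built once per test run.

# A smooth deterministic blob volume (no RNG needed).
blob_volume <- function(shape = c(24, 24, 16), spacing = c(1, 1, 1)) {
  cx <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - cx[1]) / shape[1]
  y <- (seq_len(shape[2]) - cx[2]) / shape[2]
  z <- (seq_len(shape[3]) - cx[3]) / shape[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  volume(exp(-r2 * 18), spacing = spacing)
}

rand_volume <- function(shape = c(16, 16, 16), seed = 1, spacing = c(1, 1, 1)) {
  withr::with_seed(seed, volume(array(rnorm(prod(shape)), shape), spacing))
}

# One small preprocessed phantom pair list, cached across tests.
tiny_phantom_cache <- new.env(parent = emptyenv())
tiny_phantom_pairs <- function(n = 4, grid = c(64, 64, 32), seed = 11) {
  key <- paste(n, paste(grid, collapse = "x"), seed, sep = "_")
  if (is.null(tiny_phantom_cache[[key]])) {
    raw <- phantom_dataset(phantom_spec(), n, seed = seed)
    tiny_phantom_cache[[key]] <- lapply(seq_along(raw), function(i)
      preprocess_pair(raw[[i]]$mr, raw[[i]]$ct, target_shape = grid,
                      subject_id = sprintf("s%02d", i)))
  }
  tiny_phantom_cache[[key]]
}

# Independent brute-force MSSIM oracle: direct per-window weighted sums.
mssim_bruteforce <- function(A, B, params = ssim_params()) {
  a <- as.array(A); b <- as.array(B)
  w1 <- params$w1
  L <- params$window
  w3 <- outer(outer(w1, w1), w1)          # unit-sum 3D window
  d <- dim(a)
  vals <- c()
  for (k in seq_len(d[3] - L + 1))
    for (j in seq_len(d[2] - L + 1))
      for (i in seq_len(d[1] - L + 1)) {
        wa <- a[i:(i + L - 1), j:(j + L - 1), k:(k + L - 1)]
        wb <- b[i:(i + L - 1), j:(j + L - 1), k:(k + L - 1)]
        muA <- sum(w3 * wa); muB <- sum(w3 * wb)
        sA <- sqrt(max(sum(w3 * (wa - muA)^2), 0))
        sB <- sqrt(max(sum(w3 * (wb - muB)^2), 0))
        cov <- sum(w3 * (wa - muA) * (wb - muB))
        l <- (2 * muA * muB + params$C1) / (muA^2 + muB^2 + params$C1)
        cc <- (2 * sA * sB + params$C2) / (sA^2 + sB^2 + params$C2)
        s <- (cov + params$C3) / (sA * sB + params$C3)
        vals <- c(vals, l * cc * s)
      }
  mean(vals)
}
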