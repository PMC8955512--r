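#' Cosine angle distance between two volumes
#'
#' Both volumes are flattened to vectors; the statistic is the cosine of
#' the angle between them, `sum(A * B) / (||A|| * ||B||)`, so identical
#' volumes score 1 and anti-parallel volumes -1.
#'
#' @param A,B [volume()]s or 3D arrays of identical shape.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
cad <- function(A, B) {
  a <- as.numeric(vol_data(A)); b <- as.numeric(vol_data(B))
  check_same_shape(A, B)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("cosine angle distance is undefined for an all-zero volume")
  sum(a * b) / (na * nb)
}

#' Euclidean (L2) distance between two volumes
#'
#' `sqrt(sum((A - B)^2))` over all voxels.
#'
#' @inheritParams cad
#' @return Non-negative scalar in intensity units.
#' @export
l2_distance <- function(A, B) {
  check_same_shape(A, B)
  sqrt(sum((vol_data(A) - vol_data(B))^2))
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `mse` is the mean squared voxel difference; `psnr` is
#' `10 * log10(L^2 / mse)` in dB for data range `L`, reported as `Inf` for
#' identical inputs.
#'
#' @inheritParams cad
#' @param L data range of the intensities (1 for volumes rescaled to
#'   \eqn{[0, 1]}).
#' @return Scalar.
#' @export
mse <- function(A, B) {
  check_same_shape(A, B)
  mean((vol_data(A) - vol_data(B))^2)
}

#' @rdname mse
#' @export
psnr <- function(A, B, L = 1) {
  stopifnot(L > 0)
  m <- mse(A, B)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

#' Parameters of the structural-similarity computation
#'
#' The default window is a 3D circular-symmetric Gaussian with a standard
#' deviation of 1.5 samples on an 11-voxel side, normalized to unit sum;
#' `window_type = "uniform"` switches to a flat window (side 7 by
#' convention) instead. Stability constants follow the standard choice
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`, and the three
#' factor exponents are all 1.
#'
#' @param window window side length in voxels.
#' @param sigma Gaussian standard deviation in samples.
#' @param window_type `"gaussian"` or `"uniform"`.
#' @param L data range of the compared volumes.
#' @param alpha,beta,gamma exponents of the luminance, contrast and
#'   structure factors.
#' @return An `ssim_params` object.
#' @export
ssim_params <- function(window = NULL, sigma = 1.5,
                        window_type = c("gaussian", "uniform"), L = 1,
                        alpha = 1, beta = 1, gamma = 1) {
  window_type <- match.arg(window_type)
  window <- as.integer(window %||% if (window_type == "gaussian") 11L else 7L)
  stopifnot(window >= 2L, L > 0)
  w1 <- if (window_type == "gaussian") {
    d <- seq_len(window) - (window + 1) / 2
    exp(-d^2 / (2 * sigma^2))
  } else rep(1, window)
  structure(list(window = window, w1 = w1 / sum(w1), sigma = sigma,
                 window_type = window_type, L = L,
                 C1 = (0.01 * L)^2, C2 = (0.03 * L)^2, C3 = (0.03 * L)^2 / 2,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "ssim_params")
}

#' Mean structural similarity of two volumes
#'
#' SSIM compares local luminance, contrast and structure: within each
#' sliding window (one per valid voxel position) weighted means, weighted
#' standard deviations and the weighted covariance of the two volumes are
#' combined into
#' \deqn{SSIM = l^\alpha c^\beta s^\gamma,\quad
#'   l = \frac{2\mu_A\mu_B + C_1}{\mu_A^2 + \mu_B^2 + C_1},\
#'   c = \frac{2\sigma_A\sigma_B + C_2}{\sigma_A^2 + \sigma_B^2 + C_2},\
#'   s = \frac{\sigma_{AB} + C_3}{\sigma_A\sigma_B + C_3},}
#' and MSSIM is the mean of the per-window scores. Identical volumes score
#' exactly 1; the statistic is symmetric in its arguments.
#'
#' @inheritParams cad
#' @param params an [ssim_params()].
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
mssim <- function(A, B, params = ssim_params()) {
  stopifnot(inherits(params, "ssim_params"))
  a <- vol_data(A); b <- vol_data(B)
  check_same_shape(A, B)
  if (any(dim(a) < params$window))
    stop("volume smaller than the ", params$window, "-voxel SSIM window")
  w <- params$w1
  muA <- cpp_sepfilter3_valid(a, w)
  muB <- cpp_sepfilter3_valid(b, w)
  vA <- cpp_sepfilter3_valid(a * a, w) - muA * muA
  vB <- cpp_sepfilter3_valid(b * b, w) - muB * muB
  covAB <- cpp_sepfilter3_valid(a * b, w) - muA * muB
  sA <- sqrt(pmax(vA, 0)); sB <- sqrt(pmax(vB, 0))
  l <- (2 * muA * muB + params$C1) / (muA^2 + muB^2 + params$C1)
  cc <- (2 * sA * sB + params$C2) / (sA^2 + sB^2 + params$C2)
  s <- (covAB + params$C3) / (sA * sB + params$C3)
  mean(l^params$alpha * cc^params$beta * s^params$gamma)
}

#' Full similarity report for a target/prediction pair
#'
#' Computes all five indices. The cosine angle distance and Euclidean
#' distance use the raw intensities; for MSE, PSNR and MSSIM both volumes
#' are first rescaled onto \eqn{[0, 1]} by one affine map over their joint
#' intensity range, so the data range is `L = 1`.
#'
#' @param target the measured volume.
#' @param prediction the synthetic volume on the same grid.
#' @param params an [ssim_params()] for the MSSIM term.
#' @param rescale rescale to \eqn{[0, 1]} before MSE/PSNR/MSSIM (default).
#' @return A one-row tibble with columns `cad`, `l2`, `mse`, `psnr`,
#'   `mssim`. Identical inputs give (1, 0, 0, Inf, 1).
#' @export
evaluate_pair <- function(target, prediction, params = ssim_params(),
                          rescale = TRUE) {
  check_same_shape(target, prediction)
  a <- vol_data(target); b <- vol_data(prediction)
  if (rescale) {
    lo <- min(a, b); hi <- max(a, b)
    if (hi > lo) {
      a01 <- (a - lo) / (hi - lo); b01 <- (b - lo) / (hi - lo)
    } else { a01 <- a * 0; b01 <- b * 0 }
  } else { a01 <- a; b01 <- b }
  tibble::tibble(cad = cad(a, b), l2 = l2_distance(a, b),
                 mse = mse(a01, b01), psnr = psnr(a01, b01, L = params$L),
                 mssim = mssim(a01, b01, params))
}

check_same_shape <- function(A, B) {
  if (!identical(dim(vol_data(A)), dim(vol_data(B))))
    stop("volumes must have identical shapes")
  invisible(TRUE)
}
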