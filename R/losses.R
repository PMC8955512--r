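#' Conditional GAN losses with L1 reconstruction
#'
#' The discriminator loss is the negative log likelihood of labelling the
#' measured pair real and the synthetic pair fake,
#' `loss_D = -mean(log D(c, x)) - mean(log(1 - D(c, G(c, z))))`.
#' The generator loss uses the non-saturating adversarial form plus the
#' L1 reconstruction term weighted by `lambda`,
#' `loss_G = -mean(log D(c, G(c, z))) + lambda * mean(|x - G(c, z)|)`,
#' with `lambda = 100` by default. Scores at exactly 0 or 1 are clamped to
#' `[eps, 1 - eps]` before the logs.
#'
#' @param d_real,d_fake discriminator score grids (values in (0, 1)) for
#'   the measured and synthetic candidate respectively.
#' @param target the measured target patch.
#' @param prediction the generator output, same shape as `target`.
#' @param lambda weight of the L1 term (default 100).
#' @param eps clamping epsilon for degenerate scores.
#' @return List with `loss_d`, `loss_g` and the unweighted `l1` term.
#' @examples
#' # at the equilibrium score 0.5 with perfect reconstruction:
#' x <- array(0, c(4, 4, 4))
#' cgan_losses(array(0.5, c(2, 2, 2)), array(0.5, c(2, 2, 2)), x, x)
#' @export
cgan_losses <- function(d_real, d_fake, target, prediction, lambda = 100,
                        eps = 1e-7) {
  d_real <- as.numeric(d_real); d_fake <- as.numeric(d_fake)
  target <- vol_data(target); prediction <- vol_data(prediction)
  if (!identical(dim(target), dim(prediction)))
    stop("target and prediction shapes must match")
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    message("discriminator scores at 0/1 clamped to [", eps, ", 1-", eps, "]")
  }
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  l1 <- mean(abs(target - prediction))
  list(loss_d = -mean(log(d_real)) - mean(log(1 - d_fake)),
       loss_g = -mean(log(d_fake)) + lambda * l1,
       l1 = l1)
}
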