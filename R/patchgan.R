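#' Build a PatchGAN conditional discriminator
#'
#' The discriminator sees the channel concatenation of the condition (the
#' source/MR patch) and a candidate (measured or synthetic target) and maps
#' it to a grid of scores in (0, 1), one per output element, each judging
#' only its own receptive field. The body is `depth` stride-2 convolutions
#' (filters doubling from `f`, instance normalization after all but the
#' first, LeakyReLU activations) followed by a stride-1 convolution to one
#' channel and a sigmoid.
#'
#' @param cfg a [generator_config()]; kernel size and base filters are
#'   shared with the paired generator.
#' @param input_shape voxel counts of the condition/candidate patches.
#' @param depth number of stride-2 levels (default 3, keeping the judgment
#'   receptive-field-limited).
#' @param seed optional weight-initialization seed.
#' @return A `vox_discriminator`.
#' @export
build_discriminator <- function(cfg, input_shape = c(128, 128, 128),
                                depth = 3L, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  input_shape <- as.integer(input_shape)
  depth <- as.integer(depth)
  if (any(input_shape %% (2L^depth) != 0L))
    stop("input sides must be divisible by 2^depth = ", 2L^depth)
  ch <- pmin(cfg$f * 2L^(0:(depth - 1L)), cfg$cap * cfg$f)
  cin <- c(2L, ch[-depth])
  k <- cfg$k; k3 <- k^3
  build <- function() {
    params <- list()
    for (l in seq_len(depth)) {
      params[[sprintf("c%d_W", l)]] <- init_w(k3 * cin[l], ch[l])
      params[[sprintf("c%d_b", l)]] <- numeric(ch[l])
      if (l > 1L) {
        params[[sprintf("c%d_g", l)]] <- rep(1, ch[l])
        params[[sprintf("c%d_be", l)]] <- numeric(ch[l])
      }
    }
    params[["out_W"]] <- init_w(k3 * ch[depth], 1L)
    params[["out_b"]] <- numeric(1L)
    params
  }
  params <- if (is.null(seed)) build() else with_private_seed(seed, build())
  structure(list(cfg = cfg, depth = depth, ch = ch,
                 input_shape = input_shape, params = params),
            class = "vox_discriminator")
}

#' @rdname build_discriminator
#' @param disc a `vox_discriminator`.
#' @return `discriminator_receptive_field()`: the side length (voxels) of
#'   the input region influencing one output score.
#' @export
discriminator_receptive_field <- function(disc) {
  k <- disc$cfg$k
  rf <- 1; jump <- 1
  for (l in seq_len(disc$depth)) { rf <- rf + (k - 1) * jump; jump <- jump * 2 }
  rf + (k - 1) * jump   # final stride-1 conv
}

#' @export
print.vox_discriminator <- function(x, ...) {
  cat(sprintf("<vox_discriminator> k=%d, depth %d, receptive field %d voxels\n",
              x$cfg$k, x$depth, discriminator_receptive_field(x)))
  invisible(x)
}

disc_forward <- function(disc, cond, cand, training = FALSE) {
  P <- disc$params; k <- disc$cfg$k; pad <- conv_pad(k, 2L)
  cond <- vol_data(cond); cand <- vol_data(cand)
  if (!identical(dim(cond), dim(cand)))
    stop("condition and candidate shapes must match")
  if (!identical(dim(cond)[1:3], disc$input_shape))
    stop("input shape does not match the discriminator configuration")
  x <- concat_ch(as4d(cond), as4d(cand))
  layers <- vector("list", disc$depth)
  a <- x
  for (l in seq_len(disc$depth)) {
    z <- cpp_conv3d_fwd(a, P[[sprintf("c%d_W", l)]],
                        P[[sprintf("c%d_b", l)]], k, 2L, pad)
    if (l > 1L) {
      nf <- inorm_fwd(z, P[[sprintf("c%d_g", l)]], P[[sprintf("c%d_be", l)]])
      zn <- nf$y; ncache <- nf$cache
    } else { zn <- z; ncache <- NULL }
    out <- lrelu_fwd(zn)
    layers[[l]] <- list(x = a, zn = zn, ncache = ncache)
    a <- out
  }
  pad1 <- as.integer((k - 1) %/% 2)
  logits <- cpp_conv3d_fwd(a, P[["out_W"]], P[["out_b"]], k, 1L, pad1)
  p <- 1 / (1 + exp(-logits))
  list(p = p, logits = logits,
       cache = list(layers = layers, top = a, p = p, pad1 = pad1))
}

# dlogits: gradient of the loss w.r.t. the pre-sigmoid score grid.
disc_backward <- function(disc, cache, dlogits) {
  P <- disc$params; k <- disc$cfg$k; pad <- conv_pad(k, 2L)
  grads <- list()
  bw <- cpp_conv3d_bwd(cache$top, P[["out_W"]], dlogits, k, 1L, cache$pad1)
  grads[["out_W"]] <- bw$dW
  grads[["out_b"]] <- bw$db
  da <- bw$dx
  for (l in rev(seq_len(disc$depth))) {
    lc <- cache$layers[[l]]
    dzn <- lrelu_bwd(da, lc$zn)
    if (l > 1L) {
      nb <- inorm_bwd(dzn, lc$ncache)
      dz <- nb$dx
      grads[[sprintf("c%d_g", l)]] <- nb$dg
      grads[[sprintf("c%d_be", l)]] <- nb$dbe
    } else dz <- dzn
    bw <- cpp_conv3d_bwd(lc$x, P[[sprintf("c%d_W", l)]], dz, k, 2L, pad)
    grads[[sprintf("c%d_W", l)]] <- bw$dW
    grads[[sprintf("c%d_b", l)]] <- bw$db
    da <- bw$dx
  }
  list(grads = grads, dx = da)
}

#' Score a condition/candidate pair with a discriminator
#'
#' @param disc a `vox_discriminator`.
#' @param cond condition patch (source/MR), [volume()] or array.
#' @param cand candidate patch (target or synthetic), same shape.
#' @return 3D array of probability-real scores in (0, 1); its side is
#'   strictly smaller than the input side.
#' @export
discriminator_scores <- function(disc, cond, cand) {
  p <- disc_forward(disc, cond, cand, training = FALSE)$p
  array(p, dim(p)[1:3])
}
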