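#' Generator architecture configuration
#'
#' The generator is a 3D U-Net: an encoder of stride-2 convolutions with
#' cubic kernels of side `k` whose filter counts double from `f` per level
#' (capped at `cap * f`), mirrored by a decoder of stride-2 transpose
#' convolutions with skip concatenations at matching resolutions, and a
#' final tanh squashing the output into (-1, 1). Instance normalization is
#' applied in all but the first encoder and last decoder blocks; dropout in
#' the first decoder blocks injects the stochastic component during
#' training.
#'
#' Three production presets pair kernel size with base filter count:
#' `k4_f80` (k = 4, f = 80), `k6_f60` and `k8_f30`; see [preset_config()].
#' The stride of every (transpose) convolution is (2, 2, 2).
#'
#' @param k cubic kernel side in voxels (even, so stride-2 shapes tile).
#' @param f base filter count of the first encoder level.
#' @param depth number of stride-2 levels, or `NULL` to choose at build
#'   time so the bottleneck reaches 2-4 voxels per axis (6 levels for
#'   128^3 inputs).
#' @param cap filter doubling is capped at `cap * f`.
#' @param dropout decoder dropout rate during training.
#' @param name optional preset label.
#' @return A `generator_config`.
#' @export
generator_config <- function(k = 4, f = 80, depth = NULL, cap = 8,
                             dropout = 0.5, name = NULL) {
  if (k %% 2 != 0) stop("kernel size must be even for stride-2 tiling")
  structure(list(k = as.integer(k), f = as.integer(f),
                 depth = if (!is.null(depth)) as.integer(depth),
                 cap = cap, dropout = dropout,
                 name = name %||% sprintf("k%d_f%d", k, f)),
            class = "generator_config")
}

#' @rdname generator_config
#' @param preset one of `"k4_f80"`, `"k6_f60"`, `"k8_f30"`.
#' @param ... overrides passed on to [generator_config()].
#' @export
preset_config <- function(preset = c("k4_f80", "k6_f60", "k8_f30"), ...) {
  preset <- match.arg(preset)
  kf <- switch(preset,
               k4_f80 = c(4L, 80L), k6_f60 = c(6L, 60L), k8_f30 = c(8L, 30L))
  generator_config(k = kf[1], f = kf[2], name = preset, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unet_plan <- function(cfg, input_shape) {
  input_shape <- as.integer(input_shape)
  depth <- cfg$depth %||% max(1L, min(6L, floor(log2(min(input_shape))) - 1L))
  if (any(input_shape %% (2L^depth) != 0L))
    stop("input sides ", paste(input_shape, collapse = "x"),
         " must be divisible by 2^depth = ", 2L^depth)
  enc_ch <- pmin(cfg$f * 2L^(0:(depth - 1L)), cfg$cap * cfg$f)
  dec_in <- dec_out <- integer(depth)
  for (t in seq_len(depth)) {
    dec_in[t] <- if (t == 1L) enc_ch[depth] else dec_out[t - 1L] + enc_ch[depth - t + 1L]
    dec_out[t] <- if (t == depth) 1L else enc_ch[depth - t]
  }
  list(depth = depth, enc_in = c(1L, enc_ch[-depth]), enc_out = enc_ch,
       dec_in = dec_in, dec_out = dec_out,
       drop_steps = seq_len(max(0L, min(3L, depth - 1L))),
       pad = conv_pad(cfg$k, 2L), input_shape = input_shape)
}

#' Number of trainable generator parameters
#'
#' Computed from the channel plan without allocating weights; full-size
#' production presets land in the hundreds of millions.
#'
#' @param cfg a [generator_config()].
#' @param input_shape voxel counts of the intended input (determines the
#'   automatic depth).
#' @return Parameter count (double, to avoid integer overflow).
#' @export
generator_n_params <- function(cfg, input_shape = c(128, 128, 128)) {
  pl <- unet_plan(cfg, input_shape)
  k3 <- as.numeric(cfg$k)^3
  n <- 0
  for (l in seq_len(pl$depth)) {
    n <- n + k3 * pl$enc_in[l] * pl$enc_out[l] + pl$enc_out[l]
    if (l > 1L) n <- n + 2 * pl$enc_out[l]
  }
  for (t in seq_len(pl$depth)) {
    n <- n + k3 * pl$dec_in[t] * pl$dec_out[t] + pl$dec_out[t]
    if (t < pl$depth) n <- n + 2 * pl$dec_out[t]
  }
  n
}

#' Build a U-Net generator
#'
#' @inheritParams generator_n_params
#' @param input_shape voxel counts of the (possibly non-cubic) input patch;
#'   every side must be divisible by `2^depth`.
#' @param seed optional seed for weight initialization (N(0, 0.02)); when
#'   `NULL` the current RNG stream is used.
#' @return A `vox_generator` holding the architecture plan and parameters.
#'   Apply it with [predict()][predict.vox_generator]: output shape equals
#'   input shape, values in (-1, 1).
#' @export
build_generator <- function(cfg, input_shape = c(128, 128, 128), seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  pl <- unet_plan(cfg, input_shape)
  build <- function() {
    params <- list()
    k3 <- cfg$k^3
    for (l in seq_len(pl$depth)) {
      params[[sprintf("enc%d_W", l)]] <- init_w(k3 * pl$enc_in[l], pl$enc_out[l])
      params[[sprintf("enc%d_b", l)]] <- numeric(pl$enc_out[l])
      if (l > 1L) {
        params[[sprintf("enc%d_g", l)]] <- rep(1, pl$enc_out[l])
        params[[sprintf("enc%d_be", l)]] <- numeric(pl$enc_out[l])
      }
    }
    for (t in seq_len(pl$depth)) {
      params[[sprintf("dec%d_W", t)]] <- init_w(k3 * pl$dec_out[t], pl$dec_in[t])
      params[[sprintf("dec%d_b", t)]] <- numeric(pl$dec_out[t])
      if (t < pl$depth) {
        params[[sprintf("dec%d_g", t)]] <- rep(1, pl$dec_out[t])
        params[[sprintf("dec%d_be", t)]] <- numeric(pl$dec_out[t])
      }
    }
    params
  }
  params <- if (is.null(seed)) build() else with_private_seed(seed, build())
  structure(list(cfg = cfg, plan = pl, params = params),
            class = "vox_generator")
}

#' @export
print.vox_generator <- function(x, ...) {
  cat(sprintf("<vox_generator> %s, depth %d, input %s, %.3g parameters\n",
              x$cfg$name, x$plan$depth,
              paste(x$plan$input_shape, collapse = "x"),
              generator_n_params(x$cfg, x$plan$input_shape)))
  invisible(x)
}

unet_forward <- function(gen, x, training = FALSE) {
  pl <- gen$plan; P <- gen$params; k <- gen$cfg$k; pad <- pl$pad
  x <- as4d(vol_data(x))
  if (!identical(dim(x)[1:3], pl$input_shape))
    stop("input shape does not match the generator configuration")
  enc <- vector("list", pl$depth)
  a <- x
  for (l in seq_len(pl$depth)) {
    z <- cpp_conv3d_fwd(a, P[[sprintf("enc%d_W", l)]],
                        P[[sprintf("enc%d_b", l)]], k, 2L, pad)
    if (l > 1L) {
      nf <- inorm_fwd(z, P[[sprintf("enc%d_g", l)]], P[[sprintf("enc%d_be", l)]])
      zn <- nf$y; ncache <- nf$cache
    } else { zn <- z; ncache <- NULL }
    out <- lrelu_fwd(zn)
    enc[[l]] <- list(x = a, zn = zn, ncache = ncache, a = out)
    a <- out
  }
  dec <- vector("list", pl$depth)
  for (t in seq_len(pl$depth)) {
    h <- if (t == 1L) a else concat_ch(a, enc[[pl$depth - t + 1L]]$a)
    z <- cpp_tconv3d_fwd(h, P[[sprintf("dec%d_W", t)]],
                         P[[sprintf("dec%d_b", t)]], k, 2L, pad, pl$dec_out[t])
    if (t < pl$depth) {
      nf <- inorm_fwd(z, P[[sprintf("dec%d_g", t)]], P[[sprintf("dec%d_be", t)]])
      v <- nf$y; ncache <- nf$cache
      mask <- NULL
      if (training && t %in% pl$drop_steps && gen$cfg$dropout > 0) {
        dr <- dropout_fwd(v, gen$cfg$dropout)
        v <- dr$y; mask <- dr$mask
      }
      out <- relu_fwd(v)
      dec[[t]] <- list(h = h, ncache = ncache, mask = mask, v = v)
    } else {
      out <- tanh(z)
      dec[[t]] <- list(h = h, y = out)
    }
    a <- out
  }
  list(y = array(a, pl$input_shape),
       cache = list(enc = enc, dec = dec))
}

unet_backward <- function(gen, cache, dy) {
  pl <- gen$plan; P <- gen$params; k <- gen$cfg$k; pad <- pl$pad
  grads <- list()
  denc <- vector("list", pl$depth)   # grads w.r.t. encoder activations
  da <- as4d(dy)
  for (t in rev(seq_len(pl$depth))) {
    dc <- cache$dec[[t]]
    if (t == pl$depth) {
      dz <- da * (1 - dc$y^2)
    } else {
      dv <- relu_bwd(da, dc$v)
      if (!is.null(dc$mask)) dv <- dv * dc$mask
      nb <- inorm_bwd(dv, dc$ncache)
      dz <- nb$dx
      grads[[sprintf("dec%d_g", t)]] <- nb$dg
      grads[[sprintf("dec%d_be", t)]] <- nb$dbe
    }
    bw <- cpp_tconv3d_bwd(dc$h, P[[sprintf("dec%d_W", t)]], dz, k, 2L, pad)
    grads[[sprintf("dec%d_W", t)]] <- bw$dW
    grads[[sprintf("dec%d_b", t)]] <- bw$db
    dh <- bw$dx
    if (t == 1L) {
      denc[[pl$depth]] <- add_or(denc[[pl$depth]], dh)
    } else {
      nprev <- pl$dec_out[t - 1L]
      dprev <- dh[, , , seq_len(nprev), drop = FALSE]
      dskip <- dh[, , , -seq_len(nprev), drop = FALSE]
      l <- pl$depth - t + 1L
      denc[[l]] <- add_or(denc[[l]], dskip)
      da <- dprev
      next
    }
    da <- NULL
  }
  dx <- NULL
  for (l in rev(seq_len(pl$depth))) {
    ec <- cache$enc[[l]]
    dzn <- lrelu_bwd(denc[[l]], ec$zn)
    if (l > 1L) {
      nb <- inorm_bwd(dzn, ec$ncache)
      dz <- nb$dx
      grads[[sprintf("enc%d_g", l)]] <- nb$dg
      grads[[sprintf("enc%d_be", l)]] <- nb$dbe
    } else dz <- dzn
    bw <- cpp_conv3d_bwd(ec$x, P[[sprintf("enc%d_W", l)]], dz, k, 2L, pad)
    grads[[sprintf("enc%d_W", l)]] <- bw$dW
    grads[[sprintf("enc%d_b", l)]] <- bw$db
    if (l > 1L) denc[[l - 1L]] <- add_or(denc[[l - 1L]], bw$dx)
    else dx <- bw$dx
  }
  list(grads = grads, dx = dx)
}

add_or <- function(a, b) if (is.null(a)) b else a + b

# Wait-free path shared by training eval and user predict.
unet_predict <- function(gen, x) unet_forward(gen, x, training = FALSE)$y

#' Apply a generator to a source patch
#'
#' Inference is deterministic (dropout inactive): repeated calls on the
#' same input produce identical outputs, with the same shape as the input
#' and values in (-1, 1).
#'
#' @param object a `vox_generator` (from [build_generator()]) or
#'   `vox_model` (from [train_model()]).
#' @param newdata the source patch, a [volume()] or 3D array matching the
#'   generator's input shape.
#' @param ... unused.
#' @return The predicted patch; a [volume()] when `newdata` is one, else a
#'   3D array.
#' @export
predict.vox_generator <- function(object, newdata, ...) {
  y <- unet_predict(object, newdata)
  if (is_volume(newdata)) volume(y, newdata$spacing, newdata$origin) else y
}
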