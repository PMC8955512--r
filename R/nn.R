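# Internal layer primitives. Tensors are R arrays with dims (x, y, z, ch);
# convolution arithmetic lives in src/conv3d.cpp, everything pointwise is
# plain vectorised R. Each *_fwd returns the output plus whatever the
# matching *_bwd needs.

conv_pad <- function(k, stride) {
  p <- (k - stride) / 2
  if (p != floor(p) || p < 0)
    stop("kernel size ", k, " incompatible with stride ", stride)
  as.integer(p)
}

init_w <- function(nrow, ncol, sd = 0.02) {
  matrix(rnorm(nrow * ncol, 0, sd), nrow, ncol)
}

as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

lrelu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(dy, x, slope = 0.2) dy * ifelse(x > 0, 1, slope)
relu_fwd  <- function(x) pmax(x, 0)
relu_bwd  <- function(dy, x) dy * (x > 0)

inorm_fwd <- function(x, g, be, eps = 1e-5) {
  d <- dim(x); n <- prod(d[1:3]); C <- d[4]
  M <- matrix(x, n, C)
  mu <- colMeans(M)
  xc <- sweep(M, 2, mu, `-`)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, be, `+`)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g, d = d))
}

inorm_bwd <- function(dy, cache) {
  d <- cache$d; n <- prod(d[1:3]); C <- d[4]
  Dy <- matrix(dy, n, C)
  xhat <- cache$xhat
  dg <- colSums(Dy * xhat)
  dbe <- colSums(Dy)
  dxh <- sweep(Dy, 2, cache$g, `*`)
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xhat)
  dx <- sweep(dxh, 2, m1, `-`) - sweep(xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$inv, `*`)
  dim(dx) <- d
  list(dx = dx, dg = dg, dbe = dbe)
}

dropout_fwd <- function(x, rate) {
  keep <- 1 - rate
  mask <- array(rbinom(length(x), 1L, keep) / keep, dim(x))
  list(y = x * mask, mask = mask)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

# Adam with the pix2pix defaults (lr 2e-4, beta1 0.5).
adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim(as.array(p))))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, st, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
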