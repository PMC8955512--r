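#' Train one patch-specific generator/discriminator pair
#'
#' Alternating adversarial training at batch size 1: each iteration takes
#' one subject's patch pair, updates the discriminator on a measured and a
#' synthetic pair, then updates the generator with the cGAN + L1 objective
#' ([cgan_losses()], `lambda = 100`). One epoch is one pass over the
#' training subjects. When a [rotation_schedule()] is supplied, every
#' epoch starts by rotating all training pairs by that epoch's angle triple
#' ([draw_angles()]); evaluation always uses the original, unrotated data.
#' Every `eval_every` iterations the mean [mssim()] of the current
#' generator against the training pairs (and `test_pairs`, if given) is
#' recorded.
#'
#' Training is reproducible: the same `seed`, data and configuration give
#' identical histories. Optimization uses Adam with the pix2pix defaults
#' (learning rate 2e-4, momentum decay 0.5).
#'
#' @param pairs list of [paired_sample()] patches (the patched training
#'   dataset).
#' @param cfg a [generator_config()].
#' @param iterations total training iterations (batch size 1).
#' @param schedule a [rotation_schedule()] to augment with, or `NULL` to
#'   disable augmentation.
#' @param test_pairs held-out patch pairs evaluated alongside the training
#'   pairs.
#' @param eval_every evaluation cadence in iterations (26 when one epoch is
#'   26 subjects).
#' @param seed integer; seeds weight initialization, dropout and all other
#'   training randomness.
#' @param lambda L1 weight of the generator objective.
#' @param lr,beta1 Adam step size and first-moment decay.
#' @param disc_depth stride-2 levels of the discriminator.
#' @param ssim_window window side for the evaluation MSSIM.
#' @param verbose print one line per evaluation block.
#' @return A `vox_model`: list with the trained `generator`, the
#'   discriminator, `out_range` (min/max of the final predictions over the
#'   training patches), and `history`, a tibble with one row per evaluation
#'   (iteration, epoch, loss_d, loss_g, l1, train_mssim, test_mssim).
#' @export
train_model <- function(pairs, cfg, iterations, schedule = NULL,
                        test_pairs = list(), eval_every = 26L, seed = 1L,
                        lambda = 100, lr = 2e-4, beta1 = 0.5,
                        disc_depth = 3L, ssim_window = 11L, verbose = FALSE) {
  stopifnot(length(pairs) >= 1L, iterations >= 1L)
  shape <- dim(pairs[[1]]$mr$data)
  with_private_seed(seed, {
    G <- build_generator(cfg, shape)
    D <- build_discriminator(cfg, shape, depth = disc_depth)
    stG <- adam_init(G$params)
    stD <- adam_init(D$params)
    n <- length(pairs)
    cur <- pairs
    hist <- list()
    for (it in seq_len(iterations)) {
      epoch <- (it - 1L) %/% n
      si <- (it - 1L) %% n + 1L
      if (si == 1L && !is.null(schedule)) {
        ang <- draw_angles(schedule, epoch)
        cur <- lapply(pairs, rotate_pair, angles = ang)
      }
      cond <- pairs_mr(cur[[si]])
      x <- pairs_ct(cur[[si]])
      gf <- unet_forward(G, cond, training = TRUE)
      y <- gf$y
      dr <- disc_forward(D, cond, x, training = TRUE)
      df <- disc_forward(D, cond, y, training = TRUE)
      nM <- length(dr$p)
      # discriminator step
      br <- disc_backward(D, dr$cache, (dr$p - 1) / nM)
      bf <- disc_backward(D, df$cache, df$p / nM)
      up <- adam_step(D$params, add_grads(br$grads, bf$grads), stD, lr, beta1)
      D$params <- up$params; stD <- up$state
      # generator step against the updated discriminator
      df2 <- disc_forward(D, cond, y, training = TRUE)
      bg <- disc_backward(D, df2$cache, (df2$p - 1) / length(df2$p))
      dy_adv <- array(bg$dx[, , , 2L], shape)
      dy <- dy_adv + lambda * sign(y - x) / length(y)
      gb <- unet_backward(G, gf$cache, dy)
      up <- adam_step(G$params, gb$grads, stG, lr, beta1)
      G$params <- up$params; stG <- up$state

      losses <- cgan_losses(dr$p, df$p, x, y, lambda)
      if (!is.finite(losses$loss_d) || !is.finite(losses$loss_g))
        stop(sprintf(paste0("non-finite loss at iteration %d ",
                            "(loss_d = %g, loss_g = %g, |y| max = %g)"),
                     it, losses$loss_d, losses$loss_g, max(abs(y))))
      if (it %% eval_every == 0L || it == iterations) {
        tr_ms <- mean(vapply(pairs, function(p)
          mssim(unet_predict(G, pairs_mr(p)), pairs_ct(p),
                ssim_params(window = ssim_window)), 1))
        te_ms <- if (length(test_pairs))
          mean(vapply(test_pairs, function(p)
            mssim(unet_predict(G, pairs_mr(p)), pairs_ct(p),
                  ssim_params(window = ssim_window)), 1))
          else NA_real_
        hist[[length(hist) + 1L]] <- tibble::tibble(
          iteration = it, epoch = epoch, loss_d = losses$loss_d,
          loss_g = losses$loss_g, l1 = losses$l1,
          train_mssim = tr_ms, test_mssim = te_ms)
        if (verbose)
          cat(sprintf("it %5d  loss_d %.3f  loss_g %.3f  l1 %.4f  train %.4f  test %s\n",
                      it, losses$loss_d, losses$loss_g, losses$l1, tr_ms,
                      ifelse(is.na(te_ms), "-", sprintf("%.4f", te_ms))))
      }
    }
    final_preds <- lapply(pairs, function(p) unet_predict(G, pairs_mr(p)))
    rng <- range(unlist(lapply(final_preds, range)))
    structure(list(generator = G, discriminator = D, cfg = cfg,
                   out_range = c(min = rng[1], max = rng[2]),
                   history = do.call(rbind, hist), seed = seed),
              class = "vox_model")
  })
}

pairs_mr <- function(p) if (inherits(p, "paired_sample")) p$mr$data else vol_data(p$mr)
pairs_ct <- function(p) if (inherits(p, "paired_sample")) p$ct$data else vol_data(p$ct)

#' @export
print.vox_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<vox_model> %s, %d iterations, final train MSSIM %.4f\n",
              x$cfg$name, max(h$iteration), h$train_mssim[nrow(h)]))
  invisible(x)
}

#' @rdname predict.vox_generator
#' @export
predict.vox_model <- function(object, newdata, ...) {
  predict(object$generator, newdata)
}

#' @export
glance.vox_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(preset = x$cfg$name, iterations = max(h$iteration),
                 loss_d = h$loss_d[nrow(h)], loss_g = h$loss_g[nrow(h)],
                 l1 = h$l1[nrow(h)],
                 train_mssim = h$train_mssim[nrow(h)],
                 test_mssim = h$test_mssim[nrow(h)],
                 out_min = x$out_range[["min"]], out_max = x$out_range[["max"]])
}

#' @export
tidy.vox_model <- function(x, ...) x$history
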