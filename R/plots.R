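#' Plot a training history
#'
#' MSSIM of the generator against training (and, when recorded, test)
#' pairs over iterations.
#'
#' @param object a `vox_model` from [train_model()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.vox_model <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(iteration = h$iteration, mssim = h$train_mssim,
                         data = "train"),
              data.frame(iteration = h$iteration, mssim = h$test_mssim,
                         data = "test"))
  df <- df[is.finite(df$mssim), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$mssim,
                                   colour = .data$data)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "mean MSSIM",
                  title = object$cfg$name) +
    ggplot2::theme_minimal()
}

#' Plot the augmentation-ablation curves
#'
#' Train/test MSSIM trajectories of the two experiment arms (with and
#' without rotation augmentation), one panel per arm.
#'
#' @param object an `ablation_report` from [run_ablation()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ablation_report <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(iteration = h$iteration, mssim = h$train_mssim,
                         data = "train", experiment = h$experiment),
              data.frame(iteration = h$iteration, mssim = h$test_mssim,
                         data = "test", experiment = h$experiment))
  df <- df[is.finite(df$mssim), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$mssim,
                                   colour = .data$data)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~experiment) +
    ggplot2::labs(x = "iteration", y = "mean MSSIM") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a volume
#'
#' @param vol a [volume()] or 3D array.
#' @param z slice index (defaults to the middle slice).
#' @param title optional plot title.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(vol, z = NULL, title = NULL) {
  arr <- vol_data(vol)
  z <- z %||% ((dim(arr)[3] + 1) %/% 2)
  sl <- arr[, , z]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
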