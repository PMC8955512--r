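#' Mix predictions from models with different kernel sizes
#'
#' The per-patch outputs of the k4_f80, k6_f60 and k8_f30 models are mixed
#' in fixed 1:1:1 proportion, i.e. the voxelwise arithmetic mean, before
#' any range alignment or patch merging. The merged value at every voxel is
#' therefore bounded by the per-voxel minimum and maximum of the inputs.
#'
#' @param ... two or more predictions ([volume()]s or 3D arrays) of
#'   identical shape; the production ensemble mixes three.
#' @return The voxelwise mean, a [volume()] if the first input is one.
#' @export
merge_kernels <- function(...) {
  preds <- list(...)
  if (length(preds) == 1L && is.list(preds[[1]]) && !is_volume(preds[[1]]))
    preds <- preds[[1]]
  stopifnot(length(preds) >= 1L)
  arrs <- lapply(preds, vol_data)
  d <- dim(arrs[[1]])
  for (a in arrs)
    if (!identical(dim(a), d)) stop("predictions must share one shape")
  # extended-precision mean: identical inputs mix to themselves exactly
  out <- cpp_merge_patches(arrs, matrix(0L, length(arrs), 3), as.integer(d))
  ref <- preds[[1]]
  if (is_volume(ref)) volume(out, ref$spacing, ref$origin) else volume(out)
}

#' Observed output range of a prediction
#'
#' @param x a [volume()] or 3D array.
#' @return A `range_stats` object with `min` and `max`.
#' @export
range_stats <- function(x) {
  r <- range(vol_data(x))
  if (r[1] >= r[2]) warning("constant prediction: degenerate range")
  structure(list(min = r[1], max = r[2]), class = "range_stats")
}

#' Linearly align a prediction's output range to a reference
#'
#' Applies the affine map sending `(min(pred), max(pred))` to
#' `(ref$min, ref$max)`. In the patch ensemble the reference is the centre
#' (p3) model's range, which gives the five patch models a common intensity
#' baseline before overlap merging; the p3 prediction itself passes through
#' unchanged. A constant prediction is returned unchanged with a warning.
#'
#' @param pred a [volume()] or 3D array.
#' @param ref a [range_stats()].
#' @return The aligned prediction, same type and shape.
#' @export
align_range <- function(pred, ref) {
  stopifnot(inherits(ref, "range_stats"))
  arr <- vol_data(pred)
  lo <- min(arr); hi <- max(arr)
  if (hi <= lo) {
    warning("constant prediction left unaligned")
    return(pred)
  }
  if (lo == ref$min && hi == ref$max) return(pred)  # exact pass-through
  out <- ref$min + (arr - lo) * ((ref$max - ref$min) / (hi - lo))
  if (is_volume(pred)) volume(out, pred$spacing, pred$origin) else volume(out)
}

#' Bundle trained models for full-volume synthesis
#'
#' A complete bundle for the production pipeline holds one model per
#' (patch, preset) combination: 5 patches x 3 presets = 15 models, keyed
#' `p1_k4_f80` ... `p5_k8_f30`.
#'
#' @param models named list of `vox_model`s, keys `p<i>_<preset>`.
#' @param layout the [patch_layout()] the models were trained on.
#' @param presets character vector of preset names in the bundle.
#' @return A `model_bundle`.
#' @export
model_bundle <- function(models, layout, presets) {
  stopifnot(inherits(layout, "patch_layout"))
  structure(list(models = models, layout = layout, presets = presets),
            class = "model_bundle")
}

#' @rdname model_bundle
#' @param bundle a `model_bundle`.
#' @export
bundle_size <- function(bundle) length(bundle$models)

bundle_check <- function(bundle) {
  need <- as.vector(outer(seq_len(n_patches(bundle$layout)), bundle$presets,
                          function(i, p) sprintf("p%d_%s", i, p)))
  missing <- setdiff(need, names(bundle$models))
  if (length(missing))
    stop("incomplete model bundle; missing: ", paste(missing, collapse = ", "))
  invisible(need)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %d models (%d patches x %d presets: %s)\n",
              bundle_size(x), n_patches(x$layout), length(x$presets),
              paste(x$presets, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.model_bundle <- function(x, ...) {
  do.call(rbind, lapply(names(x$models), function(nm) {
    m <- x$models[[nm]]
    tibble::tibble(model = nm,
                   patch = as.integer(sub("^p(\\d+)_.*$", "\\1", nm)),
                   preset = sub("^p\\d+_", "", nm),
                   k = m$cfg$k, f = m$cfg$f,
                   iterations = max(m$history$iteration),
                   train_mssim = m$history$train_mssim[nrow(m$history)],
                   out_min = m$out_range[["min"]],
                   out_max = m$out_range[["max"]])
  }))
}

#' Train a full bundle of patch-specific models
#'
#' Trains one model per (patch, preset) combination on the patched
#' datasets extracted from preprocessed training pairs.
#'
#' @param train_samples list of preprocessed [paired_sample()]s on the
#'   layout's grid.
#' @param layout a [patch_layout()].
#' @param cfgs list of [generator_config()]s (one per preset).
#' @param test_samples optional held-out pairs, evaluated during training.
#' @param seed integer; per-model seeds are derived from it.
#' @param ... further arguments passed to [train_model()].
#' @inheritParams train_model
#' @return A [model_bundle()].
#' @export
train_bundle <- function(train_samples, layout, cfgs, iterations,
                         test_samples = list(), schedule = NULL, seed = 1L,
                         verbose = FALSE, ...) {
  if (inherits(cfgs, "generator_config")) cfgs <- list(cfgs)
  models <- list()
  for (p in seq_len(n_patches(layout))) {
    tr <- lapply(train_samples, patch_pair, layout = layout, index = p)
    te <- lapply(test_samples, patch_pair, layout = layout, index = p)
    for (ci in seq_along(cfgs)) {
      cfg <- cfgs[[ci]]
      key <- sprintf("p%d_%s", p, cfg$name)
      if (verbose) cat("training", key, "\n")
      models[[key]] <- train_model(
        tr, cfg, iterations, schedule = schedule, test_pairs = te,
        seed = derive_seed(seed, p * 31L + ci), verbose = verbose, ...)
    }
  }
  model_bundle(models, layout, vapply(cfgs, function(cf) cf$name, ""))
}

# Extract the index-th patch of both volumes of a pair.
patch_pair <- function(sample, layout, index) {
  paired_sample(extract_patch(sample$mr, layout, index),
                extract_patch(sample$ct, layout, index),
                subject_id = sample$subject_id)
}

#' Synthesize a full target volume from a source volume
#'
#' For every patch of the layout, each preset's generator predicts the
#' target patch; the per-kernel predictions are mixed 1:1:1
#' ([merge_kernels()]), every mixed patch prediction is range-aligned to
#' the centre (p3) patch ([align_range()]), and the aligned patches are
#' merged onto the full grid with overlap division ([merge_patches()]).
#'
#' @param mr_full preprocessed source [volume()] on the layout's grid.
#' @param bundle a complete [model_bundle()].
#' @param layout optional override of the bundle's layout.
#' @param stats `"volume"` aligns ranges observed on the current
#'   predictions (default); `"training"` uses the ranges stored in the
#'   bundle at training time.
#' @return The synthetic target [volume()] on the full grid.
#' @export
synthesize <- function(mr_full, bundle, layout = NULL,
                       stats = c("volume", "training")) {
  stopifnot(inherits(bundle, "model_bundle"))
  stats <- match.arg(stats)
  layout <- layout %||% bundle$layout
  bundle_check(bundle)
  np <- n_patches(layout)
  center <- 3L  # p3 is the centre patch of the corners-plus-centre layout
  merged <- vector("list", np)
  tr_range <- numeric(0)
  for (p in seq_len(np)) {
    mr_patch <- extract_patch(mr_full, layout, p)
    preds <- lapply(bundle$presets, function(ps)
      predict(bundle$models[[sprintf("p%d_%s", p, ps)]], mr_patch))
    merged[[p]] <- merge_kernels(preds)
  }
  ref <- if (stats == "volume") range_stats(merged[[center]]) else {
    rr <- sapply(bundle$presets, function(ps)
      bundle$models[[sprintf("p%d_%s", center, ps)]]$out_range)
    structure(list(min = mean(rr["min", ]), max = mean(rr["max", ])),
              class = "range_stats")
  }
  aligned <- lapply(merged, align_range, ref = ref)
  merge_patches(aligned, layout)
}
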