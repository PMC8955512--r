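#' End-to-end phantom translation study
#'
#' Runs the complete pipeline at phantom scale: generate a paired dataset,
#' split it (outliers to the test set), preprocess every pair onto the
#' common grid, train one generator per patch, synthesize the test
#' subjects' target volumes, and score them against the known targets with
#' [evaluate_pair()]. Each test subject is also scored with the source
#' volume used *as* the prediction — the do-nothing baseline any useful
#' translation must beat.
#'
#' The defaults are sized so a full study runs on one CPU in minutes:
#' 31 subjects on a 64 x 64 x 32 grid with 32^3 patches, a reduced
#' generator (k = 4, f = 8, depth 3) and a training length chosen where
#' pilot runs of the phantom task reach a stable L1 plateau.
#'
#' @param seed master seed for data generation and training.
#' @param n_subjects,n_test dataset size and held-out count (26 train / 5
#'   test by default).
#' @param grid,patch common grid and patch voxel counts.
#' @param cfgs one [generator_config()] or a list of them (one model per
#'   patch and preset).
#' @param iterations training iterations per model.
#' @param augment train with the cyclic rotation schedule.
#' @param spec the [phantom_spec()] defining the data conditions.
#' @param eval_every evaluation cadence passed to [train_model()].
#' @param verbose print progress.
#' @return A `phantom_study`: list with `results` (one row per test
#'   subject: similarity indices of the synthetic and of the baseline),
#'   the trained `bundle`, the `layout`, and the preprocessed test pairs.
#' @export
run_phantom_study <- function(seed = 1L, n_subjects = 31L, n_test = 5L,
                              grid = c(64, 64, 32), patch = c(32, 32, 32),
                              cfgs = generator_config(k = 4, f = 8, depth = 3),
                              iterations = 520L, augment = TRUE,
                              spec = phantom_spec(), eval_every = 26L,
                              verbose = FALSE) {
  pairs <- phantom_dataset(spec, n_subjects, seed = seed)
  sp <- split_phantoms(pairs, n_test = n_test)
  pp <- function(p, id) preprocess_pair(p$mr, p$ct, target_shape = grid,
                                        subject_id = id)
  train_pp <- Map(pp, sp$train, sprintf("train%02d", seq_along(sp$train)))
  test_pp <- Map(pp, sp$test, sprintf("test%02d", seq_along(sp$test)))
  layout <- default_layout(grid, patch)
  schedule <- if (augment) rotation_schedule(derive_seed(seed, 512L))
  bundle <- train_bundle(train_pp, layout, cfgs, iterations,
                         test_samples = test_pp, schedule = schedule,
                         seed = seed, eval_every = eval_every,
                         verbose = verbose)
  rows <- lapply(seq_along(test_pp), function(i) {
    s <- test_pp[[i]]
    sct <- synthesize(s$mr, bundle)
    synth <- evaluate_pair(s$ct, sct)
    base <- evaluate_pair(s$ct, s$mr)
    tibble::tibble(subject = s$subject_id,
                   mssim = synth$mssim, mssim_baseline = base$mssim,
                   mse = synth$mse, mse_baseline = base$mse,
                   psnr = synth$psnr, psnr_baseline = base$psnr,
                   cad = synth$cad, cad_baseline = base$cad,
                   l2 = synth$l2, l2_baseline = base$l2)
  })
  structure(list(results = do.call(rbind, rows), bundle = bundle,
                 layout = layout, test_pairs = test_pp, seed = seed,
                 iterations = iterations),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> %d test subjects, %d models, %d iterations each\n",
              nrow(x$results), bundle_size(x$bundle), x$iterations))
  print(glance(x))
  invisible(x)
}

#' @export
glance.phantom_study <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_test = nrow(r),
    mean_mssim = mean(r$mssim), sd_mssim = sd(r$mssim),
    mean_mssim_baseline = mean(r$mssim_baseline),
    mean_mse = mean(r$mse), mean_mse_baseline = mean(r$mse_baseline),
    n_beat_baseline = sum(r$mssim > r$mssim_baseline & r$mse < r$mse_baseline))
}

#' @export
tidy.phantom_study <- function(x, ...) x$results

#' Augmentation ablation on the centre patch
#'
#' Trains the centre-patch (p3) model twice on identical data with the
#' same seed and configuration — once without augmentation and once with
#' the cyclic rotation schedule — recording train and test MSSIM every
#' `eval_every` iterations. The paired curves expose the overfitting gap:
#' without augmentation the train-test MSSIM gap at the final checkpoint
#' is expected to exceed the augmented run's gap.
#'
#' @inheritParams run_phantom_study
#' @param cfg the [generator_config()] trained in both arms.
#' @return An `ablation_report`: list with `history` (tibble of both arms'
#'   evaluation curves), and the two fitted models.
#' @export
run_ablation <- function(seed = 1L, n_subjects = 31L, n_test = 5L,
                         grid = c(64, 64, 32), patch = c(32, 32, 32),
                         cfg = generator_config(k = 4, f = 8, depth = 3),
                         iterations = 520L, spec = phantom_spec(),
                         eval_every = 26L, verbose = FALSE) {
  pairs <- phantom_dataset(spec, n_subjects, seed = seed)
  sp <- split_phantoms(pairs, n_test = n_test)
  pp <- function(p, id) preprocess_pair(p$mr, p$ct, target_shape = grid,
                                        subject_id = id)
  train_pp <- Map(pp, sp$train, sprintf("train%02d", seq_along(sp$train)))
  test_pp <- Map(pp, sp$test, sprintf("test%02d", seq_along(sp$test)))
  layout <- default_layout(grid, patch)
  p3 <- 3L
  tr <- lapply(train_pp, patch_pair, layout = layout, index = p3)
  te <- lapply(test_pp, patch_pair, layout = layout, index = p3)
  run <- function(schedule, label) {
    m <- train_model(tr, cfg, iterations, schedule = schedule,
                     test_pairs = te, eval_every = eval_every,
                     seed = seed, verbose = verbose)
    h <- m$history
    h$experiment <- label
    list(model = m, history = h)
  }
  off <- run(NULL, "no_augmentation")
  on <- run(rotation_schedule(derive_seed(seed, 512L)), "augmentation")
  hist <- rbind(off$history, on$history)
  gap <- function(h) {
    last <- h[nrow(h), ]
    last$train_mssim - last$test_mssim
  }
  structure(list(history = hist, model_off = off$model, model_on = on$model,
                 gap_no_augmentation = gap(off$history),
                 gap_augmentation = gap(on$history),
                 seed = seed, iterations = iterations),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf(paste0("<ablation_report> %d iterations; final train-test ",
                     "MSSIM gap %.4f without augmentation vs %.4f with\n"),
              x$iterations, x$gap_no_augmentation, x$gap_augmentation))
  invisible(x)
}

#' @export
tidy.ablation_report <- function(x, ...) x$history

#' @export
glance.ablation_report <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 gap_no_augmentation = x$gap_no_augmentation,
                 gap_augmentation = x$gap_augmentation,
                 gap_reduction = x$gap_no_augmentation - x$gap_augmentation)
}
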