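#' Common field of view of a co-registered pair
#'
#' The shared field of view (FOV) for a source/target pair is defined by the
#' source (MR) volume, which in practice covers the smaller physical extent.
#' If the source extent is not fully contained in the target's, the box is
#' clipped to the intersection and a warning is issued — voxels outside the
#' common FOV are discarded downstream.
#'
#' @param mr,ct [volume()] objects (source and target of a pair).
#' @return A `fov_box`: list with `lower` and `upper` physical corners (mm).
#' @export
common_fov <- function(mr, ct) {
  stopifnot(is_volume(mr), is_volume(ct))
  em <- vol_extent(mr); ec <- vol_extent(ct)
  lo <- em$lower; up <- em$upper
  if (any(em$lower < ec$lower) || any(em$upper > ec$upper)) {
    warning("source FOV exceeds target FOV; clipping to the intersection")
    lo <- pmax(em$lower, ec$lower)
    up <- pmin(em$upper, ec$upper)
  }
  if (any(lo >= up)) stop("volumes have no overlapping field of view")
  fov_box(lo, up)
}

#' @rdname common_fov
#' @param lower,upper physical corners in mm; `lower < upper` on every axis.
#' @export
fov_box <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(lower >= upper))
    stop("fov_box needs lower < upper on every axis")
  structure(list(lower = lower, upper = upper), class = "fov_box")
}

#' Crop a volume to a field-of-view box
#'
#' Keeps exactly the voxels whose *centres* lie inside the half-open box
#' `[lower, upper)`, updating the origin accordingly.
#'
#' @param vol a [volume()].
#' @param box a `fov_box` from [common_fov()] or [fov_box()].
#' @return The cropped [volume()].
#' @export
crop_to_fov <- function(vol, box) {
  stopifnot(is_volume(vol), inherits(box, "fov_box"))
  d <- dim(vol$data)
  idx <- lapply(1:3, function(a) {
    centers <- vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a]
    which(centers >= box$lower[a] & centers < box$upper[a])
  })
  if (any(lengths(idx) == 0L))
    stop("field-of-view box does not intersect the volume")
  new_origin <- vol$origin + (vapply(idx, min, 1L) - 1) * vol$spacing
  volume(vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         spacing = vol$spacing, origin = new_origin)
}

# Resample `vol` onto the grid defined by a physical box and a voxel count:
# spacing = box size / shape, voxel centres at lower + (i - 1/2) * spacing.
# Separable cubic (Catmull-Rom) interpolation per axis.
resample_to_box <- function(vol, box, target_shape) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stop("`target_shape` must be 3 voxel counts, all >= 2")
  size <- box$upper - box$lower
  new_sp <- size / target_shape
  new_or <- box$lower + new_sp / 2
  arr <- vol_data(vol)
  for (a in 1:3) {
    centers <- new_or[a] + (seq_len(target_shape[a]) - 1) * new_sp[a]
    coords <- (centers - vol$origin[a]) / vol$spacing[a]  # 0-based index
    arr <- cpp_resample_axis(arr, a - 1L, coords)
  }
  volume(arr, spacing = new_sp, origin = new_or)
}

#' Resample a volume to a new voxel count
#'
#' The returned volume covers the same physical extent as the input on a new
#' grid of `target_shape` voxels, with values obtained by cubic spline
#' interpolation (separable Catmull-Rom; samples are reproduced exactly at
#' the original grid points, and polynomial ramps up to the kernel's
#' reproduction order are preserved, including through the boundary fringe
#' via linear extrapolation of edge samples).
#'
#' @param vol a [volume()].
#' @param target_shape integer length-3 voxel counts, all >= 2.
#' @return The resampled [volume()].
#' @export
resample <- function(vol, target_shape) {
  stopifnot(is_volume(vol))
  resample_to_box(vol, do.call(fov_box, vol_extent(vol)), target_shape)
}

#' Two-stage intensity normalization onto [-1, 1]
#'
#' Stage 1 standardizes: `img' = (img - mu) / sigma` with `mu`, `sigma` the
#' image mean and standard deviation. Stage 2 maps the standardized range
#' affinely onto \eqn{[-1, 1]}: with `m = (max + min)/2` and
#' `d = (max - min)/2` of `img'`, the result is `img'' = (img' - m)/d`, so
#' the minimum maps to -1 and the maximum to +1. The returned record holds
#' (mu, sigma, m, d) and makes the map invertible via
#' [denormalize_intensity()].
#'
#' @param img a [volume()] or 3D array with non-constant intensities.
#' @return A list with `vol` (the normalized [volume()]) and `record`
#'   (class `normalization_record`).
#' @export
normalize_intensity <- function(img) {
  arr <- vol_data(img)
  mu <- mean(arr)
  sigma <- sqrt(mean((arr - mu)^2))
  if (!is.finite(sigma) || sigma <= 0)
    stop("cannot normalize a constant image (zero standard deviation)")
  z <- (arr - mu) / sigma
  m <- (max(z) + min(z)) / 2
  d <- (max(z) - min(z)) / 2
  if (d <= 0) stop("cannot normalize a constant image")
  out <- (z - m) / d
  rec <- structure(list(mu = mu, sigma = sigma, m = m, d = d),
                   class = "normalization_record")
  vol <- if (is_volume(img)) volume(out, img$spacing, img$origin) else volume(out)
  list(vol = vol, record = rec)
}

#' @rdname normalize_intensity
#' @param vol a normalized [volume()] (or array) in \eqn{[-1, 1]}.
#' @param record the `normalization_record` returned by
#'   [normalize_intensity()].
#' @export
denormalize_intensity <- function(vol, record) {
  stopifnot(inherits(record, "normalization_record"))
  arr <- vol_data(vol)
  out <- record$mu + record$sigma * (record$d * arr + record$m)
  if (is_volume(vol)) volume(out, vol$spacing, vol$origin) else volume(out)
}

#' Preprocess a co-registered source/target pair onto a common grid
#'
#' The full preprocessing workflow applied to every pair: (1) define the
#' common FOV from the source volume, (2) crop both volumes to it, (3)
#' resample both onto the identical `target_shape` grid spanning that box
#' with cubic spline interpolation, (4) normalize each volume independently
#' onto \eqn{[-1, 1]} with [normalize_intensity()].
#'
#' @param mr_raw,ct_raw co-registered source and target [volume()]s.
#' @param target_shape integer length-3; the common grid (the production
#'   pipeline uses 200 x 200 x 128).
#' @param subject_id optional label carried through to the result.
#' @return A `paired_sample`: list with `subject_id`, `mr`, `ct` (volumes on
#'   the identical grid, intensities in \eqn{[-1, 1]}), and `mr_norm`,
#'   `ct_norm` normalization records.
#' @export
preprocess_pair <- function(mr_raw, ct_raw, target_shape = c(200, 200, 128),
                            subject_id = NA_character_) {
  box <- common_fov(mr_raw, ct_raw)
  mr_c <- crop_to_fov(mr_raw, box)
  ct_c <- crop_to_fov(ct_raw, box)
  mr_r <- resample_to_box(mr_c, box, target_shape)
  ct_r <- resample_to_box(ct_c, box, target_shape)
  mr_n <- normalize_intensity(mr_r)
  ct_n <- normalize_intensity(ct_r)
  paired_sample(mr_n$vol, ct_n$vol, mr_norm = mr_n$record,
                ct_norm = ct_n$record, subject_id = subject_id)
}

#' @rdname preprocess_pair
#' @param mr,ct preprocessed [volume()]s sharing shape, spacing and origin.
#' @param mr_norm,ct_norm normalization records (may be `NULL` for pairs
#'   built directly, e.g. in tests).
#' @export
paired_sample <- function(mr, ct, mr_norm = NULL, ct_norm = NULL,
                          subject_id = NA_character_) {
  stopifnot(is_volume(mr), is_volume(ct))
  if (!identical(dim(mr$data), dim(ct$data)))
    stop("paired volumes must share an identical grid shape")
  if (max(abs(mr$spacing - ct$spacing)) > 1e-9 ||
      max(abs(mr$origin - ct$origin)) > 1e-9)
    stop("paired volumes must share spacing and origin")
  structure(list(subject_id = subject_id, mr = mr, ct = ct,
                 mr_norm = mr_norm, ct_norm = ct_norm),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  d <- dim(x$mr$data)
  cat(sprintf("<paired_sample> subject %s, grid %d x %d x %d\n",
              x$subject_id, d[1], d[2], d[3]))
  invisible(x)
}
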