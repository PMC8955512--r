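#' Overlapping patch layout for a common grid
#'
#' The grid is decomposed into five overlapping patches: the four in-plane
#' corners plus one centred patch, each spanning the full z extent. For the
#' production grid (200, 200, 128) with 128^3 patches this puts the patch
#' lower corners (0-based voxels) at p1 = (0,0,0), p2 = (72,0,0),
#' p3 = (36,36,0) (the centre patch), p4 = (0,72,0) and p5 = (72,72,0).
#' Offsets are explicit in the returned object, so other grids follow the
#' same corners-plus-centre construction.
#'
#' @param grid_shape integer length-3 voxel counts of the common grid.
#' @param patch_shape integer length-3 voxel counts of each patch;
#'   `patch_shape <= grid_shape` per axis, and the patch z extent must equal
#'   the grid z extent (the z axis is never subdivided).
#' @return A `patch_layout`: list with `grid_shape`, `patch_shape` and
#'   `offsets`, a 5 x 3 integer matrix of 0-based lower-corner voxel
#'   indices (rows p1..p5).
#' @export
default_layout <- function(grid_shape, patch_shape) {
  g <- as.integer(grid_shape); p <- as.integer(patch_shape)
  if (length(g) != 3L || length(p) != 3L) stop("shapes must have length 3")
  if (any(p > g)) stop("patch larger than grid")
  if (p[3] != g[3])
    stop("patch z extent must equal grid z extent (z is never subdivided)")
  hi <- g - p                       # far-corner offset per axis
  ce <- hi %/% 2L                   # centred offset
  offs <- rbind(p1 = c(0L,    0L,    0L),
                p2 = c(hi[1], 0L,    0L),
                p3 = c(ce[1], ce[2], 0L),
                p4 = c(0L,    hi[2], 0L),
                p5 = c(hi[1], hi[2], 0L))
  layout <- structure(list(grid_shape = g, patch_shape = p, offsets = offs),
                      class = "patch_layout")
  if (any(overlap_map(layout) == 0L))
    stop("patches do not cover the grid; enlarge the patch or shrink the grid")
  layout
}

#' @rdname default_layout
#' @param offsets integer matrix of 0-based lower-corner voxel indices, one
#'   row per patch.
#' @export
patch_layout <- function(grid_shape, patch_shape, offsets) {
  g <- as.integer(grid_shape); p <- as.integer(patch_shape)
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (any(offsets < 0L) || any(t(t(offsets) + p) > matrix(g, nrow(offsets), 3, byrow = TRUE)))
    stop("every offset + patch_shape must fit inside grid_shape")
  structure(list(grid_shape = g, patch_shape = p, offsets = offsets),
            class = "patch_layout")
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("<patch_layout> grid %s, patch %s, %d patches\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$patch_shape, collapse = "x"), nrow(x$offsets)))
  print(x$offsets)
  invisible(x)
}

n_patches <- function(layout) nrow(layout$offsets)

#' Per-voxel overlap counts of a patch layout
#'
#' Counts, for every grid voxel, how many patches contain it. The counts
#' are the divisor when per-patch predictions are merged back onto the
#' grid: predictions are summed into a zero-initialised base map and each
#' voxel is divided by its overlap count.
#'
#' @param layout a [patch_layout()].
#' @return Integer 3D array of counts, min >= 1 for covering layouts and
#'   max <= the number of patches.
#' @export
overlap_map <- function(layout) {
  stopifnot(inherits(layout, "patch_layout"))
  cnt <- array(0L, layout$grid_shape)
  p <- layout$patch_shape
  for (r in seq_len(nrow(layout$offsets))) {
    o <- layout$offsets[r, ]
    cnt[o[1] + seq_len(p[1]), o[2] + seq_len(p[2]), o[3] + seq_len(p[3])] <-
      cnt[o[1] + seq_len(p[1]), o[2] + seq_len(p[2]), o[3] + seq_len(p[3])] + 1L
  }
  cnt
}

#' Extract one patch from a volume
#'
#' @param vol a [volume()] (or 3D array) on the layout's grid.
#' @param layout a [patch_layout()].
#' @param index patch number (1-based; `p1` is index 1).
#' @return A [volume()] holding the sub-grid, with origin shifted to the
#'   patch's physical position.
#' @export
extract_patch <- function(vol, layout, index) {
  stopifnot(inherits(layout, "patch_layout"))
  if (!(index %in% seq_len(n_patches(layout))))
    stop("patch index must be in 1..", n_patches(layout))
  arr <- vol_data(vol)
  if (!identical(dim(arr), layout$grid_shape))
    stop("volume shape does not match the layout grid")
  o <- layout$offsets[index, ]
  p <- layout$patch_shape
  sub <- arr[o[1] + seq_len(p[1]), o[2] + seq_len(p[2]), o[3] + seq_len(p[3]),
             drop = FALSE]
  if (is_volume(vol))
    volume(sub, vol$spacing, vol$origin + o * vol$spacing)
  else volume(sub)
}

#' Merge per-patch predictions into a full volume
#'
#' An all-zero base map on the full grid receives each patch prediction at
#' its offsets; every voxel is then divided by its overlap count. Patches
#' cut from a single volume therefore merge back to that volume exactly,
#' and each merged voxel is a convex combination of the predictions that
#' cover it.
#'
#' @param preds list of per-patch predictions ([volume()]s or 3D arrays),
#'   one per layout patch, each of `patch_shape`.
#' @param layout a [patch_layout()].
#' @return A [volume()] on the full grid.
#' @export
merge_patches <- function(preds, layout) {
  stopifnot(inherits(layout, "patch_layout"))
  if (length(preds) != n_patches(layout))
    stop("need exactly one prediction per patch")
  arrs <- lapply(preds, vol_data)
  for (a in arrs)
    if (!identical(dim(a), layout$patch_shape))
      stop("prediction shape does not match the layout patch shape")
  merged <- cpp_merge_patches(arrs, layout$offsets, layout$grid_shape)
  ref <- preds[[1]]
  if (is_volume(ref)) {
    o <- layout$offsets[1, ]
    volume(merged, ref$spacing, ref$origin - o * ref$spacing)
  } else volume(merged)
}
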