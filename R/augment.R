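#' Cyclic rotation-angle schedule for training augmentation
#'
#' Each training epoch rotates every image of the epoch by one angle triple
#' \eqn{(\theta_x, \theta_y, \theta_z)}. Each component is the sum of a
#' fixed part, drawn in order from the sequence (1, -1, 3, -3, 5, -5, 7, -7)
#' degrees, and a random jitter drawn uniformly from the open interval
#' (-1, 1) degrees, independently per axis. The fixed parts enumerate all
#' 8^3 = 512 triples lexicographically with the z component varying fastest,
#' so the schedule cycles with period 512 epochs: epoch 0 uses fixed triple
#' (1, 1, 1), epoch 1 uses (1, 1, -1), and epoch 511 uses (-7, -7, -7).
#' With `n` training subjects and one subject per iteration, one full
#' augmentation period spans `512 * n` iterations (13,312 for n = 26).
#'
#' @param seed integer; seeds the jitter stream. Draws are reproducible
#'   given (`seed`, `epoch`) and do not disturb the caller's RNG.
#' @return A `rotation_schedule` object.
#' @export
rotation_schedule <- function(seed = 0L) {
  structure(list(theta_f = c(1, -1, 3, -3, 5, -5, 7, -7),
                 seed = as.integer(seed)),
            class = "rotation_schedule")
}

#' @rdname rotation_schedule
#' @param epoch non-negative epoch counter; taken modulo 512.
#' @return `fixed_triple()`: the fixed-part angles in degrees.
#' @export
fixed_triple <- function(epoch) {
  stopifnot(epoch >= 0)
  tf <- c(1, -1, 3, -3, 5, -5, 7, -7)
  e <- as.integer(epoch) %% 512L
  i <- e %/% 64L
  j <- (e %/% 8L) %% 8L
  k <- e %% 8L
  c(tf[i + 1L], tf[j + 1L], tf[k + 1L])
}

#' @rdname rotation_schedule
#' @param schedule a `rotation_schedule`.
#' @return `draw_angles()`: the epoch's full angles (fixed + jitter),
#'   degrees.
#' @export
draw_angles <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "rotation_schedule"))
  jitter <- with_private_seed(derive_seed(schedule$seed, epoch),
                              runif(3, -1, 1))
  fixed_triple(epoch) + jitter
}

#' @rdname rotation_schedule
#' @param n_subjects training subjects per epoch (one iteration each).
#' @return `augmentation_period()`: iterations per full 512-epoch cycle.
#' @export
augmentation_period <- function(n_subjects) 512L * as.integer(n_subjects)

# Intrinsic rotation matrix: rotate about x, then y, then z (degrees).
rotation_matrix <- function(angles) {
  r <- angles * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotate a volume about its grid centre
#'
#' Rotates the voxel coordinates by the given angles (degrees; applied about
#' x, then y, then z) around the geometric centre of the grid, in physical
#' coordinates. Values are resampled with trilinear interpolation;
#' coordinates falling outside the original extent are filled with `fill`
#' (-1, the air/background level of normalized volumes).
#'
#' @param vol a [volume()].
#' @param angles numeric length-3, degrees.
#' @param inverse apply the inverse rotation instead (undoes a previous
#'   `rotate_volume` call with the same `angles`, up to interpolation blur).
#' @param fill value assigned outside the original extent.
#' @return The rotated [volume()] on the unchanged grid.
#' @export
rotate_volume <- function(vol, angles, inverse = FALSE, fill = -1) {
  stopifnot(is_volume(vol))
  R <- rotation_matrix(angles)
  Rsamp <- if (inverse) R else t(R)      # out(p) = in(R^-1 p); R orthogonal
  d <- dim(vol$data)
  sp <- vol$spacing
  ctr <- (d - 1) / 2                      # centre in index units
  # source index = S^-1 Rsamp S (idx - ctr) + ctr, S = diag(spacing)
  M <- diag(1 / sp) %*% Rsamp %*% diag(sp)
  A <- cbind(M, as.numeric(ctr - M %*% ctr))
  out <- cpp_affine_trilinear(vol$data, A, as.integer(d), fill)
  volume(out, vol$spacing, vol$origin)
}

#' Rotate both volumes of a pair by the same angles
#'
#' Source and target receive the identical transform, so their
#' co-registration is preserved: augmentation changes pose, never the
#' source-target correspondence.
#'
#' @param sample a [paired_sample()] (intensities expected in \eqn{[-1, 1]}).
#' @param angles numeric length-3, degrees (e.g. from [draw_angles()]).
#' @inheritParams rotate_volume
#' @return The rotated `paired_sample`.
#' @export
rotate_pair <- function(sample, angles, inverse = FALSE, fill = -1) {
  stopifnot(inherits(sample, "paired_sample"))
  paired_sample(rotate_volume(sample$mr, angles, inverse, fill),
                rotate_volume(sample$ct, angles, inverse, fill),
                mr_norm = sample$mr_norm, ct_norm = sample$ct_norm,
                subject_id = sample$subject_id)
}
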