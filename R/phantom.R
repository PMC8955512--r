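#' Specification of the synthetic paired head phantom
#'
#' The phantom emulates the structure of a co-registered head MR/CT pair:
#' an ellipsoidal head (rotated axes, jittered centre) inside an air
#' background, an outer skull shell, a textured brain interior and a
#' variable number of soft-edged lesion blobs. The source (MR-like) volume
#' shows the skull dark and the brain bright and textured; the target
#' (CT-like) volume is a *deterministic function of the tissue classes and
#' the same texture field* (skull bright, brain mid-grey with inverted,
#' damped texture), so the true target of the translation task is exactly
#' known. The source is generated on a finer grid with a smaller field of
#' view than the target, exercising the FOV harmonisation and resampling
#' path.
#'
#' "Outlier" subjects mimic the atypical cases of a clinical test set:
#' more and larger lesions, a CT-bright (postoperative-like) lesion
#' variant, and a skull defect.
#'
#' @param mr_shape,mr_spacing source grid (voxels) and voxel size (mm).
#' @param ct_shape,ct_spacing target grid and voxel size; covers a larger
#'   FOV than the source.
#' @param semi_axes_frac range of head semi-axes as a fraction of the
#'   source half-extent.
#' @param shell_mm skull shell thickness in mm.
#' @param n_lesions_range inclusive range of lesion counts per subject.
#' @param lesion_radius_mm lesion radius range in mm.
#' @param texture_len_mm correlation length of the smooth intensity
#'   texture (lattice spacing of the interpolated noise field).
#' @param noise_sd standard deviation of additive Gaussian noise as a
#'   fraction of the unit dynamic range; 0 gives exactly reproducible
#'   clean pairs.
#' @param outlier_frac fraction of subjects drawn from the extreme ends of
#'   the lesion/defect ranges (default 2 of every 31).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(mr_shape = c(64, 64, 32), mr_spacing = c(3, 3, 4),
                         ct_shape = c(48, 48, 32), ct_spacing = c(5, 5, 5),
                         semi_axes_frac = c(0.65, 0.80), shell_mm = 6,
                         n_lesions_range = c(0, 3),
                         lesion_radius_mm = c(8, 18),
                         texture_len_mm = 18, noise_sd = 0.01,
                         outlier_frac = 2 / 31) {
  stopifnot(noise_sd >= 0, shell_mm > 0,
            semi_axes_frac[1] <= semi_axes_frac[2],
            semi_axes_frac[2] < 1)
  structure(list(mr_shape = as.integer(mr_shape), mr_spacing = mr_spacing,
                 ct_shape = as.integer(ct_shape), ct_spacing = ct_spacing,
                 semi_axes_frac = semi_axes_frac, shell_mm = shell_mm,
                 n_lesions_range = as.integer(n_lesions_range),
                 lesion_radius_mm = lesion_radius_mm,
                 texture_len_mm = texture_len_mm, noise_sd = noise_sd,
                 outlier_frac = outlier_frac),
            class = "phantom_spec")
}

# tissue classes: 0 air, 1 skull, 2 brain, 3 lesion, 4 CT-bright lesion
phantom_mr_base <- c(0.02, 0.12, 0.72, 0.52, 0.47)
phantom_mr_texw <- c(0.00, 0.02, 0.16, 0.10, 0.10)
phantom_ct_base <- c(0.03, 0.92, 0.34, 0.46, 0.85)
phantom_ct_texw <- c(0.00, 0.02, -0.08, -0.06, -0.04)

#' Deterministic class-to-intensity mappings of the phantom
#'
#' These two functions *are* the ground-truth relationship between the
#' phantom's source and target modalities: given the tissue-class map and
#' the shared texture field, they reproduce the clean source and target
#' volumes exactly. They are exported so tests can verify generated pairs
#' against the mapping they were built from.
#'
#' @param classes integer array of tissue classes (0 air, 1 skull, 2
#'   brain, 3 lesion, 4 CT-bright lesion).
#' @param tex numeric array, the smooth texture field on the same grid.
#' @return Numeric array of intensities (arbitrary units, roughly [0, 1]).
#' @export
phantom_ct_intensity <- function(classes, tex) {
  out <- phantom_ct_base[classes + 1L] + phantom_ct_texw[classes + 1L] * tex
  array(out, dim(classes))
}

#' @rdname phantom_ct_intensity
#' @export
phantom_mr_intensity <- function(classes, tex) {
  out <- phantom_mr_base[classes + 1L] + phantom_mr_texw[classes + 1L] * tex
  array(out, dim(classes))
}

# Physical voxel-centre coordinate arrays of a grid.
grid_coords <- function(shape, spacing, origin) {
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

# Tissue classes on a grid for one subject's geometry.
phantom_classes <- function(shape, spacing, origin, geo) {
  co <- grid_coords(shape, spacing, origin)
  n <- prod(shape)
  X <- array(co$x, shape)
  Y <- array(rep(co$y, each = shape[1]), shape)
  Z <- array(rep(co$z, each = shape[1] * shape[2]), shape)
  P <- rbind(as.numeric(X) - geo$center[1],
             as.numeric(Y) - geo$center[2],
             as.numeric(Z) - geo$center[3])
  U <- crossprod(geo$rot, P)              # head frame
  r2 <- (U[1, ] / geo$a[1])^2 + (U[2, ] / geo$a[2])^2 + (U[3, ] / geo$a[3])^2
  ai <- geo$a - geo$shell
  r2i <- (U[1, ] / ai[1])^2 + (U[2, ] / ai[2])^2 + (U[3, ] / ai[3])^2
  cls <- integer(n)                        # air
  cls[r2 <= 1] <- 1L                       # skull shell
  cls[r2i <= 1] <- 2L                      # brain interior
  if (nrow(geo$lesions)) {
    for (li in seq_len(nrow(geo$lesions))) {
      L <- geo$lesions[li, ]
      d2 <- (as.numeric(X) - L[1])^2 + (as.numeric(Y) - L[2])^2 +
        (as.numeric(Z) - L[3])^2
      hit <- d2 <= L[4]^2 & cls == 2L
      cls[hit] <- as.integer(L[5])
    }
  }
  if (!is.null(geo$defect)) {
    d2 <- (as.numeric(X) - geo$defect[1])^2 + (as.numeric(Y) - geo$defect[2])^2 +
      (as.numeric(Z) - geo$defect[3])^2
    cls[d2 <= geo$defect[4]^2 & cls == 1L] <- 0L
  }
  array(cls, shape)
}

# Smooth texture: trilinear interpolation of a coarse N(0,1) lattice
# shared by both grids of a pair.
phantom_texture <- function(shape, spacing, origin, lat) {
  A <- cbind(diag(spacing / lat$spacing),
             (origin - lat$origin) / lat$spacing)
  cpp_affine_trilinear(lat$values, A, as.integer(shape), 0)
}

#' Generate one synthetic co-registered source/target pair
#'
#' Draws a subject geometry (head ellipsoid, skull shell, lesions) and a
#' texture field from `subject_seed`, then renders the source volume on
#' the fine source grid and the target volume on the coarser, larger
#' target grid via the deterministic mappings [phantom_mr_intensity()] and
#' [phantom_ct_intensity()], plus additive Gaussian noise. With
#' `noise_sd = 0` the generated volumes equal the mappings exactly, so
#' translation error against the known target can be measured absolutely.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer seed; identical seeds give identical pairs.
#' @param outlier draw this subject from the extreme lesion/defect ranges.
#' @return A `phantom_pair`: list with `mr` and `ct` [volume()]s, the
#'   per-grid class maps and texture fields, the clean (pre-noise)
#'   intensity arrays, the geometry, and the flags used.
#' @export
phantom_pair <- function(spec, subject_seed, outlier = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_private_seed(subject_seed, {
    ct_origin <- spec$ct_spacing / 2
    ct_extent <- spec$ct_shape * spec$ct_spacing
    center_fov <- ct_origin - spec$ct_spacing / 2 + ct_extent / 2
    mr_extent <- spec$mr_shape * spec$mr_spacing
    mr_origin <- center_fov - mr_extent / 2 + spec$mr_spacing / 2
    half <- mr_extent / 2

    a <- runif(3, spec$semi_axes_frac[1], spec$semi_axes_frac[2]) * half
    rot <- rotation_matrix(c(runif(1, -6, 6), 0, runif(1, -8, 8)))
    center <- center_fov + runif(3, -5, 5)
    les_choices <- seq(spec$n_lesions_range[1], spec$n_lesions_range[2])
    nles <- if (outlier) sample(4:6, 1) else
      les_choices[sample.int(length(les_choices), 1)]
    rmax <- if (outlier) spec$lesion_radius_mm[2] * 1.3 else spec$lesion_radius_mm[2]
    lesions <- matrix(numeric(0), 0, 5)
    for (li in seq_len(nles)) {
      r <- runif(1, spec$lesion_radius_mm[1], rmax)
      u <- runif(3, -1, 1)
      while (sum(u^2) > 1) u <- runif(3, -1, 1)
      pos <- center + as.numeric(rot %*% (u * pmax(a - spec$shell_mm - r, 1)))
      cls <- if (outlier && li == 1L) 4 else 3
      lesions <- rbind(lesions, c(pos, r, cls))
    }
    defect <- NULL
    if (outlier) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      defect <- c(center + as.numeric(rot %*% (dir * a)), 15)
    }
    geo <- list(center = center, a = a, rot = rot, shell = spec$shell_mm,
                lesions = lesions, defect = defect)

    lat_sp <- rep(spec$texture_len_mm, 3)
    lat_lo <- ct_origin - spec$ct_spacing / 2 - lat_sp
    lat_n <- as.integer(ceiling(ct_extent / lat_sp) + 3)
    lat <- list(values = array(rnorm(prod(lat_n)), lat_n),
                spacing = lat_sp, origin = lat_lo)

    mr_cls <- phantom_classes(spec$mr_shape, spec$mr_spacing, mr_origin, geo)
    ct_cls <- phantom_classes(spec$ct_shape, spec$ct_spacing, ct_origin, geo)
    mr_tex <- phantom_texture(spec$mr_shape, spec$mr_spacing, mr_origin, lat)
    ct_tex <- phantom_texture(spec$ct_shape, spec$ct_spacing, ct_origin, lat)
    mr_clean <- phantom_mr_intensity(mr_cls, mr_tex)
    ct_clean <- phantom_ct_intensity(ct_cls, ct_tex)
    mr_arr <- mr_clean + if (spec$noise_sd > 0)
      array(rnorm(length(mr_clean), 0, spec$noise_sd), dim(mr_clean)) else 0
    ct_arr <- ct_clean + if (spec$noise_sd > 0)
      array(rnorm(length(ct_clean), 0, spec$noise_sd), dim(ct_clean)) else 0

    structure(list(
      mr = volume(mr_arr, spec$mr_spacing, mr_origin),
      ct = volume(ct_arr, spec$ct_spacing, ct_origin),
      mr_classes = mr_cls, ct_classes = ct_cls,
      mr_tex = mr_tex, ct_tex = ct_tex,
      mr_clean = mr_clean, ct_clean = ct_clean,
      geometry = geo, outlier = outlier, subject_seed = subject_seed),
      class = "phantom_pair")
  })
}

#' Generate a reproducible phantom dataset
#'
#' Draws `n_subjects` pairs with distinct derived seeds; a fraction of
#' subjects (by default 2 of every 31, always the last ones drawn) are
#' generated as outliers with extreme lesion counts and a skull defect,
#' mimicking the atypical subjects of a clinical test set.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of pairs.
#' @param seed master seed; subject seeds are derived deterministically.
#' @return List of `phantom_pair`s.
#' @export
phantom_dataset <- function(spec = phantom_spec(), n_subjects = 31L,
                            seed = 1L) {
  stopifnot(n_subjects >= 1L)
  n_out <- round(n_subjects * spec$outlier_frac)
  lapply(seq_len(n_subjects), function(i)
    phantom_pair(spec, derive_seed(seed, i),
                 outlier = i > n_subjects - n_out))
}

#' Split a phantom dataset into training and test pairs
#'
#' Outlier subjects are assigned to the test set first (the atypical cases
#' belong with validation, as in the study design the phantom emulates);
#' the remaining test slots take the last ordinary subjects. The default
#' split of a 31-subject dataset is 26 training / 5 test pairs.
#'
#' @param pairs list of `phantom_pair`s from [phantom_dataset()].
#' @param n_test number of test pairs.
#' @return List with `train` and `test` lists.
#' @export
split_phantoms <- function(pairs, n_test = 5L) {
  stopifnot(n_test >= 1L, n_test < length(pairs))
  is_out <- vapply(pairs, function(p) isTRUE(p$outlier), TRUE)
  test_idx <- which(is_out)
  if (length(test_idx) > n_test) test_idx <- tail(test_idx, n_test)
  rest <- setdiff(seq_along(pairs), test_idx)
  extra <- tail(rest, n_test - length(test_idx))
  test_idx <- sort(c(test_idx, extra))
  list(train = pairs[setdiff(seq_along(pairs), test_idx)],
       test = pairs[test_idx])
}
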