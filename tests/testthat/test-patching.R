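# Independent membership-count oracle used against overlap_map().
brute_counts <- function(layout) {
  cnt <- array(0L, layout$grid_shape)
  p <- layout$patch_shape
  for (r in seq_len(nrow(layout$offsets))) {
    o <- layout$offsets[r, ]
    for (k in seq_len(p[3])) for (j in seq_len(p[2])) for (i in seq_len(p[1]))
      cnt[o[1] + i, o[2] + j, o[3] + k] <- cnt[o[1] + i, o[2] + j, o[3] + k] + 1L
  }
  cnt
}

test_that("the production layout places corners plus centre and covers the grid", {
  lay <- default_layout(c(200, 200, 128), c(128, 128, 128))
  expect_identical(unname(lay$offsets),
                   matrix(as.integer(c(0, 0, 0, 72, 0, 0, 36, 36, 0,
                                       0, 72, 0, 72, 72, 0)),
                          ncol = 3, byrow = TRUE))
  om <- overlap_map(lay)
  expect_identical(sum(om == 0L), 0L)                      # full coverage
  expect_identical(range(om), c(1L, 5L))
  expect_equal(sum(as.numeric(om)), 5 * 128^3)             # conservation
  # centre overlap of all five patches, corner covered only by p1
  expect_true(all(om[73:128, 73:128, ] == 5L))
  expect_true(all(om[1:36, 1:36, ] == 1L))
})

test_that("layout construction generalizes and degenerates safely", {
  lay <- default_layout(c(64, 64, 32), c(40, 40, 32))
  expect_setequal(apply(lay$offsets, 1, paste, collapse = ","),
                  c("0,0,0", "24,0,0", "0,24,0", "24,24,0", "12,12,0"))
  expect_identical(overlap_map(lay), brute_counts(lay))

  degen <- default_layout(c(32, 32, 16), c(32, 32, 16))
  expect_true(all(degen$offsets == 0L))
  expect_true(all(overlap_map(degen) == 5L))

  expect_error(default_layout(c(32, 32, 16), c(40, 40, 16)), "larger")
  expect_error(default_layout(c(64, 64, 32), c(32, 32, 16)), "z extent")
  # a too-small patch leaves an uncovered gap between the corner patches
  expect_error(default_layout(c(64, 64, 32), c(24, 24, 32)), "cover")
})

test_that("extract_patch slices exactly and updates the origin", {
  lay <- default_layout(c(64, 64, 32), c(32, 32, 32))
  v <- rand_volume(c(64, 64, 32), seed = 4, spacing = c(3, 3, 4))
  p1 <- extract_patch(v, lay, 1)
  expect_identical(p1$data, v$data[1:32, 1:32, 1:32])
  expect_identical(unname(lay$offsets[1, ]), c(0L, 0L, 0L))  # upper-left corner
  p3 <- extract_patch(v, lay, 3)
  expect_identical(p3$data, v$data[17:48, 17:48, 1:32])
  expect_equal(p3$origin, v$origin + c(16, 16, 0) * v$spacing)
  expect_error(extract_patch(v, lay, 6), "index")
})

test_that("merging patches of one volume restores it exactly", {
  lay <- default_layout(c(64, 64, 32), c(32, 32, 32))
  v <- rand_volume(c(64, 64, 32), seed = 8)
  patches <- lapply(1:5, function(i) extract_patch(v, lay, i))
  merged <- merge_patches(patches, lay)
  expect_identical(merged$data, v$data)
})

test_that("merged values are convex combinations of the patch predictions", {
  lay <- default_layout(c(64, 64, 32), c(32, 32, 32))
  # constant predictions 0 and 1 on two overlapping patches: averages in between
  preds <- lapply(1:5, function(i) array((i - 1) %% 2, c(32, 32, 32)))
  merged <- merge_patches(preds, lay)
  om <- overlap_map(lay)
  expect_true(all(merged$data >= 0 & merged$data <= 1))
  # p1 (value 0) and p2 (value 1) overlap in x 33:48 where y is p1/p2 only
  expect_true(all(merged$data[33:48, 1:17, ][om[33:48, 1:17, ] == 2L] == 0.5))

  # constant-c everywhere is conserved under overlap division
  const <- lapply(1:5, function(i) array(0.37, c(32, 32, 32)))
  expect_true(all(merge_patches(const, lay)$data == 0.37))

  expect_error(merge_patches(preds[1:4], lay), "one prediction per patch")
  bad <- preds; bad[[2]] <- array(0, c(16, 32, 32))
  expect_error(merge_patches(bad, lay), "shape")
})
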