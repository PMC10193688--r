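test_that("resampling through the identity returns the volume unchanged", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  can <- cached_anatomy(cfg)$volume
  out <- resample_volume(can)
  expect_equal(out$data, can$data, tolerance = 1e-12)
})

test_that("a one-voxel translation shifts grid contents by one index", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  can <- cached_anatomy(cfg)$volume
  vs <- voxel_size(can)[1]
  # pull convention: sampling at x + one voxel shifts content down an index
  out <- resample_volume(can, rigid_transform(translation_mm = c(vs, 0, 0)),
                         fill = -99)
  d <- dim(can)
  expect_equal(out$data[1:(d[1] - 1), , ], can$data[2:d[1], , ],
               tolerance = 1e-12)
  expect_true(all(out$data[d[1], , ] == -99))
})

test_that("resampling round-trip error is below 1% of dynamic range", {
  # smooth analytic field: sum of broad Gaussian blobs
  d <- c(48, 48, 32)
  ijk <- nigramap:::grid_index_matrix(d)
  blob <- function(c0, s, a) a * exp(-colSums((ijk - c0)^2) / (2 * s^2))
  f <- blob(c(20, 24, 16), 10, 100) + blob(c(30, 20, 12), 8, 60) +
    blob(c(24, 32, 20), 12, 40)
  smooth <- nm_volume(array(f, d), voxel_size_mm = 0.8)
  xf <- rigid_transform(c(2, -1, 3), c(1.1, -0.7, 0.4))
  fwd <- resample_volume(smooth, xf, fill = 0)
  back <- resample_volume(fwd, invert_rigid(xf), fill = 0)
  interior <- nigramap:::erode_mask(array(TRUE, d), 4)
  err <- abs(back$data - smooth$data)[interior]
  expect_lt(max(err), 0.01 * diff(range(smooth$data)))
})

test_that("intensity normalization fixes the reference mean at 1 and is idempotent", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  anat <- cached_anatomy(cfg)
  ref <- anat$masks$reference
  v <- nm_volume(anat$volume$data * 3.7, affine = anat$volume$affine)
  n1 <- normalize_intensity(v, ref)
  expect_equal(mean(n1$data[ref]), 1.0, tolerance = 1e-12)
  # scale invariance: any positive rescaling normalizes to the same volume
  n2 <- normalize_intensity(
    nm_volume(v$data * 0.25, affine = v$affine), ref)
  expect_equal(n1$data, n2$data, tolerance = 1e-12)
  # idempotence
  expect_equal(normalize_intensity(n1, ref)$data, n1$data,
               tolerance = 1e-12)
  expect_error(normalize_intensity(v, ref & FALSE), "empty")
})

test_that("CR is invariant under global rescaling and intensity normalization", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  anat <- cached_anatomy(cfg)
  v <- anat$volume
  cr0 <- contrast_ratio(v, anat$masks$left_n1, anat$masks$reference)
  v2 <- nm_volume(v$data * 12.3, affine = v$affine)
  expect_equal(contrast_ratio(v2, anat$masks$left_n1, anat$masks$reference),
               cr0, tolerance = 1e-12)
  v3 <- normalize_intensity(v2, anat$masks$reference)
  expect_equal(contrast_ratio(v3, anat$masks$left_n1, anat$masks$reference),
               cr0, tolerance = 1e-12)
})

test_that("foreground stripping recovers the head region and flags degenerate input", {
  cfg <- phantom_config(grid_shape = c(48, 48, 32), n_per_group = 2,
                        seed = 5)
  anat <- cached_anatomy(cfg)
  # noise-free: mask equals the foreground ellipsoid
  fg <- strip_background(anat$volume)
  expect_true(all(fg[anat$masks$left_snpc]))
  expect_true(all(fg[anat$masks$reference]))
  expect_gt(mean(fg == anat$masks$foreground), 0.99)
  # noisy subject: mask still contains all SNpc and reference voxels
  sim <- simulate_cohort(cfg, aligned = TRUE)
  fg2 <- strip_background(sim$volumes[[1]])
  expect_true(all(fg2[anat$masks$left_snpc | anat$masks$right_snpc]))
  expect_error(strip_background(nm_volume(array(1, c(8, 8, 8)))),
               "constant")
})

test_that("registration recovers identity for self-registration", {
  cfg <- phantom_config(grid_shape = c(48, 48, 32), n_per_group = 2)
  can <- cached_anatomy(cfg)$volume
  xf <- register_rigid(can, can)
  expect_lt(max(abs(xf$rotation_deg)), 0.1)
  expect_lt(sqrt(sum(xf$translation_mm^2)), 0.1)
})

test_that("registration recovers known transforms to sub-voxel accuracy", {
  cfg <- phantom_config(grid_shape = c(48, 48, 32), n_per_group = 2)
  can <- cached_anatomy(cfg)$volume
  # rotation + translation case at the documented tolerance
  xf <- rigid_transform(c(4, 0, 0), c(1.5, 0, 0))
  mov <- render_moved_anatomy(cfg, xf)
  rec <- register_rigid(mov, can)
  expect_rigid_close(rec, xf, rot_tol = 0.5, trans_tol = 0.4)
  # pure translation of two voxels: analytic optimum, < 0.1 voxel error
  xf2 <- rigid_transform(c(0, 0, 0), c(2 * 0.8, 0, 0))
  mov2 <- render_moved_anatomy(cfg, xf2)
  rec2 <- register_rigid(mov2, can)
  expect_rigid_close(rec2, xf2, rot_tol = 0.2, trans_tol = 0.1 * 0.8)
})
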