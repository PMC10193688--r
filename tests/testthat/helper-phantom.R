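# Shared fixtures, built in code. Small grids keep the unit suite fast;
# full-size (64 x 64 x 48) cohorts are reserved for the acceptance checks.

small_config <- function(...) {
  phantom_config(grid_shape = c(48, 48, 32), n_per_group = 3, seed = 101,
                 ...)
}

# Canonical anatomy cache (grids are deterministic given the config).
.anat_cache <- new.env(parent = emptyenv())
cached_anatomy <- function(config) {
  key <- paste(c(config$grid_shape, config$background_intensity,
                 config$snpc_intensity), collapse = "x")
  if (is.null(.anat_cache[[key]]))
    .anat_cache[[key]] <- make_canonical_anatomy(config)
  .anat_cache[[key]]
}

# Render the canonical anatomy observed through a rigid transform, exactly
# (no interpolation): the analytic counterpart of resample_volume().
render_moved_anatomy <- function(config, xform) {
  can <- cached_anatomy(config)$volume
  m <- solve(can$affine) %*% rigid_matrix(xform) %*% can$affine
  coords <- m[1:3, 1:3] %*% nigramap:::grid_index_matrix(dim(can)) +
    m[1:3, 4]
  nm_volume(array(nigramap:::render_anatomy(config, coords), dim(can)),
            affine = can$affine)
}

# Ground-truth ROI set (the fixed-mask convention of the phantom pipeline).
truth_roiset <- function(sim) {
  labs <- sim$masks[c("left_n1", "left_n2", "right_n1", "right_n2",
                      "left_snpc", "right_snpc", "reference")]
  vv <- prod(voxel_size(sim$canonical))
  structure(list(
    labels = labs,
    volumes_mm3 = tibble::tibble(
      label = names(labs),
      n_voxels = unname(vapply(labs, sum, numeric(1))),
      volume_mm3 = unname(vapply(labs, function(m) sum(m) * vv,
                                 numeric(1)))),
    affine = sim$canonical$affine, alpha = NA_real_,
    status = character(0)), class = "nm_roiset")
}

# Aligned cohort -> reference-normalized volumes + CR table against the
# ground-truth ROI set.
cohort_cr_table <- function(config) {
  sim <- simulate_cohort(config, aligned = TRUE)
  normed <- lapply(sim$volumes, function(v)
    normalize_intensity(v, sim$masks$reference))
  list(sim = sim,
       cr = build_cr_table(sim$cohort, normed, truth_roiset(sim)))
}

expect_rigid_close <- function(a, b, rot_tol, trans_tol) {
  err <- nigramap:::rigid_magnitude(compose_rigid(a, b))
  expect_lt(err[["rot_deg"]], rot_tol)
  expect_lt(err[["trans_mm"]], trans_tol)
}
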