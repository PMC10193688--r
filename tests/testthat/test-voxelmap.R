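make_noise_volumes <- function(n, canon, noise_sd = 4, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    nm_volume(canon$data +
                array(stats::rnorm(length(canon$data), 0, noise_sd),
                      dim(canon$data)),
              affine = canon$affine)))
}

test_that("relabeling identical groups yields zero statistics and p = 1", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  anat <- cached_anatomy(cfg)
  vols <- make_noise_volumes(3, anat$volume, seed = 2)
  amask <- dilate_mask(anat$masks$left_snpc | anat$masks$right_snpc, 1)
  sm <- voxelwise_test(vols, vols, amask, n_perm = 100, seed = 3)
  idx <- which(amask)
  expect_true(all(abs(sm$statistic[idx]) < 1e-12))
  expect_true(all(sm$p_raw[idx] > 1 - 1e-12))
  expect_true(all(sm$p_corrected[idx] == 1))
})

test_that("zero-variance voxels are flagged and excluded from correction", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  anat <- cached_anatomy(cfg)
  # constant volumes: every voxel in the mask is degenerate
  vols <- lapply(1:4, function(i) anat$volume)
  amask <- dilate_mask(anat$masks$left_snpc, 1)
  sm <- voxelwise_test(vols[1:2], vols[3:4], amask, n_perm = 50, seed = 1)
  idx <- which(amask)
  expect_true(all(is.na(sm$statistic[idx])))
  expect_true(all(is.na(sm$p_corrected[idx])))
})

test_that("statistics match a direct pooled t-test voxel by voxel", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2)
  anat <- cached_anatomy(cfg)
  va <- make_noise_volumes(5, anat$volume, seed = 10)
  vb <- make_noise_volumes(4, anat$volume, seed = 11)
  amask <- array(FALSE, dim(anat$volume))
  amask[15:17, 15:17, 15:17] <- TRUE
  sm <- voxelwise_test(va, vb, amask, n_perm = 10, seed = 1)
  for (idx in sample(which(amask), 5)) {
    xa <- vapply(va, function(v) v$data[idx], numeric(1))
    xb <- vapply(vb, function(v) v$data[idx], numeric(1))
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    expect_equal(sm$statistic[idx], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(sm$p_raw[idx], tt$p.value, tolerance = 1e-10)
  }
})

test_that("corrected p never undercuts raw p and thresholds nest monotonically", {
  cfg <- phantom_config(grid_shape = c(48, 48, 32), n_per_group = 8,
                        seed = 21, sn_deficit_mean = 0, asymmetry_boost = 0)
  sim <- simulate_cohort(cfg, aligned = TRUE)
  normed <- lapply(sim$volumes, function(v)
    normalize_intensity(v, sim$masks$reference))
  amask <- dilate_mask(sim$masks$left_snpc | sim$masks$right_snpc, 2)
  hc <- normed[sim$cohort$subject_id[sim$cohort$group == "HC"]]
  ipd <- normed[sim$cohort$subject_id[sim$cohort$group == "IPD"]]
  sm <- voxelwise_test(hc, ipd, amask, n_perm = 200, seed = 5)
  idx <- which(amask)
  good <- !is.na(sm$statistic[idx])
  expect_true(all(sm$p_corrected[idx][good] >= sm$p_raw[idx][good]))
  sig1 <- sm$p_corrected < 0.01 & sm$statistic > 0
  sig5 <- sm$p_corrected < 0.05 & sm$statistic > 0
  expect_true(all(which(sig1) %in% which(sig5)))
})

test_that("constructed two-blob maps extract labeled ROIs with exact volumes", {
  d <- c(64, 64, 48)
  cfg <- phantom_config(grid_shape = d, n_per_group = 2)
  anat <- cached_anatomy(cfg)
  amask <- dilate_mask(anat$masks$left_snpc | anat$masks$right_snpc, 2)
  p <- array(NA_real_, d)
  tstat <- array(NA_real_, d)
  p[amask] <- 1
  tstat[amask] <- 0
  # plant significant blobs exactly on the ground-truth nigrosome masks
  for (lab in c("left_n1", "left_n2", "right_n1", "right_n2")) {
    p[anat$masks[[lab]]] <- 0.001
    tstat[anat$masks[[lab]]] <- 6
  }
  sm <- structure(list(statistic = tstat, p_raw = p, p_corrected = p,
                       mask = amask, affine = anat$volume$affine,
                       n_a = 10, n_b = 10, df = 18, n_perm = 1000,
                       max_t = numeric(0), method = "constructed"),
                  class = "nm_statmap")
  rois <- extract_rois(sm, anat$masks, anat$masks$reference, alpha = 0.05)
  for (lab in c("left_n1", "left_n2", "right_n1", "right_n2")) {
    expect_equal(rois$labels[[lab]], anat$masks[[lab]])
    expect_equal(
      rois$volumes_mm3$volume_mm3[rois$volumes_mm3$label == lab],
      sum(anat$masks[[lab]]) * 0.512)
  }
  # nothing significant -> hard error
  sm$p_corrected[amask] <- 1
  expect_error(extract_rois(sm, anat$masks, anat$masks$reference),
               "no significant voxels")
})

test_that("a single-component side yields N1 with a warning, N2 missing", {
  d <- c(64, 64, 48)
  cfg <- phantom_config(grid_shape = d, n_per_group = 2)
  anat <- cached_anatomy(cfg)
  amask <- dilate_mask(anat$masks$left_snpc | anat$masks$right_snpc, 2)
  p <- array(NA_real_, d); tstat <- array(NA_real_, d)
  p[amask] <- 1; tstat[amask] <- 0
  for (lab in c("left_n1", "left_n2", "right_n1")) {
    p[anat$masks[[lab]]] <- 0.001
    tstat[anat$masks[[lab]]] <- 6
  }
  sm <- structure(list(statistic = tstat, p_raw = p, p_corrected = p,
                       mask = amask, affine = anat$volume$affine,
                       n_a = 10, n_b = 10, df = 18, n_perm = 1000,
                       max_t = numeric(0), method = "constructed"),
                  class = "nm_statmap")
  w <- capture_warnings(
    rois <- extract_rois(sm, anat$masks, anat$masks$reference))
  expect_true(any(grepl("only one significant component on the right", w)))
  expect_null(rois$labels$right_n2)
  expect_equal(rois$labels$right_n1, anat$masks$right_n1)
  expect_equal(rois$labels$left_n1, anat$masks$left_n1)
})
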