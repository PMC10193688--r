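test_that("canonical anatomy satisfies the ground-truth mask invariants", {
  for (grid in list(c(64, 64, 48), c(48, 48, 32), c(32, 32, 32))) {
    cfg <- phantom_config(grid_shape = grid, n_per_group = 2)
    m <- make_canonical_anatomy(cfg)$masks
    for (side in c("left", "right")) {
      n1 <- m[[paste0(side, "_n1")]]
      n2 <- m[[paste0(side, "_n2")]]
      sn <- m[[paste0(side, "_snpc")]]
      expect_false(any(n1 & n2))
      expect_true(all(sn[n1]) && all(sn[n2]))
      expect_false(any(m$reference & sn))
      expect_gt(sum(n1), sum(n2))
    }
    # left N1 larger than right N1, mirroring the template-study asymmetry
    expect_gt(sum(m$left_n1), sum(m$right_n1))
  }
  expect_error(phantom_config(grid_shape = c(8, 8, 8)), "at least 16")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(phantom_config(n1_deficit_mean = 1.2), "\\[0, 1\\)")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(n_per_group = 1), "n_per_group")
})

test_that("zero contrast yields zero CR in every region", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2,
                        snpc_intensity = 100)
  anat <- make_canonical_anatomy(cfg)
  for (lab in c("left_n1", "right_n2", "left_snpc"))
    expect_equal(contrast_ratio(anat$volume, anat$masks[[lab]],
                                anat$masks$reference), 0)
})

test_that("noise-free subjects realize injected deficits exactly", {
  cfg <- small_config(noise_sd = 0, deficit_sd = 0, intensity_scale_sd = 0,
                      misalign_rot_deg_sd = 0, misalign_trans_mm_sd = 0,
                      asymmetry_boost = 0, n1_deficit_mean = 0.3,
                      n2_deficit_mean = 0.1, sn_deficit_mean = 0.05)
  anat <- cached_anatomy(cfg)
  params <- list(group = "IPD", scale = 1,
                 rotation_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
                 deficits = list(left_n1 = 0.3, right_n1 = 0.3,
                                 left_n2 = 0.1, right_n2 = 0.1,
                                 left_sn = 0.05, right_sn = 0.05))
  subj <- simulate_subject(anat$volume, anat$masks, params, cfg)
  m <- anat$masks
  expect_equal(mean(subj$data[m$left_n1]) / mean(anat$volume$data[m$left_n1]),
               0.7, tolerance = 1e-12)
  expect_equal(mean(subj$data[m$right_n2]) / mean(anat$volume$data[m$right_n2]),
               0.9, tolerance = 1e-12)
  rest <- m$left_snpc & !m$left_n1 & !m$left_n2
  expect_equal(mean(subj$data[rest]) / mean(anat$volume$data[rest]),
               0.95, tolerance = 1e-12)
  # HC with unit scale and no perturbation is the canonical volume
  hc <- list(group = "HC", scale = 1, rotation_deg = c(0, 0, 0),
             translation_mm = c(0, 0, 0), deficits = list())
  expect_equal(simulate_subject(anat$volume, anat$masks, hc, cfg)$data,
               anat$volume$data)
  # subject scale multiplies the whole volume
  hc$scale <- 1.7
  expect_equal(simulate_subject(anat$volume, anat$masks, hc, cfg)$data,
               1.7 * anat$volume$data)
})

test_that("cohort generation is a pure function of config and seed", {
  cfg <- small_config()
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$volumes[[5]]$data, s2$volumes[[5]]$data)
  s3 <- simulate_cohort(phantom_config(grid_shape = cfg$grid_shape,
                                       n_per_group = 3, seed = 102))
  expect_false(identical(s1$volumes[[1]]$data, s3$volumes[[1]]$data))
})

test_that("increasing the N1 deficit strictly decreases noise-free IPD N1 CR", {
  crs <- vapply(c(0.05, 0.15, 0.3), function(d) {
    cfg <- small_config(noise_sd = 0, deficit_sd = 0,
                        intensity_scale_sd = 0, misalign_rot_deg_sd = 0,
                        misalign_trans_mm_sd = 0, asymmetry_boost = 0,
                        n1_deficit_mean = d)
    sim <- simulate_cohort(cfg, aligned = TRUE)
    ipd <- sim$cohort$subject_id[sim$cohort$group == "IPD"]
    mean(vapply(ipd, function(id)
      contrast_ratio(sim$volumes[[id]], sim$masks$left_n1,
                     sim$masks$reference), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(crs) < 0))
})

test_that("group-mean CR is lower in patients in all eight regions", {
  out <- cohort_cr_table(phantom_config(grid_shape = c(48, 48, 32),
                                        n_per_group = 10, seed = 77))
  cr <- out$cr
  for (rg in cr_regions()) {
    expect_lt(mean(cr[[rg]][cr$group == "IPD"]),
              mean(cr[[rg]][cr$group == "HC"]))
  }
})

test_that("write_cohort produces a complete, reproducible bundle", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 3,
                        seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cohort(cfg, d1)
  write_cohort(cfg, d2)
  expect_length(p1$images, 6)
  expect_true(all(file.exists(p1$images)))
  csv <- readr::read_csv(p1$cohort_csv, show_col_types = FALSE)
  expect_equal(nrow(csv), 6)
  expect_setequal(unique(csv$group), c("IPD", "HC"))
  expect_identical(readLines(p1$cohort_csv),
                   readLines(file.path(d2, "cohort.csv")))
  expect_identical(readLines(p1$ground_truth_json),
                   readLines(file.path(d2, "ground_truth.json")))
})

test_that("rician noise mode yields non-negative intensities", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_per_group = 2,
                        noise_model = "rician", seed = 4)
  sim <- simulate_cohort(cfg, aligned = TRUE)
  expect_true(all(sim$volumes[[1]]$data >= 0))
})
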