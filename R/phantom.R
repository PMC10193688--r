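#' Configuration of the synthetic midbrain phantom
#'
#' Defines the study conditions the simulated cohorts emulate: two groups
#' (patients and controls), bilateral hyperintense SNpc crescents containing
#' a larger posterolateral nigrosome-1 (N1) and a smaller anteromedial
#' nigrosome-2 (N2) subregion, patient signal loss strongest in N1, then N2,
#' then the remaining SNpc, left/right asymmetry coupled to simulated
#' clinical laterality, per-subject rigid misalignment, global intensity
#' scaling, and additive noise.
#'
#' Intensities are arbitrary units. With the defaults the canonical contrast
#' ratio of every nigral region against the reference region is
#' `(120 - 100) / 100 = 0.2`, and patient deficits put group CR values and
#' effect sizes in the range reported for early-stage disease cohorts.
#'
#' @param grid_shape integer(3) voxels per axis.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_per_group subjects per group (>= 2).
#' @param background_intensity,snpc_intensity arbitrary units; the SNpc
#'   value includes the neuromelanin contrast above background.
#' @param n1_deficit_mean,n2_deficit_mean,sn_deficit_mean mean fractional
#'   signal reduction in patients for N1, N2 and the remaining SNpc, each in
#'   `[0, 1)`.
#' @param deficit_sd between-subject SD of each deficit draw (draws are
#'   truncated at 0).
#' @param asymmetry_boost extra fractional deficit added on the side
#'   contralateral to the simulated dominant symptom side, in `[0, 1)`.
#' @param noise_sd additive noise SD (>= 0).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param misalign_rot_deg_sd,misalign_trans_mm_sd SDs of the per-subject
#'   rigid perturbation (degrees / mm).
#' @param intensity_scale_sd SD of the per-subject log-normal global
#'   intensity scale.
#' @param seed RNG seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return list of class `nm_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 48),
                           voxel_size_mm = 0.8,
                           n_per_group = 50,
                           background_intensity = 100,
                           snpc_intensity = 120,
                           n1_deficit_mean = 0.036,
                           n2_deficit_mean = 0.032,
                           sn_deficit_mean = 0.004,
                           deficit_sd = 0.03,
                           asymmetry_boost = 0.02,
                           noise_sd = 4,
                           noise_model = c("gaussian", "rician"),
                           misalign_rot_deg_sd = 2,
                           misalign_trans_mm_sd = 1,
                           intensity_scale_sd = 0.1,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_per_group = as.integer(n_per_group),
              background_intensity = background_intensity,
              snpc_intensity = snpc_intensity,
              n1_deficit_mean = n1_deficit_mean,
              n2_deficit_mean = n2_deficit_mean,
              sn_deficit_mean = sn_deficit_mean,
              deficit_sd = deficit_sd,
              asymmetry_boost = asymmetry_boost,
              noise_sd = noise_sd,
              noise_model = noise_model,
              misalign_rot_deg_sd = misalign_rot_deg_sd,
              misalign_trans_mm_sd = misalign_trans_mm_sd,
              intensity_scale_sd = intensity_scale_sd,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "nm_phantom_config")
}

validate_phantom_config <- function(cfg) {
  defs <- c(cfg$n1_deficit_mean, cfg$n2_deficit_mean, cfg$sn_deficit_mean,
            cfg$asymmetry_boost)
  if (any(defs < 0 | defs >= 1))
    stop("deficit means and asymmetry_boost must lie in [0, 1)",
         call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 16))
    stop("grid_shape must be three axis lengths of at least 16 voxels",
         call. = FALSE)
  invisible(cfg)
}

# Ellipsoid mask helper: centre and semi-axes in (possibly fractional)
# voxel units on the given grid.
ellipsoid_mask <- function(dim, center, semi) {
  ix <- seq_len(dim[1]) - 1
  iy <- seq_len(dim[2]) - 1
  iz <- seq_len(dim[3]) - 1
  dx2 <- ((ix - center[1]) / semi[1])^2
  dy2 <- ((iy - center[2]) / semi[2])^2
  dz2 <- ((iz - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# The parametric anatomy: every structure is an ellipsoid with centre and
# semi-axes expressed in voxel units of the configured grid, so geometry
# scales with grid size. Returns a named list of (center, semi) pairs.
phantom_geometry <- function(d) {
  cx <- (d - 1) / 2
  st <- list()
  st$foreground <- list(center = cx, semi = c(0.40, 0.34, 0.40) * d)
  for (side in c("left", "right")) {
    s <- if (side == "left") -1 else 1   # RAS+: left = -x
    sn_c <- cx + c(s * 0.145 * d[1], -0.03 * d[2], 0)
    st[[paste0(side, "_snpc")]] <-
      list(center = sn_c, semi = c(0.058, 0.100, 0.175) * d)
    n1_semi <- if (side == "left") c(0.032, 0.048, 0.085) else
      c(0.024, 0.036, 0.068)
    n2_semi <- if (side == "left") c(0.026, 0.032, 0.050) else
      c(0.021, 0.027, 0.044)
    # N1 posterolateral (lateral = away from midline, posterior = -y),
    # N2 anteromedial
    st[[paste0(side, "_n1")]] <- list(
      center = sn_c + c(s * 0.012 * d[1], -0.042 * d[2], -0.030 * d[3]),
      semi = n1_semi * d)
    st[[paste0(side, "_n2")]] <- list(
      center = sn_c + c(-s * 0.012 * d[1], 0.046 * d[2], 0.020 * d[3]),
      semi = n2_semi * d)
  }
  st$reference <- list(center = cx + c(0, 0.20 * d[2], 0),
                       semi = c(0.078, 0.047, 0.083) * d)
  # internal landmarks (aqueduct / red-nucleus / crus-cerebri surrogates):
  # they give the image gradient content in every rotation direction — a
  # featureless ellipsoid leaves rigid rotation nearly unidentifiable —
  # and are never touched by disease effects
  st$aqueduct <- list(center = cx + c(0, -0.11 * d[2], 0),
                      semi = c(0.035 * d[1], 0.035 * d[2], 10 * d[3]))
  for (side in c("left", "right")) {
    s <- if (side == "left") -1 else 1
    st[[paste0(side, "_red")]] <- list(
      center = cx + c(s * 0.06 * d[1], 0.035 * d[2], 0.02 * d[3]),
      semi = c(0.040, 0.050, 0.070) * d)
    st[[paste0(side, "_crus")]] <- list(
      center = cx + c(s * 0.17 * d[1], 0.13 * d[2], 0),
      semi = c(0.070, 0.060, 0.160) * d)
  }
  st
}

# Evaluate structure membership at arbitrary (fractional) 0-based voxel
# coordinates (3 x n matrix).
inside_structure <- function(st, coords) {
  ((coords[1, ] - st$center[1]) / st$semi[1])^2 +
    ((coords[2, ] - st$center[2]) / st$semi[2])^2 +
    ((coords[3, ] - st$center[3]) / st$semi[3])^2 <= 1
}

# Render the anatomy at given voxel coordinates, with optional per-region
# signal multipliers (named left_n1, right_n1, left_n2, right_n2, left_sn,
# right_sn). Because the anatomy is analytic, a rigidly moved subject can
# be rendered exactly by passing transformed coordinates — no interpolation
# enters the simulation.
render_anatomy <- function(config, coords, multipliers = NULL) {
  geo <- phantom_geometry(config$grid_shape)
  bg <- config$background_intensity
  n <- ncol(coords)
  fg <- inside_structure(geo$foreground, coords)
  val <- numeric(n)
  val[fg] <- bg
  for (side in c("left", "right")) {
    val[inside_structure(geo[[paste0(side, "_crus")]], coords) & fg] <-
      0.88 * bg
    val[inside_structure(geo[[paste0(side, "_red")]], coords) & fg] <-
      1.12 * bg
  }
  val[inside_structure(geo$aqueduct, coords) & fg] <- 0.55 * bg
  val[inside_structure(geo$reference, coords)] <- bg
  for (side in c("left", "right")) {
    sn <- inside_structure(geo[[paste0(side, "_snpc")]], coords)
    val[sn] <- config$snpc_intensity
    if (!is.null(multipliers)) {
      n1 <- inside_structure(geo[[paste0(side, "_n1")]], coords)
      n2 <- inside_structure(geo[[paste0(side, "_n2")]], coords)
      val[n1] <- val[n1] * multipliers[[paste0(side, "_n1")]]
      val[n2] <- val[n2] * multipliers[[paste0(side, "_n2")]]
      rest <- sn & !n1 & !n2
      val[rest] <- val[rest] * multipliers[[paste0(side, "_sn")]]
    }
  }
  val
}

#' Canonical noise-free anatomy and ground-truth masks
#'
#' Builds the parametric midbrain surrogate on the configured grid: a large
#' foreground ellipsoid at `background_intensity`, two brighter SNpc
#' crescents (ellipsoids at `snpc_intensity`), posterolateral N1 and
#' anteromedial N2 sub-ellipsoids per side (left N1 larger than right,
#' matching the left-dominant ROI volumes seen in template studies), and a
#' reference-region ellipsoid in homogeneous anterior midline tissue, never
#' touched by disease effects. Geometry scales with the grid so reduced-size
#' phantoms keep the same layout.
#'
#' @param config a [phantom_config()].
#' @return list with `volume` (an `nm_volume`) and `masks` (named list of
#'   logical arrays: `left_n1`, `right_n1`, `left_n2`, `right_n2`,
#'   `left_snpc`, `right_snpc`, `reference`, `foreground`).
#' @export
make_canonical_anatomy <- function(config) {
  d <- config$grid_shape
  geo <- phantom_geometry(d)
  masks <- lapply(geo[c("left_snpc", "right_snpc", "left_n1", "right_n1",
                        "left_n2", "right_n2", "reference", "foreground")],
                  function(st) ellipsoid_mask(d, st$center, st$semi))
  check_anatomy_masks(masks, config)
  coords <- grid_index_matrix(d)
  vol <- array(render_anatomy(config, coords), dim = d)
  list(volume = nm_volume(vol, voxel_size_mm = config$voxel_size_mm),
       masks = masks)
}

check_anatomy_masks <- function(masks, config) {
  need <- c("left_n1", "right_n1", "left_n2", "right_n2",
            "left_snpc", "right_snpc", "reference")
  for (nm in need) {
    if (!any(masks[[nm]]))
      stop(sprintf("grid too small: %s mask is empty", nm), call. = FALSE)
    if (any(masks[[nm]] & !masks$foreground))
      stop(sprintf("grid too small: %s extends outside the foreground", nm),
           call. = FALSE)
  }
  for (side in c("left", "right")) {
    n1 <- masks[[paste0(side, "_n1")]]
    n2 <- masks[[paste0(side, "_n2")]]
    sn <- masks[[paste0(side, "_snpc")]]
    if (any(n1 & n2))
      stop("invalid geometry: N1 and N2 overlap", call. = FALSE)
    if (any((n1 | n2) & !sn))
      stop("invalid geometry: N1/N2 not contained in the SNpc",
           call. = FALSE)
    if (any(masks$reference & sn))
      stop("invalid geometry: reference region overlaps the SNpc",
           call. = FALSE)
  }
  if (sum(masks$left_n1) <= sum(masks$right_n1))
    stop("invalid geometry: left N1 must be larger than right N1",
         call. = FALSE)
  invisible(masks)
}

# Draw the per-subject disease/nuisance parameters. Deficits are drawn
# independently per region per side and truncated at zero; the asymmetry
# boost is added on the side contralateral to the dominant symptom side.
draw_subject_params <- function(group, config) {
  p <- list(group = group)
  p$scale <- exp(stats::rnorm(1, 0, config$intensity_scale_sd))
  p$rotation_deg <- stats::rnorm(3, 0, config$misalign_rot_deg_sd)
  p$translation_mm <- stats::rnorm(3, 0, config$misalign_trans_mm_sd)
  regions <- c(n1 = config$n1_deficit_mean, n2 = config$n2_deficit_mean,
               sn = config$sn_deficit_mean)
  defs <- stats::setNames(numeric(6), c(t(outer(c("left", "right"),
                                                names(regions),
                                                paste, sep = "_"))))
  if (group == "IPD") {
    p$dominant_side <- sample(c("right", "left"), 1)
    affected <- if (p$dominant_side == "right") "left" else "right"
    for (side in c("left", "right")) {
      for (rg in names(regions)) {
        d <- stats::rnorm(1, regions[[rg]], config$deficit_sd)
        if (side == affected) d <- d + config$asymmetry_boost
        defs[[paste(side, rg, sep = "_")]] <- min(max(d, 0), 0.95)
      }
    }
    base <- stats::rpois(1, 4)
    dom_score <- base + 2 + stats::rpois(1, 3)
    if (p$dominant_side == "right") {
      p$right_motor_score <- dom_score; p$left_motor_score <- base
    } else {
      p$left_motor_score <- dom_score; p$right_motor_score <- base
    }
  } else {
    p$dominant_side <- NA_character_
    p$right_motor_score <- stats::rpois(1, 1)
    p$left_motor_score <- stats::rpois(1, 1)
  }
  p$deficits <- defs
  p
}

#' Simulate one subject volume from the canonical anatomy
#'
#' Controls receive only the per-subject intensity scale, rigid perturbation
#' and noise; patients additionally have the signal inside each N1, N2 and
#' remaining-SNpc region multiplied by `(1 - deficit)` with the subject's
#' drawn deficits. The rigid misalignment is applied by rendering the
#' analytic anatomy at transformed coordinates, so the simulation involves
#' no interpolation: the subject volume equals the canonical anatomy
#' observed through the subject's transform exactly (the subject volume at
#' voxel world position `x` is the anatomy at `T(x)`, matching the pull
#' convention of [resample_volume()]).
#'
#' @param canonical canonical `nm_volume` from [make_canonical_anatomy()].
#' @param masks ground-truth mask list from [make_canonical_anatomy()]
#'   (kept for interface symmetry; the renderer evaluates the same
#'   geometry analytically).
#' @param params per-subject parameter list (`draw_subject_params()` output;
#'   stored per subject in the cohort ground truth).
#' @param config a [phantom_config()].
#' @return `nm_volume` for the subject.
#' @export
simulate_subject <- function(canonical, masks, params, config) {
  d <- dim(canonical)
  mult <- NULL
  if (params$group == "IPD") {
    mult <- list()
    for (k in names(params$deficits)) mult[[k]] <- 1 - params$deficits[[k]]
  }
  xf <- rigid_transform(params$rotation_deg, params$translation_mm,
                        center_mm = c(0, 0, 0))
  coords <- grid_index_matrix(d)
  if (any(params$rotation_deg != 0) || any(params$translation_mm != 0)) {
    m <- solve(canonical$affine) %*% rigid_matrix(xf) %*% canonical$affine
    coords <- m[1:3, 1:3] %*% coords + m[1:3, 4]
  }
  y <- render_anatomy(config, coords, mult) * params$scale
  if (config$noise_sd > 0) {
    if (config$noise_model == "rician") {
      y <- sqrt((y + stats::rnorm(length(y), 0, config$noise_sd))^2 +
                  stats::rnorm(length(y), 0, config$noise_sd)^2)
    } else {
      y <- y + stats::rnorm(length(y), 0, config$noise_sd)
    }
  }
  nm_volume(array(y, dim = d), affine = canonical$affine)
}

#' Simulate a full two-group cohort
#'
#' Deterministic given `config` (which carries the seed): returns subject
#' volumes, the cohort table, and the ground truth (masks plus per-subject
#' drawn parameters).
#'
#' @param config a [phantom_config()].
#' @param aligned if `TRUE`, per-subject rigid misalignment is suppressed
#'   (volumes stay on the canonical grid); used when studying the
#'   statistical chain in isolation from registration.
#' @return list with `volumes` (named list of `nm_volume`), `cohort`
#'   (tibble: subject_id, group, right_motor_score, left_motor_score),
#'   `canonical`, `masks`, and `truth` (tibble of per-subject parameters).
#' @export
simulate_cohort <- function(config, aligned = FALSE) {
  anat <- make_canonical_anatomy(config)
  withr::with_seed(config$seed, {
    n <- config$n_per_group
    ids <- sprintf("sub-%03d", seq_len(2 * n))
    groups <- rep(c("IPD", "HC"), each = n)
    volumes <- vector("list", 2 * n)
    names(volumes) <- ids
    truth <- vector("list", 2 * n)
    for (i in seq_len(2 * n)) {
      p <- draw_subject_params(groups[i], config)
      if (aligned) {
        p$rotation_deg <- c(0, 0, 0)
        p$translation_mm <- c(0, 0, 0)
      }
      truth[[i]] <- p
      volumes[[i]] <- simulate_subject(anat$volume, anat$masks, p, config)
    }
    cohort <- tibble::tibble(
      subject_id = ids,
      group = groups,
      right_motor_score = vapply(truth, `[[`, 0, "right_motor_score"),
      left_motor_score = vapply(truth, `[[`, 0, "left_motor_score"))
    truth_tbl <- tibble::tibble(
      subject_id = ids,
      group = groups,
      dominant_side = vapply(truth, `[[`, "", "dominant_side"),
      scale = vapply(truth, `[[`, 0, "scale"),
      rot_x = vapply(truth, function(p) p$rotation_deg[1], 0),
      rot_y = vapply(truth, function(p) p$rotation_deg[2], 0),
      rot_z = vapply(truth, function(p) p$rotation_deg[3], 0),
      trans_x = vapply(truth, function(p) p$translation_mm[1], 0),
      trans_y = vapply(truth, function(p) p$translation_mm[2], 0),
      trans_z = vapply(truth, function(p) p$translation_mm[3], 0))
    for (k in names(truth[[1]]$deficits))
      truth_tbl[[paste0("deficit_", k)]] <-
        vapply(truth, function(p) p$deficits[[k]], 0)
    list(volumes = volumes, cohort = cohort, canonical = anat$volume,
         masks = anat$masks, truth = truth_tbl)
  })
}

#' Write a simulated cohort to disk
#'
#' One NIfTI-1 file per subject, a cohort CSV, a ground-truth label volume,
#' and a ground-truth JSON (per-subject parameters plus mask volumes in
#' mm^3). Re-running with the same config reproduces identical content.
#'
#' @param config a [phantom_config()].
#' @param out_dir writable output directory (created if missing).
#' @param aligned see [simulate_cohort()].
#' @return invisibly, the paths written (named list).
#' @export
write_cohort <- function(config, out_dir, aligned = FALSE) {
  sim <- simulate_cohort(config, aligned = aligned)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  paths <- character(0)
  cohort <- sim$cohort
  cohort$image_path <- file.path("images",
                                 paste0(cohort$subject_id, ".nii.gz"))
  for (i in seq_len(nrow(cohort))) {
    write_volume(sim$volumes[[cohort$subject_id[i]]],
                 file.path(out_dir, cohort$image_path[i]))
  }
  csv_path <- file.path(out_dir, "cohort.csv")
  readr::write_csv(cohort, csv_path)
  # label volume: 1/2 SNpc L/R, 3/4 N1 L/R, 5/6 N2 L/R, 7 reference
  lab <- array(0L, dim(sim$canonical))
  m <- sim$masks
  lab[m$left_snpc] <- 1L; lab[m$right_snpc] <- 2L
  lab[m$left_n1] <- 3L; lab[m$right_n1] <- 4L
  lab[m$left_n2] <- 5L; lab[m$right_n2] <- 6L
  lab[m$reference] <- 7L
  lab_path <- file.path(out_dir, "ground_truth_labels.nii.gz")
  write_volume(nm_volume(lab + 0, affine = sim$canonical$affine), lab_path)
  vv <- prod(voxel_size(sim$canonical))
  gt <- list(
    config = unclass(config),
    label_legend = list(left_snpc = 1, right_snpc = 2, left_n1 = 3,
                        right_n1 = 4, left_n2 = 5, right_n2 = 6,
                        reference = 7),
    mask_volumes_mm3 = lapply(
      m[c("left_n1", "right_n1", "left_n2", "right_n2",
          "left_snpc", "right_snpc", "reference")],
      function(x) sum(x) * vv),
    subjects = sim$truth)
  json_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(cohort_csv = csv_path, ground_truth_json = json_path,
                 labels = lab_path, images = file.path(out_dir,
                                                       cohort$image_path)))
}
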