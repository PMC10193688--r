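#' Settings for rigid registration
#'
#' Deterministic multi-resolution optimization of a mean-squared-error
#' metric (the pipeline is mono-modal). Optimization is Nelder-Mead at each
#' pyramid level, warm-started from the previous level; initialization comes
#' from a fixed list of starting transforms (identity by default), never
#' from random draws, so results are reproducible bit-for-bit.
#'
#' @param levels integer downsampling factors, coarse to fine.
#' @param max_iter Nelder-Mead iteration cap per level (recycled).
#' @param sample_stride per-level voxel stride for metric evaluation
#'   (recycled): at the full-resolution level the metric is evaluated on a
#'   regular subgrid (stride 2 by default), which keeps full-resolution
#'   image content while costing an eighth of the voxels.
#' @param smooth_sigma per-level Gaussian smoothing (voxels, recycled)
#'   applied to both images before metric evaluation. Smoothing both images
#'   identically leaves the metric optimum at the true alignment while
#'   removing the kinks that sharp edges induce in a trilinear MSE
#'   landscape.
#' @param tolerance relative convergence tolerance passed to the optimizer.
#' @param starts list of `nm_rigid` starting points tried at the coarsest
#'   level; the best few by metric value are refined and the best result
#'   kept. The default is a fixed 27-point grid of rotations (-4, 0, 4
#'   degrees per axis): large rotations can leave the identity inside a
#'   shallow local basin of the coarse metric, and a deterministic start
#'   grid escapes it without random restarts.
#' @return list of class `nm_register_settings`.
#' @export
register_settings <- function(levels = c(4, 2, 1),
                              max_iter = c(500, 400, 400),
                              sample_stride = c(1, 2, 2),
                              smooth_sigma = c(1, 1, 1),
                              tolerance = 1e-7,
                              starts = default_start_grid()) {
  structure(list(levels = levels,
                 max_iter = rep_len(max_iter, length(levels)),
                 sample_stride = rep_len(sample_stride, length(levels)),
                 smooth_sigma = rep_len(smooth_sigma, length(levels)),
                 tolerance = tolerance, starts = starts),
            class = "nm_register_settings")
}

# Fixed deterministic start grid: identity plus rotations of -4/0/4
# degrees about each axis, zero translation.
default_start_grid <- function(step_deg = 4) {
  g <- expand.grid(x = c(-step_deg, 0, step_deg),
                   y = c(-step_deg, 0, step_deg),
                   z = c(-step_deg, 0, step_deg))
  lapply(seq_len(nrow(g)), function(i)
    rigid_transform(as.numeric(g[i, ])))
}

# MSE between fixed and moving-resampled-at-T, over the full fixed grid.
# Out-of-view voxels compare against fill = 0 (the background level), which
# keeps the metric continuous in the transform parameters; excluding them
# instead would change the averaging set discontinuously and create
# spurious local minima at grid-aligned transforms.
rigid_mse <- function(par, moving, fixed_data, ijk, inv_mov_aff, fix_aff,
                      center) {
  xf <- rigid_transform(par[1:3], par[4:6], center)
  m <- inv_mov_aff %*% rigid_matrix(xf) %*% fix_aff
  cpp_mse_affine(as.numeric(moving), dim(moving), m[1:3, , drop = FALSE],
                 ijk, fixed_data, 0)
}

#' Rigid registration of one volume to another
#'
#' Estimates the rigid transform `T` minimizing the mean squared intensity
#' difference between `fixed` and `moving` resampled through `T` (pull
#' convention: `moving(T(x)) ~ fixed(x)`), so
#' `resample_volume(moving, T, fixed)` aligns `moving` into fixed space.
#' Rotation centre is the fixed volume's grid centre in world mm.
#'
#' @param moving,fixed `nm_volume` objects with overlapping fields of view.
#' @param settings a [register_settings()] list.
#' @return an `nm_rigid` with attributes `metric` (final MSE) and
#'   `converged` (logical; `FALSE` flags hitting the iteration cap at the
#'   finest level, with the best transform found still returned and a
#'   warning raised).
#' @export
register_rigid <- function(moving, fixed, settings = register_settings()) {
  center <- as.numeric(voxel_to_world(fixed$affine,
                                      matrix((dim(fixed) - 1) / 2, 3, 1)))
  par <- NULL
  best_val <- Inf
  converged <- TRUE
  for (li in seq_along(settings$levels)) {
    f <- settings$levels[li]
    # scale-space order: smooth at full resolution (sigma scaled by the
    # level factor), then downsample — smoothing after block-mean leaves
    # edge artifacts that bias the metric at fractional offsets
    sg <- settings$smooth_sigma[li] * f
    fx <- downsample_volume(nm_volume(gaussian_smooth(fixed$data, sg),
                                      affine = fixed$affine), f)
    mv <- downsample_volume(nm_volume(gaussian_smooth(moving$data, sg),
                                      affine = moving$affine), f)
    fx_data <- fx$data
    mv_data <- mv$data
    ijk <- grid_index_matrix(dim(fx))
    fixed_data <- as.numeric(fx_data)
    # exclude a boundary shell of 3*sigma (level voxels): smoothing smears
    # content toward the grid edge, where comparison against the
    # out-of-view fill would otherwise penalize every non-identity
    # transform and bias the optimum
    m <- ceiling(3 * settings$smooth_sigma[li])
    d_l <- dim(fx)
    keep <- ijk[1, ] >= m & ijk[1, ] <= d_l[1] - 1 - m &
      ijk[2, ] >= m & ijk[2, ] <= d_l[2] - 1 - m &
      ijk[3, ] >= m & ijk[3, ] <= d_l[3] - 1 - m
    s <- settings$sample_stride[li]
    if (s > 1)
      keep <- keep & ijk[1, ] %% s == 0 & ijk[2, ] %% s == 0 &
        ijk[3, ] %% s == 0
    if (any(keep)) {
      ijk <- ijk[, keep, drop = FALSE]
      fixed_data <- fixed_data[keep]
    }
    inv_mov_aff <- solve(mv$affine)
    obj <- function(p) rigid_mse(p, mv_data, fixed_data, ijk,
                                 inv_mov_aff, fx$affine, center)
    run_nm <- function(p0) {
      # Nelder-Mead with restarts: a fresh simplex from the previous
      # optimum escapes collapsed simplices.
      conv <- FALSE
      val <- Inf
      for (run in 1:3) {
        opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                            control = list(maxit = settings$max_iter[li],
                                           reltol = settings$tolerance))
        p0 <- opt$par
        val <- opt$value
        if (opt$convergence == 0) {
          conv <- TRUE
          break
        }
      }
      list(par = p0, value = val, converged = conv)
    }
    if (is.null(par)) {
      # fixed multi-start list at the coarsest level: refine the best few
      cand <- lapply(settings$starts, function(s)
        c(s$rotation_deg, s$translation_mm))
      vals <- vapply(cand, obj, numeric(1))
      top <- order(vals)[seq_len(min(3L, length(cand)))]
      fits <- lapply(cand[top], run_nm)
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    } else {
      fit <- run_nm(par)
    }
    par <- fit$par
    best_val <- fit$value
    if (li == length(settings$levels) && !fit$converged)
      converged <- FALSE
  }
  if (!converged)
    warning("registration hit the iteration cap; returning best transform",
            call. = FALSE)
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "metric") <- best_val
  attr(out, "converged") <- converged
  out
}
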