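#' Build a group template by iterative registration and averaging
#'
#' Iteration 0 registers every (intensity-normalized) volume to an initial
#' reference — the voxelwise median of the unregistered volumes by default,
#' which is robust and input-order invariant — and averages the aligned
#' volumes. Each subsequent iteration re-registers all volumes to the
#' current average and re-averages. Voxels outside a subject's field of view
#' are excluded from that subject's contribution to the average.
#'
#' @param volumes list of `nm_volume` objects on a common grid.
#' @param n_iter number of re-registration iterations after the initial
#'   alignment (default 3). `n_iter = 0` with `register = FALSE` reduces to
#'   plain voxelwise averaging with identity transforms.
#' @param initial_reference `"median"` (voxelwise median of inputs) or
#'   `"first"` (first volume).
#' @param settings [register_settings()] passed to each registration.
#' @param register set `FALSE` to skip registration entirely (inputs already
#'   aligned); transforms are identity.
#' @return list of class `nm_template` with `template` (`nm_volume`),
#'   `transforms` (named list of `nm_rigid`, one per input),
#'   `iterations_run`, and `convergence` (per-iteration mean MSE against
#'   the reference being registered to).
#' @export
build_template <- function(volumes, n_iter = 3,
                           initial_reference = c("median", "first"),
                           settings = register_settings(),
                           register = TRUE) {
  if (length(volumes) < 2) stop("need at least 2 volumes", call. = FALSE)
  initial_reference <- match.arg(initial_reference)
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("vol%03d", seq_along(volumes))
  grid <- volumes[[1]]

  if (!register) {
    avg <- average_volumes(volumes, lapply(volumes, function(v)
      rigid_transform()), grid, resample = FALSE)
    xfs <- stats::setNames(lapply(volumes, function(v) rigid_transform()),
                           ids)
    return(structure(list(template = avg, transforms = xfs,
                          iterations_run = 0L, convergence = numeric(0)),
                     class = "nm_template"))
  }

  reference <- switch(initial_reference,
    median = {
      stack <- vapply(volumes, function(v) v$data,
                      array(0, dim(grid)))
      nm_volume(apply(stack, 1:3, stats::median), affine = grid$affine)
    },
    first = volumes[[1]])

  xfs <- vector("list", length(volumes))
  convergence <- numeric(0)
  template <- NULL
  for (it in seq_len(n_iter + 1)) {
    target <- if (it == 1) reference else template
    mse_it <- numeric(length(volumes))
    for (i in seq_along(volumes)) {
      xf <- tryCatch(register_rigid(volumes[[i]], target, settings),
                     error = function(e)
                       stop(sprintf("registration failed for %s: %s",
                                    ids[i], conditionMessage(e)),
                            call. = FALSE))
      xfs[[i]] <- xf
      mse_it[i] <- attr(xf, "metric")
    }
    convergence <- c(convergence, mean(mse_it))
    template <- average_volumes(volumes, xfs, grid)
    if (it > n_iter) break
  }
  structure(list(template = template,
                 transforms = stats::setNames(xfs, ids),
                 iterations_run = length(convergence),
                 convergence = convergence),
            class = "nm_template")
}

# Average volumes after resampling through their transforms; out-of-view
# voxels (NA) excluded per subject, voxels covered by no subject set to 0.
average_volumes <- function(volumes, xfs, grid, resample = TRUE) {
  acc <- array(0, dim(grid))
  cnt <- array(0, dim(grid))
  for (i in seq_along(volumes)) {
    v <- if (resample)
      resample_volume(volumes[[i]], xfs[[i]], target = grid,
                      fill = NA_real_)$data
    else volumes[[i]]$data
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  out <- acc
  pos <- cnt > 0
  out[pos] <- acc[pos] / cnt[pos]
  nm_volume(out, affine = grid$affine)
}

#' @export
print.nm_template <- function(x, ...) {
  cat(sprintf("<nm_template> %d subjects, %d iterations\n",
              length(x$transforms), x$iterations_run))
  if (length(x$convergence))
    cat("  mean MSE per iteration:",
        paste(signif(x$convergence, 4), collapse = " "), "\n")
  invisible(x)
}

#' Map template-space ROI masks into a subject's native space
#'
#' Applies the inverse of the subject's template transform to each label
#' mask with nearest-neighbour interpolation, and recomputes volumes in
#' subject space. Provided for the native-space measurement convention; the
#' default pipeline measures CRs in template space on the spatially
#' normalized volumes.
#'
#' @param rois an `nm_roiset` (see [extract_rois()]) or a named list of
#'   logical arrays on the template grid.
#' @param xform the subject's `nm_rigid` (template from subject, as
#'   estimated by registering the subject to the template).
#' @param template template `nm_volume` (geometry source).
#' @param subject subject `nm_volume` (target grid).
#' @return named list of logical masks on the subject grid, with an
#'   attribute `volumes_mm3`.
#' @export
map_rois_to_subject <- function(rois, xform, template, subject) {
  masks <- if (inherits(rois, "nm_roiset")) rois$labels else rois
  inv <- invert_rigid(xform)
  out <- lapply(stats::setNames(names(masks), names(masks)), function(nm) {
    m <- masks[[nm]]
    sm <- resample_mask_nn(m, template$affine, inv, dim(subject),
                           subject$affine)
    if (any(m) && !any(sm))
      stop(sprintf("ROI '%s' fell outside the subject field of view", nm),
           call. = FALSE)
    sm
  })
  vv <- prod(voxel_size(subject))
  attr(out, "volumes_mm3") <- vapply(out, function(m) sum(m) * vv,
                                     numeric(1))
  out
}
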