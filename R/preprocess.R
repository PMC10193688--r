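# Spatial and intensity normalization: trilinear resampling through rigid
# transforms, reference-based intensity normalization, foreground stripping.

# Trilinear interpolation of `arr` at 0-based voxel coordinates `xyz`
# (3 x n matrix). Coordinates outside the grid return `fill`.
sample_trilinear <- function(arr, xyz, fill = NA_real_) {
  cpp_trilinear(as.numeric(arr), dim(arr), xyz, fill)
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' For each target voxel at world position `x`, the output takes the
#' trilinearly interpolated value of `vol` at `xform(x)` ("pull" convention:
#' the transform maps target/fixed space into the source volume's space, as
#' returned by [register_rigid()]). Voxels that map outside the source field
#' of view are set to `fill`.
#'
#' @param vol source `nm_volume`.
#' @param xform an `nm_rigid`; identity by default.
#' @param target target grid: an `nm_volume` or a list with `dim` and
#'   `affine`. Defaults to the source grid.
#' @param fill value for out-of-view voxels.
#' @return `nm_volume` on the target grid.
#' @export
resample_volume <- function(vol, xform = rigid_transform(), target = vol,
                            fill = 0) {
  tdim <- if (inherits(target, "nm_volume")) dim(target) else target$dim
  taff <- if (inherits(target, "nm_volume")) target$affine else target$affine
  m <- solve(vol$affine) %*% rigid_matrix(xform) %*% taff
  ijk <- grid_index_matrix(tdim)
  src <- m[1:3, 1:3] %*% ijk + m[1:3, 4]
  vals <- sample_trilinear(vol$data, src, fill = fill)
  nm_volume(array(vals, dim = tdim), affine = taff)
}

# Resample a logical label mask with nearest-neighbour interpolation.
resample_mask_nn <- function(mask, src_affine, xform, target_dim,
                             target_affine) {
  m <- solve(src_affine) %*% rigid_matrix(xform) %*% target_affine
  ijk <- grid_index_matrix(target_dim)
  src <- round(m[1:3, 1:3] %*% ijk + m[1:3, 4])
  d <- dim(mask)
  valid <- src[1, ] >= 0 & src[1, ] <= d[1] - 1 &
    src[2, ] >= 0 & src[2, ] <= d[2] - 1 &
    src[3, ] >= 0 & src[3, ] <= d[3] - 1
  out <- logical(prod(target_dim))
  idx <- 1 + src[1, valid] + d[1] * src[2, valid] + d[1] * d[2] * src[3, valid]
  out[valid] <- mask[idx]
  array(out, dim = target_dim)
}

# Block-mean downsampling by an integer factor; trims trailing voxels that
# do not fill a complete block and updates the affine accordingly.
downsample_volume <- function(vol, factor) {
  if (factor == 1) return(vol)
  d <- dim(vol)
  nd <- d %/% factor
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- apply(a, c(2, 4, 6), mean)
  aff <- vol$affine
  naff <- aff
  naff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  naff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  nm_volume(a, affine = naff)
}

#' Intensity-normalize a volume by its reference-region mean
#'
#' Divides the volume by the mean intensity inside `reference_mask`, so the
#' reference region has mean 1.0 in every normalized volume. Contrast ratios
#' are invariant under this operation; it puts subjects on a common intensity
#' scale before template averaging and voxelwise testing.
#'
#' @param vol an `nm_volume`.
#' @param reference_mask logical array on the same grid.
#' @return normalized `nm_volume`.
#' @export
normalize_intensity <- function(vol, reference_mask) {
  if (!identical(dim(reference_mask), dim(vol)))
    stop("reference mask is not on the volume grid", call. = FALSE)
  if (!any(reference_mask))
    stop("reference mask is empty", call. = FALSE)
  m <- mean(vol$data[reference_mask])
  if (!is.finite(m) || m <= 0)
    stop("reference-region mean must be positive", call. = FALSE)
  nm_volume(vol$data / m, affine = vol$affine)
}

#' Foreground mask by thresholding ("skull-stripping" surrogate)
#'
#' Otsu threshold, largest 26-connected component, then morphological
#' closing. On phantoms the result contains the whole head surrogate,
#' including the SNpc and reference regions.
#'
#' @param vol an `nm_volume`.
#' @return logical 3-D array.
#' @export
strip_background <- function(vol) {
  x <- vol$data
  rng <- range(x)
  if (diff(rng) < 1e-12)
    stop("volume is constant: no separable foreground", call. = FALSE)
  thr <- otsu_threshold(x)
  fg <- x > thr
  if (!any(fg)) stop("empty foreground after thresholding", call. = FALSE)
  fg <- largest_component(fg)
  close_mask(fg)
}

# Separable Gaussian smoothing of a 3-D array (sigma in voxels, kernel
# truncated at 3 sigma, edges replicated).
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    out <- matrix(0, dp[1], ncol(m))
    for (i in seq_along(k)) {
      rows <- pmin(pmax(seq_len(dp[1]) + i - r - 1L, 1L), dp[1])
      out <- out + k[i] * m[rows, , drop = FALSE]
    }
    dim(out) <- dp
    aperm(out, order(perm))
  }
  smooth_axis(smooth_axis(smooth_axis(arr, 1), 2), 3)
}

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(x) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}
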