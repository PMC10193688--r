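#' 3-D image volume
#'
#' Lightweight container for a 3-D scalar image together with its
#' voxel-to-world geometry. World coordinates are RAS+ millimetres; voxel
#' indices are 0-based in all geometric computations (1-based only when
#' subscripting the underlying R array).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to an axis-aligned
#'   grid with the given voxel size, centred on the world origin.
#' @param voxel_size_mm voxel edge length(s) in mm, length 1 or 3; used only
#'   when `affine` is `NULL`.
#' @return An object of class `nm_volume` with fields `data` and `affine`.
#' @export
nm_volume <- function(data, affine = NULL, voxel_size_mm = 0.8) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (is.null(affine)) {
    vs <- rep_len(as.numeric(voxel_size_mm), 3L)
    affine <- centered_affine(dim(data), vs)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, affine = unname(affine)), class = "nm_volume")
}

#' @export
dim.nm_volume <- function(x) dim(x$data)

#' @export
print.nm_volume <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf("<nm_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel size of a volume in mm
#' @param vol an `nm_volume`.
#' @return numeric length-3 vector.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

# Axis-aligned affine with the grid centre at the world origin.
centered_affine <- function(dim, voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -voxel_size * (dim - 1) / 2
  a
}

#' Read / write volumes as NIfTI-1
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an `nm_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # drop NIfTI bookkeeping attributes
  nm_volume(a, affine = aff)
}

#' @rdname read_volume
#' @param vol an `nm_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_size(vol)
  aff <- structure(vol$affine, code = 2L)
  RNifti::`qform<-`(img, aff) -> img
  RNifti::`sform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Map 0-based voxel indices (3 x n matrix) to world mm through an affine.
voxel_to_world <- function(affine, ijk) {
  affine[1:3, 1:3] %*% ijk + affine[1:3, 4]
}

# 3 x n matrix of 0-based voxel indices of every voxel in a grid, in array
# order (first index fastest). Cached by callers that reuse it.
grid_index_matrix <- function(dim) {
  rbind(
    rep_len(seq_len(dim[1]) - 1, prod(dim)),
    rep(rep(seq_len(dim[2]) - 1, each = dim[1]), times = dim[3]),
    rep(seq_len(dim[3]) - 1, each = dim[1] * dim[2])
  )
}

#' Volume of a mask in cubic millimetres
#' @param mask logical 3-D array.
#' @param vol the `nm_volume` the mask lives on (supplies voxel size).
#' @return scalar mm^3.
#' @export
mask_volume_mm3 <- function(mask, vol) {
  sum(mask) * prod(voxel_size(vol))
}

# Mean intensity inside a logical mask; errors on empty masks.
mask_mean <- function(vol, mask, what = "mask") {
  if (!any(mask)) stop(sprintf("%s is empty", what), call. = FALSE)
  mean(vol$data[mask])
}

# Centroid of a mask in world coordinates (mm).
mask_centroid_world <- function(mask, affine) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  ijk <- t(arrayInd(idx, dim(mask))) - 1
  rowMeans(voxel_to_world(affine, ijk))
}
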