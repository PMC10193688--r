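#' Rigid (6 degree-of-freedom) spatial transform
#'
#' Parameterized as three Euler rotation angles in degrees (applied as
#' `Rz %*% Ry %*% Rx`) about a world-space centre, plus a translation in mm.
#' The transform maps a world point `x` to `R (x - c) + c + t`.
#'
#' @param rotation_deg numeric(3), rotations about the x, y, z axes in degrees.
#' @param translation_mm numeric(3), translation in mm.
#' @param center_mm numeric(3), rotation centre in world mm.
#' @return object of class `nm_rigid`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3,
            length(center_mm) == 3)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "nm_rigid")
}

#' @export
print.nm_rigid <- function(x, ...) {
  cat(sprintf("<nm_rigid> rot (deg): %.3f %.3f %.3f | trans (mm): %.3f %.3f %.3f\n",
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cg <- cos(r[3]); sg <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param xform an `nm_rigid`.
#' @return 4x4 matrix mapping world mm to world mm.
#' @export
rigid_matrix <- function(xform) {
  r <- rotation_matrix(xform$rotation_deg)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- xform$center_mm + xform$translation_mm -
    r %*% xform$center_mm
  m
}

# Recover Euler angles (deg, Rz Ry Rx convention) from a rotation matrix.
euler_from_rotation <- function(r) {
  beta <- asin(max(-1, min(1, -r[3, 1])))
  alpha <- atan2(r[3, 2], r[3, 3])
  gamma <- atan2(r[2, 1], r[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Build a rigid transform from a homogeneous matrix
#' @param m 4x4 rigid homogeneous matrix.
#' @param center_mm rotation centre to parameterize around.
#' @return an `nm_rigid`.
#' @export
rigid_from_matrix <- function(m, center_mm = c(0, 0, 0)) {
  r <- m[1:3, 1:3]
  rot <- euler_from_rotation(r)
  trans <- m[1:3, 4] - center_mm + r %*% center_mm
  rigid_transform(rot, as.numeric(trans), center_mm)
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform `x -> a(b(x))`.
#'
#' @param a,b,xform `nm_rigid` objects.
#' @return an `nm_rigid` (parameterized around `a`'s centre).
#' @export
compose_rigid <- function(a, b) {
  rigid_from_matrix(rigid_matrix(a) %*% rigid_matrix(b), a$center_mm)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(xform) {
  rigid_from_matrix(solve(rigid_matrix(xform)), xform$center_mm)
}

#' Serialize rigid transforms as JSON
#'
#' Angles in degrees, translations in mm, explicit rotation centre.
#'
#' @param xform an `nm_rigid` (or, for writing, a named list of them).
#' @param path file path.
#' @export
write_rigid_json <- function(xform, path) {
  to_list <- function(x) list(rotation_deg = x$rotation_deg,
                              translation_mm = x$translation_mm,
                              center_mm = x$center_mm)
  obj <- if (inherits(xform, "nm_rigid")) to_list(xform) else
    lapply(xform, to_list)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid_json
#' @export
read_rigid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_list <- function(o)
    rigid_transform(o$rotation_deg, o$translation_mm, o$center_mm)
  if (!is.null(obj$rotation_deg)) from_list(obj) else lapply(obj, from_list)
}

# Magnitude of a transform relative to identity: max abs rotation (deg) and
# euclidean translation (mm), used in recovery tests and diagnostics.
rigid_magnitude <- function(xform) {
  c(rot_deg = max(abs(xform$rotation_deg)),
    trans_mm = sqrt(sum(xform$translation_mm^2)))
}
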