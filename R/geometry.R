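#' Voxel geometry of an OCT volume
#'
#' Describes the physical sampling of a macular volume scan. The default
#' geometry matches a 6 x 6 mm^2 macular cube acquired as 256 B-scans of
#' 992 (axial) x 512 (lateral) pixels: slice pitch 6000/256 um, lateral
#' pitch 6000/512 um, and an axial pitch of 2.6 um/pixel (so that 448
#' axial pixels span 1164.8 um).
#'
#' @param n_slices,n_axial,n_lateral integer array extents
#'   (slice, axial row, lateral column).
#' @param scan_width lateral/slice field of view in um (square field).
#' @param axial_pitch axial sampling in um per pixel.
#' @return An object of class `voxel_geometry`: a list with the extents and
#'   the three pitches `slice_pitch`, `axial_pitch`, `lateral_pitch` (um).
#' @export
voxel_geometry <- function(n_slices = 256L, n_axial = 992L, n_lateral = 512L,
                           scan_width = 6000, axial_pitch = 2.6) {
  stopifnot(n_slices >= 1, n_axial >= 1, n_lateral >= 1,
            scan_width > 0, axial_pitch > 0)
  structure(list(
    n_slices = as.integer(n_slices),
    n_axial = as.integer(n_axial),
    n_lateral = as.integer(n_lateral),
    scan_width = scan_width,
    slice_pitch = scan_width / n_slices,
    axial_pitch = axial_pitch,
    lateral_pitch = scan_width / n_lateral
  ), class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("OCT voxel geometry: %d x %d x %d (slice x axial x lateral)\n",
              x$n_slices, x$n_axial, x$n_lateral))
  cat(sprintf("  pitches (um): slice %.4f, axial %.4f, lateral %.5f\n",
              x$slice_pitch, x$axial_pitch, x$lateral_pitch))
  invisible(x)
}

# Physical coordinates (um) of voxel centres. Voxel (1,1,1) sits at the
# origin; axis order is (slice, axial, lateral) matching array indexing.
voxel_coords <- function(geometry, slice, axial, lateral) {
  cbind((slice - 1) * geometry$slice_pitch,
        (axial - 1) * geometry$axial_pitch,
        (lateral - 1) * geometry$lateral_pitch)
}

volume_center_um <- function(geometry) {
  c((geometry$n_slices - 1) / 2 * geometry$slice_pitch,
    (geometry$n_axial - 1) / 2 * geometry$axial_pitch,
    (geometry$n_lateral - 1) / 2 * geometry$lateral_pitch)
}

#' Rigid 3-D transform
#'
#' A proper rigid motion `p -> R p + t` acting on physical coordinates in
#' um, axis order (slice, axial, lateral). Used both to misalign phantom
#' volumes and as the output of the RPE-surface least-squares registration.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric, um.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Build a rigid transform from Euler angles about a centre point
#'
#' Angles are in degrees about the slice, axial and lateral axes (applied in
#' that order, extrinsic). The rotation pivots about `center` (um), then
#' `translation` is added, so small-angle misalignments of a volume stay
#' within its field of view.
#'
#' @param angles_deg length-3 rotation angles (deg) about the
#'   (slice, axial, lateral) axes.
#' @param translation length-3 translation, um.
#' @param center pivot point, um.
#' @return A `rigid_transform`.
#' @export
rt_from_angles <- function(angles_deg = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  r1 <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  r2 <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  r3 <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rot <- r3 %*% r2 %*% r1
  tr <- as.numeric(center + translation - rot %*% center)
  rigid_transform(rot, tr)
}

#' Apply, compose and invert rigid transforms
#'
#' `rt_apply` maps an N x 3 matrix of points (um); `rt_compose(a, b)` returns
#' the transform equivalent to applying `b` first, then `a`; `rt_invert`
#' returns the inverse motion.
#'
#' @param transform,a,b `rigid_transform` objects.
#' @param points N x 3 numeric matrix of physical coordinates (um).
#' @return `rt_apply`: transformed N x 3 matrix; the others: a
#'   `rigid_transform`.
#' @export
rt_apply <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @rdname rt_apply
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rt_apply
#' @export
rt_invert <- function(transform) {
  rinv <- t(transform$rotation)
  rigid_transform(rinv, as.numeric(-rinv %*% transform$translation))
}

#' Rotation angle and translation norm of a rigid transform
#'
#' The rotation angle is the angle of the axis-angle decomposition, in
#' degrees; useful for comparing a recovered registration against a known
#' misalignment.
#'
#' @param transform a `rigid_transform`.
#' @return `rt_angle_deg`: rotation magnitude in degrees.
#' @export
rt_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

rt_is_identity <- function(transform, tol = 1e-12) {
  max(abs(transform$rotation - diag(3))) < tol &&
    max(abs(transform$translation)) < tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: rotation %.4f deg, translation (%.2f, %.2f, %.2f) um\n",
              rt_angle_deg(x), x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# Clip while preserving dim attributes (pmin/pmax with a scalar first
# argument drop them).
clip_range <- function(x, lo, hi) {
  d <- dim(x)
  x <- pmin(pmax(x, lo), hi)
  dim(x) <- d
  x
}
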