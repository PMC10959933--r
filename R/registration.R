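# RPE-surface based rigid registration. The retinal pigment epithelium is
# the brightest outer band and is not manipulated during macular hole
# surgery, so the preoperative volume is aligned onto the postoperative RPE
# point cloud by closed-form least squares (orthogonal Procrustes), with
# correspondence taken by (slice, column) grid position.

#' Extract the RPE surface from an OCT volume
#'
#' For every (slice, lateral column) A-scan the axial position of the
#' maximal smoothed-intensity response within the lower retinal search band
#' is located, refined to sub-pixel precision by the intensity centroid of
#' the peak's plateau, median-filtered across the grid, and columns whose
#' deviation from the local median exceeds `mad_k` MADs — or with no signal
#' above `intensity_threshold` — are masked invalid rather than fabricated.
#'
#' @param volume an [oct_volume()].
#' @param smoothing_window axial moving-average window, pixels (odd).
#' @param search_band fraction of the axial extent searched
#'   (default the lower 60% excluding the bottom 10%).
#' @param intensity_threshold minimal peak intensity (8-bit units) for a
#'   column to count as signal.
#' @param mad_k outlier cut in MAD units around the local median surface.
#' @return An object of class `rpe_surface`: `height_px` (slice x lateral
#'   fractional axial pixel rows, 1-based), `valid` (logical mask) and the
#'   volume `geometry`.
#' @export
extract_rpe_surface <- function(volume, smoothing_window = 5,
                                search_band = c(0.4, 0.9),
                                intensity_threshold = 40, mad_k = 5) {
  stopifnot(inherits(volume, "oct_volume"))
  g <- volume$geometry
  a <- g$n_axial
  r0 <- max(1L, floor(search_band[1] * a))
  r1 <- min(a, ceiling(search_band[2] * a))
  rows <- r0:r1
  nb <- length(rows)
  height <- matrix(NA_real_, g$n_slices, g$n_lateral)
  valid <- matrix(FALSE, g$n_slices, g$n_lateral)
  w <- max(1L, as.integer(smoothing_window))
  kern <- rep(1 / w, w)
  for (s in seq_len(g$n_slices)) {
    band <- matrix(as.numeric(volume$data[s, rows, ]), nb, g$n_lateral)
    sm <- if (w > 1) {
      f <- stats::filter(band, kern, sides = 2)
      f[is.na(f)] <- 0
      matrix(f, nb, g$n_lateral)
    } else band
    peak_val <- apply(sm, 2, max)
    peak_row <- max.col(t(sm), ties.method = "first")
    ok <- peak_val >= intensity_threshold
    # 3-point parabolic sub-pixel refinement of the peak (exact for the
    # locally quadratic band profile; boxcar smoothing preserves the vertex)
    cols <- seq_len(g$n_lateral)
    pm1 <- pmax(peak_row - 1, 1)
    pp1 <- pmin(peak_row + 1, nb)
    a <- sm[cbind(pm1, cols)]
    b <- sm[cbind(peak_row, cols)]
    cc <- sm[cbind(pp1, cols)]
    den <- a - 2 * b + cc
    delta <- ifelse(abs(den) > 1e-9, 0.5 * (a - cc) / den, 0)
    delta <- pmin(pmax(delta, -1), 1)
    height[s, ] <- peak_row + delta + r0 - 1
    valid[s, ] <- ok
  }
  height[!valid] <- NA_real_
  # 3x3 grid median filter, then mask outliers against it; border rows and
  # columns keep the raw centroid (a clamped window would bias them on a
  # curved surface)
  med <- grid_median3(height)
  dev <- abs(height - med)
  mad_all <- stats::mad(dev[valid & is.finite(dev)], center = 0, na.rm = TRUE)
  if (is.finite(mad_all) && mad_all > 0)
    valid <- valid & is.finite(dev) & (dev <= mad_k * mad_all)
  interior <- matrix(FALSE, nrow(height), ncol(height))
  if (nrow(height) > 2 && ncol(height) > 2)
    interior[2:(nrow(height) - 1), 2:(ncol(height) - 1)] <- TRUE
  replace <- interior & is.finite(med)
  height[replace] <- med[replace]
  height[!valid] <- NA_real_
  structure(list(height_px = height, valid = valid, geometry = g),
            class = "rpe_surface")
}

# 3x3 neighbourhood median with NA handling (edges use the available part).
grid_median3 <- function(h) {
  nr <- nrow(h); nc <- ncol(h)
  stack <- array(NA_real_, c(nr, nc, 9))
  k <- 0
  for (ds in -1:1) for (dc in -1:1) {
    k <- k + 1
    rs <- pmin(pmax(seq_len(nr) + ds, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    stack[, , k] <- h[rs, cs]
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

# Surface grid points in physical um; rows are (slice, axial, lateral).
surface_points <- function(surface, mask = surface$valid) {
  g <- surface$geometry
  idx <- which(mask & is.finite(surface$height_px), arr.ind = TRUE)
  cbind((idx[, 1] - 1) * g$slice_pitch,
        (surface$height_px[idx] - 1) * g$axial_pitch,
        (idx[, 2] - 1) * g$lateral_pitch)
}

#' Least-squares rigid fit between two RPE surfaces
#'
#' Closed-form orthogonal Procrustes (SVD/Kabsch) on the corresponding 3-D
#' point clouds of the two surfaces in physical um, correspondence by
#' (slice, column) grid position over the jointly valid grid points. The
#' returned transform maps `moving` points onto `fixed` and minimises the
#' sum of squared 3-D distances. Attributes `rms_before`, `rms_after`
#' (full 3-D RMS, um) and `rms_axial_after` (axial-only RMS) record the fit.
#'
#' @param moving,fixed `rpe_surface` objects on the same grid.
#' @return A [rigid_transform()].
#' @export
fit_rigid_transform <- function(moving, fixed) {
  stopifnot(inherits(moving, "rpe_surface"), inherits(fixed, "rpe_surface"),
            all(dim(moving$height_px) == dim(fixed$height_px)))
  joint <- moving$valid & fixed$valid &
    is.finite(moving$height_px) & is.finite(fixed$height_px)
  if (sum(joint) < 3)
    stop("fewer than 3 jointly valid surface points")
  p <- surface_points(moving, joint)
  q <- surface_points(fixed, joint)
  out <- fit_rigid_points(p, q)
  moved <- rt_apply(out, p)
  attr(out, "rms_before") <- sqrt(mean(rowSums((p - q)^2)))
  attr(out, "rms_after") <- sqrt(mean(rowSums((moved - q)^2)))
  attr(out, "rms_axial_after") <- sqrt(mean((moved[, 2] - q[, 2])^2))
  out
}

#' Least-squares rigid fit between corresponding 3-D point clouds
#'
#' Closed-form Kabsch/orthogonal Procrustes solution for the proper rigid
#' motion minimising `sum || R p_i + t - q_i ||^2` over point pairs in um.
#' With exact correspondences (e.g. a known transform applied to a surface
#' point cloud) the generating transform is recovered to machine precision.
#'
#' @param p,q N x 3 matrices of corresponding points (moving, fixed).
#' @return A [rigid_transform()] mapping `p` onto `q`.
#' @export
fit_rigid_points <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 3)
  q <- matrix(as.numeric(q), ncol = 3)
  stopifnot(nrow(p) == nrow(q), nrow(p) >= 3)
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2, pc); q0 <- sweep(q, 2, qc)
  sv <- svd(crossprod(p0, q0))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) surface point set")
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  rot <- sv$v %*% s %*% t(sv$u)
  rigid_transform(rot, as.numeric(qc - rot %*% pc))
}

#' Resample a volume through a rigid transform
#'
#' Returns the volume moved by `transform`: each output voxel takes the
#' trilinearly interpolated intensity of the input volume at the inverse-
#' mapped physical position. Voxels mapping outside the field are
#' zero-filled. The identity transform returns the input bit-exactly.
#'
#' @param volume an [oct_volume()].
#' @param transform a [rigid_transform()] (um, volume coordinate frame with
#'   voxel (1,1,1) at the origin).
#' @return An [oct_volume()] on the same grid.
#' @export
apply_transform <- function(volume, transform) {
  stopifnot(inherits(volume, "oct_volume"),
            inherits(transform, "rigid_transform"))
  if (rt_is_identity(transform)) return(volume)
  g <- volume$geometry
  inv <- rt_invert(transform)
  ns <- g$n_slices; na_ <- g$n_axial; nl <- g$n_lateral
  out <- array(0L, c(ns, na_, nl))
  ax <- (seq_len(na_) - 1) * g$axial_pitch
  lat <- (seq_len(nl) - 1) * g$lateral_pitch
  grid_a <- matrix(ax, na_, nl)
  grid_l <- matrix(lat, na_, nl, byrow = TRUE)
  vol <- volume$data
  for (s in seq_len(ns)) {
    pts <- cbind((s - 1) * g$slice_pitch, as.vector(grid_a), as.vector(grid_l))
    src <- rt_apply(inv, pts)
    fs <- src[, 1] / g$slice_pitch + 1
    fa <- src[, 2] / g$axial_pitch + 1
    fl <- src[, 3] / g$lateral_pitch + 1
    out[s, , ] <- trilinear_gather(vol, fs, fa, fl, ns, na_, nl)
  }
  oct_volume(out, g)
}

trilinear_gather <- function(vol, fs, fa, fl, ns, na_, nl) {
  s0 <- floor(fs); a0 <- floor(fa); l0 <- floor(fl)
  ws <- fs - s0; wa <- fa - a0; wl <- fl - l0
  acc <- numeric(length(fs))
  inside <- rep(TRUE, length(fs))
  for (ds in 0:1) for (da in 0:1) for (dl in 0:1) {
    si <- s0 + ds; ai <- a0 + da; li <- l0 + dl
    w <- (if (ds) ws else 1 - ws) * (if (da) wa else 1 - wa) *
      (if (dl) wl else 1 - wl)
    ok <- si >= 1 & si <= ns & ai >= 1 & ai <= na_ & li >= 1 & li <= nl
    idx <- si[ok] + ns * ((ai[ok] - 1) + na_ * (li[ok] - 1))
    v <- numeric(length(fs))
    v[ok] <- vol[idx]
    acc <- acc + w * v
  }
  as.integer(round(pmin(255, pmax(0, acc))))
}

#' RMS distance between two RPE surfaces
#'
#' Axial height difference over jointly valid grid points, reported as an
#' RMS in um together with the per-point difference map.
#'
#' @param a,b `rpe_surface` objects on the same grid.
#' @return List with `rms_um`, `rms_px` (axial pixels) and `difference_um`
#'   (slice x lateral map, NA where not jointly valid).
#' @export
surface_residual <- function(a, b) {
  stopifnot(inherits(a, "rpe_surface"), inherits(b, "rpe_surface"),
            all(dim(a$height_px) == dim(b$height_px)))
  joint <- a$valid & b$valid & is.finite(a$height_px) & is.finite(b$height_px)
  if (!any(joint)) stop("surfaces have no jointly valid overlap")
  d <- (a$height_px - b$height_px) * a$geometry$axial_pitch
  d[!joint] <- NA_real_
  rms <- sqrt(mean(d[joint]^2))
  list(rms_um = rms, rms_px = rms / a$geometry$axial_pitch,
       difference_um = d)
}

#' Register a preoperative volume onto a postoperative RPE surface
#'
#' Convenience wrapper running the full registration protocol: extract both
#' RPE surfaces, fit the rigid transform by least squares, resample the
#' preoperative volume, and report residuals before and after.
#'
#' @param pre,post [oct_volume()] objects on the same grid.
#' @param ... passed to [extract_rpe_surface()].
#' @return List with `registered` (the resampled preoperative volume),
#'   `transform`, `rms_before_um`, `rms_after_um`, `rms_after_px`.
#' @export
register_volumes <- function(pre, post, ...) {
  rpe_pre <- extract_rpe_surface(pre, ...)
  rpe_post <- extract_rpe_surface(post, ...)
  tf <- fit_rigid_transform(rpe_pre, rpe_post)
  before <- surface_residual(rpe_pre, rpe_post)
  registered <- apply_transform(pre, tf)
  rpe_reg <- extract_rpe_surface(registered, ...)
  after <- surface_residual(rpe_reg, rpe_post)
  list(registered = registered, transform = tf,
       rms_before_um = before$rms_um,
       rms_after_um = after$rms_um,
       rms_after_px = after$rms_px)
}
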