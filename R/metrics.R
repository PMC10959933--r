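# Quantitative agreement between predicted (AI-OCT) and ground-truth
# (GT-OCT) slices: neurosensory-area concordance, retinal thickness
# profiles, percentage Bland-Altman limits of agreement, ELM/EZ band
# continuity, and a phantom-only layer-visibility proxy of the 10-point
# image-quality score.

#' Segment the neurosensory retina in a slice image
#'
#' Per column the internal limiting membrane is the first sustained
#' above-threshold crossing from the top, and the RPE the brightest
#' smoothed band below it; both curves are median-smoothed and the mask is
#' filled between them. Supplying `ilm` / `rpe` curves bypasses detection
#' (the hook for external boundary corrections).
#'
#' @param image matrix in [0, 1].
#' @param threshold ILM detection threshold (intensity in [0, 1]).
#' @param sustain number of consecutive above-threshold rows required.
#' @param smooth_window axial smoothing window (pixels) for RPE detection.
#' @param ilm,rpe optional externally supplied per-column curves
#'   (fractional rows); used verbatim when given.
#' @return An object of class `retina_mask`: logical `mask`, `ilm_curve`,
#'   `rpe_curve` (per-column fractional rows, NA where invalid), and
#'   `valid` per column.
#' @export
segment_neurosensory <- function(image, threshold = 0.15, sustain = 3L,
                                 smooth_window = 5L, ilm = NULL, rpe = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  supplied <- !is.null(ilm) && !is.null(rpe)
  if (!supplied) {
    kern <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(image, kern, sides = 2)
    sm[is.na(sm)] <- 0
    sm <- matrix(sm, nr, nc)
    ilm <- rep(NA_real_, nc)
    rpe <- rep(NA_real_, nc)
    above <- image >= threshold
    run <- matrix(0L, nr, nc)
    run[1, ] <- above[1, ]
    for (r in 2:nr) run[r, ] <- ifelse(above[r, ], run[r - 1, ] + 1L, 0L)
    for (cx in seq_len(nc)) {
      hit <- which(run[, cx] >= sustain)
      if (!length(hit)) next
      ilm[cx] <- hit[1] - sustain + 1
      below <- seq.int(min(nr, floor(ilm[cx]) + 5), nr)
      if (length(below) < 3) next
      prof <- sm[below, cx]
      pk <- which.max(prof)
      if (prof[pk] < threshold) next
      w <- pmax(prof - 0.8 * prof[pk], 0)
      w[abs(seq_along(prof) - pk) > 10] <- 0
      rpe[cx] <- sum(seq_along(prof) * w) / sum(w) + below[1] - 1
    }
    ok <- is.finite(ilm) & is.finite(rpe) & rpe > ilm
    if (sum(ok) >= 3) {
      k <- min(5, 2 * (sum(ok) %/% 2) - 1)
      ilm[ok] <- stats::runmed(ilm[ok], k)
      rpe[ok] <- stats::runmed(rpe[ok], k)
    }
  }
  valid <- is.finite(ilm) & is.finite(rpe) & rpe > ilm
  rows <- matrix(seq_len(nr), nr, nc)
  im <- matrix(ilm, nr, nc, byrow = TRUE)
  rm_ <- matrix(rpe, nr, nc, byrow = TRUE)
  mask <- !is.na(im) & !is.na(rm_) & rows >= im & rows <= rm_
  mask[, !valid] <- FALSE
  structure(list(mask = mask, ilm_curve = ilm, rpe_curve = rpe,
                 valid = valid),
            class = "retina_mask")
}

#' Pixel-wise concordance between AI and GT masks
#'
#' Confusion counts take the GT mask as the reference (TP = TRUE in both).
#' F1 is the harmonic mean of precision and recall, reported as 0 (with
#' `f1_defined = FALSE`) when precision + recall is 0.
#'
#' @param mask_ai,mask_gt logical matrices of identical shape (or
#'   `retina_mask` objects).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, the four
#'   confusion counts and `f1_defined`.
#' @export
concordance <- function(mask_ai, mask_gt) {
  if (inherits(mask_ai, "retina_mask")) mask_ai <- mask_ai$mask
  if (inherits(mask_gt, "retina_mask")) mask_gt <- mask_gt$mask
  if (!all(dim(mask_ai) == dim(mask_gt)))
    stop("mask shapes differ")
  tp <- sum(mask_ai & mask_gt)
  fp <- sum(mask_ai & !mask_gt)
  fn <- sum(!mask_ai & mask_gt)
  tn <- sum(!mask_ai & !mask_gt)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  defined <- (precision + recall) > 0
  list(accuracy = (tp + tn) / (tp + fp + fn + tn),
       precision = precision, recall = recall,
       f1 = if (defined) 2 * precision * recall / (precision + recall) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn, f1_defined = defined)
}

#' Retinal thickness profile of a segmented slice
#'
#' Thickness per column is `(rpe - ilm) * axial_pitch`. Foveolar height
#' (FH) is the thickness at the foveolar column; mean foveal thickness
#' (MFT) averages columns within 500 um of the foveola; mean nasal and
#' temporal parafoveal thickness (MNPT / MTPT) average the (500, 1500] um
#' annuli (nasal = increasing column index). um-to-column windows round
#' half-up with inclusive bounds.
#'
#' @param mask a `retina_mask`.
#' @param fovea_col foveolar column (1-based).
#' @param axial_pitch,lateral_pitch image pixel pitches, um (use
#'   [slice_image_geometry()] values for cropped/resized slices).
#' @return List with `fh`, `mft`, `mnpt`, `mtpt` (um) and the per-column
#'   `thickness_um`.
#' @export
thickness_profile <- function(mask, fovea_col, axial_pitch, lateral_pitch) {
  stopifnot(inherits(mask, "retina_mask"))
  nc <- length(mask$ilm_curve)
  if (fovea_col < 1 || fovea_col > nc || !mask$valid[fovea_col])
    stop("invalid foveolar column")
  th <- (mask$rpe_curve - mask$ilm_curve) * axial_pitch
  th[!mask$valid] <- NA_real_
  w_f <- round_half_up(500 / lateral_pitch)
  w_p <- round_half_up(1500 / lateral_pitch)
  cols_mft <- max(1, fovea_col - w_f):min(nc, fovea_col + w_f)
  cols_n <- (fovea_col + w_f + 1):min(nc, fovea_col + w_p)
  cols_t <- max(1, fovea_col - w_p):(fovea_col - w_f - 1)
  list(fh = th[fovea_col],
       mft = mean(th[cols_mft], na.rm = TRUE),
       mnpt = mean(th[cols_n[cols_n <= nc]], na.rm = TRUE),
       mtpt = mean(th[cols_t[cols_t >= 1]], na.rm = TRUE),
       thickness_um = th)
}

#' Bland-Altman agreement on percentage differences
#'
#' For pairs (a_i, g_i) the percentage difference is
#' `d_i = 100 (a_i - g_i) / ((a_i + g_i) / 2)`; the bias is `mean(d)` and
#' the 95% limits of agreement are `bias +- 1.96 sd(d)` (sample SD). The
#' pair set passes when both limits lie within +-30%.
#'
#' @param ai,gt numeric vectors of paired measurements (>= 2 pairs, no pair
#'   with mean zero).
#' @param limit acceptability bound on the limits of agreement, percent.
#' @return List with `bias`, `loa_low`, `loa_high` (percent), `pass_30`,
#'   and the per-pair `differences_pct`.
#' @export
bland_altman <- function(ai, gt, limit = 30) {
  stopifnot(length(ai) == length(gt))
  if (length(ai) < 2) stop("need at least 2 pairs")
  m <- (ai + gt) / 2
  if (any(m == 0)) stop("pair with mean zero")
  d <- 100 * (ai - gt) / m
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  list(bias = bias, loa_low = loa[1], loa_high = loa[2],
       pass_30 = loa[1] >= -limit && loa[2] <= limit,
       differences_pct = d)
}

#' ELM / EZ band continuity status
#'
#' Within a +-1000 um foveal window, each column is tested for a local
#' intensity maximum above `detect_threshold` inside the band's expected
#' depth stratum relative to the RPE curve (between the outer nuclear
#' region and the RPE for the ELM; between the ELM locus and the RPE for
#' the EZ). The largest run of consecutive detection failures, in um, is
#' the band gap; the band is `restored` iff the gap is at most
#' `gap_tolerance`.
#'
#' @param image slice matrix in [0, 1].
#' @param mask a `retina_mask` for the slice.
#' @param fovea_col foveolar column.
#' @param axial_pitch,lateral_pitch pixel pitches, um.
#' @param band `"elm"` or `"ez"`.
#' @param gap_tolerance largest gap still called restored, um.
#' @param detect_threshold minimal band peak intensity.
#' @param band_thicknesses ELM / EZ / RPE band thicknesses in um used to
#'   place the search strata relative to the RPE curve (defaults to the
#'   native phantom anatomy; pass the generating spec's values for scaled
#'   phantoms).
#' @return List with `band`, `status` (`"restored"`/`"disrupted"`),
#'   `largest_gap_um` and the per-column detection vector.
#' @export
band_status <- function(image, mask, fovea_col, axial_pitch, lateral_pitch,
                        band = c("elm", "ez"), gap_tolerance = 50,
                        detect_threshold = 0.35,
                        band_thicknesses = c(elm = 10, ez = 20, rpe = 25)) {
  band <- match.arg(band)
  nc <- ncol(image); nr <- nrow(image)
  w <- round_half_up(1000 / lateral_pitch)
  cols <- max(1, fovea_col - w):min(nc, fovea_col + w)
  # stratum centred on the band's expected depth (RPE curve marks the RPE
  # band centre), shrunk to its interior so curve quantisation cannot leak
  # into the neighbouring bright band
  bt <- band_thicknesses
  center <- if (band == "ez") -(bt[["rpe"]] / 2 + bt[["ez"]] / 2)
            else -(bt[["rpe"]] / 2 + bt[["ez"]] + bt[["elm"]] / 2)
  half <- max(axial_pitch, 0.3 * bt[[band]])
  stratum <- c(center - half, center + half) / axial_pitch
  detected <- logical(length(cols))
  for (k in seq_along(cols)) {
    cx <- cols[k]
    if (!mask$valid[cx]) next
    r0 <- ceiling(mask$rpe_curve[cx] + stratum[1])
    r1 <- floor(mask$rpe_curve[cx] + stratum[2])
    if (r1 < r0) r1 <- r0
    rr <- max(1, r0):min(nr, r1)
    if (length(rr) < 1) next
    detected[k] <- max(image[rr, cx]) >= detect_threshold
  }
  gaps <- rle(!detected)
  largest <- if (any(gaps$values)) max(gaps$lengths[gaps$values]) else 0
  gap_um <- largest * lateral_pitch
  list(band = band,
       status = if (gap_um <= gap_tolerance) "restored" else "disrupted",
       largest_gap_um = gap_um, detected = detected, columns = cols)
}

#' Layer-visibility score of a phantom slice (0-10)
#'
#' Machine proxy for the human 10-point image-quality reading, defined only
#' for phantoms: one point per retinal band whose mean intensity at its
#' ground-truth location contrasts against its neighbours in the expected
#' direction with at least `contrast_fraction` of the contrast the palette
#' renders (a relative rule, since the EZ band's nominal contrast against
#' its bright neighbours is small).
#'
#' @param image native-geometry slice matrix (0..255 scale or [0, 1]).
#' @param truth phantom truth (from [make_phantom_case()]); supplies band
#'   locations and the rendered palette.
#' @param spec the generating [phantom_spec()].
#' @param slice slice index the image was taken from.
#' @param contrast_fraction minimal fraction of the palette's nominal
#'   neighbour contrast that must be realised.
#' @return Integer score 0-10.
#' @export
layer_visibility_score <- function(image, truth, spec, slice,
                                   contrast_fraction = 0.5) {
  if (is.null(truth)) stop("phantom truth required for the visibility proxy")
  if (max(image) <= 1) image <- image * 255
  geom <- phantom_geometry(spec)
  b <- phantom_boundaries_slice(spec, geom, slice)
  pal <- truth$palette
  # sample columns away from the fovea (hole / gap region)
  guard <- ceiling((max(spec$hole_diameter, spec$elm_gap, spec$ez_gap) / 2 +
                      200) / geom$lateral_pitch)
  cols <- setdiff(seq(5, spec$n_lateral - 4, by = 4),
                  (spec$fovea_col - guard):(spec$fovea_col + guard))
  if (!length(cols)) stop("no columns outside the foveal guard zone")
  bext <- rbind(0, b, (spec$n_axial - 1) * spec$axial_pitch)
  band_mean <- function(k) {  # region k in 1..12
    tops <- bext[k, cols]; bots <- bext[k + 1, cols]
    mid <- (tops + bots) / 2
    rows <- pmin(spec$n_axial, pmax(1, round(mid / spec$axial_pitch) + 1))
    mean(image[cbind(rows, cols)])
  }
  means <- vapply(1:12, band_mean, numeric(1))
  score <- 0L
  for (k in 2:11) {   # the ten retinal bands
    expected <- pal[k] - (pal[k - 1] + pal[k + 1]) / 2
    actual <- means[k] - (means[k - 1] + means[k + 1]) / 2
    if (sign(actual) == sign(expected) &&
        abs(actual) >= contrast_fraction * abs(expected)) score <- score + 1L
  }
  score
}

#' Evaluate one test case end to end
#'
#' Runs the representative-slice protocol: (1) extract both RPE surfaces,
#' (2) register the preoperative volume onto the postoperative RPE
#' surface, (3) feed the central registered preoperative slice (index
#' `n_slices / 2`; the 128th of 256 at native geometry) to the predictor, (4) take the
#' same postoperative slice as GT, (5) compute concordance, thickness
#' profiles, and ELM/EZ status for both.
#'
#' @param pre_vol,post_vol [oct_volume()] objects.
#' @param predictor a trained [octvae] model, a function
#'   `function(image, condition)` returning the predicted slice, or
#'   `"oracle"` (returns the GT slice; used to validate the protocol).
#' @param fovea_col foveolar column in the native slice (defaults to the
#'   volume centre).
#' @param crop_size,out_size preprocessing geometry.
#' @param gap_tolerance ELM/EZ gap tolerance, um.
#' @param band_thicknesses passed to [band_status()].
#' @return An agreement report: list with `concordance`, `thickness_ai`,
#'   `thickness_gt`, `elm_ai`, `ez_ai`, `elm_gt`, `ez_gt`,
#'   `registration` (residuals), and the slice index used.
#' @export
evaluate_case <- function(pre_vol, post_vol, predictor, fovea_col = NULL,
                          crop_size = 448L, out_size = 224L,
                          gap_tolerance = 50,
                          band_thicknesses = c(elm = 10, ez = 20, rpe = 25)) {
  g <- pre_vol$geometry
  reg <- register_volumes(pre_vol, post_vol)
  s <- max(1L, g$n_slices %/% 2L)
  pre_slice <- matrix(as.numeric(reg$registered$data[s, , ]),
                      g$n_axial, g$n_lateral)
  post_slice <- matrix(as.numeric(post_vol$data[s, , ]),
                       g$n_axial, g$n_lateral)
  com <- center_of_mass(pre_slice)
  pre_img <- crop_resize(pre_slice, com, crop_size, out_size)
  gt_img <- crop_resize(post_slice, com, crop_size, out_size)
  ai_img <- if (identical(predictor, "oracle")) gt_img
  else if (inherits(predictor, "octvae")) predict(predictor, pre_img, 0L)
  else predictor(pre_img, 0L)

  sg <- slice_image_geometry(g, crop_size, out_size)
  mask_ai <- segment_neurosensory(ai_img)
  mask_gt <- segment_neurosensory(gt_img)
  if (is.null(fovea_col)) fovea_col <- round_half_up(g$n_lateral / 2)
  # fovea column in the cropped/resized frame
  fc <- round_half_up((fovea_col - (round_half_up(com[2]) - crop_size / 2)) /
                        (crop_size / out_size))
  fc <- min(max(fc, 1L), out_size)
  conc <- concordance(mask_ai, mask_gt)
  th_ai <- thickness_profile(mask_ai, fc, sg$axial_pitch, sg$lateral_pitch)
  th_gt <- thickness_profile(mask_gt, fc, sg$axial_pitch, sg$lateral_pitch)
  bands <- list()
  for (img_tag in c("ai", "gt")) {
    img <- if (img_tag == "ai") ai_img else gt_img
    msk <- if (img_tag == "ai") mask_ai else mask_gt
    for (bd in c("elm", "ez"))
      bands[[paste0(bd, "_", img_tag)]] <-
        band_status(img, msk, fc, sg$axial_pitch, sg$lateral_pitch, bd,
                    gap_tolerance, band_thicknesses = band_thicknesses)
  }
  c(list(slice_index = s, fovea_col_image = fc, concordance = conc,
         thickness_ai = th_ai, thickness_gt = th_gt,
         registration = reg[c("rms_before_um", "rms_after_um",
                              "rms_after_px")],
         ai_image = ai_img, gt_image = gt_img),
    bands)
}
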