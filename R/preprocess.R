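# Conditioned preprocessing of registered volume pairs into 224 x 224 slice
# pairs: centre-of-mass crop, Lanczos downscale, six-fold geometric
# augmentation of the training split, fovea-distance condition labels, and
# inverse-frequency sampling weights.

#' Intensity centre of mass of an image
#'
#' @param image numeric matrix (any non-negative intensity scale).
#' @return `c(row, col)` fractional 1-based pixel coordinates.
#' @export
center_of_mass <- function(image) {
  tot <- sum(image)
  if (!is.finite(tot) || tot <= 0) stop("center of mass of an all-zero image")
  rows <- rowSums(image)
  cols <- colSums(image)
  c(sum(rows * seq_len(nrow(image))) / tot,
    sum(cols * seq_len(ncol(image))) / tot)
}

# Lanczos kernel, a = 4 lobes.
lanczos4 <- function(x, a = 4) {
  y <- numeric(length(x))
  inside <- abs(x) < a
  xi <- x[inside]
  y[inside] <- ifelse(xi == 0, 1,
                      a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2))
  y
}

# Row-resampling matrix (n_out x n_in) for Lanczos interpolation with
# pixel-centre alignment. For downscaling the kernel support is widened by
# the inverse scale (antialiased windowed sinc); taps are clamped to the
# edge and each row is normalised to unit sum.
lanczos_matrix <- function(n_in, n_out, a = 4) {
  scale <- n_out / n_in
  support <- if (scale < 1) a / scale else a
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / scale + 0.5           # centre in input coords (1-based)
    j0 <- floor(src - support) ; j1 <- ceiling(src + support)
    taps <- j0:j1
    w <- lanczos4((src - taps) * min(1, scale), a)
    taps <- pmin(pmax(taps, 1), n_in)
    for (k in seq_along(taps)) m[i, taps[k]] <- m[i, taps[k]] + w[k]
  }
  m / rowSums(m)
}

#' Resize an image with 4-lobed windowed-sinc (Lanczos) interpolation
#'
#' Separable Lanczos-4 resampling with edge clamping and antialiasing when
#' downscaling — the interpolation used for the 448 to 224 pixel reduction.
#'
#' @param image numeric matrix.
#' @param out_rows,out_cols output size.
#' @return Resized matrix.
#' @export
lanczos_resize <- function(image, out_rows, out_cols) {
  wr <- lanczos_matrix(nrow(image), out_rows)
  wc <- lanczos_matrix(ncol(image), out_cols)
  wr %*% image %*% t(wc)
}

#' Crop a square window about the centre of mass and downscale
#'
#' Crops a `crop_size` square centred on the (half-up rounded) centre of
#' mass, zero-padding where the window exceeds the native slice, downscales
#' by 1/2 with Lanczos-4 interpolation, and rescales intensities to [0, 1].
#' At the native 6 x 6 mm^2 / 512-column sampling the 448-column window
#' spans exactly 5250.0 um (and 448 axial pixels at 2.6 um span 1164.8 um).
#'
#' @param slice_2d native axial x lateral matrix (0..255).
#' @param com `c(row, col)` centre of mass (from the preoperative member).
#' @param crop_size square crop, native pixels.
#' @param out_size output size, pixels.
#' @return `out_size` square matrix in [0, 1] (a slice image).
#' @export
crop_resize <- function(slice_2d, com, crop_size = 448L, out_size = 224L) {
  rc <- round_half_up(com[1]); cc <- round_half_up(com[2])
  half <- crop_size %/% 2
  r0 <- rc - half + 1; c0 <- cc - half + 1
  win <- matrix(0, crop_size, crop_size)
  rr <- r0:(r0 + crop_size - 1); csq <- c0:(c0 + crop_size - 1)
  rok <- which(rr >= 1 & rr <= nrow(slice_2d))
  cok <- which(csq >= 1 & csq <= ncol(slice_2d))
  win[rok, cok] <- slice_2d[rr[rok], csq[cok]]
  out <- lanczos_resize(win, out_size, out_size) / 255
  clip_range(out, 0, 1)
}

# Inverse-mapped affine resampling with bilinear interpolation, zero fill.
# map: output (r, c) -> input coords; used by rotation and shift.
affine_sample <- function(image, rot_deg = 0, center = NULL, shift_cols = 0) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- rot_deg * pi / 180
  # positive angle = counterclockwise in the displayed image (x right =
  # columns, y up = decreasing rows); inverse map rotates by -th.
  co <- cos(th); si <- sin(th)
  rg <- matrix(seq_len(nr), nr, nc) - center[1]
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2] - shift_cols
  src_r <- co * rg + si * cg + center[1]
  src_c <- -si * rg + co * cg + center[2]
  bilinear_gather(image, src_r, src_c)
}

bilinear_gather <- function(image, src_r, src_c) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- floor(src_r); c0 <- floor(src_c)
  wr <- src_r - r0; wc <- src_c - c0
  acc <- matrix(0, nrow(src_r), ncol(src_r))
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (if (dr) wr else 1 - wr) * (if (dc) wc else 1 - wc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(0, nrow(src_r), ncol(src_r))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    acc <- acc + w * v
  }
  acc
}

#' Six-fold geometric augmentation of a slice pair
#'
#' Produces the training-set variants of one preprocessed pair: the
#' original, a horizontal flip, counterclockwise rotations by 4 and 8
#' degrees about the centre of mass, and lateral shifts of 15 pixels to the
#' temporal and nasal sides. The identical geometric operation is applied to
#' both members; the centre of mass is the preoperative one for both.
#'
#' @param pre,post slice-image matrices in [0, 1] (same size).
#' @param com centre of mass `c(row, col)` in the image's own pixel grid.
#' @param angles_deg rotation angles (counterclockwise).
#' @param shift_px lateral shift magnitude, pixels.
#' @return Named list of 6 pairs (`orig`, `flip`, `rot4`, `rot8`,
#'   `shift_t`, `shift_n`), each `list(pre=, post=, tag=)`.
#' @export
augment_pair <- function(pre, post, com = NULL, angles_deg = c(4, 8),
                         shift_px = 15) {
  stopifnot(all(dim(pre) == dim(post)))
  ops <- list(
    orig = function(x) x,
    flip = function(x) x[, rev(seq_len(ncol(x)))],
    rot4 = function(x) affine_sample(x, rot_deg = angles_deg[1], center = com),
    rot8 = function(x) affine_sample(x, rot_deg = angles_deg[2], center = com),
    shift_t = function(x) affine_sample(x, shift_cols = -shift_px),
    shift_n = function(x) affine_sample(x, shift_cols = shift_px)
  )
  out <- lapply(names(ops), function(tag)
    list(pre = clip_range(ops[[tag]](pre), 0, 1),
         post = clip_range(ops[[tag]](post), 0, 1), tag = tag))
  names(out) <- names(ops)
  out
}

#' Select the fovea-centred window of slices
#'
#' Returns `window` contiguous slice indices centred on the fovea, shifted
#' (clamped) to stay inside the volume when the fovea sits near an edge.
#'
#' @param n_slices total number of slices in the volume.
#' @param fovea_slice fovea slice index (1-based).
#' @param window window length (200 at native geometry).
#' @return Integer vector of `window` slice indices.
#' @export
select_slices <- function(n_slices, fovea_slice, window = 200L) {
  window <- as.integer(window)
  if (n_slices < window)
    stop("volume has fewer slices than the selection window")
  start <- fovea_slice - window %/% 2
  start <- min(max(start, 1L), n_slices - window + 1L)
  seq.int(start, length.out = window)
}

# Band sizes per condition for a window length, scaled from the native
# 43/42/43/72 split of the 200-slice window by largest remainder.
condition_band_sizes <- function(window = 200L) {
  base <- c(43, 42, 43, 72)
  if (window == 200L) return(base)
  raw <- base / 200 * window
  fl <- floor(raw)
  rem <- window - sum(fl)
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Condition label of each slice in the fovea-centred window
#'
#' Slices are banded by distance from the window centre: the most central
#' 43 slices are condition 0, the next 42 condition 1, the next 43
#' condition 2 and the outermost 72 condition 3 (sizes scaled for other
#' window lengths). Ties at band edges are broken toward the lower slice
#' index, which fixes the one-slice asymmetries forced by the odd band
#' sizes. Over 100 training cases with six-fold augmentation this yields
#' the 25,800 / 25,200 / 25,800 / 43,200 pairs per condition.
#'
#' @param window window length.
#' @return `condition_bands`: integer vector of length `window` with values
#'   0-3, position i giving the condition of the i-th slice in the window.
#' @export
condition_bands <- function(window = 200L) {
  sizes <- condition_band_sizes(window)
  center <- (window + 1) / 2
  d <- abs(seq_len(window) - center)
  ord <- order(d, seq_len(window))
  cond <- integer(window)
  cond[ord] <- rep.int(0:3, sizes)
  cond
}

#' @rdname condition_bands
#' @param offset signed slice offset from the window centre (0 for the
#'   foveal slice); accepts a vector.
#' @return `assign_condition`: integer condition(s) 0-3.
#' @export
assign_condition <- function(offset, window = 200L) {
  center <- (window + 1) / 2
  pos <- round(offset + center)
  if (any(pos < 1 | pos > window))
    stop("slice offset outside the selection window")
  condition_bands(window)[pos]
}

#' Inverse-frequency sampling weights for condition balance
#'
#' Weight proportional to 1 / count(condition of the row), so the expected
#' condition distribution of a weighted draw is uniform — the weighted
#' random sampling used to counter the condition imbalance.
#'
#' @param manifest data.frame with a `condition` column.
#' @return Numeric vector of strictly positive weights, one per row.
#' @export
sampling_weights <- function(manifest) {
  if (nrow(manifest) == 0) stop("empty manifest")
  counts <- table(manifest$condition)
  as.numeric(1 / counts[as.character(manifest$condition)])
}

#' One-hot encoding of a condition label
#'
#' @param condition integer 0-3 (vectorised).
#' @return length-4 vector (or 4-column matrix) summing to 1 per label.
#' @export
condition_one_hot <- function(condition) {
  stopifnot(all(condition %in% 0:3))
  m <- diag(4)[condition + 1, , drop = FALSE]
  if (length(condition) == 1) as.numeric(m) else m
}

#' Build the conditioned, augmented slice-pair dataset
#'
#' Converts a phantom cohort (registered pre + post volumes, or specs only)
#' plus a split assignment into a training manifest, optionally rendering
#' and writing the slice-pair images. The training split is augmented
#' six-fold; validation and test splits keep the originals only. With
#' `write_images = FALSE` the manifest is produced without touching any
#' voxel data, so pair and condition counts can be audited cheaply.
#'
#' @param cohort a `phantom_cohort` (rendered cases required when images are
#'   written). Cases whose spec carries a non-identity misalignment are
#'   expected to have been registered first (see [register_volumes()]);
#'   `registered` can supply the registered preoperative volumes.
#' @param split data.frame from [split_cases()] with one row per case.
#' @param out_dir directory for PNG images (created when writing).
#' @param window fovea-centred slice window per case.
#' @param crop_size,out_size crop/resize geometry (448 -> 224 native).
#' @param write_images render and write PNG pairs.
#' @param registered optional list of registered preoperative
#'   [oct_volume()]s, parallel to `cohort$specs`.
#' @return Training manifest data.frame (see [write_manifest()]), with
#'   sampling weights filled on the training split.
#' @export
build_dataset <- function(cohort, split, out_dir = NULL, window = 200L,
                          crop_size = 448L, out_size = 224L,
                          write_images = TRUE, registered = NULL) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  specs <- cohort$specs
  n_cases <- length(specs)
  stopifnot(nrow(split) == n_cases)
  if (write_images && is.null(cohort$cases) && is.null(registered))
    stop("write_images = TRUE requires rendered cases")
  if (write_images && !is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aug_tags <- c("orig", "flip", "rot4", "rot8", "shift_t", "shift_n")
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec <- specs[[i]]
    sl <- select_slices(spec$n_slices, spec$fovea_slice, window)
    cond <- condition_bands(window)
    is_train <- split$split[i] == "train"
    tags <- if (is_train) aug_tags else "orig"
    df <- expand.grid(slice_index = sl, augmentation_tag = tags,
                      stringsAsFactors = FALSE)
    df$condition <- rep(cond, times = length(tags))
    df$case_id <- split$case_id[i]
    df$split <- as.character(split$split[i])
    dirp <- if (is.null(out_dir)) "." else out_dir
    df$pre_path <- file.path(dirp,
                             sprintf("%s_s%03d_%s_pre.png", split$case_id[i],
                                     df$slice_index, df$augmentation_tag))
    df$post_path <- sub("_pre\\.png$", "_post.png", df$pre_path)
    rows[[i]] <- df
    if (write_images) {
      pre_vol <- if (!is.null(registered)) registered[[i]]
                 else cohort$cases[[i]]$pre
      post_vol <- cohort$cases[[i]]$post
      for (s in sl) {
        pre_slice <- matrix(as.numeric(pre_vol$data[s, , ]),
                            spec$n_axial, spec$n_lateral)
        post_slice <- matrix(as.numeric(post_vol$data[s, , ]),
                             spec$n_axial, spec$n_lateral)
        com <- center_of_mass(pre_slice)
        pre_img <- crop_resize(pre_slice, com, crop_size, out_size)
        post_img <- crop_resize(post_slice, com, crop_size, out_size)
        if (is_train) {
          pairs <- augment_pair(pre_img, post_img)
        } else {
          pairs <- list(orig = list(pre = pre_img, post = post_img,
                                    tag = "orig"))
        }
        for (p in pairs) {
          png::writePNG(p$pre,
                        file.path(out_dir, sprintf("%s_s%03d_%s_pre.png",
                                                   split$case_id[i], s, p$tag)))
          png::writePNG(p$post,
                        file.path(out_dir, sprintf("%s_s%03d_%s_post.png",
                                                   split$case_id[i], s, p$tag)))
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$sampling_weight <- NA_real_
  tr <- manifest$split == "train"
  if (any(tr)) manifest$sampling_weight[tr] <- sampling_weights(manifest[tr, ])
  manifest[, manifest_columns]
}

# Physical pitch of a cropped/resized slice image: the native pitches scaled
# by crop_size / out_size.
slice_image_geometry <- function(geometry, crop_size = 448L, out_size = 224L) {
  f <- crop_size / out_size
  list(axial_pitch = geometry$axial_pitch * f,
       lateral_pitch = geometry$lateral_pitch * f)
}

#' Load slice pairs referenced by a manifest into arrays
#'
#' @param manifest training manifest (paths must exist).
#' @return List with `pre`, `post` (n x rows x cols arrays in [0, 1]),
#'   `condition`, `split`, `weight`, and the manifest row order.
#' @export
load_slice_pairs <- function(manifest) {
  n <- nrow(manifest)
  stopifnot(n > 0)
  first <- png::readPNG(manifest$pre_path[1])
  pre <- array(0, c(n, nrow(first), ncol(first)))
  post <- array(0, c(n, nrow(first), ncol(first)))
  for (i in seq_len(n)) {
    pre[i, , ] <- png::readPNG(manifest$pre_path[i])
    post[i, , ] <- png::readPNG(manifest$post_path[i])
  }
  list(pre = pre, post = post,
       condition = as.integer(manifest$condition),
       split = as.character(manifest$split),
       weight = manifest$sampling_weight)
}
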