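#' Construct an OCT volume
#'
#' An OCT volume is a 3-D array of 8-bit intensities indexed
#' (slice, axial row, lateral column) plus its [voxel_geometry()]. Lateral
#' column 1 is taken to be the temporal side for right eyes; this is a fixed,
#' documented convention of the package rather than a property of any device
#' export.
#'
#' @param data 3-D numeric/integer array with values in [0, 255].
#' @param geometry a [voxel_geometry()]; extents must match `dim(data)`.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  d <- dim(data)
  if (length(d) != 3)
    stop("volume data must be a 3-D array (slice, axial, lateral)")
  if (!all(d == c(geometry$n_slices, geometry$n_axial, geometry$n_lateral)))
    stop("volume shape does not match its geometry")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255)
    stop("volume intensities must lie in [0, 255]")
  storage.mode(data) <- "integer"
  structure(list(data = data, geometry = geometry), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OCT volume: %d slices x %d axial x %d lateral, 8-bit\n",
              d[1], d[2], d[3]))
  print(x$geometry)
  invisible(x)
}

#' Write / read an OCT volume as a multipage TIFF with a JSON sidecar
#'
#' The volume is stored losslessly as one 8-bit grayscale TIFF page per
#' slice; the voxel geometry goes to `<path>.json`. `read_volume` refuses to
#' read a TIFF without its sidecar or with mismatched extents, so geometry is
#' never silently defaulted.
#'
#' @param volume an [oct_volume()].
#' @param path TIFF file path.
#' @return `write_volume`: `path`, invisibly. `read_volume`: an
#'   [oct_volume()] bit-identical to the one written.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  g <- volume$geometry
  pages <- lapply(seq_len(g$n_slices), function(s)
    matrix(volume$data[s, , ], g$n_axial, g$n_lateral) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  sidecar <- list(n_slices = g$n_slices, n_axial = g$n_axial,
                  n_lateral = g$n_lateral, scan_width = g$scan_width,
                  slice_pitch = g$slice_pitch, axial_pitch = g$axial_pitch,
                  lateral_pitch = g$lateral_pitch)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing geometry sidecar: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  needed <- c("n_slices", "n_axial", "n_lateral", "scan_width", "axial_pitch")
  if (!all(needed %in% names(sc)))
    stop("corrupt geometry sidecar: ", sidecar_path)
  g <- voxel_geometry(sc$n_slices, sc$n_axial, sc$n_lateral,
                      scan_width = sc$scan_width, axial_pitch = sc$axial_pitch)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != g$n_slices)
    stop("TIFF page count does not match sidecar n_slices")
  arr <- array(0L, c(g$n_slices, g$n_axial, g$n_lateral))
  for (s in seq_along(pages)) {
    pg <- pages[[s]]
    if (!all(dim(pg)[1:2] == c(g$n_axial, g$n_lateral)))
      stop("TIFF page shape does not match sidecar geometry")
    arr[s, , ] <- as.integer(round(pg * 255))
  }
  oct_volume(arr, g)
}

#' Split cases into training / validation / test sets
#'
#' Cases are assigned by a non-repeating random permutation in a 4:1:1
#' ratio, first filling the validation and test sets with `floor(n/6)` cases
#' each and giving every remainder to training, so 150 cases split into
#' 100 training / 25 validation / 25 test.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param ratios length-3 positive ratio (train, validation, test).
#' @param seed integer RNG seed; the same seed reproduces the assignment.
#' @return A data.frame with columns `case_id` and
#'   `split` (factor: train/validation/test) — the skeleton of a training
#'   manifest.
#' @export
split_cases <- function(case_ids, ratios = c(4, 1, 1), seed = 1L) {
  n <- length(case_ids)
  if (n < 1) stop("no cases to split")
  stopifnot(length(ratios) == 3, all(ratios > 0))
  total <- sum(ratios)
  n_val <- floor(n * ratios[2] / total)
  n_test <- floor(n * ratios[3] / total)
  n_train <- n - n_val - n_test
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[perm[n_train + seq_len(n_val)]] <- "validation"
  if (n_test > 0) split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  data.frame(case_id = case_ids,
             split = factor(split, levels = c("train", "validation", "test")))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

manifest_columns <- c("case_id", "split", "slice_index", "condition",
                      "augmentation_tag", "sampling_weight",
                      "pre_path", "post_path")

#' Write / read a training manifest CSV
#'
#' A manifest has one row per slice pair with columns `case_id`, `split`,
#' `slice_index`, `condition` (0-3), `augmentation_tag` (orig, flip, rot4,
#' rot8, shift_t, shift_n), `sampling_weight`, `pre_path`, `post_path`.
#'
#' @param manifest data.frame with the manifest columns.
#' @param path CSV path.
#' @return `read_manifest`: the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(manifest_columns %in% names(manifest)))
  utils::write.csv(manifest[, manifest_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(manifest_columns %in% names(m)))
    stop("not a training manifest: ", path)
  m
}
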