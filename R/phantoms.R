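# Synthetic macular phantoms: layered retinal volumes with a foveal pit, a
# full-thickness macular hole crater preoperatively, a closed hole (with
# optional ELM/EZ band gaps) postoperatively, a known rigid misalignment and
# additive noise. Ground truth (surfaces, statuses, transform) is returned
# alongside so every downstream stage is testable without patient data.

phantom_layers <- c("nfl", "gcl", "ipl", "inl", "opl", "onl",
                    "elm", "ez", "rpe", "choroid")

# Mean gray level per region: vitreous, the ten retinal bands, and the
# space below the choroid. Bands alternate bright/dark so each of the ten
# layers of the image-quality checklist has measurable contrast against its
# neighbours; the RPE is the brightest band, as in real OCT, so it can act
# as the registration landmark.
phantom_palette <- c(vitreous = 8, nfl = 170, gcl = 70, ipl = 120, inl = 60,
                     opl = 110, onl = 40, elm = 150, ez = 200, rpe = 240,
                     choroid = 90, below = 15)

#' Specification of a synthetic macular phantom
#'
#' Defines the geometry and anatomy of one paired pre/postoperative phantom.
#' Defaults reproduce the native scan geometry (256 slices of 992 x 512
#' 8-bit pixels over a 6 x 6 mm^2 field at 2.6 um axial pitch) with ten
#' retinal bands (NFL, GCL, IPL, INL, OPL, ONL, ELM, EZ, RPE, choroid), a
#' foveal pit, and a 450 um full-thickness hole — near the 448 um mean hole
#' size of the modelled cohort.
#'
#' @param n_slices,n_axial,n_lateral volume extents.
#' @param scan_width field of view, um.
#' @param axial_pitch axial sampling, um/pixel.
#' @param layer_thicknesses named or ordered numeric of the 10 band
#'   thicknesses in um (NFL to choroid).
#' @param fovea_slice,fovea_col fovea position (1-based indices); defaults to
#'   the volume centre.
#' @param pit_depth,pit_width foveal pit depth and FWHM, um.
#' @param hole_diameter preoperative full-thickness hole diameter, um
#'   (0 = no hole).
#' @param elm_gap,ez_gap postoperative band gap widths, um (0 = intact band).
#' @param misalignment a [rigid_transform()] applied to the preoperative
#'   volume (identity by default).
#' @param noise_sd additive Gaussian noise SD in 8-bit intensity units.
#' @param seed integer; fully determines the rendered volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 256L, n_axial = 992L, n_lateral = 512L,
                         scan_width = 6000, axial_pitch = 2.6,
                         layer_thicknesses = c(nfl = 20, gcl = 40, ipl = 35,
                                               inl = 35, opl = 30, onl = 80,
                                               elm = 10, ez = 20, rpe = 25,
                                               choroid = 150),
                         fovea_slice = NULL, fovea_col = NULL,
                         pit_depth = 120, pit_width = 1200,
                         hole_diameter = 450,
                         elm_gap = 0, ez_gap = 0,
                         misalignment = rt_identity(),
                         noise_sd = 8, seed = 1L) {
  stopifnot(length(layer_thicknesses) == 10, all(layer_thicknesses > 0),
            hole_diameter >= 0, elm_gap >= 0, ez_gap >= 0, noise_sd >= 0,
            pit_depth >= 0, pit_width > 0,
            inherits(misalignment, "rigid_transform"))
  names(layer_thicknesses) <- phantom_layers
  if (is.null(fovea_slice)) fovea_slice <- as.integer(round(n_slices / 2))
  if (is.null(fovea_col)) fovea_col <- as.integer(round(n_lateral / 2))
  spec <- structure(list(
    n_slices = as.integer(n_slices), n_axial = as.integer(n_axial),
    n_lateral = as.integer(n_lateral), scan_width = scan_width,
    axial_pitch = axial_pitch, layer_thicknesses = layer_thicknesses,
    fovea_slice = as.integer(fovea_slice), fovea_col = as.integer(fovea_col),
    pit_depth = pit_depth, pit_width = pit_width,
    hole_diameter = hole_diameter, elm_gap = elm_gap, ez_gap = ez_gap,
    misalignment = misalignment, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
  # Geometry overflow: the whole stack (plus the retinal depth offset and
  # pit) must fit inside the axial extent.
  extent <- (n_axial - 1) * axial_pitch
  if (sum(layer_thicknesses) / axial_pitch >= n_axial)
    stop("geometry overflow: layer stack exceeds the axial extent")
  b <- phantom_boundary_params(spec)
  if (b$z_rpe_top + layer_thicknesses["rpe"] + layer_thicknesses["choroid"] >=
      extent || b$z_rpe_top - b$above_rpe - sum(layer_thicknesses[1:6]) <= 0)
    stop("geometry overflow: layer stack exceeds the axial extent")
  spec
}

phantom_geometry <- function(spec) {
  voxel_geometry(spec$n_slices, spec$n_axial, spec$n_lateral,
                 scan_width = spec$scan_width, axial_pitch = spec$axial_pitch)
}

phantom_boundary_params <- function(spec) {
  extent <- (spec$n_axial - 1) * spec$axial_pitch
  th <- spec$layer_thicknesses
  list(extent = extent,
       z_rpe_top = 0.58 * extent,      # RPE anterior surface at flat field
       bowl_amp = 40,                  # gentle posterior-pole curvature, um
       above_rpe = th[["ez"]] + th[["elm"]],
       inner_total = sum(th[1:6]),
       pit_sigma = spec$pit_width / 2.3548)  # FWHM -> sigma
}

# Boundary depths (um) for one slice: an 11 x n_lateral matrix, rows are the
# interfaces vitreous|NFL ... choroid|below in depth order.
phantom_boundaries_slice <- function(spec, geom, slice) {
  bp <- phantom_boundary_params(spec)
  th <- spec$layer_thicknesses
  x <- (slice - spec$fovea_slice) * geom$slice_pitch
  zc <- (seq_len(spec$n_lateral) - spec$fovea_col) * geom$lateral_pitch
  r2 <- x^2 + zc^2
  dmax <- spec$scan_width / 2
  z_rpe_top <- bp$z_rpe_top + bp$bowl_amp * r2 / dmax^2
  pit <- exp(-r2 / (2 * bp$pit_sigma^2))
  f <- 1 - pmin(0.95, spec$pit_depth / bp$inner_total) * pit
  b7 <- z_rpe_top - bp$above_rpe               # ONL | ELM
  b1 <- b7 - bp$inner_total * f                # ILM
  inner <- outer(cumsum(th[1:5]), f)           # 5 interfaces within inner stack
  rbind(b1,
        sweep(inner, 2, b1, "+"),
        b7,
        b7 + th[["elm"]],
        z_rpe_top,
        z_rpe_top + th[["rpe"]],
        z_rpe_top + th[["rpe"]] + th[["choroid"]])
}

# Render one noise-free slice (doubles in [0,255]).
render_phantom_slice <- function(spec, geom, slice, hole, elm_gap, ez_gap) {
  a <- spec$n_axial; l <- spec$n_lateral
  b <- phantom_boundaries_slice(spec, geom, slice)
  z <- matrix((seq_len(a) - 1) * spec$axial_pitch, a, l)
  idx <- matrix(1L, a, l)
  for (k in 1:11)
    idx <- idx + (z >= matrix(b[k, ], a, l, byrow = TRUE))
  bext <- rbind(-Inf, b, Inf)                  # 13 x l
  colix <- 13L * rep(0:(l - 1), each = a)
  top <- bext[as.vector(idx) + colix]
  bot <- bext[as.vector(idx) + 1L + colix]
  frac <- (as.vector(z) - top) / (bot - top)
  profile <- ifelse(is.finite(frac), 1 - 0.35 * (2 * frac - 1)^2, 1)
  img <- matrix(phantom_palette[as.vector(idx)] * profile, a, l)

  x <- (slice - spec$fovea_slice) * geom$slice_pitch
  zc <- (seq_len(l) - spec$fovea_col) * geom$lateral_pitch
  r <- sqrt(x^2 + zc^2)
  if (hole && spec$hole_diameter > 0) {
    # smooth super-Gaussian crater; tissue removed where the profile > 1/2
    w <- exp(-(2 * r / spec$hole_diameter)^4)
    crater_cols <- which(w > 0.5)
    if (length(crater_cols)) {
      m <- idx[, crater_cols, drop = FALSE] >= 2L &
        idx[, crater_cols, drop = FALSE] <= 9L
      sub <- img[, crater_cols, drop = FALSE]
      sub[m] <- phantom_palette[["vitreous"]]
      img[, crater_cols] <- sub
    }
  }
  for (band in c("elm", "ez")) {
    gap <- if (band == "elm") elm_gap else ez_gap
    if (gap > 0) {
      gcols <- which(r < gap / 2)
      if (length(gcols)) {
        code <- if (band == "elm") 8L else 9L
        m <- idx[, gcols, drop = FALSE] == code
        sub <- img[, gcols, drop = FALSE]
        sub[m] <- phantom_palette[["onl"]]
        img[, gcols] <- sub
      }
    }
  }
  img
}

# Render a full volume as 8-bit integers, slice by slice (noise added per
# slice) so the peak memory stays near one integer array even at the native
# 256 x 992 x 512 geometry.
render_phantom_volume <- function(spec, geom, hole, elm_gap = 0, ez_gap = 0,
                                  noise_sd = spec$noise_sd) {
  arr <- array(0L, c(spec$n_slices, spec$n_axial, spec$n_lateral))
  for (s in seq_len(spec$n_slices)) {
    img <- render_phantom_slice(spec, geom, s, hole, elm_gap, ez_gap)
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    arr[s, , ] <- as.integer(round(pmin(pmax(img, 0), 255)))
  }
  oct_volume(arr, geom)
}

# Add per-slice clipped Gaussian noise to an existing 8-bit volume.
add_volume_noise <- function(volume, noise_sd) {
  if (noise_sd <= 0) return(volume)
  arr <- volume$data
  d <- dim(arr)
  for (s in seq_len(d[1])) {
    img <- arr[s, , ] + stats::rnorm(d[2] * d[3], 0, noise_sd)
    arr[s, , ] <- as.integer(round(pmin(pmax(img, 0), 255)))
  }
  oct_volume(arr, volume$geometry)
}

#' Generate one paired pre/postoperative phantom case
#'
#' Renders the postoperative volume (closed hole, optional ELM/EZ band
#' gaps) and the preoperative volume (full-thickness crater), resamples the
#' preoperative volume through the spec's rigid misalignment, adds seeded
#' Gaussian noise clipped to the 8-bit range, and returns both volumes with
#' the generating ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case` with elements `pre`, `post`
#'   ([oct_volume()]s) and `truth`, itself a list with `ilm_surface` and
#'   `rpe_surface` (slice x lateral depth maps in um), `fovea_slice`,
#'   `fovea_col`, `elm_status` / `ez_status` (`"restored"` or
#'   `"disrupted"`), and `misalignment`.
#' @export
make_phantom_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  post <- render_phantom_volume(spec, geom, hole = FALSE,
                                elm_gap = spec$elm_gap,
                                ez_gap = spec$ez_gap)
  if (rt_is_identity(spec$misalignment)) {
    pre <- render_phantom_volume(spec, geom, hole = TRUE)
  } else {
    # resample the clean anatomy, then add acquisition noise in the
    # misaligned frame
    pre <- render_phantom_volume(spec, geom, hole = TRUE, noise_sd = 0)
    pre <- add_volume_noise(apply_transform(pre, spec$misalignment),
                            spec$noise_sd)
  }

  truth <- phantom_truth(spec, geom)
  structure(list(pre = pre, post = post, truth = truth, spec = spec),
            class = "phantom_case")
}

# Ground truth for a spec: surfaces of the aligned (postoperative) anatomy.
phantom_truth <- function(spec, geom) {
  th <- spec$layer_thicknesses
  ilm <- matrix(0, spec$n_slices, spec$n_lateral)
  rpe <- matrix(0, spec$n_slices, spec$n_lateral)
  for (s in seq_len(spec$n_slices)) {
    b <- phantom_boundaries_slice(spec, geom, s)
    ilm[s, ] <- b[1, ]
    rpe[s, ] <- b[9, ] + th[["rpe"]] / 2    # RPE band centre
  }
  stopifnot(all(rpe > ilm))
  list(ilm_surface = ilm, rpe_surface = rpe,
       fovea_slice = spec$fovea_slice, fovea_col = spec$fovea_col,
       elm_status = if (spec$elm_gap > 0) "disrupted" else "restored",
       ez_status = if (spec$ez_gap > 0) "disrupted" else "restored",
       misalignment = spec$misalignment,
       palette = phantom_palette,
       layer_thicknesses = th)
}

#' Generate a cohort of phantom cases with jittered anatomy
#'
#' Draws per-case hole diameters, layer-thickness multipliers, pit shapes
#' and rigid misalignments around `base_spec`, reproducibly under `seed`.
#' With `render = FALSE` only the per-case specs are produced (enough to
#' build manifests without rendering any voxel data).
#'
#' @param n_cases number of cases (>= 1).
#' @param base_spec a [phantom_spec()] providing the central values.
#' @param seed integer RNG seed.
#' @param hole_range uniform range of hole diameters, um.
#' @param thickness_jitter relative SD of per-case layer-thickness scaling.
#' @param rot_max_deg,trans_max_um misalignment magnitude bounds (per axis).
#' @param elm_gap_prob,ez_gap_prob probability a case keeps a disrupted
#'   postoperative ELM / EZ band (gap drawn from `gap_range`).
#' @param gap_range uniform range of band-gap widths for disrupted cases, um.
#' @param render if `TRUE`, volumes are rendered for every case.
#' @return An object of class `phantom_cohort`: list with `specs` (always)
#'   and `cases` (when rendered).
#' @export
make_cohort <- function(n_cases, base_spec = phantom_spec(), seed = 1L,
                        hole_range = c(200, 800), thickness_jitter = 0.08,
                        rot_max_deg = 1.5, trans_max_um = 100,
                        elm_gap_prob = 0.25, ez_gap_prob = 0.3,
                        gap_range = c(120, 400), render = TRUE) {
  stopifnot(n_cases >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  geom <- phantom_geometry(base_spec)
  center <- volume_center_um(geom)
  specs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    th <- base_spec$layer_thicknesses *
      pmax(0.6, 1 + stats::rnorm(10, 0, thickness_jitter))
    mis <- rt_from_angles(stats::runif(3, -rot_max_deg, rot_max_deg),
                          stats::runif(3, -trans_max_um, trans_max_um),
                          center = center)
    elm_gap <- if (stats::runif(1) < elm_gap_prob)
      stats::runif(1, gap_range[1], gap_range[2]) else 0
    ez_gap <- if (stats::runif(1) < ez_gap_prob)
      stats::runif(1, gap_range[1], gap_range[2]) else max(elm_gap, 0)
    specs[[i]] <- phantom_spec(
      n_slices = base_spec$n_slices, n_axial = base_spec$n_axial,
      n_lateral = base_spec$n_lateral, scan_width = base_spec$scan_width,
      axial_pitch = base_spec$axial_pitch,
      layer_thicknesses = th,
      fovea_slice = base_spec$fovea_slice, fovea_col = base_spec$fovea_col,
      pit_depth = base_spec$pit_depth * stats::runif(1, 0.8, 1.2),
      pit_width = base_spec$pit_width * stats::runif(1, 0.85, 1.15),
      hole_diameter = stats::runif(1, hole_range[1], hole_range[2]),
      elm_gap = elm_gap, ez_gap = ez_gap,
      misalignment = mis, noise_sd = base_spec$noise_sd,
      seed = base_spec$seed + i)
  }
  cases <- if (render) lapply(specs, make_phantom_case) else NULL
  structure(list(specs = specs, cases = cases, seed = seed),
            class = "phantom_cohort")
}
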