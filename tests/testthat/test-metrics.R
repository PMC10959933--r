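# Agreement metrics: segmentation against generator truth, concordance
# against a brute-force oracle, thickness arithmetic, Bland-Altman closed
# forms, band continuity and the layer-visibility proxy.

test_that("segmentation recovers the phantom boundaries within a pixel", {
  case <- make_phantom_case(tiny_spec(noise_sd = 0, hole_diameter = 0))
  s <- case$spec$fovea_slice
  g <- case$post$geometry
  img <- case$post$data[s, , ] / 255
  seg <- segment_neurosensory(img)
  ilm_truth <- case$truth$ilm_surface[s, ] / g$axial_pitch + 1
  rpe_truth <- case$truth$rpe_surface[s, ] / g$axial_pitch + 1
  expect_true(all(seg$valid))
  expect_lt(max(abs(seg$ilm_curve - ilm_truth)), 2)
  expect_lt(max(abs(seg$rpe_curve - rpe_truth)), 1.5)
  # blank image: nothing segmented, no crash
  blank <- segment_neurosensory(matrix(0, 50, 40))
  expect_false(any(blank$valid))
  expect_false(any(blank$mask))
  # supplied-curves hook bypasses detection exactly
  hook <- segment_neurosensory(img, ilm = rep(30, ncol(img)),
                               rpe = rep(90, ncol(img)))
  expect_equal(hook$ilm_curve, rep(30, ncol(img)))
  expect_equal(sum(hook$mask), ncol(img) * 61)
})

test_that("concordance equals hand counts and a brute-force oracle", {
  m <- matrix(FALSE, 20, 20)
  c1 <- concordance(m | TRUE, m | TRUE)
  expect_equal(c(c1$accuracy, c1$precision, c1$recall, c1$f1), rep(1, 4))

  # 4x4 toy with 6 TRUE in each mask, 4 overlapping
  gt <- matrix(FALSE, 4, 4); gt[1:6] <- TRUE
  ai <- matrix(FALSE, 4, 4); ai[3:8] <- TRUE
  cc <- concordance(ai, gt)
  expect_equal(cc$accuracy, 12 / 16)
  expect_equal(cc$precision, 2 / 3)
  expect_equal(cc$recall, 2 / 3)
  expect_equal(cc$f1, 2 / 3)

  oracle <- function(ai, gt) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(ai)) {
      if (ai[i] && gt[i]) tp <- tp + 1
      else if (ai[i] && !gt[i]) fp <- fp + 1
      else if (!ai[i] && gt[i]) fn <- fn + 1
      else tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(acc = (tp + tn) / length(ai), prec = prec, rec = rec,
      f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  set.seed(40)
  for (k in 1:100) {
    a <- matrix(runif(64) < runif(1), 8, 8)
    g <- matrix(runif(64) < runif(1), 8, 8)
    got <- concordance(a, g)
    want <- oracle(a, g)
    expect_equal(c(got$accuracy, got$precision, got$recall, got$f1),
                 unname(want))
  }
  expect_error(concordance(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("thickness profiles follow the window arithmetic and scale linearly", {
  nc <- 224
  ilm <- rep(50, nc); rpe <- rep(150, nc)   # uniform 100 px thickness
  mask <- segment_neurosensory(matrix(0, 224, nc), ilm = ilm, rpe = rpe)
  th <- thickness_profile(mask, fovea_col = 112, axial_pitch = 5.2,
                          lateral_pitch = 23.4375)
  expect_equal(th$fh, 520)
  expect_equal(th$mft, 520)
  expect_equal(th$mnpt, 520)
  expect_equal(th$mtpt, 520)
  # linearity: doubling the thickness doubles every profile value
  mask2 <- segment_neurosensory(matrix(0, 400, nc), ilm = ilm,
                                rpe = rep(250, nc))
  th2 <- thickness_profile(mask2, 112, 5.2, 23.4375)
  expect_equal(c(th2$fh, th2$mft, th2$mnpt, th2$mtpt),
               2 * c(th$fh, th$mft, th$mnpt, th$mtpt))
  # FH is the thickness at the foveolar column alone
  ilm3 <- ilm; ilm3[112] <- 100
  mask3 <- segment_neurosensory(matrix(0, 224, nc), ilm = ilm3, rpe = rpe)
  expect_equal(thickness_profile(mask3, 112, 5.2, 23.4375)$fh, 50 * 5.2)
  expect_error(thickness_profile(mask, 0, 5.2, 23.4375), "foveolar")
})

test_that("Bland-Altman agrees with its closed form and the 30% rule", {
  b0 <- bland_altman(c(100, 200, 300), c(100, 200, 300))
  expect_equal(c(b0$bias, b0$loa_low, b0$loa_high), c(0, 0, 0))
  expect_true(b0$pass_30)

  # construct pairs whose percentage differences are exactly -10, 0, +10
  gt <- c(100, 100, 100)
  d_target <- c(-10, 0, 10)
  ai <- gt * (1 + d_target / 200) / (1 - d_target / 200)
  ba <- bland_altman(ai, gt)
  expect_equal(ba$differences_pct, d_target, tolerance = 1e-12)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sd(d_target), tolerance = 1e-12)
  expect_equal(ba$loa_high, 19.6, tolerance = 1e-9)
  expect_true(ba$pass_30)

  # a bound just past +30% fails
  d2 <- c(-5, 30.1 * 1:0)  # bias + 1.96 sd beyond 30 by construction
  ai2 <- gt * (1 + d2 / 200) / (1 - d2 / 200)
  ba2 <- bland_altman(ai2, gt)
  expect_gt(ba2$loa_high, 30)
  expect_false(ba2$pass_30)

  expect_error(bland_altman(c(1), c(1)), "2 pairs")
  expect_error(bland_altman(c(1, -1), c(-1, 1)), "mean zero")
})

test_that("ELM/EZ continuity classification follows the generating gaps", {
  g <- octvae:::phantom_geometry(tiny_spec())
  eval_bands <- function(spec) {
    case <- make_phantom_case(spec)
    s <- spec$fovea_slice
    img <- case$post$data[s, , ] / 255
    seg <- segment_neurosensory(img)
    bt <- spec$layer_thicknesses[c("elm", "ez", "rpe")]
    list(elm = band_status(img, seg, spec$fovea_col, g$axial_pitch,
                           g$lateral_pitch, "elm", band_thicknesses = bt),
         ez = band_status(img, seg, spec$fovea_col, g$axial_pitch,
                          g$lateral_pitch, "ez", band_thicknesses = bt))
  }
  intact <- eval_bands(tiny_spec(noise_sd = 0))
  expect_identical(intact$elm$status, "restored")
  expect_identical(intact$ez$status, "restored")
  expect_equal(intact$elm$largest_gap_um, 0)

  broken <- eval_bands(tiny_spec(noise_sd = 0, elm_gap = 200))
  expect_identical(broken$elm$status, "disrupted")

  # a gap below the tolerance (one lateral pixel) still counts as restored
  one_px <- eval_bands(tiny_spec(noise_sd = 0, elm_gap = 1.5 *
                                   g$lateral_pitch))
  expect_identical(one_px$elm$status, "restored")
})

test_that("the layer-visibility proxy scores 10, drops defective bands, and 0 on blanks", {
  spec <- tiny_spec(noise_sd = 0, hole_diameter = 0)
  case <- make_phantom_case(spec)
  s <- spec$fovea_slice
  img <- case$post$data[s, , ]
  expect_equal(layer_visibility_score(img, case$truth, spec, s), 10)
  # zero out the EZ band at its truth location: one point lost
  g <- case$post$geometry
  bpars <- octvae:::phantom_boundaries_slice(spec, g, s)
  ez_top <- bpars[8, ]; ez_bot <- bpars[9, ]
  img2 <- img
  for (cx in seq_len(ncol(img))) {
    rows <- (floor(ez_top[cx] / spec$axial_pitch) + 1):
      (ceiling(ez_bot[cx] / spec$axial_pitch) + 1)
    img2[rows, cx] <- 40
  }
  expect_equal(layer_visibility_score(img2, case$truth, spec, s), 9)
  blank <- matrix(0, spec$n_axial, spec$n_lateral)
  expect_equal(layer_visibility_score(blank, case$truth, spec, s), 0)
})

test_that("the oracle predictor closes the evaluation loop perfectly", {
  case <- make_phantom_case(tiny_spec(noise_sd = 0))
  rep <- evaluate_case(case$pre, case$post, "oracle",
                       fovea_col = case$spec$fovea_col,
                       crop_size = 128L, out_size = 64L)
  expect_equal(rep$concordance$accuracy, 1)
  expect_equal(rep$concordance$f1, 1)
  expect_equal(rep$thickness_ai$fh, rep$thickness_gt$fh)
  expect_equal(rep$thickness_ai$mft, rep$thickness_gt$mft)
  expect_identical(rep$elm_ai$status, rep$elm_gt$status)
  # report carries every section
  expect_true(all(c("concordance", "thickness_ai", "thickness_gt",
                    "elm_ai", "ez_ai", "elm_gt", "ez_gt",
                    "registration") %in% names(rep)))
})
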