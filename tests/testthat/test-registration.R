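# RPE extraction, orthogonal Procrustes fitting, rigid resampling and
# surface residuals.

test_that("a flat bright plane yields a constant surface", {
  g <- voxel_geometry(4, 100, 20, scan_width = 1000, axial_pitch = 2)
  arr <- array(0L, c(4, 100, 20))
  arr[, 60:62, ] <- 200L
  surf <- extract_rpe_surface(oct_volume(arr, g), smoothing_window = 3)
  expect_true(all(surf$valid))
  expect_true(all(abs(surf$height_px - 61) < 1))
})

test_that("an all-zero volume gives an all-invalid mask without crashing", {
  g <- voxel_geometry(4, 80, 16, scan_width = 800, axial_pitch = 2)
  surf <- extract_rpe_surface(oct_volume(array(0L, c(4, 80, 16)), g))
  expect_false(any(surf$valid))
})

test_that("identical surfaces fit to the identity transform", {
  case <- make_phantom_case(reg_spec())
  surf <- extract_rpe_surface(case$post)
  tf <- fit_rigid_transform(surf, surf)
  # SVD round-off on mm-scale coordinates leaves ~1e-6 degree jitter
  expect_lt(rt_angle_deg(tf), 1e-5)
  expect_lt(max(abs(tf$translation)), 1e-3)
  res <- surface_residual(surf, surf)
  expect_equal(res$rms_um, 0)
})

test_that("a known rigid transform is recovered exactly from noise-free point clouds", {
  case <- make_phantom_case(reg_spec())
  p <- truth_rpe_points(case)
  tf_true <- rt_from_angles(c(3, -4, 5), c(80, -120, 150),
                            center = colMeans(p))
  fit <- fit_rigid_points(p, rt_apply(tf_true, p))
  expect_lt(rt_angle_deg(rt_compose(rt_invert(fit), tf_true)), 0.05)
  expect_lt(sqrt(sum((fit$translation - tf_true$translation)^2)), 0.5)
})

test_that("recovery is unbiased under Gaussian height noise", {
  case <- make_phantom_case(reg_spec())
  p <- truth_rpe_points(case)
  tf_true <- rt_from_angles(c(1, -2, 1.5), c(50, -40, 80),
                            center = colMeans(p))
  q <- rt_apply(tf_true, p)
  sigma <- 3  # um of axial height noise
  angles <- trans_err <- resid <- numeric(20)
  set.seed(42)
  for (k in 1:20) {
    pn <- p
    pn[, 2] <- pn[, 2] + rnorm(nrow(p), 0, sigma)
    fit <- fit_rigid_points(pn, q)
    angles[k] <- rt_angle_deg(rt_compose(rt_invert(fit), tf_true))
    trans_err[k] <- sqrt(sum((fit$translation - tf_true$translation)^2))
    moved <- rt_apply(fit, pn)
    resid[k] <- sqrt(mean(rowSums((moved - q)^2)))
  }
  # residual RMS settles at the noise level; recovery errors stay small
  expect_lt(abs(mean(resid) - sigma) / sigma, 0.25)
  expect_lt(mean(angles), 0.2)
  expect_lt(mean(trans_err), 10)
})

test_that("degenerate point sets are rejected", {
  p <- cbind(seq_len(10), 2 * seq_len(10), 0)  # collinear
  expect_error(fit_rigid_points(p, p), "degenerate")
})

test_that("rigid resampling behaves analytically", {
  case <- make_phantom_case(reg_spec())
  vol <- case$post
  # identity is bit-exact
  expect_identical(apply_transform(vol, rt_identity())$data, vol$data)
  # pure translation by integer voxel pitches is an exact shift
  g <- vol$geometry
  tf <- rigid_transform(diag(3), c(0, 5 * g$axial_pitch, 0))
  shifted <- apply_transform(vol, tf)
  expect_identical(shifted$data[, 6:g$n_axial, ],
                   vol$data[, 1:(g$n_axial - 5), ])
  # T then T^-1 correlates > 0.99 with the original in the interior
  tf2 <- rt_from_angles(c(1.5, 0, -1), c(30, 20, -40),
                        center = octvae:::volume_center_um(g))
  back <- apply_transform(apply_transform(vol, tf2), rt_invert(tf2))
  interior <- vol$data[3:22, 60:420, 5:60]
  expect_gt(stats::cor(as.vector(interior),
                       as.vector(back$data[3:22, 60:420, 5:60])), 0.99)
})

test_that("surface residual equals a constant offset analytically", {
  case <- make_phantom_case(reg_spec())
  surf <- extract_rpe_surface(case$post)
  shifted <- surf
  shifted$height_px <- surf$height_px + 4  # 4 px at 2.6 um
  res <- surface_residual(shifted, surf)
  expect_equal(res$rms_um, 4 * 2.6, tolerance = 1e-10)
  expect_equal(res$rms_px, 4, tolerance = 1e-10)
})

test_that("rotations stay orthonormal under composition", {
  set.seed(3)
  tf <- rt_identity()
  for (k in 1:50)
    tf <- rt_compose(tf, rt_from_angles(runif(3, -10, 10), runif(3, -50, 50)))
  expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-10)
})

test_that("end-to-end registration drives the RPE residual below one pixel", {
  spec <- reg_spec(seed = 21L)
  g <- octvae:::phantom_geometry(spec)
  mis <- rt_from_angles(c(1.2, -2, 1.8), c(60, -40, 90),
                        center = octvae:::volume_center_um(g))
  case <- make_phantom_case(reg_spec(seed = 21L, misalignment = mis))
  reg <- register_volumes(case$pre, case$post)
  expect_gt(reg$rms_before_um, reg$rms_after_um)
  expect_lt(reg$rms_after_px, 1)
})
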