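# Centre-of-mass crop/resize, augmentation, slice selection, condition
# bands and sampling weights.

test_that("centre of mass follows hand-computed cases", {
  img <- matrix(0, 30, 40)
  img[10, 20] <- 5
  expect_equal(center_of_mass(img), c(10, 20))
  uni <- matrix(1, 30, 40)
  expect_equal(center_of_mass(uni), c(15.5, 20.5))
  two <- matrix(0, 20, 10)
  two[1, 3] <- 1; two[11, 3] <- 1
  expect_equal(center_of_mass(two)[1], 6)
  expect_error(center_of_mass(matrix(0, 4, 4)), "all-zero")
})

test_that("the 448-column crop spans exactly 5250.0 um at native sampling", {
  g <- voxel_geometry()
  expect_identical(448 * g$lateral_pitch, 5250.0)
  expect_identical(448 * g$axial_pitch, 1164.8)
})

test_that("crop/resize preserves constants and matches a direct Lanczos oracle", {
  const <- matrix(128, 300, 200)
  out <- crop_resize(const, c(150, 100), crop_size = 64L, out_size = 32L)
  expect_equal(dim(out), c(32, 32))
  # interior of a constant stays constant (edges see the zero padding)
  expect_true(all(abs(out[10:22, 10:22] - 128 / 255) < 1e-9))

  # independent oracle: brute-force, non-separable direct summation of the
  # same antialiased Lanczos-4 kernel definition
  lan <- function(x, a = 4) ifelse(abs(x) >= a, 0,
    ifelse(x == 0, 1, a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2)))
  oracle_resize <- function(img, out_n) {
    n_in <- nrow(img)
    scale <- out_n / n_in
    sup <- 4 / scale
    out <- matrix(0, out_n, out_n)
    for (i in seq_len(out_n)) for (j in seq_len(out_n)) {
      sr <- (i - 0.5) / scale + 0.5
      sc <- (j - 0.5) / scale + 0.5
      acc <- 0; wsum <- 0
      for (r in floor(sr - sup):ceiling(sr + sup))
        for (cc in floor(sc - sup):ceiling(sc + sup)) {
          w <- lan((sr - r) * scale) * lan((sc - cc) * scale)
          rr <- min(max(r, 1), n_in); ccl <- min(max(cc, 1), n_in)
          acc <- acc + w * img[rr, ccl]
          wsum <- wsum + w
        }
      out[i, j] <- acc / wsum
    }
    out
  }
  set.seed(8)
  img <- matrix(0, 32, 32)
  img[8:24, 8:24] <- 200
  img <- img + matrix(runif(32 * 32, 0, 30), 32, 32)
  mine <- lanczos_resize(img, 16, 16)
  ref <- oracle_resize(img, 16)
  expect_lt(max(abs(mine - ref)), 1 / 255 * 255)  # within one gray level
})

test_that("augmentation produces six pairs with involutive flip and invertible rotation", {
  set.seed(2)
  # smooth band-structured images (rotation invertibility is a geometric
  # property; bilinear resampling low-passes, so white noise would not
  # round-trip)
  gr <- outer(seq_len(64), seq_len(64), function(r, c)
    0.5 + 0.3 * sin(r / 4) + 0.2 * cos(c / 5))
  pre <- matrix(pmin(pmax(gr + runif(64 * 64, 0, 0.05), 0), 1), 64, 64)
  post <- matrix(pmin(pmax(0.9 * gr + runif(64 * 64, 0, 0.05), 0), 1), 64, 64)
  aug <- augment_pair(pre, post, com = c(32, 32))
  expect_length(aug, 6)
  expect_identical(names(aug), c("orig", "flip", "rot4", "rot8",
                                 "shift_t", "shift_n"))
  expect_equal(aug$orig$pre, pre)
  # flip twice restores the original
  flipped_twice <- aug$flip$pre[, rev(seq_len(64))]
  expect_equal(flipped_twice, pre)
  # rotation by +4 then -4 degrees correlates > 0.99 in the interior
  r4 <- octvae:::affine_sample(pre, rot_deg = 4, center = c(32, 32))
  back <- octvae:::affine_sample(r4, rot_deg = -4, center = c(32, 32))
  i <- 12:52
  expect_gt(cor(as.vector(pre[i, i]), as.vector(back[i, i])), 0.99)
  # integer shifts are exact
  expect_equal(aug$shift_n$pre[, 16:64], pre[, 1:49], tolerance = 1e-12)
  # identical geometric op applied to both members: pre == post input
  same <- augment_pair(pre, pre, com = c(30, 40))
  for (p in same) expect_identical(p$pre, p$post)
})

test_that("slice windows are fovea-centred and clamped at the edges", {
  expect_equal(select_slices(256, 128), 28:227)
  expect_equal(select_slices(256, 11), 1:200)
  expect_equal(select_slices(256, 250), 57:256)
  expect_length(select_slices(256, 60), 200)
  expect_error(select_slices(100, 50), "fewer slices")
  expect_length(select_slices(16, 8, window = 8), 8)
})

test_that("condition bands reproduce the 43/42/43/72 histogram", {
  cond <- condition_bands(200)
  expect_equal(as.vector(table(cond)), c(43, 42, 43, 72))
  # the foveal slice (offset 0) is condition 0
  expect_equal(assign_condition(0), 0)
  # bands are monotone in distance from the centre
  d <- abs(seq_len(200) - 100.5)
  for (k in 0:2)
    expect_lte(max(d[cond == k]), min(d[cond == k + 1]) + 1)
  expect_error(assign_condition(150), "outside")
  # scaled windows keep the proportions and the total
  expect_equal(sum(condition_bands(8) == 0), 2)
  expect_length(condition_bands(8), 8)
})

test_that("inverse-frequency weights balance the condition distribution", {
  m <- data.frame(condition = rep(0:3, c(43, 42, 43, 72)))
  w <- sampling_weights(m)
  expect_true(all(w > 0))
  set.seed(4)
  draw <- sample(m$condition, 40000, replace = TRUE, prob = w)
  prop <- as.vector(table(draw)) / 40000
  expect_true(all(abs(prop - 0.25) < 0.01))
  expect_true(all(sampling_weights(data.frame(condition = rep(2, 10))) ==
                    sampling_weights(data.frame(condition = rep(2, 10)))[1]))
})

test_that("manifests obey the pair-count identities", {
  cohort <- make_cohort(6, tiny_spec(n_slices = 256L), seed = 5,
                        render = FALSE)
  split <- split_cases(sprintf("c%d", 1:6), seed = 6)
  m <- build_dataset(cohort, split, window = 200L, write_images = FALSE)
  expect_equal(sum(m$split == "train"), 4 * 200 * 6)
  expect_equal(sum(m$split == "validation"), 1 * 200)
  expect_equal(sum(m$split == "test"), 1 * 200)
  # every (case, slice, tag) unique
  expect_false(any(duplicated(m[, c("case_id", "slice_index",
                                    "augmentation_tag")])))
  # per-case condition histogram identical across cases
  tr <- m[m$split == "train" & m$augmentation_tag == "orig", ]
  hists <- tapply(tr$condition, tr$case_id, function(x) as.vector(table(x)))
  expect_true(all(vapply(hists, identical, logical(1), hists[[1]])))
})
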