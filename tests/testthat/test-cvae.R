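# Model mechanics: KLD closed forms, the reparameterized sampler, the loss
# schedule, architecture shapes, and deterministic inference.

test_that("KLD matches its closed forms and stays non-negative", {
  expect_equal(kld(rep(0, 8), rep(0, 8)), 0)
  expect_equal(kld(1, 0), 0.5)
  set.seed(20)
  for (k in 1:50) {
    d <- sample(1:16, 1)
    expect_gte(kld(rnorm(d), rnorm(d, 0, 0.5)), 0)
  }
})

test_that("the reparameterized sampler has the right limits and moments", {
  mu <- c(0.5, -1, 2)
  # degenerate variance: z = mu exactly
  expect_equal(sample_latent(mu, rep(-Inf, 3), seed = 1), mu)
  # seeded reproducibility
  expect_identical(sample_latent(mu, c(0, 0.5, -0.5), seed = 7),
                   sample_latent(mu, c(0, 0.5, -0.5), seed = 7))
  # empirical moments over 1e5 draws within 3 standard errors
  n <- 1e5
  set.seed(8)
  z <- replicate(n, sample_latent(0.7, log(0.25)))
  se_mean <- 0.5 / sqrt(n)
  expect_lt(abs(mean(z) - 0.7), 3 * se_mean)
  se_var <- 0.25 * sqrt(2 / (n - 1))
  expect_lt(abs(var(z) - 0.25), 3 * se_var)
})

test_that("the KLD warm-up ramps linearly from 0 to 1", {
  expect_equal(beta_schedule(0, 50), 0)
  expect_equal(beta_schedule(50, 50), 1)
  expect_equal(beta_schedule(25, 50), 0.5)
  b <- beta_schedule(0:100, 50)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("the reconstruction family switches exactly at the configured epoch", {
  cfg <- octvae_config(image_size = 32, base_channels = 2, latent_dim = 4,
                       fc_hidden = c(16, 8, 8, 8), max_epochs = 10,
                       recon_switch_epoch = 5, kld_warmup = 4)
  x <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  xh <- clip_stub <- pmin(pmax(x + rnorm(length(x), 0, 0.02), 0.01), 0.99)
  dim(xh) <- dim(x)
  mu <- rnorm(4); lv <- rnorm(4, 0, 0.3)
  at_switch <- cvae_loss(xh, x, mu, lv, epoch = 5, cfg)
  after <- cvae_loss(xh, x, mu, lv, epoch = 6, cfg)
  expect_identical(at_switch$family, "bce_msssim")
  expect_identical(after$family, "perceptual")
  # KLD term identical across the switch; only the recon family changes
  expect_equal(at_switch$kld, after$kld)
  # a perfect prediction zeroes the MS-SSIM and perceptual terms
  perfect <- cvae_loss(x, x, rep(0, 4), rep(0, 4), epoch = 5, cfg)
  bce_floor <- -mean(x * log(x) + (1 - x) * log(1 - x))
  expect_equal(perfect$recon, bce_floor, tolerance = 1e-6)
  perfect2 <- cvae_loss(x, x, rep(0, 4), rep(0, 4), epoch = 6, cfg)
  expect_equal(perfect2$recon, 0, tolerance = 1e-12)
  # out-of-domain predictions are rejected (BCE domain)
  expect_error(cvae_loss(x + 1, x, mu, lv, 1, cfg), "\\[0, 1\\]")
})

test_that("encoder/decoder shapes follow the four-pool architecture", {
  shapes <- cvae_shapes(octvae_config())
  expect_equal(shapes$spatial[shapes$stage == "enc_conv4"], 14)  # 224 / 2^4
  expect_equal(shapes$spatial[shapes$stage == "input"], 224)
  cfg <- octvae_config(image_size = 64, base_channels = 4, latent_dim = 8,
                       fc_hidden = c(32, 16, 16, 16), dropout = 0)
  model <- octvae_untrained(cfg)
  img <- matrix(runif(64 * 64), 64, 64)
  enc <- cvae_encode(model, img, 1L)
  expect_length(enc$mu, 8)
  expect_length(enc$logvar, 8)
  out <- cvae_decode(model, enc$mu, 1L)
  expect_equal(dim(out), c(64, 64))
  expect_true(all(out > 0 & out < 1))
  # the condition input reaches the latent code: different condition,
  # different output (fixed weights, evaluation mode)
  enc2 <- cvae_encode(model, img, 3L)
  expect_gt(max(abs(enc$mu - enc2$mu)), 0)
})

test_that("training is seed-deterministic and exposes best-epoch selection", {
  set.seed(30)
  n <- 24
  base <- matrix(0, 32, 32); base[10:22, 8:24] <- 0.8
  pre <- array(rep(base, each = n), c(n, 32, 32)) +
    array(runif(n * 32 * 32, 0, 0.05), c(n, 32, 32))
  post <- pre * 0.9
  data <- list(pre = pre, post = post, condition = rep(0:3, 6),
               split = rep(c("train", "validation"), c(16, 8)),
               weight = rep(1, n))
  cfg <- octvae_config(image_size = 32, base_channels = 2, latent_dim = 4,
                       fc_hidden = c(16, 8, 8, 8), batch_size = 8,
                       max_epochs = 3, recon_switch_epoch = 3,
                       kld_warmup = 2, lr = 1e-3, seed = 5)
  m1 <- octvae(data, cfg)
  m2 <- octvae(data, cfg)
  expect_equal(m1$history$train_loss, m2$history$train_loss)
  expect_equal(m1$history$val_loss, m2$history$val_loss)
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
  # deterministic inference: same input twice gives the same output
  p1 <- predict(m1, pre[1, , ], 0L)
  p2 <- predict(m1, pre[1, , ], 0L)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # untrained models refuse silent inference
  expect_error(predict(octvae_untrained(cfg), pre[1, , ], 0L), "untrained")
  # simulate() decodes prior draws reproducibly
  s1 <- simulate(m1, nsim = 2, seed = 3)
  s2 <- simulate(m1, nsim = 2, seed = 3)
  expect_identical(s1, s2)
})
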