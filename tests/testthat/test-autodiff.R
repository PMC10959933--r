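# The reverse-mode tape against central finite differences, op by op and
# through the full encoder/sampler/decoder objective.

num_grad <- function(f, x, i, h = 1e-6) {
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}

check_op <- function(build, x, n_probe = 5, tol = 1e-5) {
  tp <- octvae:::ad_tape()
  xi <- octvae:::ad_leaf(tp, x)
  li <- build(tp, xi)
  g <- octvae:::ad_backward(tp, li)[[xi]]
  f <- function(xv) {
    t2 <- octvae:::ad_tape()
    octvae:::ad_val(t2, build(t2, octvae:::ad_const(t2, xv)))
  }
  for (k in seq_len(n_probe)) {
    i <- sample(length(x), 1)
    num <- num_grad(f, x, i)
    expect_lt(abs(num - g[i]) / (abs(num) + abs(g[i]) + 1e-8), tol)
  }
}

test_that("elementwise, pooling, upsampling and blur gradients match finite differences", {
  set.seed(10)
  x <- array(runif(2 * 8 * 8 * 3, 0.1, 0.9), c(2, 8, 8, 3))
  sq <- function(tp, a) octvae:::ad_mean(tp, octvae:::ad_mul(tp, a, a))
  check_op(function(tp, a) sq(tp, octvae:::ad_sigmoid(tp, a)), x)
  check_op(function(tp, a) sq(tp, octvae:::ad_lrelu(tp, a, 0.2)), x + 0.3)
  check_op(function(tp, a) sq(tp, octvae:::ad_maxpool2(tp, a)), x)
  check_op(function(tp, a) sq(tp, octvae:::ad_avgpool2(tp, a)), x)
  check_op(function(tp, a) sq(tp, octvae:::ad_upnn2(tp, a)), x)
  k <- octvae:::gaussian_kernel1d(5, 1.0)
  check_op(function(tp, a) sq(tp, octvae:::ad_blur(tp, a, k)), x)
})

test_that("nearest-neighbour unpooling fills 2x2 blocks with the same value", {
  tp <- octvae:::ad_tape()
  a <- octvae:::ad_const(tp, array(7, c(1, 1, 1, 1)))
  y <- octvae:::ad_val(tp, octvae:::ad_upnn2(tp, a))
  expect_equal(as.vector(y), rep(7, 4))
  expect_equal(dim(y), c(1, 2, 2, 1))
})

test_that("SSIM of an image with itself is 1 and MS-SSIM gradients check out", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ms_ssim(img, img), 1, tolerance = 1e-9)
  x <- array(runif(1 * 32 * 32, 0.2, 0.8), c(1, 32, 32, 1))
  y <- array(runif(1 * 32 * 32, 0.2, 0.8), c(1, 32, 32, 1))
  check_op(function(tp, a)
    octvae:::ad_ms_ssim(tp, a, octvae:::ad_const(tp, y)), x, tol = 1e-4)
})

test_that("the full conditional-VAE objective differentiates correctly in both phases", {
  set.seed(12)
  cfg <- octvae_config(image_size = 32, base_channels = 2, latent_dim = 4,
                       fc_hidden = c(16, 8, 8, 8), dropout = 0,
                       max_epochs = 3, recon_switch_epoch = 2, kld_warmup = 2)
  params <- octvae_untrained(cfg)$params
  x <- array(runif(2 * 32 * 32), c(2, 32, 32, 1))
  y <- array(runif(2 * 32 * 32), c(2, 32, 32, 1))
  cond <- condition_one_hot(c(0, 2))
  eps <- matrix(rnorm(2 * 4), 2, 4)
  lossfun <- function(params, epoch, want_grads = FALSE) {
    tp <- octvae:::ad_tape()
    bn <- octvae:::new_bn_state()
    ids <- octvae:::bind_params(tp, params)
    enc <- octvae:::cvae_encode_graph(tp, ids, cfg, bn,
                                      octvae:::ad_const(tp, x),
                                      octvae:::ad_const(tp, cond), TRUE)
    z <- octvae:::ad_add(tp, enc$mu, octvae:::ad_mul(tp,
           octvae:::ad_exp(tp, octvae:::ad_scale(tp, enc$logvar, 0.5)),
           octvae:::ad_const(tp, eps)))
    xhat <- octvae:::cvae_decode_graph(tp, ids, cfg, bn, z,
                                       octvae:::ad_const(tp, cond), TRUE)
    obj <- octvae:::ad_cvae_objective(tp, xhat, octvae:::ad_const(tp, y),
                                      enc$mu, enc$logvar, epoch, cfg)
    out <- list(val = octvae:::ad_val(tp, obj$total))
    if (want_grads) {
      g <- octvae:::ad_backward(tp, obj$total)
      out$grads <- lapply(ids, function(i) g[[i]])
    }
    out
  }
  for (epoch in c(1, 3)) {   # BCE+MS-SSIM phase and perceptual phase
    r <- lossfun(params, epoch, TRUE)
    for (nm in c("enc_conv1_w", "enc_fc1_w", "dec_fc3_w", "dec_conv2_w",
                 "enc_bn2_g", "dec_conv4_b")) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num <- (lossfun(pp, epoch)$val - lossfun(pm, epoch)$val) / 2e-5
      ana <- r$grads[[nm]][i]
      expect_lt(abs(num - ana) / (abs(num) + abs(ana) + 1e-6), 1e-4)
    }
  }
})
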