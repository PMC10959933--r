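# Training objective of the conditional VAE: a reconstruction term (binary
# cross-entropy plus multi-scale structural similarity up to the switch
# epoch, then a perceptual feature distance) plus KL divergence against the
# standard-normal prior, whose weight beta ramps linearly from 0 to 1 over
# the warm-up epochs.

gaussian_kernel1d <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Standard 5-scale MS-SSIM weights.
ms_ssim_weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# Luminance and contrast-structure means of SSIM at one scale; x, y are
# node ids of [N, H, W, C] arrays in [0, 1].
ad_ssim_terms <- function(tp, x, y, kernel, c1 = 0.01^2, c2 = 0.03^2) {
  force(x)
  force(y)
  mx <- ad_blur(tp, x, kernel)
  my <- ad_blur(tp, y, kernel)
  mx2 <- ad_mul(tp, mx, mx)
  my2 <- ad_mul(tp, my, my)
  mxy <- ad_mul(tp, mx, my)
  sx <- ad_sub(tp, ad_blur(tp, ad_mul(tp, x, x), kernel), mx2)
  sy <- ad_sub(tp, ad_blur(tp, ad_mul(tp, y, y), kernel), my2)
  sxy <- ad_sub(tp, ad_blur(tp, ad_mul(tp, x, y), kernel), mxy)
  l <- ad_div(tp, ad_shift(tp, ad_scale(tp, mxy, 2), c1),
              ad_shift(tp, ad_add(tp, mx2, my2), c1))
  cs <- ad_div(tp, ad_shift(tp, ad_scale(tp, sxy, 2), c2),
               ad_shift(tp, ad_add(tp, sx, sy), c2))
  list(l = ad_mean(tp, l), cs = ad_mean(tp, cs))
}

# Number of usable MS-SSIM scales for an image size: each scale halves the
# image and the Gaussian window must still fit.
ms_ssim_scales <- function(size, window = 11, max_scales = 5) {
  n <- 1
  while (n < max_scales && floor(size / 2^n) >= window) n <- n + 1
  n
}

# MS-SSIM as a tape node: product over scales of cs_j^w_j with the
# luminance term at the coarsest scale, weights renormalised when fewer
# than 5 scales fit. Terms are clamped to (eps, 1] before the power.
ad_ms_ssim <- function(tp, x, y, window = 11, sigma = 1.5) {
  force(x)
  force(y)
  d <- dim(tp$val[[x]])
  m <- ms_ssim_scales(min(d[2], d[3]), window)
  w <- ms_ssim_weights[seq_len(m)]
  w <- w / sum(w)
  kernel <- gaussian_kernel1d(window, sigma)
  acc <- NULL
  for (j in seq_len(m)) {
    terms <- ad_ssim_terms(tp, x, y, kernel)
    tj <- if (j == m) ad_mul(tp, terms$l, terms$cs) else terms$cs
    fj <- ad_pow_const(tp, ad_clamp(tp, tj, 1e-6, 1), w[j])
    acc <- if (is.null(acc)) fj else ad_mul(tp, acc, fj)
    if (j < m) {
      x <- ad_avgpool2(tp, x)
      y <- ad_avgpool2(tp, y)
    }
  }
  acc
}

# Mean binary cross-entropy between prediction xhat (in (0,1)) and target x.
ad_bce <- function(tp, xhat, x, eps = 1e-7) {
  force(xhat)
  force(x)
  xh <- ad_clamp(tp, xhat, eps, 1 - eps)
  term1 <- ad_mul(tp, x, ad_log(tp, xh))
  term2 <- ad_mul(tp, ad_shift(tp, ad_scale(tp, x, -1), 1),
                  ad_log(tp, ad_shift(tp, ad_scale(tp, xh, -1), 1)))
  ad_scale(tp, ad_mean(tp, ad_add(tp, term1, term2)), -1)
}

# KLD per image (summed over latent dimensions, averaged over the batch)
# as a tape node. mu, logvar: [N, d] nodes.
ad_kld <- function(tp, mu, logvar) {
  force(mu)
  force(logvar)
  n <- nrow(tp$val[[mu]])
  inner <- ad_sub(tp, ad_shift(tp, logvar, 1),
                  ad_add(tp, ad_mul(tp, mu, mu), ad_exp(tp, logvar)))
  ad_scale(tp, ad_sum(tp, inner), -0.5 / n)
}

#' Kullback-Leibler divergence to the standard-normal prior
#'
#' Closed-form KLD of a diagonal Gaussian `N(mu, exp(logvar))` against
#' `N(0, I)`: `-1/2 * sum(1 + logvar - mu^2 - exp(logvar))`. Zero when
#' `mu = 0, logvar = 0`; `0.5` for a single dimension with `mu = 1,
#' logvar = 0`.
#'
#' @param mu,logvar numeric vectors (one latent sample's parameters).
#' @return Non-negative scalar.
#' @export
kld <- function(mu, logvar) {
  stopifnot(length(mu) == length(logvar), all(is.finite(mu)),
            all(is.finite(logvar)))
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
}

#' KLD warm-up schedule
#'
#' The weight beta of the KLD term ramps linearly from 0 at epoch 0 to 1 at
#' epoch `warmup` and stays 1 afterwards, preventing early latent-vector
#' deactivation.
#'
#' @param epoch epoch counter starting at 0 (vectorised).
#' @param warmup warm-up length in epochs.
#' @return beta in [0, 1], monotone nondecreasing in `epoch`.
#' @export
beta_schedule <- function(epoch, warmup) {
  if (warmup <= 0) return(rep(1, length(epoch)))
  pmin(1, pmax(0, epoch / warmup))
}

# Fixed random-convolution feature extractor for the perceptual loss:
# two 3x3 conv + leaky-ReLU stages with average pooling, weights drawn once
# from a seeded stream. Deterministic and self-contained; a pretrained-
# network LPIPS can be plugged in through the same interface.
perceptual_filters <- function(channels = c(8, 16), seed = 7L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  f <- list()
  cin <- 1L
  for (i in seq_along(channels)) {
    co <- channels[i]
    f[[i]] <- list(
      w = array(stats::rnorm(9 * cin * co, 0, sqrt(2 / (9 * cin))),
                c(3, 3, cin, co)),
      b = numeric(co))
    cin <- co
  }
  f
}

# Perceptual distance as a tape node: mean squared feature difference
# across the stages.
ad_perceptual <- function(tp, xhat, x, filters) {
  force(xhat)
  force(x)
  fx <- xhat
  fy <- x
  acc <- NULL
  for (st in filters) {
    w <- ad_const(tp, st$w); b <- ad_const(tp, st$b)
    fx <- ad_avgpool2(tp, ad_lrelu(tp, ad_conv3x3(tp, fx, w, b), 0.2))
    fy <- ad_avgpool2(tp, ad_lrelu(tp, ad_conv3x3(tp, fy, w, b), 0.2))
    dsq <- ad_mul(tp, ad_sub(tp, fx, fy), ad_sub(tp, fx, fy))
    m <- ad_mean(tp, dsq)
    acc <- if (is.null(acc)) m else ad_add(tp, acc, m)
  }
  acc
}

# Assemble the full objective on a tape. Returns node ids for the total and
# the components. Epochs are 1-based; epochs <= recon_switch_epoch use
# BCE + lambda_s * (1 - MS-SSIM), later epochs the perceptual distance
# (optionally retaining BCE). beta = beta_schedule(epoch - 1, warmup).
ad_cvae_objective <- function(tp, xhat, x, mu, logvar, epoch, config,
                              filters = NULL) {
  force(xhat)
  force(x)
  force(mu)
  force(logvar)
  beta <- beta_schedule(epoch - 1, config$kld_warmup)
  if (epoch <= config$recon_switch_epoch) {
    bce_id <- ad_bce(tp, xhat, x)
    ms <- ad_ms_ssim(tp, xhat, x)
    ms_term <- ad_scale(tp, ad_shift(tp, ad_scale(tp, ms, -1), 1),
                        config$ms_ssim_weight)
    recon <- ad_add(tp, bce_id, ms_term)
    family <- "bce_msssim"
  } else {
    if (is.null(filters)) filters <- perceptual_filters(seed = config$perceptual_seed)
    recon <- ad_scale(tp, ad_perceptual(tp, xhat, x, filters),
                      config$perceptual_weight)
    if (isTRUE(config$keep_bce_after_switch))
      recon <- ad_add(tp, recon, ad_bce(tp, xhat, x))
    family <- "perceptual"
  }
  kld_id <- ad_kld(tp, mu, logvar)
  total <- ad_add(tp, recon, ad_scale(tp, kld_id, beta))
  list(total = total, recon = recon, kld = kld_id, beta = beta,
       family = family)
}

#' Evaluate the conditional-VAE loss for given tensors
#'
#' Computes the epoch-dependent objective without training: the
#' reconstruction family is BCE + `ms_ssim_weight * (1 - MS-SSIM)` for
#' epochs up to `recon_switch_epoch` and the perceptual feature distance
#' afterwards; the KLD term is weighted by the warm-up beta.
#'
#' @param xhat,x prediction and target: matrices or [N, H, W, 1] arrays with
#'   values in [0, 1] (`xhat` strictly inside for the BCE domain).
#' @param mu,logvar latent parameters, vectors or [N, d] matrices.
#' @param epoch 1-based epoch number.
#' @param config an [octvae_config()].
#' @return List with `total`, `recon`, `kld`, `beta` and the reconstruction
#'   `family` in effect.
#' @export
cvae_loss <- function(xhat, x, mu, logvar, epoch, config = octvae_config()) {
  if (min(xhat) < 0 || max(xhat) > 1)
    stop("predictions must lie in [0, 1] for the binary cross-entropy")
  xhat <- as_nhwc(xhat); x <- as_nhwc(x)
  if (!is.matrix(mu)) mu <- rbind(mu)
  if (!is.matrix(logvar)) logvar <- rbind(logvar)
  tp <- ad_tape()
  obj <- ad_cvae_objective(tp, ad_leaf(tp, xhat), ad_const(tp, x),
                           ad_leaf(tp, mu), ad_leaf(tp, logvar),
                           epoch, config)
  list(total = ad_val(tp, obj$total), recon = ad_val(tp, obj$recon),
       kld = ad_val(tp, obj$kld), beta = obj$beta, family = obj$family)
}

as_nhwc <- function(x) {
  if (is.matrix(x)) array(x, c(1, nrow(x), ncol(x), 1))
  else if (length(dim(x)) == 3) array(x, c(dim(x), 1))
  else x
}

#' Multi-scale structural similarity of two images
#'
#' Standard MS-SSIM (Gaussian window 11, sigma 1.5, standard scale weights,
#' clipped to the scales that fit the image) between images in [0, 1].
#'
#' @param x,y numeric matrices in [0, 1].
#' @return Scalar in (0, 1].
#' @export
ms_ssim <- function(x, y) {
  tp <- ad_tape()
  ad_val(tp, ad_ms_ssim(tp, ad_const(tp, as_nhwc(x)),
                        ad_const(tp, as_nhwc(y))))
}
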