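# Conditional variational autoencoder for postoperative OCT B-scan
# prediction. Encoder: four 3x3/stride-1/pad-1 conv blocks with channel
# doubling, each followed by batch normalization, leaky ReLU, dropout and
# 2x max pooling, then five fully connected layers with the condition
# one-hot concatenated at the first, producing mean and log-variance
# vectors. Sampler: reparameterization trick. Decoder: the mirror image —
# five fully connected layers (condition concatenated to z), four conv
# blocks with nearest-neighbour 2x unpooling, sigmoid output.

#' Configuration of the conditional VAE
#'
#' Layer counts, kernel geometry (3x3, stride 1, padding 1, channel
#' doubling, 2x pooling), the 600-epoch budget and the epoch-400
#' reconstruction-loss switch are fixed by the modelled architecture;
#' everything else (latent width, channels, optimizer settings, warm-up and
#' early-stopping) is a stated default.
#'
#' @param image_size input size (multiple of 16; 224 native, 64 for small
#'   studies).
#' @param base_channels first conv-layer channels C; later layers use 2C,
#'   4C, 8C.
#' @param latent_dim latent dimension d.
#' @param fc_hidden widths of the four hidden fully connected layers
#'   (the fifth maps to/from the latent or flattened feature vector).
#' @param dropout dropout rate in the conv blocks.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training budget.
#' @param recon_switch_epoch last epoch using BCE + MS-SSIM; later epochs
#'   use the perceptual loss.
#' @param kld_warmup epochs over which the KLD weight beta ramps 0 to 1.
#' @param ms_ssim_weight,perceptual_weight loss-term weights.
#' @param keep_bce_after_switch retain the BCE term alongside the
#'   perceptual loss after the switch.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param perceptual_seed seed of the fixed random-convolution perceptual
#'   feature extractor.
#' @param seed RNG seed governing initialisation, sampling, dropout and
#'   data order.
#' @return An object of class `octvae_config`.
#' @export
octvae_config <- function(image_size = 224L, base_channels = 32L,
                          latent_dim = 256L,
                          fc_hidden = c(512L, 256L, 128L, 64L),
                          dropout = 0.1, leaky_slope = 0.2,
                          lr = 1e-4, batch_size = 32L,
                          max_epochs = 600L, recon_switch_epoch = 400L,
                          kld_warmup = 50L, ms_ssim_weight = 1,
                          perceptual_weight = 1,
                          keep_bce_after_switch = FALSE,
                          patience = 30L, perceptual_seed = 7L, seed = 1L) {
  stopifnot(image_size %% 16 == 0, latent_dim >= 1,
            recon_switch_epoch <= max_epochs, length(fc_hidden) == 4,
            base_channels >= 1, dropout >= 0, dropout < 1)
  structure(list(image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 latent_dim = as.integer(latent_dim),
                 fc_hidden = as.integer(fc_hidden),
                 dropout = dropout, leaky_slope = leaky_slope,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 recon_switch_epoch = as.integer(recon_switch_epoch),
                 kld_warmup = as.integer(kld_warmup),
                 ms_ssim_weight = ms_ssim_weight,
                 perceptual_weight = perceptual_weight,
                 keep_bce_after_switch = keep_bce_after_switch,
                 patience = as.integer(patience),
                 perceptual_seed = as.integer(perceptual_seed),
                 seed = as.integer(seed)),
            class = "octvae_config")
}

#' Per-stage tensor shapes of the encoder/decoder
#'
#' Audits the architecture arithmetic: four 2x poolings reduce a 224 input
#' to 14 x 14 before flattening; the decoder mirrors the sequence.
#'
#' @param config an [octvae_config()].
#' @return data.frame with stage names, spatial sizes and channel counts.
#' @export
cvae_shapes <- function(config) {
  s <- config$image_size
  ch <- config$base_channels * c(1, 2, 4, 8)
  spatial <- s / 2^(0:4)
  data.frame(
    stage = c("input", paste0("enc_conv", 1:4), "flatten", "latent"),
    spatial = c(spatial, 1, 1),
    channels = c(1, ch, ch[4] * (s / 16)^2, config$latent_dim))
}

cvae_channels <- function(config) config$base_channels * c(1, 2, 4, 8)
cvae_flat_dim <- function(config) {
  sp <- config$image_size / 16
  cvae_channels(config)[4] * sp * sp
}

init_w <- function(n, fanin) stats::rnorm(n, 0, sqrt(2 / fanin))

# Initialise all weights (He initialisation, seeded by config$seed).
cvae_init_params <- function(config) {
  ch <- cvae_channels(config)
  flat <- cvae_flat_dim(config)
  h <- config$fc_hidden
  d <- config$latent_dim
  p <- list()
  cin <- 1L
  for (k in 1:4) {
    co <- ch[k]
    p[[paste0("enc_conv", k, "_w")]] <-
      array(init_w(9 * cin * co, 9 * cin), c(3, 3, cin, co))
    p[[paste0("enc_conv", k, "_b")]] <- numeric(co)
    p[[paste0("enc_bn", k, "_g")]] <- rep(1, co)
    p[[paste0("enc_bn", k, "_b")]] <- numeric(co)
    cin <- co
  }
  enc_dims <- c(flat + 4L, h, 2L * d)
  for (k in 1:5) {
    p[[paste0("enc_fc", k, "_w")]] <-
      matrix(init_w(enc_dims[k] * enc_dims[k + 1], enc_dims[k]),
             enc_dims[k], enc_dims[k + 1])
    p[[paste0("enc_fc", k, "_b")]] <- numeric(enc_dims[k + 1])
  }
  dec_dims <- c(d + 4L, rev(h), flat)
  for (k in 1:5) {
    p[[paste0("dec_fc", k, "_w")]] <-
      matrix(init_w(dec_dims[k] * dec_dims[k + 1], dec_dims[k]),
             dec_dims[k], dec_dims[k + 1])
    p[[paste0("dec_fc", k, "_b")]] <- numeric(dec_dims[k + 1])
  }
  dch <- c(ch[4], ch[3], ch[2], ch[1], 1L)
  for (k in 1:4) {
    p[[paste0("dec_conv", k, "_w")]] <-
      array(init_w(9 * dch[k] * dch[k + 1], 9 * dch[k]),
            c(3, 3, dch[k], dch[k + 1]))
    p[[paste0("dec_conv", k, "_b")]] <- numeric(dch[k + 1])
    if (k < 4) {
      p[[paste0("dec_bn", k, "_g")]] <- rep(1, dch[k + 1])
      p[[paste0("dec_bn", k, "_b")]] <- numeric(dch[k + 1])
    }
  }
  p
}

new_bn_state <- function() {
  st <- new.env(parent = emptyenv())
  st$running_mean <- list()
  st$running_var <- list()
  st
}

#' Initialise an untrained conditional VAE
#'
#' @param config an [octvae_config()].
#' @return An object of class `octvae` with freshly initialised weights,
#'   `trained = FALSE` and an empty history.
#' @export
octvae_untrained <- function(config = octvae_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  structure(list(params = cvae_init_params(config), bn = new_bn_state(),
                 config = config, history = NULL, best_epoch = NA_integer_,
                 trained = FALSE),
            class = "octvae")
}

# Bind all parameters as tape leaves; returns named id vector.
bind_params <- function(tp, params) {
  ids <- integer(length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- ad_leaf(tp, params[[nm]])
  ids
}

bind_consts <- function(tp, params) {
  ids <- integer(length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- ad_const(tp, params[[nm]])
  ids
}

# Encoder forward. x: [N, H, W, 1] node; cond: [N, 4] node.
cvae_encode_graph <- function(tp, ids, cfg, bn, x, cond, training) {
  h <- x
  for (k in 1:4) {
    h <- ad_conv3x3(tp, h, ids[[paste0("enc_conv", k, "_w")]],
                    ids[[paste0("enc_conv", k, "_b")]])
    h <- ad_batchnorm(tp, h, ids[[paste0("enc_bn", k, "_g")]],
                      ids[[paste0("enc_bn", k, "_b")]], bn,
                      paste0("enc", k), training)
    h <- ad_lrelu(tp, h, cfg$leaky_slope)
    h <- ad_dropout(tp, h, cfg$dropout, training)
    h <- ad_maxpool2(tp, h)
  }
  n <- dim(tp$val[[x]])[1]
  h <- ad_reshape(tp, h, c(n, cvae_flat_dim(cfg)))
  h <- ad_concat_cols(tp, h, cond)
  for (k in 1:5) {
    h <- ad_matmul(tp, h, ids[[paste0("enc_fc", k, "_w")]])
    h <- ad_addbias(tp, h, ids[[paste0("enc_fc", k, "_b")]])
    if (k < 5) h <- ad_lrelu(tp, h, cfg$leaky_slope)
  }
  d <- cfg$latent_dim
  list(mu = ad_slice_cols(tp, h, seq_len(d)),
       logvar = ad_slice_cols(tp, h, d + seq_len(d)))
}

# Decoder forward. z: [N, d] node.
cvae_decode_graph <- function(tp, ids, cfg, bn, z, cond, training) {
  h <- ad_concat_cols(tp, z, cond)
  for (k in 1:5) {
    h <- ad_matmul(tp, h, ids[[paste0("dec_fc", k, "_w")]])
    h <- ad_addbias(tp, h, ids[[paste0("dec_fc", k, "_b")]])
    h <- ad_lrelu(tp, h, cfg$leaky_slope)
  }
  n <- nrow(tp$val[[z]])
  sp <- cfg$image_size / 16
  h <- ad_reshape(tp, h, c(n, sp, sp, cvae_channels(cfg)[4]))
  for (k in 1:4) {
    h <- ad_upnn2(tp, h)
    h <- ad_conv3x3(tp, h, ids[[paste0("dec_conv", k, "_w")]],
                    ids[[paste0("dec_conv", k, "_b")]])
    if (k < 4) {
      h <- ad_batchnorm(tp, h, ids[[paste0("dec_bn", k, "_g")]],
                        ids[[paste0("dec_bn", k, "_b")]], bn,
                        paste0("dec", k), training)
      h <- ad_lrelu(tp, h, cfg$leaky_slope)
      h <- ad_dropout(tp, h, cfg$dropout, training)
    }
  }
  ad_sigmoid(tp, h)
}

#' Encode images to latent mean and log-variance
#'
#' @param object an `octvae` model.
#' @param image matrix (one image) or [N, H, W] / [N, H, W, 1] array in
#'   [0, 1], matching the configured size.
#' @param condition integer 0-3 (scalar or length N).
#' @return List with `mu` and `logvar` ([N, d] matrices; vectors for a
#'   single image).
#' @export
cvae_encode <- function(object, image, condition) {
  x <- as_nhwc(image)
  cfg <- object$config
  if (dim(x)[2] != cfg$image_size || dim(x)[3] != cfg$image_size)
    stop("image size does not match the model configuration")
  n <- dim(x)[1]
  cond <- condition_one_hot(rep_len(condition, n))
  if (is.null(dim(cond))) cond <- rbind(cond)
  tp <- ad_tape()
  ids <- bind_consts(tp, object$params)
  enc <- cvae_encode_graph(tp, ids, cfg, object$bn, ad_const(tp, x),
                           ad_const(tp, cond), training = FALSE)
  mu <- ad_val(tp, enc$mu); lv <- ad_val(tp, enc$logvar)
  if (n == 1) list(mu = as.numeric(mu), logvar = as.numeric(lv))
  else list(mu = mu, logvar = lv)
}

#' Reparameterized latent sample
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` drawn from a
#' seeded stream.
#'
#' @param mu,logvar numeric vectors or [N, d] matrices.
#' @param seed integer seed for the noise draw (`NULL` = current stream).
#' @return z with the shape of `mu`.
#' @export
sample_latent <- function(mu, logvar, seed = NULL) {
  stopifnot(all(is.finite(mu)), length(mu) == length(logvar))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  eps <- stats::rnorm(length(mu))
  if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  mu + exp(logvar / 2) * eps
}

#' Decode a latent vector to an image
#'
#' @param object an `octvae` model.
#' @param z latent vector (length d) or [N, d] matrix.
#' @param condition integer 0-3.
#' @return Image matrix in (0, 1) (or [N, H, W] array for batches).
#' @export
cvae_decode <- function(object, z, condition) {
  cfg <- object$config
  if (is.null(dim(z))) z <- rbind(z)
  n <- nrow(z)
  cond <- condition_one_hot(rep_len(condition, n))
  if (is.null(dim(cond))) cond <- rbind(cond)
  tp <- ad_tape()
  ids <- bind_consts(tp, object$params)
  out <- cvae_decode_graph(tp, ids, cfg, object$bn, ad_const(tp, z),
                           ad_const(tp, cond), training = FALSE)
  v <- ad_val(tp, out)
  if (n == 1) matrix(v[1, , , 1], cfg$image_size, cfg$image_size)
  else array(v, dim(v)[1:3])
}

# Adam optimizer step (in place on the params list; state env keeps m, v).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[nm]] <- m; state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

#' Fit the conditional variational autoencoder
#'
#' Trains the encoder/sampler/decoder on preoperative-to-postoperative
#' slice pairs with condition vectors, using weighted random sampling of
#' the training rows, the epoch-scheduled reconstruction loss (BCE +
#' MS-SSIM, switching to the perceptual distance after
#' `recon_switch_epoch`), linear KLD warm-up, early stopping on the
#' validation loss, and selection of the best-validation-epoch weights.
#'
#' @param data list with `pre`, `post` ([N, H, W] arrays in [0, 1]),
#'   `condition` (integer 0-3), `split` (character: train/validation/...),
#'   and optionally `weight` (training sampling weights) — the layout
#'   returned by [load_slice_pairs()].
#' @param config an [octvae_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `octvae`: best-epoch weights, batch-norm
#'   statistics, the config, a per-epoch `history` (train/validation loss,
#'   beta, loss family) and `best_epoch = argmin` of the validation loss.
#' @export
octvae <- function(data, config = octvae_config(), verbose = FALSE) {
  stopifnot(is.list(data), !is.null(data$pre), !is.null(data$post))
  cfg <- config
  tr_idx <- which(data$split == "train")
  va_idx <- which(data$split == "validation")
  if (!length(tr_idx)) stop("empty training split")
  if (!length(va_idx)) stop("empty validation split")
  wts <- if (!is.null(data$weight)) data$weight[tr_idx] else
    rep(1, length(tr_idx))
  wts[!is.finite(wts)] <- 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  params <- cvae_init_params(cfg)
  bn <- new_bn_state()
  adam <- new.env(parent = emptyenv())
  adam$t <- 0; adam$m <- list(); adam$v <- list()
  filters <- perceptual_filters(seed = cfg$perceptual_seed)

  nb <- cfg$batch_size
  history <- data.frame()
  best <- Inf; best_epoch <- NA_integer_; best_params <- NULL
  best_bn <- NULL; stall <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- tr_idx[sample.int(length(tr_idx), length(tr_idx),
                                   replace = TRUE, prob = wts)]
    batch_losses <- c()
    for (b0 in seq(1, length(order_idx), by = nb)) {
      bi <- order_idx[b0:min(b0 + nb - 1, length(order_idx))]
      x <- array(data$pre[bi, , , drop = FALSE],
                 c(length(bi), dim(data$pre)[2], dim(data$pre)[3], 1))
      y <- array(data$post[bi, , , drop = FALSE],
                 c(length(bi), dim(data$post)[2], dim(data$post)[3], 1))
      cond <- condition_one_hot(data$condition[bi])
      if (is.null(dim(cond))) cond <- rbind(cond)
      tp <- ad_tape()
      ids <- bind_params(tp, params)
      enc <- cvae_encode_graph(tp, ids, cfg, bn, ad_const(tp, x),
                               ad_const(tp, cond), training = TRUE)
      eps <- matrix(stats::rnorm(length(bi) * cfg$latent_dim),
                    length(bi), cfg$latent_dim)
      z <- ad_add(tp, enc$mu,
                  ad_mul(tp, ad_exp(tp, ad_scale(tp, enc$logvar, 0.5)),
                         ad_const(tp, eps)))
      xhat <- cvae_decode_graph(tp, ids, cfg, bn, z, ad_const(tp, cond),
                                training = TRUE)
      obj <- ad_cvae_objective(tp, xhat, ad_const(tp, y), enc$mu, enc$logvar,
                               epoch, cfg, filters)
      batch_losses <- c(batch_losses, ad_val(tp, obj$total))
      grads_by_id <- ad_backward(tp, obj$total)
      grads <- lapply(ids, function(i) grads_by_id[[i]])
      params <- adam_step(params, grads, adam, cfg$lr)
    }
    val <- cvae_eval_loss(params, bn, cfg, data, va_idx, epoch, filters)
    fam <- if (epoch <= cfg$recon_switch_epoch) "bce_msssim" else "perceptual"
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(batch_losses), val_loss = val$total,
      val_recon = val$recon, val_kld = val$kld,
      beta = beta_schedule(epoch - 1, cfg$kld_warmup), family = fam))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  beta %.2f  [%s]",
                      epoch, mean(batch_losses), val$total,
                      history$beta[epoch], fam))
    if (val$total < best - 1e-12) {
      best <- val$total; best_epoch <- epoch
      best_params <- params
      best_bn <- list(running_mean = as.list(bn$running_mean),
                      running_var = as.list(bn$running_var))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  bn_best <- new_bn_state()
  bn_best$running_mean <- best_bn$running_mean
  bn_best$running_var <- best_bn$running_var
  structure(list(params = best_params, bn = bn_best, config = cfg,
                 history = history, best_epoch = best_epoch,
                 n_train = length(tr_idx), n_validation = length(va_idx),
                 trained = TRUE),
            class = "octvae")
}

# Validation loss in evaluation mode (running BN statistics, no dropout,
# z = mu) under the epoch's objective.
cvae_eval_loss <- function(params, bn, cfg, data, idx, epoch, filters) {
  nb <- cfg$batch_size
  tot <- rec <- kl <- 0
  n <- 0
  for (b0 in seq(1, length(idx), by = nb)) {
    bi <- idx[b0:min(b0 + nb - 1, length(idx))]
    x <- array(data$pre[bi, , , drop = FALSE],
               c(length(bi), dim(data$pre)[2], dim(data$pre)[3], 1))
    y <- array(data$post[bi, , , drop = FALSE],
               c(length(bi), dim(data$post)[2], dim(data$post)[3], 1))
    cond <- condition_one_hot(data$condition[bi])
    if (is.null(dim(cond))) cond <- rbind(cond)
    tp <- ad_tape()
    ids <- bind_consts(tp, params)
    enc <- cvae_encode_graph(tp, ids, cfg, bn, ad_const(tp, x),
                             ad_const(tp, cond), training = FALSE)
    xhat <- cvae_decode_graph(tp, ids, cfg, bn, enc$mu, ad_const(tp, cond),
                              training = FALSE)
    obj <- ad_cvae_objective(tp, xhat, ad_const(tp, y), enc$mu, enc$logvar,
                             epoch, cfg, filters)
    w <- length(bi)
    tot <- tot + w * ad_val(tp, obj$total)
    rec <- rec + w * ad_val(tp, obj$recon)
    kl <- kl + w * ad_val(tp, obj$kld)
    n <- n + w
  }
  list(total = tot / n, recon = rec / n, kld = kl / n)
}

#' Predict the postoperative slice from a preoperative slice
#'
#' Deterministic inference: the image is encoded, the latent mean is used
#' directly (no sampling), and the decoder runs in evaluation mode (no
#' dropout, fixed normalization statistics), so the same input always gives
#' the same AI-OCT output. Set `sample = TRUE` to draw z stochastically for
#' diversity studies.
#'
#' @param object a trained `octvae` model.
#' @param image preoperative slice matrix in [0, 1] at the configured size.
#' @param condition integer 0-3.
#' @param sample draw z by the reparameterization trick instead of using mu.
#' @param allow_untrained permit inference from an untrained model (used
#'   for baseline comparisons); otherwise untrained models are an error.
#' @param ... unused.
#' @return Predicted slice matrix in (0, 1).
#' @export
predict.octvae <- function(object, image, condition = 0L, sample = FALSE,
                           allow_untrained = FALSE, ...) {
  if (!isTRUE(object$trained) && !allow_untrained)
    stop("model is untrained; fit it with octvae() first")
  enc <- cvae_encode(object, image, condition)
  z <- if (sample) sample_latent(enc$mu, enc$logvar) else enc$mu
  cvae_decode(object, z, condition)
}

#' @export
print.octvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Conditional VAE (%dx%d, C=%d, d=%d)%s\n",
              cfg$image_size, cfg$image_size, cfg$base_channels,
              cfg$latent_dim,
              if (isTRUE(x$trained)) "" else " [untrained]"))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; best epoch %d (val loss %.4f)\n",
                nrow(x$history), x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.octvae <- function(object, ...) {
  npar <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("Conditional VAE: %s parameters\n", format(npar, big.mark = ",")))
  print(cvae_shapes(object$config))
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.octvae <- function(object, ...) object$params

#' @export
plot.octvae <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
simulate.octvae <- function(object, nsim = 1, seed = NULL, condition = 0L,
                            ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  d <- object$config$latent_dim
  z <- matrix(stats::rnorm(nsim * d), nsim, d)
  cvae_decode(object, z, condition)
}

#' @export
residuals.octvae <- function(object, data, ...) {
  n <- dim(data$pre)[1]
  vapply(seq_len(n), function(i) {
    pred <- predict(object, data$pre[i, , ], data$condition[i])
    mean(abs(pred - data$post[i, , ]))
  }, numeric(1))
}
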