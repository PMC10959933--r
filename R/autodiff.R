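# Minimal reverse-mode automatic differentiation on dense arrays.
#
# The network, its losses (BCE, MS-SSIM, KLD, perceptual) and their
# gradients are all expressed through this tape, so a single backward pass
# differentiates the whole objective. Nodes hold plain R arrays; the heavy
# ops (convolution, fully connected layers) reduce to BLAS matrix products.
# Gradient correctness is checked against finite differences in the tests.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- list()
  tp$bw <- list()
  tp$req <- logical(0)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, val, bw = NULL, req = FALSE) {
  i <- tp$n + 1L
  tp$n <- i
  tp$val[[i]] <- val
  tp$bw[i] <- if (req && !is.null(bw)) list(bw) else list(NULL)
  tp$req[i] <- req
  i
}

ad_val <- function(tp, i) {
  force(i)
  tp$val[[i]]
}
ad_const <- function(tp, v) ad_node(tp, v)
ad_leaf <- function(tp, v) ad_node(tp, v, req = TRUE)

ad_req <- function(tp, ...) any(tp$req[c(...)])

# Reduce a gradient to the shape of a scalar parent (broadcast adjoint).
ad_fit_grad <- function(g, v) {
  if (length(v) == 1 && length(g) > 1) sum(g) else g
}

# Backward pass from a scalar loss node; returns a list of gradients
# indexed by node id (only nodes with req = TRUE are populated).
ad_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss]] <- 1
  for (i in tp$n:1) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$bw[[i]])) next
    for (ct in tp$bw[[i]](g)) {
      j <- ct[[1]]
      if (!tp$req[j]) next
      grads[[j]] <- if (is.null(grads[[j]])) ct[[2]] else grads[[j]] + ct[[2]]
    }
    grads[i] <- list(NULL)   # free as we go (keep list length stable)
  }
  grads
}

# ---- elementwise ops -------------------------------------------------------

ad_add <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  ad_node(tp, va + vb, req = ad_req(tp, a, b), bw = function(g)
    list(list(a, ad_fit_grad(g, va)), list(b, ad_fit_grad(g, vb))))
}

ad_sub <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  ad_node(tp, va - vb, req = ad_req(tp, a, b), bw = function(g)
    list(list(a, ad_fit_grad(g, va)), list(b, ad_fit_grad(-g, vb))))
}

ad_mul <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  ad_node(tp, va * vb, req = ad_req(tp, a, b), bw = function(g)
    list(list(a, ad_fit_grad(g * vb, va)), list(b, ad_fit_grad(g * va, vb))))
}

ad_div <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  ad_node(tp, va / vb, req = ad_req(tp, a, b), bw = function(g)
    list(list(a, ad_fit_grad(g / vb, va)),
         list(b, ad_fit_grad(-g * va / vb^2, vb))))
}

ad_scale <- function(tp, a, k) {
  force(a)
   # k plain numeric scalar
  va <- tp$val[[a]]
  ad_node(tp, va * k, req = ad_req(tp, a), bw = function(g) list(list(a, g * k)))
}

ad_shift <- function(tp, a, k) {
  force(a)
   # add plain numeric scalar
  ad_node(tp, tp$val[[a]] + k, req = ad_req(tp, a),
          bw = function(g) list(list(a, g)))
}

ad_exp <- function(tp, a) {
  force(a)

  v <- exp(tp$val[[a]])
  ad_node(tp, v, req = ad_req(tp, a), bw = function(g) list(list(a, g * v)))
}

ad_log <- function(tp, a) {
  force(a)

  va <- tp$val[[a]]
  ad_node(tp, log(va), req = ad_req(tp, a),
          bw = function(g) list(list(a, g / va)))
}

ad_pow_const <- function(tp, a, p) {
  force(a)

  va <- tp$val[[a]]
  ad_node(tp, va^p, req = ad_req(tp, a),
          bw = function(g) list(list(a, g * p * va^(p - 1))))
}

ad_clamp <- function(tp, a, lo, hi) {
  force(a)

  va <- tp$val[[a]]
  inside <- (va > lo) & (va < hi)
  ad_node(tp, pmin(hi, pmax(lo, va)), req = ad_req(tp, a),
          bw = function(g) list(list(a, g * inside)))
}

ad_sigmoid <- function(tp, a) {
  force(a)

  v <- 1 / (1 + exp(-tp$val[[a]]))
  ad_node(tp, v, req = ad_req(tp, a),
          bw = function(g) list(list(a, g * v * (1 - v))))
}

ad_lrelu <- function(tp, a, slope = 0.2) {
  force(a)

  va <- tp$val[[a]]
  fac <- (va > 0) + slope * (va <= 0)
  ad_node(tp, va * fac, req = ad_req(tp, a),
          bw = function(g) list(list(a, g * fac)))
}

ad_dropout <- function(tp, a, rate, training) {
  force(a)

  if (!training || rate <= 0)
    return(a)
  va <- tp$val[[a]]
  keep <- 1 - rate
  mask <- (array(stats::runif(length(va)), dim_of(va)) < keep) / keep
  ad_node(tp, va * mask, req = ad_req(tp, a),
          bw = function(g) list(list(a, g * mask)))
}

dim_of <- function(v) if (is.null(dim(v))) length(v) else dim(v)

# ---- reductions and shapes -------------------------------------------------

ad_sum <- function(tp, a) {
  force(a)

  va <- tp$val[[a]]
  ad_node(tp, sum(va), req = ad_req(tp, a), bw = function(g)
    list(list(a, array(g, dim_of(va)))))
}

ad_mean <- function(tp, a) {
  force(a)

  va <- tp$val[[a]]
  n <- length(va)
  ad_node(tp, sum(va) / n, req = ad_req(tp, a), bw = function(g)
    list(list(a, array(g / n, dim_of(va)))))
}

ad_reshape <- function(tp, a, newdim) {
  force(a)

  va <- tp$val[[a]]
  olddim <- dim_of(va)
  v <- va
  dim(v) <- newdim
  ad_node(tp, v, req = ad_req(tp, a), bw = function(g) {
    dim(g) <- olddim
    list(list(a, g))
  })
}

ad_slice_cols <- function(tp, a, cols) {
  force(a)

  va <- tp$val[[a]]
  ad_node(tp, va[, cols, drop = FALSE], req = ad_req(tp, a), bw = function(g) {
    ga <- array(0, dim(va))
    ga[, cols] <- g
    list(list(a, ga))
  })
}

ad_concat_cols <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  pa <- ncol(va)
  ad_node(tp, cbind(va, vb), req = ad_req(tp, a, b), bw = function(g)
    list(list(a, g[, seq_len(pa), drop = FALSE]),
         list(b, g[, -seq_len(pa), drop = FALSE])))
}

# ---- linear algebra --------------------------------------------------------

ad_matmul <- function(tp, a, b) {
  force(a)
  force(b)

  va <- tp$val[[a]]; vb <- tp$val[[b]]
  ad_node(tp, va %*% vb, req = ad_req(tp, a, b), bw = function(g)
    list(list(a, g %*% t(vb)), list(b, crossprod(va, g))))
}

ad_addbias <- function(tp, a, b) {
  force(a)
  force(b)
   # a [n, q] + bias [q]
  va <- tp$val[[a]]; vb <- tp$val[[b]]
  n <- nrow(va)
  ad_node(tp, va + rep(vb, each = n), req = ad_req(tp, a, b), bw = function(g)
    list(list(a, g), list(b, colSums(g))))
}

# ---- image ops on [N, H, W, C] arrays --------------------------------------

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2, d[3] + 2, d[4]))
  xp[, 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  xp
}

conv3x3_fwd <- function(x, w, b) {
  d <- dim(x); n <- d[1]; h <- d[2]; wd <- d[3]; ci <- d[4]
  co <- dim(w)[4]
  patches <- im2col3x3(x)
  ymat <- patches %*% matrix(w, 9 * ci, co) +
    rep(b, each = n * h * wd)
  dim(ymat) <- c(n, h, wd, co)
  list(y = ymat, patches = patches)
}

# Patch matrix [N*H*W, 9*Cin] of the 3x3 neighbourhoods (zero padded),
# ordered to match the [3, 3, Cin, Cout] weight layout.
im2col3x3 <- function(x) {
  d <- dim(x); n <- d[1]; h <- d[2]; wd <- d[3]; ci <- d[4]
  xp <- pad_hw(x)
  patches <- matrix(0, n * h * wd, 9 * ci)
  for (cc in seq_len(ci)) for (dx in 0:2) for (dy in 0:2) {
    xs <- xp[, dy + seq_len(h), dx + seq_len(wd), cc, drop = FALSE]
    patches[, dy + 1 + 3 * dx + 9 * (cc - 1)] <- xs
  }
  patches
}

# 180-degree kernel flip with channel transpose: the gradient of a
# stride-1/pad-1 convolution w.r.t. its input is a convolution of the
# output adjoint with this kernel.
flip_kernel <- function(w) {
  aperm(w[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
}

# 3x3 convolution, stride 1, zero padding 1. w: [3, 3, Cin, Cout], b: [Cout].
ad_conv3x3 <- function(tp, x, w, b) {
  force(x)
  force(w)
  force(b)
  vx <- tp$val[[x]]; vw <- tp$val[[w]]; vb <- tp$val[[b]]
  d <- dim(vx); n <- d[1]; h <- d[2]; wd <- d[3]; ci <- d[4]
  co <- dim(vw)[4]
  fw <- conv3x3_fwd(vx, vw, vb)
  patches <- fw$patches
  ad_node(tp, fw$y, req = ad_req(tp, x, w, b), bw = function(g) {
    gmat <- g
    dim(gmat) <- c(n * h * wd, co)
    dw <- crossprod(patches, gmat)
    dim(dw) <- dim(vw)
    gx <- conv3x3_fwd(g, flip_kernel(vw), numeric(ci))$y
    list(list(x, gx), list(w, dw), list(b, colSums(gmat)))
  })
}

# 2x2 max pooling (H, W even), ties routed to the first maximal position.
ad_maxpool2 <- function(tp, x) {
  force(x)

  vx <- tp$val[[x]]
  d <- dim(vx); n <- d[1]; h <- d[2]; wd <- d[3]; c_ <- d[4]
  io <- seq(1, h, 2); jo <- seq(1, wd, 2)
  a <- vx[, io, jo, , drop = FALSE]
  b <- vx[, io + 1, jo, , drop = FALSE]
  cc <- vx[, io, jo + 1, , drop = FALSE]
  dd <- vx[, io + 1, jo + 1, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  wa <- (a == y)
  wb <- (b == y) & !wa
  wc <- (cc == y) & !wa & !wb
  wd_ <- (dd == y) & !wa & !wb & !wc
  ad_node(tp, y, req = ad_req(tp, x), bw = function(g) {
    gx <- array(0, d)
    gx[, io, jo, ] <- g * wa
    gx[, io + 1, jo, ] <- g * wb
    gx[, io, jo + 1, ] <- g * wc
    gx[, io + 1, jo + 1, ] <- g * wd_
    list(list(x, gx))
  })
}

ad_avgpool2 <- function(tp, x) {
  force(x)

  vx <- tp$val[[x]]
  d <- dim(vx); h <- d[2]; wd <- d[3]
  io <- seq(1, h, 2); jo <- seq(1, wd, 2)
  y <- (vx[, io, jo, , drop = FALSE] + vx[, io + 1, jo, , drop = FALSE] +
        vx[, io, jo + 1, , drop = FALSE] +
        vx[, io + 1, jo + 1, , drop = FALSE]) / 4
  ad_node(tp, y, req = ad_req(tp, x), bw = function(g) {
    gx <- array(0, d)
    g4 <- g / 4
    gx[, io, jo, ] <- g4; gx[, io + 1, jo, ] <- g4
    gx[, io, jo + 1, ] <- g4; gx[, io + 1, jo + 1, ] <- g4
    list(list(x, gx))
  })
}

# Nearest-neighbour 2x unpooling: each pixel fills its 2x2 neighbourhood.
ad_upnn2 <- function(tp, x) {
  force(x)

  vx <- tp$val[[x]]
  d <- dim(vx); h <- d[2]; wd <- d[3]
  y <- vx[, rep(seq_len(h), each = 2), rep(seq_len(wd), each = 2), ,
          drop = FALSE]
  io <- seq(1, 2 * h, 2); jo <- seq(1, 2 * wd, 2)
  ad_node(tp, y, req = ad_req(tp, x), bw = function(g) {
    gx <- g[, io, jo, , drop = FALSE] + g[, io + 1, jo, , drop = FALSE] +
      g[, io, jo + 1, , drop = FALSE] + g[, io + 1, jo + 1, , drop = FALSE]
    list(list(x, gx))
  })
}

# Batch normalization over (N, H, W) per channel. state: environment with
# running_mean/running_var per layer name; updated in training mode.
ad_batchnorm <- function(tp, x, gamma, beta, state, name, training,
                         momentum = 0.1, eps = 1e-5) {
  force(x)
  force(gamma)
  force(beta)

  vx <- tp$val[[x]]; vg <- tp$val[[gamma]]; vbt <- tp$val[[beta]]
  d <- dim(vx)
  c_ <- d[4]; m <- prod(d[1:3])
  xm <- vx
  dim(xm) <- c(m, c_)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    rm <- state$running_mean[[name]]
    rv <- state$running_var[[name]]
    if (is.null(rm)) { rm <- numeric(c_); rv <- rep(1, c_) }
    state$running_mean[[name]] <- (1 - momentum) * rm + momentum * mu
    state$running_var[[name]] <- (1 - momentum) * rv +
      momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$running_mean[[name]]
    va <- state$running_var[[name]]
    if (is.null(mu)) { mu <- numeric(c_); va <- rep(1, c_) }
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(istd, each = m)
  y <- xhat * rep(vg, each = m) + rep(vbt, each = m)
  dim(y) <- d
  ad_node(tp, y, req = ad_req(tp, x, gamma, beta), bw = function(g) {
    gm <- g
    dim(gm) <- c(m, c_)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(vg, each = m)
    if (training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(s1 / m, each = m) -
               xhat * rep(s2 / m, each = m)) * rep(istd, each = m)
    } else {
      dx <- dxhat * rep(istd, each = m)
    }
    dim(dx) <- d
    list(list(x, dx), list(gamma, dgamma), list(beta, dbeta))
  })
}

# Separable blur along H and W with a fixed 1-D kernel (zero padding),
# realised as banded-matrix products B_h X B_w' per image. The band
# matrices are cached per (size, kernel); the Gaussian kernel is symmetric
# so the backward pass uses the transposed bands.
.blur_cache <- new.env(parent = emptyenv())

blur_band_matrix <- function(n, k) {
  key <- paste0(n, ":", paste(signif(k, 8), collapse = ","))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(k) - 1) / 2
  m <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    src <- idx + o
    ok <- src >= 1 & src <= n
    m[cbind(idx[ok], src[ok])] <- k[o + r + 1]
  }
  .blur_cache[[key]] <- m
  m
}

blur_apply <- function(x, bh, bwt) {
  d <- dim(x)
  out <- array(0, d)
  for (n in seq_len(d[1])) for (cc in seq_len(d[4]))
    out[n, , , cc] <- bh %*% x[n, , , cc] %*% bwt   # bwt pre-transposed
  out
}

ad_blur <- function(tp, x, kernel) {
  force(x)
  vx <- tp$val[[x]]
  d <- dim(vx)
  bh <- blur_band_matrix(d[2], kernel)
  bwt <- t(blur_band_matrix(d[3], kernel))
  ad_node(tp, blur_apply(vx, bh, bwt), req = ad_req(tp, x), bw = function(g)
    list(list(x, blur_apply(g, t(bh), t(bwt)))))
}
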