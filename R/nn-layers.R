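#' Minimal neural-network layer library
#'
#' Hand-written forward/backward passes for the small set of 1-D layers the
#' two architectures need: (separable) convolutions with dilation and 'same'
#' padding, batch/layer normalization, dense layers, max/global-average
#' pooling, squeeze-and-excitation gating, attention pooling, dropout and
#' Gaussian-noise augmentation. Tensors are base-R arrays of shape
#' `[batch, time, channels]`; convolutions reduce to one GEMM per kernel
#' tap, so BLAS does the heavy lifting. All randomness (init, dropout,
#' noise) goes through R's RNG for bit-reproducible CPU training.
#'
#' @name nn_layers
#' @noRd
NULL

new_layer <- function(type, par = list(), fields = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$gr <- lapply(par, function(p) p * 0)  # preserves vector/matrix shape
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  e
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

zero_grads <- function(layers) {
  for (l in layers)
    for (n in names(l$gr)) l$gr[[n]][] <- 0
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, 0L)), 0))
}

# ---- convolution ----------------------------------------------------------

layer_conv1d <- function(cin, cout, k, dilation = 1L) {
  par <- list(b = numeric(cout))
  for (j in seq_len(k)) par[[paste0("W", j)]] <- glorot(cin * k, cout, c(cin, cout))
  l <- new_layer("conv1d", par,
                 list(cin = cin, cout = cout, k = k, dil = as.integer(dilation)))
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); B <- d[1]; Tt <- d[2]
    span <- (l$k - 1L) * l$dil
    pl <- span %/% 2L
    xp <- array(0, c(B, Tt + span, l$cin))
    xp[, pl + seq_len(Tt), ] <- x
    l$cache <- list(xp = xp, B = B, Tt = Tt, pl = pl)
    y <- matrix(l$par$b, B * Tt, l$cout, byrow = TRUE)
    for (j in seq_len(l$k)) {
      xs <- xp[, (j - 1L) * l$dil + seq_len(Tt), , drop = FALSE]
      dim(xs) <- c(B * Tt, l$cin)
      y <- y + xs %*% l$par[[paste0("W", j)]]
    }
    dim(y) <- c(B, Tt, l$cout)
    y
  }
  l$bwd <- function(dy) {
    ca <- l$cache; B <- ca$B; Tt <- ca$Tt
    dim(dy) <- c(B * Tt, l$cout)
    dxp <- array(0, dim(ca$xp))
    for (j in seq_len(l$k)) {
      sel <- (j - 1L) * l$dil + seq_len(Tt)
      xs <- ca$xp[, sel, , drop = FALSE]
      dim(xs) <- c(B * Tt, l$cin)
      l$gr[[paste0("W", j)]] <- l$gr[[paste0("W", j)]] + crossprod(xs, dy)
      dxs <- dy %*% t(l$par[[paste0("W", j)]])
      dim(dxs) <- c(B, Tt, l$cin)
      dxp[, sel, ] <- dxp[, sel, ] + dxs
    }
    l$gr$b <- l$gr$b + colSums(dy)
    dx <- dxp[, ca$pl + seq_len(Tt), , drop = FALSE]
    dx
  }
  l
}

# depthwise (one temporal filter per input channel) + pointwise 1x1
layer_sepconv1d <- function(cin, cout, k, dilation = 1L) {
  par <- list(Wd = glorot(k, k, c(k, cin)),
              Wp = glorot(cin, cout, c(cin, cout)),
              b = numeric(cout))
  l <- new_layer("sepconv1d", par,
                 list(cin = cin, cout = cout, k = k, dil = as.integer(dilation)))
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); B <- d[1]; Tt <- d[2]
    span <- (l$k - 1L) * l$dil
    pl <- span %/% 2L
    xp <- array(0, c(B, Tt + span, l$cin))
    xp[, pl + seq_len(Tt), ] <- x
    h <- array(0, c(B, Tt, l$cin))
    for (j in seq_len(l$k)) {
      xs <- xp[, (j - 1L) * l$dil + seq_len(Tt), , drop = FALSE]
      h <- h + sweep(xs, 3, l$par$Wd[j, ], "*")
    }
    l$cache <- list(xp = xp, h = h, B = B, Tt = Tt, pl = pl)
    hm <- h; dim(hm) <- c(B * Tt, l$cin)
    y <- hm %*% l$par$Wp
    y <- sweep(y, 2, l$par$b, "+")
    dim(y) <- c(B, Tt, l$cout)
    y
  }
  l$bwd <- function(dy) {
    ca <- l$cache; B <- ca$B; Tt <- ca$Tt
    dim(dy) <- c(B * Tt, l$cout)
    hm <- ca$h; dim(hm) <- c(B * Tt, l$cin)
    l$gr$Wp <- l$gr$Wp + crossprod(hm, dy)
    l$gr$b <- l$gr$b + colSums(dy)
    dh <- dy %*% t(l$par$Wp)
    dim(dh) <- c(B, Tt, l$cin)
    dxp <- array(0, dim(ca$xp))
    for (j in seq_len(l$k)) {
      sel <- (j - 1L) * l$dil + seq_len(Tt)
      xs <- ca$xp[, sel, , drop = FALSE]
      l$gr$Wd[j, ] <- l$gr$Wd[j, ] + colSums(matrix(xs * dh, ncol = l$cin))
      dxp[, sel, ] <- dxp[, sel, ] + sweep(dh, 3, l$par$Wd[j, ], "*")
    }
    dxp[, ca$pl + seq_len(Tt), , drop = FALSE]
  }
  l
}

# ---- normalization --------------------------------------------------------

layer_batchnorm <- function(c, momentum = 0.99, eps = 1e-3) {
  l <- new_layer("batchnorm",
                 list(gamma = rep(1, c), beta = numeric(c)),
                 list(c = c, momentum = momentum, eps = eps,
                      run_mean = numeric(c), run_var = numeric(c),
                      run_n = 0L))
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); B <- d[1]; Tt <- d[2]
    xm <- x; dim(xm) <- c(B * Tt, l$c)
    if (train) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu, "-")
      va <- colMeans(xc^2)
      # bias-corrected EMA: equals the plain batch average for the first
      # few steps, converges to the usual momentum EMA afterwards
      l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
      l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * va
      l$run_n <- l$run_n + 1L
    } else {
      corr <- if (l$run_n > 0L) 1 - l$momentum^l$run_n else 1
      mu <- if (l$run_n > 0L) l$run_mean / corr else numeric(l$c)
      va <- if (l$run_n > 0L) l$run_var / corr else rep(1, l$c)
      xc <- sweep(xm, 2, mu, "-")
    }
    istd <- 1 / sqrt(va + l$eps)
    xn <- sweep(xc, 2, istd, "*")
    l$cache <- list(xn = xn, istd = istd, B = B, Tt = Tt, train = train)
    y <- sweep(sweep(xn, 2, l$par$gamma, "*"), 2, l$par$beta, "+")
    dim(y) <- c(B, Tt, l$c)
    y
  }
  l$bwd <- function(dy) {
    ca <- l$cache; n <- ca$B * ca$Tt
    dim(dy) <- c(n, l$c)
    l$gr$gamma <- l$gr$gamma + colSums(dy * ca$xn)
    l$gr$beta <- l$gr$beta + colSums(dy)
    dxn <- sweep(dy, 2, l$par$gamma, "*")
    if (ca$train) {
      dx <- sweep(dxn - matrix(colMeans(dxn), n, l$c, byrow = TRUE) -
                    sweep(ca$xn, 2, colMeans(dxn * ca$xn), "*"),
                  2, ca$istd, "*")
    } else {
      dx <- sweep(dxn, 2, ca$istd, "*")
    }
    dim(dx) <- c(ca$B, ca$Tt, l$c)
    dx
  }
  l
}

layer_layernorm <- function(f, eps = 1e-3) {
  l <- new_layer("layernorm",
                 list(gamma = rep(1, f), beta = numeric(f)),
                 list(f = f, eps = eps))
  l$fwd <- function(x, train = FALSE) {
    mu <- rowMeans(x)
    xc <- x - mu
    va <- rowMeans(xc^2)
    istd <- 1 / sqrt(va + l$eps)
    xn <- xc * istd
    l$cache <- list(xn = xn, istd = istd)
    sweep(sweep(xn, 2, l$par$gamma, "*"), 2, l$par$beta, "+")
  }
  l$bwd <- function(dy) {
    ca <- l$cache
    l$gr$gamma <- l$gr$gamma + colSums(dy * ca$xn)
    l$gr$beta <- l$gr$beta + colSums(dy)
    dxn <- sweep(dy, 2, l$par$gamma, "*")
    (dxn - rowMeans(dxn) - ca$xn * rowMeans(dxn * ca$xn)) * ca$istd
  }
  l
}

# ---- dense / activations --------------------------------------------------

layer_dense <- function(fin, fout) {
  l <- new_layer("dense",
                 list(W = glorot(fin, fout, c(fin, fout)), b = numeric(fout)),
                 list(fin = fin, fout = fout))
  l$fwd <- function(x, train = FALSE) {
    l$cache <- x
    sweep(x %*% l$par$W, 2, l$par$b, "+")
  }
  l$bwd <- function(dy) {
    l$gr$W <- l$gr$W + crossprod(l$cache, dy)
    l$gr$b <- l$gr$b + colSums(dy)
    dy %*% t(l$par$W)
  }
  l
}

layer_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, train = FALSE) { l$cache <- x > 0; x * l$cache }
  l$bwd <- function(dy) dy * l$cache
  l
}

layer_tanh <- function() {
  l <- new_layer("tanh")
  l$fwd <- function(x, train = FALSE) { l$cache <- tanh(x); l$cache }
  l$bwd <- function(dy) dy * (1 - l$cache^2)
  l
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- pooling --------------------------------------------------------------

layer_maxpool2 <- function() {
  l <- new_layer("maxpool2")
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); Th <- d[2] %/% 2L
    a <- x[, 2 * seq_len(Th) - 1L, , drop = FALSE]
    b <- x[, 2 * seq_len(Th), , drop = FALSE]
    l$cache <- list(first = a >= b, d = d, Th = Th)
    pmax(a, b)
  }
  l$bwd <- function(dy) {
    ca <- l$cache
    dx <- array(0, ca$d)
    dx[, 2 * seq_len(ca$Th) - 1L, ] <- dy * ca$first
    dx[, 2 * seq_len(ca$Th), ] <- dy * !ca$first
    dx
  }
  l
}

layer_gap <- function() {
  l <- new_layer("gap")
  l$fwd <- function(x, train = FALSE) {
    l$cache <- dim(x)
    apply(x, c(1, 3), mean)
  }
  l$bwd <- function(dy) {
    d <- l$cache
    # broadcast gradient equally over time
    aperm(array(dy / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  l
}

# ---- squeeze-and-excitation ----------------------------------------------

layer_se <- function(c, bottleneck = max(c %/% 8L, 8L)) {
  l <- new_layer("se",
                 list(W1 = glorot(c, bottleneck, c(c, bottleneck)),
                      b1 = numeric(bottleneck),
                      W2 = glorot(bottleneck, c, c(bottleneck, c)),
                      b2 = numeric(c)),
                 list(c = c, r = bottleneck))
  l$fwd <- function(x, train = FALSE) {
    z <- apply(x, c(1, 3), mean)                      # [B, C]
    h <- pmax(sweep(z %*% l$par$W1, 2, l$par$b1, "+"), 0)
    g <- sigmoid(sweep(h %*% l$par$W2, 2, l$par$b2, "+"))
    l$cache <- list(x = x, z = z, h = h, g = g, Tt = dim(x)[2])
    x * aperm(array(g, c(dim(x)[1], dim(x)[3], dim(x)[2])), c(1, 3, 2))
  }
  l$bwd <- function(dy) {
    ca <- l$cache
    gB <- aperm(array(ca$g, c(dim(dy)[1], dim(dy)[3], dim(dy)[2])), c(1, 3, 2))
    dx <- dy * gB
    dg <- apply(dy * ca$x, c(1, 3), sum)              # [B, C]
    dpre2 <- dg * ca$g * (1 - ca$g)
    l$gr$W2 <- l$gr$W2 + crossprod(ca$h, dpre2)
    l$gr$b2 <- l$gr$b2 + colSums(dpre2)
    dh <- (dpre2 %*% t(l$par$W2)) * (ca$h > 0)
    l$gr$W1 <- l$gr$W1 + crossprod(ca$z, dh)
    l$gr$b1 <- l$gr$b1 + colSums(dh)
    dz <- dh %*% t(l$par$W1)
    dx + aperm(array(dz / ca$Tt, c(dim(dy)[1], dim(dy)[3], dim(dy)[2])),
               c(1, 3, 2))
  }
  l
}

# ---- attention pooling ----------------------------------------------------

layer_attention_pool <- function(c, units = 64L) {
  l <- new_layer("attention_pool",
                 list(W1 = glorot(c, units, c(c, units)), b1 = numeric(units),
                      W2 = glorot(units, 1, c(units, 1)), b2 = numeric(1)),
                 list(c = c, units = units))
  l$fwd <- function(x, train = FALSE) {
    d <- dim(x); B <- d[1]; Tt <- d[2]
    xm <- x; dim(xm) <- c(B * Tt, l$c)
    a <- tanh(sweep(xm %*% l$par$W1, 2, l$par$b1, "+"))
    s <- matrix(a %*% l$par$W2 + l$par$b2, B, Tt)
    s <- s - apply(s, 1, max)
    w <- exp(s); w <- w / rowSums(w)                  # [B, T]
    wB <- array(w, c(B, Tt, l$c))
    y <- apply(x * wB, c(1, 3), sum)                  # [B, C]
    l$cache <- list(x = x, xm = xm, a = a, w = w, B = B, Tt = Tt)
    y
  }
  l$bwd <- function(dy) {
    ca <- l$cache; B <- ca$B; Tt <- ca$Tt
    wB <- array(ca$w, c(B, Tt, l$c))
    dyB <- aperm(array(dy, c(B, l$c, Tt)), c(1, 3, 2))
    dx <- dyB * wB
    dw <- apply(dyB * ca$x, c(1, 2), sum)             # [B, T]
    ds <- ca$w * (dw - rowSums(ca$w * dw))            # softmax backward
    dsv <- matrix(as.vector(ds), B * Tt, 1)
    l$gr$W2 <- l$gr$W2 + crossprod(ca$a, dsv)
    l$gr$b2 <- l$gr$b2 + sum(dsv)
    da <- (dsv %*% t(l$par$W2)) * (1 - ca$a^2)
    l$gr$W1 <- l$gr$W1 + crossprod(ca$xm, da)
    l$gr$b1 <- l$gr$b1 + colSums(da)
    dxm <- da %*% t(l$par$W1)
    dim(dxm) <- c(B, Tt, l$c)
    dx + dxm
  }
  l
}

#' Attention pooling of a feature-frame matrix
#'
#' Softmax-weighted temporal average: the scoring head produces one score
#' per time step, weights are the softmax of the scores over time, and the
#' output is the weighted sum of the frames. Exposed as a plain function for
#' testing the pooling contract (weights non-negative and summing to 1).
#'
#' @param features `T x F` matrix of feature frames.
#' @param score_params list with `W1` (F x A), `b1`, `W2` (A x 1), `b2`.
#' @return list with `output` (length-F vector) and `weights` (length T).
#' @export
attention_pool <- function(features, score_params) {
  a <- tanh(sweep(features %*% score_params$W1, 2, score_params$b1, "+"))
  s <- drop(a %*% score_params$W2 + score_params$b2)
  s <- s - max(s)
  w <- exp(s) / sum(exp(s))
  list(output = drop(crossprod(features, w)), weights = w)
}

# ---- stochastic layers ----------------------------------------------------

layer_dropout <- function(p) {
  l <- new_layer("dropout", fields = list(p = p))
  l$fwd <- function(x, train = FALSE) {
    if (!train || l$p <= 0) { l$cache <- NULL; return(x) }
    mask <- array(stats::runif(length(x)) >= l$p, dim(x) %||% length(x))
    l$cache <- mask / (1 - l$p)
    x * l$cache
  }
  l$bwd <- function(dy) if (is.null(l$cache)) dy else dy * l$cache
  l
}

# drops whole feature channels of a [B, T, C] tensor
layer_spatial_dropout <- function(p) {
  l <- new_layer("spatial_dropout", fields = list(p = p))
  l$fwd <- function(x, train = FALSE) {
    if (!train || l$p <= 0) { l$cache <- NULL; return(x) }
    d <- dim(x)
    keep <- matrix(stats::runif(d[1] * d[3]) >= l$p, d[1], d[3])
    mask <- aperm(array(keep, c(d[1], d[3], d[2])), c(1, 3, 2)) / (1 - l$p)
    l$cache <- mask
    x * mask
  }
  l$bwd <- function(dy) if (is.null(l$cache)) dy else dy * l$cache
  l
}

layer_gaussian_noise <- function(std) {
  l <- new_layer("gaussian_noise", fields = list(std = std))
  l$fwd <- function(x, train = FALSE) {
    if (!train || l$std <= 0) return(x)
    x + array(stats::rnorm(length(x), sd = l$std), dim(x) %||% length(x))
  }
  l$bwd <- function(dy) dy
  l
}

# ---- sequential helper ----------------------------------------------------

seq_forward <- function(layers, x, train = FALSE) {
  for (l in layers) x <- l$fwd(x, train)
  x
}

seq_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}
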