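# Minimal neural-network engine.
#
# Tensors are numeric arrays dim (H, W, C, B). Each layer is an
# environment exposing fw(x, train) / bw(dy); forward calls push their
# cache on an internal stack and backward calls pop it, so a layer may
# be applied several times per step (the modality encoder is) as long
# as backward passes run in reverse order. Parameter gradients
# accumulate until `zero_grads()`.

as4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

new_rng_init <- function(seed) local_rng(seed)

conv_layer <- function(cin, cout, rng, k = 3L) {
  e <- new.env(parent = emptyenv())
  sd <- sqrt(2 / (k * k * cin))
  e$W <- array(rng$rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout))
  e$b <- numeric(cout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e$param_names <- c("W", "b")
  e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    x <- as4(x)
    e$cache[[length(e$cache) + 1L]] <- x
    conv2d_fw_cpp(x, e$W, e$b, dim(x))
  }
  e$bw <- function(dy) {
    x <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    g <- conv2d_bw_cpp(x, e$W, as4(dy), dim(x))
    e$gW <- e$gW + g$dw; e$gb <- e$gb + g$db
    g$dx
  }
  e
}

lrelu_layer <- function(alpha = 0.1) {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    m <- x < 0
    e$cache[[length(e$cache) + 1L]] <- m
    x[m] <- alpha * x[m]
    x
  }
  e$bw <- function(dy) {
    m <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    dy[m] <- alpha * dy[m]
    dy
  }
  e
}

pool_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    x <- as4(x)
    r <- maxpool2_fw_cpp(x, dim(x))
    e$cache[[length(e$cache) + 1L]] <- list(am = r$argmax, d = dim(x))
    r$y
  }
  e$bw <- function(dy) {
    cc <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    maxpool2_bw_cpp(as.numeric(dy), cc$am, cc$d)
  }
  e
}

upsample_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    x <- as4(x)
    e$cache[[length(e$cache) + 1L]] <- dim(x)
    upsample2_fw_cpp(x, dim(x))
  }
  e$bw <- function(dy) {
    d <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    upsample2_bw_cpp(as4(dy), d)
  }
  e
}

bn_layer <- function(c, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$gamma <- rep(1, c); e$beta <- rep(0, c)
  e$ggamma <- numeric(c); e$gbeta <- numeric(c)
  e$rmean <- numeric(c); e$rvar <- rep(1, c)
  e$param_names <- c("gamma", "beta")
  e$cache <- list()
  chan_stat <- function(x) {
    d <- dim(x)
    m <- matrix(x, d[1] * d[2], d[3] * d[4])
    rowMeans(matrix(colMeans(m), d[3], d[4]))
  }
  e$fw <- function(x, train = FALSE) {
    x <- as4(x); d <- dim(x)
    nper <- d[1] * d[2] * d[4]
    if (train) {
      mu <- chan_stat(x)
      xc <- x - expand_c(mu, d)
      va <- chan_stat(xc * xc)
      e$rmean <- (1 - momentum) * e$rmean + momentum * mu
      e$rvar <- (1 - momentum) * e$rvar + momentum * va * nper / max(1, nper - 1)
    } else {
      mu <- e$rmean; va <- e$rvar
      xc <- x - expand_c(mu, d)
    }
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * expand_c(istd, d)
    e$cache[[length(e$cache) + 1L]] <- list(xhat = xhat, istd = istd,
                                            d = d, train = train)
    xhat * expand_c(e$gamma, d) + expand_c(e$beta, d)
  }
  e$bw <- function(dy) {
    cc <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    d <- cc$d
    dy <- as4(dy)
    sum_c <- function(x) {
      m <- matrix(x, d[1] * d[2], d[3] * d[4])
      rowSums(matrix(colSums(m), d[3], d[4]))
    }
    e$ggamma <- e$ggamma + sum_c(dy * cc$xhat)
    e$gbeta <- e$gbeta + sum_c(dy)
    dxhat <- dy * expand_c(e$gamma, d)
    if (!cc$train) return(dxhat * expand_c(cc$istd, d))
    nper <- d[1] * d[2] * d[4]
    t1 <- sum_c(dxhat) / nper
    t2 <- sum_c(dxhat * cc$xhat) / nper
    (dxhat - expand_c(t1, d) - cc$xhat * expand_c(t2, d)) *
      expand_c(cc$istd, d)
  }
  e
}

# broadcast a per-channel vector over an (H,W,C,B) shape
expand_c <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), d[4]), d)
}

softmax_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    x <- as4(x); d <- dim(x)
    m <- matrix(aperm(x, c(3, 1, 2, 4)), d[3])
    mx <- m[1, ]
    if (d[3] > 1) for (c in 2:d[3]) mx <- pmax(mx, m[c, ])
    m <- exp(sweep(m, 2, mx))
    m <- sweep(m, 2, colSums(m), "/")
    y <- aperm(array(m, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
    e$cache[[length(e$cache) + 1L]] <- y
    y
  }
  e$bw <- function(dy) {
    y <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    d <- dim(y)
    hw <- d[1] * d[2]
    pr <- array(dy * y, c(hw, d[3], d[4]))
    s <- array(0, c(hw, d[3], d[4]))
    for (b in seq_len(d[4])) {
      dot <- rowSums(pr[, , b, drop = FALSE], dims = 1)   # per-pixel <dy, y>
      s[, , b] <- matrix(dot, hw, d[3])
    }
    dim(s) <- d
    y * (as4(dy) - s)
  }
  e
}

dense_layer <- function(nin, nout, rng) {
  e <- new.env(parent = emptyenv())
  e$W <- matrix(rng$rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  e$b <- numeric(nout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e$param_names <- c("W", "b")
  e$cache <- list()
  e$fw <- function(x, train = FALSE) {       # x: (B x nin)
    e$cache[[length(e$cache) + 1L]] <- x
    sweep(x %*% e$W, 2, e$b, "+")
  }
  e$bw <- function(dy) {
    x <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    e$gW <- e$gW + crossprod(x, dy)
    e$gb <- e$gb + colSums(dy)
    dy %*% t(e$W)
  }
  e
}

lrelu_vec_layer <- function(alpha = 0.1) {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    m <- x < 0
    e$cache[[length(e$cache) + 1L]] <- m
    x[m] <- alpha * x[m]
    x
  }
  e$bw <- function(dy) {
    m <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    dy[m] <- alpha * dy[m]
    dy
  }
  e
}

flatten_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0); e$cache <- list()
  e$fw <- function(x, train = FALSE) {
    x <- as4(x); d <- dim(x)
    e$cache[[length(e$cache) + 1L]] <- d
    t(matrix(x, d[1] * d[2] * d[3], d[4]))
  }
  e$bw <- function(dy) {
    d <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    array(t(dy), d)
  }
  e
}

# feature-wise linear modulation: y = (1 + z Wg + bg) * x + (z Wb + bb)
film_layer <- function(c, zdim, rng) {
  e <- new.env(parent = emptyenv())
  sd <- sqrt(1 / zdim)
  e$Wg <- matrix(rng$rnorm(zdim * c, sd = sd), zdim, c)
  e$Wb <- matrix(rng$rnorm(zdim * c, sd = sd), zdim, c)
  e$bg <- numeric(c); e$bb <- numeric(c)
  e$gWg <- e$Wg * 0; e$gWb <- e$Wb * 0
  e$gbg <- numeric(c); e$gbb <- numeric(c)
  e$param_names <- c("Wg", "Wb", "bg", "bb")
  e$cache <- list()
  e$fw <- function(x, z, train = FALSE) {    # z: (B x zdim)
    x <- as4(x); d <- dim(x)
    gam <- 1 + sweep(z %*% e$Wg, 2, e$bg, "+")   # (B x c)
    bet <- sweep(z %*% e$Wb, 2, e$bb, "+")
    e$cache[[length(e$cache) + 1L]] <- list(x = x, z = z, gam = gam, d = d)
    x * expand_bc(gam, d) + expand_bc(bet, d)
  }
  e$bw <- function(dy) {
    cc <- e$cache[[length(e$cache)]]
    e$cache[[length(e$cache)]] <- NULL
    d <- cc$d
    dy <- as4(dy)
    dgam <- bc_sum(dy * cc$x, d)               # (B x c)
    dbet <- bc_sum(dy, d)
    e$gWg <- e$gWg + crossprod(cc$z, dgam)
    e$gWb <- e$gWb + crossprod(cc$z, dbet)
    e$gbg <- e$gbg + colSums(dgam)
    e$gbb <- e$gbb + colSums(dbet)
    dz <- dgam %*% t(e$Wg) + dbet %*% t(e$Wb)
    list(dx = dy * expand_bc(cc$gam, d), dz = dz)
  }
  e
}

# broadcast a (B x C) matrix over (H,W,C,B)
expand_bc <- function(m, d) {
  array(rep(t(m), each = d[1] * d[2]), d)
}
bc_sum <- function(x, d) {
  t(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

collect_layers <- function(x) {
  if (is.environment(x)) return(list(x))
  unlist(lapply(x, collect_layers), recursive = FALSE)
}

zero_grads <- function(layers) {
  for (l in layers) for (p in l$param_names)
    l[[paste0("g", p)]] <- l[[paste0("g", p)]] * 0
  invisible(NULL)
}

clear_caches <- function(layers) {
  for (l in layers) l$cache <- list()
  invisible(NULL)
}

adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1L) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (l in layers) for (p in l$param_names) {
    g <- l[[paste0("g", p)]]
    mk <- paste0("adam_m_", p); vk <- paste0("adam_v_", p)
    if (is.null(l[[mk]])) { l[[mk]] <- g * 0; l[[vk]] <- g * 0 }
    l[[mk]] <- beta1 * l[[mk]] + (1 - beta1) * g
    l[[vk]] <- beta2 * l[[vk]] + (1 - beta2) * g * g
    l[[p]] <- l[[p]] - lr * (l[[mk]] / b1t) / (sqrt(l[[vk]] / b2t) + eps)
  }
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(layers, function(l)
    sum(vapply(l$param_names, function(p) length(l[[p]]), 0)), 0))
}
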