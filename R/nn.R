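# Minimal layer-graph neural network engine.
#
# Tensors are 4-D arrays (H, W, C, N); fully connected stages operate on
# (N, D) matrices. Convolution is im2col + BLAS matrix multiply. Every layer
# has a backward pass; composite layers (sequential, parallel-concat,
# parallel-add) recurse, so residual and inception-style graphs train with the
# same machinery. Gradients are returned as flat named lists keyed by the
# layer path, matching nn_collect_params() / nn_set_params().

nn_module <- function(type, params = list(), children = NULL,
                      hyper = list()) {
  structure(list(type = type, params = params, children = children,
                 hyper = hyper),
            class = "nn_module")
}

nn_conv <- function(in_ch, out_ch, kh, kw = kh, stride = 1, pad = 0,
                    bias = TRUE) {
  if (length(stride) == 1) stride <- c(stride, stride)
  if (length(pad) == 1) pad <- rep(pad, 4)          # top, bottom, left, right
  if (length(pad) == 2) pad <- c(pad[1], pad[1], pad[2], pad[2])
  K <- kh * kw * in_ch
  params <- list(W = matrix(stats::rnorm(K * out_ch, sd = sqrt(2 / K)),
                            K, out_ch))
  if (bias) params$b <- numeric(out_ch)
  nn_module("conv", params,
            hyper = list(in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw,
                         stride = stride, pad = pad))
}

nn_dense <- function(in_dim, out_dim, sd = sqrt(2 / in_dim)) {
  nn_module("dense",
            list(W = matrix(stats::rnorm(in_dim * out_dim, sd = sd),
                            in_dim, out_dim),
                 b = numeric(out_dim)),
            hyper = list(in_dim = in_dim, out_dim = out_dim))
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  nn_module("bn", list(gamma = rep(1, ch), beta = numeric(ch)),
            hyper = list(ch = ch, eps = eps, momentum = momentum,
                         running_mean = numeric(ch), running_var = rep(1, ch)))
}

nn_relu <- function() nn_module("relu")
nn_identity <- function() nn_module("identity")
nn_scale <- function(s) nn_module("scale", hyper = list(s = s))
nn_flatten <- function() nn_module("flatten")
nn_gap <- function() nn_module("gap")
nn_dropout <- function(p) nn_module("dropout", hyper = list(p = p))

nn_maxpool <- function(kh, kw = kh, stride = kh, pad = 0) {
  if (length(stride) == 1) stride <- c(stride, stride)
  if (length(pad) == 1) pad <- rep(pad, 4)
  nn_module("maxpool",
            hyper = list(kh = kh, kw = kw, stride = stride, pad = pad))
}

nn_avgpool <- function(kh, kw = kh, stride = kh, pad = 0) {
  if (length(stride) == 1) stride <- c(stride, stride)
  if (length(pad) == 1) pad <- rep(pad, 4)
  nn_module("avgpool",
            hyper = list(kh = kh, kw = kw, stride = stride, pad = pad))
}

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  nn_module("seq", children = mods)
}

# parallel branches over the same input; combine = "concat" (channel axis) or
# "add" (residual connection)
nn_par <- function(branches, combine = c("concat", "add")) {
  nn_module("par", children = branches,
            hyper = list(combine = match.arg(combine)))
}

# pad the spatial dims of a (H, W, C, N) tensor
pad_hw <- function(x, pad, value = 0) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4],
                        d[3], d[4]))
  out[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), , ] <- x
  out
}

# replicate per-image patch indices across a batch of N images laid out
# contiguously (stride elements apart)
batch_expand_idx <- function(idx, stride, N) {
  R <- nrow(idx)
  big <- idx[rep(seq_len(R), N), , drop = FALSE]
  big + as.integer(rep(seq_len(N) - 1L, each = R) * stride)
}

# linear indices into a padded (Hp, Wp, C) array for im2col patches:
# rows enumerate output positions (row-major over (Ho, Wo)), columns enumerate
# (kh, kw, channel) with kh fastest -- the same order as conv weight rows
im2col_idx <- function(Hp, Wp, C, kh, kw, sh, sw) {
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  a <- rep(seq_len(Ho), times = Wo)
  b <- rep(seq_len(Wo), each = Ho)
  i0 <- (a - 1) * sh
  j0 <- (b - 1) * sw
  p <- rep(seq_len(kh), times = kw * C)
  q <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  idx <- outer(i0, p, "+") + outer(j0, q - 1L, "+") * Hp +
    matrix((cc - 1) * (Hp * Wp), length(a), length(p), byrow = TRUE)
  storage.mode(idx) <- "integer"
  attr(idx, "out_hw") <- c(Ho, Wo)
  idx
}

scatter_add <- function(values, index, n) {
  s <- rowsum(as.numeric(values), as.integer(index))
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s
  out
}

# column-wise scatter for im2col gradients: within one kernel-offset column
# every target index is distinct (stride >= 1), so plain indexed addition is
# exact and avoids the sort inside rowsum()
col2im_add <- function(dP, bidx, n) {
  out <- numeric(n)
  for (k in seq_len(ncol(bidx))) {
    ii <- bidx[, k]
    out[ii] <- out[ii] + dP[, k]
  }
  out
}

channel_stat <- function(x, f = colSums) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(f(m), d[3], d[4]))
}

bcast_channel <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

nn_forward <- function(m, x, training = FALSE, keep_cache = FALSE) {
  cache <- NULL
  out <- switch(
    m$type,
    conv = {
      h <- m$hyper
      d <- dim(x)
      stopifnot(length(d) == 4, d[3] == h$in_ch)
      xp <- pad_hw(x, h$pad)
      dp <- dim(xp)
      idx <- im2col_idx(dp[1], dp[2], d[3], h$kh, h$kw,
                        h$stride[1], h$stride[2])
      ohw <- attr(idx, "out_hw")
      bidx <- batch_expand_idx(idx, prod(dp[1:3]), d[4])
      P <- matrix(xp[as.vector(bidx)], nrow(bidx), ncol(bidx))
      O <- P %*% m$params$W
      if (!is.null(m$params$b)) O <- O + rep(m$params$b, each = nrow(O))
      res <- aperm(array(O, c(ohw[1] * ohw[2], d[4], h$out_ch)), c(1, 3, 2))
      dim(res) <- c(ohw[1], ohw[2], h$out_ch, d[4])
      if (keep_cache)
        cache <- list(P = P, bidx = bidx, in_dim = d, pad_dim = dp)
      res
    },
    dense = {
      if (keep_cache) cache <- list(x = x)
      x %*% m$params$W + rep(m$params$b, each = nrow(x))
    },
    bn = {
      h <- m$hyper
      d <- dim(x)
      cnt <- d[1] * d[2] * d[4]
      if (training) {
        mu <- channel_stat(x) / cnt
        xc <- x - bcast_channel(mu, d)
        vr <- channel_stat(xc^2) / cnt
        ivar <- 1 / sqrt(vr + h$eps)
        xhat <- xc * bcast_channel(ivar, d)
        # running stats live in hyper; update is a side effect handled by the
        # training loop via the returned cache (R copies modules by value)
        if (keep_cache)
          cache <- list(xhat = xhat, ivar = ivar, mode = "train",
                        new_mean = (1 - h$momentum) * h$running_mean + h$momentum * mu,
                        new_var = (1 - h$momentum) * h$running_var + h$momentum * vr)
        xhat * bcast_channel(m$params$gamma, d) +
          bcast_channel(m$params$beta, d)
      } else {
        ivar <- 1 / sqrt(h$running_var + h$eps)
        scale <- m$params$gamma * ivar
        shift <- m$params$beta - scale * h$running_mean
        if (keep_cache)
          cache <- list(scale = scale, mode = "eval",
                        xhat = (x - bcast_channel(h$running_mean, d)) *
                          bcast_channel(ivar, d))
        x * bcast_channel(scale, d) + bcast_channel(shift, d)
      }
    },
    relu = {
      out <- pmax(x, 0)
      if (keep_cache) cache <- list(mask = x > 0)
      out
    },
    identity = x,
    scale = x * m$hyper$s,
    flatten = {
      d <- dim(x)
      if (keep_cache) cache <- list(in_dim = d)
      t(matrix(x, prod(d[1:3]), d[4]))
    },
    gap = {
      d <- dim(x)
      if (keep_cache) cache <- list(in_dim = d)
      cm <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
      t(matrix(cm, d[3], d[4]))
    },
    dropout = {
      if (training && m$hyper$p > 0) {
        keep <- 1 - m$hyper$p
        mask <- (array(stats::runif(length(x)), dim = dim(x) %||% length(x)) < keep) / keep
        if (keep_cache) cache <- list(mask = mask)
        x * mask
      } else x
    },
    maxpool = {
      h <- m$hyper
      d <- dim(x)
      xp <- pad_hw(x, h$pad, value = -Inf)
      dp <- dim(xp)
      # rows span output positions and channels: (Ho*Wo*C) x (kh*kw)
      idx <- pool_idx(dp[1], dp[2], d[3], h$kh, h$kw,
                      h$stride[1], h$stride[2])
      ohw <- attr(idx, "out_hw")
      bidx <- batch_expand_idx(idx, prod(dp[1:3]), d[4])
      P <- matrix(xp[as.vector(bidx)], nrow(bidx), ncol(bidx))
      res <- do.call(pmax, lapply(seq_len(ncol(P)), function(k) P[, k]))
      dim(res) <- c(ohw[1], ohw[2], d[3], d[4])
      if (keep_cache) {
        am <- max.col(P, ties.method = "first")
        cache <- list(amax = bidx[cbind(seq_len(nrow(bidx)), am)],
                      in_dim = d, pad_dim = dp)
      }
      res
    },
    avgpool = {
      h <- m$hyper
      d <- dim(x)
      xp <- pad_hw(x, h$pad)
      dp <- dim(xp)
      idx <- pool_idx(dp[1], dp[2], d[3], h$kh, h$kw,
                      h$stride[1], h$stride[2])
      ohw <- attr(idx, "out_hw")
      bidx <- batch_expand_idx(idx, prod(dp[1:3]), d[4])
      P <- matrix(xp[as.vector(bidx)], nrow(bidx), ncol(bidx))
      res <- rowMeans(P)
      dim(res) <- c(ohw[1], ohw[2], d[3], d[4])
      if (keep_cache)
        cache <- list(bidx = bidx, in_dim = d, pad_dim = dp)
      res
    },
    seq = {
      caches <- if (keep_cache) vector("list", length(m$children)) else NULL
      cur <- x
      for (i in seq_along(m$children)) {
        r <- nn_forward(m$children[[i]], cur, training, keep_cache)
        cur <- r$out
        if (keep_cache) caches[[i]] <- r$cache
      }
      if (keep_cache) cache <- list(children = caches)
      cur
    },
    par = {
      outs <- vector("list", length(m$children))
      caches <- if (keep_cache) vector("list", length(m$children)) else NULL
      for (i in seq_along(m$children)) {
        r <- nn_forward(m$children[[i]], x, training, keep_cache)
        outs[[i]] <- r$out
        if (keep_cache) caches[[i]] <- r$cache
      }
      if (m$hyper$combine == "add") {
        res <- Reduce(`+`, outs)
        if (keep_cache) cache <- list(children = caches, combine = "add")
        res
      } else {
        chs <- vapply(outs, function(o) dim(o)[3], 0)
        d1 <- dim(outs[[1]])
        res <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
        at <- 0
        for (i in seq_along(outs)) {
          res[, , at + seq_len(chs[i]), ] <- outs[[i]]
          at <- at + chs[i]
        }
        if (keep_cache)
          cache <- list(children = caches, combine = "concat", chs = chs)
        res
      }
    },
    stopf("unknown layer type '%s'", m$type)
  )
  list(out = out, cache = cache)
}

pool_idx <- function(Hp, Wp, C, kh, kw, sh, sw) {
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  a <- rep(seq_len(Ho), times = Wo * C)
  b <- rep(rep(seq_len(Wo), each = Ho), times = C)
  cc <- rep(seq_len(C), each = Ho * Wo)
  i0 <- (a - 1) * sh
  j0 <- (b - 1) * sw
  base <- (cc - 1) * (Hp * Wp)
  p <- rep(seq_len(kh), times = kw)
  q <- rep(seq_len(kw), each = kh)
  idx <- outer(i0 + base, p, "+") + outer(j0, q - 1L, "+") * Hp
  storage.mode(idx) <- "integer"
  attr(idx, "out_hw") <- c(Ho, Wo)
  idx
}

nn_backward <- function(m, cache, dout, prefix = "") {
  grads <- list()
  dx <- switch(
    m$type,
    conv = {
      h <- m$hyper
      d <- cache$in_dim
      dO <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = h$out_ch)
      grads[[paste0(prefix, "W")]] <- crossprod(cache$P, dO)
      if (!is.null(m$params$b)) grads[[paste0(prefix, "b")]] <- colSums(dO)
      dP <- dO %*% t(m$params$W)
      dxp <- array(col2im_add(dP, cache$bidx, prod(cache$pad_dim)),
                   cache$pad_dim)
      dxp[h$pad[1] + seq_len(d[1]), h$pad[3] + seq_len(d[2]), , , drop = FALSE]
    },
    dense = {
      grads[[paste0(prefix, "W")]] <- crossprod(cache$x, dout)
      grads[[paste0(prefix, "b")]] <- colSums(dout)
      dout %*% t(m$params$W)
    },
    bn = {
      d <- dim(dout)
      if (cache$mode == "eval") {
        # frozen statistics: per-channel affine map
        grads[[paste0(prefix, "gamma")]] <- channel_stat(dout * cache$xhat)
        grads[[paste0(prefix, "beta")]] <- channel_stat(dout)
        dout * bcast_channel(cache$scale, d)
      } else {
        cnt <- d[1] * d[2] * d[4]
        dgamma <- channel_stat(dout * cache$xhat)
        dbeta <- channel_stat(dout)
        grads[[paste0(prefix, "gamma")]] <- dgamma
        grads[[paste0(prefix, "beta")]] <- dbeta
        dxhat <- dout * bcast_channel(m$params$gamma, d)
        sum_dxhat <- channel_stat(dxhat)
        sum_dxhat_xhat <- channel_stat(dxhat * cache$xhat)
        (dxhat - bcast_channel(sum_dxhat / cnt, d) -
           cache$xhat * bcast_channel(sum_dxhat_xhat / cnt, d)) *
          bcast_channel(cache$ivar, d)
      }
    },
    relu = dout * cache$mask,
    identity = dout,
    scale = dout * m$hyper$s,
    flatten = array(t(dout), cache$in_dim),
    gap = {
      d <- cache$in_dim
      per <- t(dout) / (d[1] * d[2])             # C x N
      array(rep(as.vector(per), each = d[1] * d[2]), d)
    },
    dropout = if (is.null(cache)) dout else dout * cache$mask,
    maxpool = {
      d <- cache$in_dim
      h <- m$hyper
      dxp <- array(scatter_add(as.vector(dout), cache$amax,
                               prod(cache$pad_dim)), cache$pad_dim)
      dxp[h$pad[1] + seq_len(d[1]), h$pad[3] + seq_len(d[2]), , , drop = FALSE]
    },
    avgpool = {
      d <- cache$in_dim
      h <- m$hyper
      kk <- h$kh * h$kw
      dv <- as.vector(dout) / kk
      dxp <- array(col2im_add(matrix(dv, length(dv), ncol(cache$bidx)),
                              cache$bidx, prod(cache$pad_dim)),
                   cache$pad_dim)
      dxp[h$pad[1] + seq_len(d[1]), h$pad[3] + seq_len(d[2]), , , drop = FALSE]
    },
    seq = {
      cur <- dout
      for (i in rev(seq_along(m$children))) {
        r <- nn_backward(m$children[[i]], cache$children[[i]], cur,
                         prefix = paste0(prefix, "c", i, "."))
        cur <- r$dx
        grads <- c(grads, r$grads)
      }
      cur
    },
    par = {
      if (cache$combine == "add") {
        dxs <- lapply(seq_along(m$children), function(i) {
          r <- nn_backward(m$children[[i]], cache$children[[i]], dout,
                           prefix = paste0(prefix, "c", i, "."))
          grads <<- c(grads, r$grads)
          r$dx
        })
        Reduce(`+`, dxs)
      } else {
        at <- 0
        dxs <- lapply(seq_along(m$children), function(i) {
          sl <- dout[, , at + seq_len(cache$chs[i]), , drop = FALSE]
          at <<- at + cache$chs[i]
          r <- nn_backward(m$children[[i]], cache$children[[i]], sl,
                           prefix = paste0(prefix, "c", i, "."))
          grads <<- c(grads, r$grads)
          r$dx
        })
        Reduce(`+`, dxs)
      }
    },
    stopf("no backward for layer type '%s'", m$type)
  )
  list(dx = dx, grads = grads)
}

nn_collect_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (i in seq_along(m$children))
    out <- c(out, nn_collect_params(m$children[[i]],
                                    paste0(prefix, "c", i, ".")))
  out
}

nn_set_params <- function(m, flat, prefix = "") {
  for (nm in names(m$params)) {
    key <- paste0(prefix, nm)
    if (!is.null(flat[[key]])) m$params[[nm]] <- flat[[key]]
  }
  for (i in seq_along(m$children))
    m$children[[i]] <- nn_set_params(m$children[[i]], flat,
                                     paste0(prefix, "c", i, "."))
  m
}

# fold updated batch-norm running statistics (carried in forward caches) back
# into the module tree after a training step
nn_update_bn_stats <- function(m, cache) {
  if (m$type == "bn" && !is.null(cache) && identical(cache$mode, "train")) {
    m$hyper$running_mean <- cache$new_mean
    m$hyper$running_var <- cache$new_var
  }
  for (i in seq_along(m$children))
    m$children[[i]] <- nn_update_bn_stats(m$children[[i]],
                                          cache$children[[i]])
  m
}

nn_param_count <- function(m) {
  sum(vapply(nn_collect_params(m), length, 0))
}
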