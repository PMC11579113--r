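# Minimal dense tensor network used by the brain-age regressor: forward and
# reverse passes over a fixed layer sequence (conv3d / batchnorm / relu /
# maxpool / dropout / flatten / dense), with conv and pool kernels in C++.
# Activations are (D, H, W, C, N) arrays, column-major, voxel index fastest.

new_layer <- function(type, ...) c(list(type = type), list(...))

# Per-channel statistics of a (D,H,W,C,N) activation array.
channel_stats <- function(x, C) {
  d <- dim(x)
  V <- prod(d[1:3])
  arr <- array(x, c(V, C, d[5]))
  mu <- numeric(C)
  va <- numeric(C)
  for (c in seq_len(C)) {
    s <- arr[, c, ]
    mu[c] <- mean(s)
    va[c] <- mean((s - mu[c])^2)
  }
  list(mu = mu, var = va)
}

# Expand a per-channel vector to activation shape.
bcast_channel <- function(v, d) {
  array(rep(rep(v, each = prod(d[1:3])), times = d[5]), d)
}

nn_forward <- function(net, x, training = FALSE, dropout_seed = NULL,
                       need_param_grads = training) {
  layers <- net$layers
  cache <- vector("list", length(layers))
  bn_eps <- 1e-5
  bn_mom <- 0.1
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      d <- dim(x)
      if (need_param_grads) cache[[i]] <- list(x = x, dims = d)
      else cache[[i]] <- list(dims = d)
      x <- cpp_conv3d_fwd(x, as.integer(d), ly$w, ly$b, ly$k, ly$pad_lo)
    } else if (ly$type == "bn") {
      d <- dim(x)
      C <- ly$ch
      if (training) {
        st <- channel_stats(x, C)
        inv <- 1 / sqrt(st$var + bn_eps)
        xhat <- (x - bcast_channel(st$mu, d)) * bcast_channel(inv, d)
        x <- xhat * bcast_channel(ly$gamma, d) + bcast_channel(ly$beta, d)
        net$layers[[i]]$rmean <- (1 - bn_mom) * ly$rmean + bn_mom * st$mu
        net$layers[[i]]$rvar <- (1 - bn_mom) * ly$rvar + bn_mom * st$var
        cache[[i]] <- list(xhat = xhat, inv = inv, dims = d)
      } else {
        inv <- 1 / sqrt(ly$rvar + bn_eps)
        scale <- ly$gamma * inv
        x <- x * bcast_channel(scale, d) +
          bcast_channel(ly$beta - ly$gamma * ly$rmean * inv, d)
        cache[[i]] <- list(scale = scale, dims = d)
      }
    } else if (ly$type == "relu") {
      x <- pmax(x, 0)
      cache[[i]] <- list(mask = x > 0)
      if (!is.null(net$capture_layer) && net$capture_layer == i) {
        cache[[i]]$activation <- x
      }
    } else if (ly$type == "pool") {
      d <- dim(x)
      res <- cpp_maxpool_fwd(x, as.integer(d), ly$k)
      cache[[i]] <- list(argmax = res$argmax, in_dims = d)
      x <- res$out
    } else if (ly$type == "dropout") {
      if (training) {
        seed_i <- derive_seed(dropout_seed %||% 0, paste0("dropout-", i))
        mask <- with_seed(seed_i,
                          (runif(length(x)) >= ly$p) / (1 - ly$p))
        dim(mask) <- dim(x)
        x <- x * mask
        cache[[i]] <- list(mask = mask)
      } else {
        cache[[i]] <- list()
      }
    } else if (ly$type == "flatten") {
      d <- dim(x)
      cache[[i]] <- list(in_dims = d)
      x <- t(matrix(x, prod(d[1:4]), d[5]))
    } else if (ly$type == "dense") {
      if (need_param_grads) cache[[i]] <- list(x = x) else cache[[i]] <- list()
      x <- x %*% ly$w + matrix(ly$b, nrow(x), length(ly$b), byrow = TRUE)
    } else stop("unknown layer type: ", ly$type)
  }
  list(y = as.vector(x), cache = cache, net = net)
}

# Reverse pass. `dy` is the gradient of a scalar objective w.r.t. each
# sample's network output. mode: "train" accumulates parameter gradients
# (batch-norm in train statistics); "input" and "guided" compute input
# gradients with batch-norm and dropout frozen; "guided" additionally zeroes
# negative incoming backward signals at every ReLU. `stop_at` returns the
# gradient arriving at that layer's output (used by GradCAM).
nn_backward <- function(net, cache, dy, mode = c("train", "input", "guided"),
                        stop_at = NULL) {
  mode <- match.arg(mode)
  layers <- net$layers
  g <- matrix(dy, ncol = 1)
  pgrads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (!is.null(stop_at) && i == stop_at) {
      return(list(gx = g, pgrads = pgrads))
    }
    ly <- layers[[i]]
    ca <- cache[[i]]
    if (ly$type == "dense") {
      if (mode == "train") {
        pgrads[[i]] <- list(w = crossprod(ca$x, g), b = colSums(g))
      }
      g <- g %*% t(ly$w)
    } else if (ly$type == "flatten") {
      g <- array(t(g), ca$in_dims)
    } else if (ly$type == "dropout") {
      if (mode == "train") g <- g * ca$mask
    } else if (ly$type == "pool") {
      g <- cpp_maxpool_bwd(g, ca$argmax, as.integer(ca$in_dims))
    } else if (ly$type == "relu") {
      if (mode == "guided") g <- g * (g > 0)
      g <- g * ca$mask
    } else if (ly$type == "bn") {
      d <- ca$dims
      C <- ly$ch
      if (mode == "train") {
        m <- prod(d[1:3]) * d[5]
        V <- prod(d[1:3])
        garr <- array(g, c(V, C, d[5]))
        xh <- array(ca$xhat, c(V, C, d[5]))
        dx <- array(0, c(V, C, d[5]))
        ggamma <- numeric(C)
        gbeta <- numeric(C)
        for (c in seq_len(C)) {
          gc <- array(garr[, c, ], c(V, d[5]))
          xc <- array(xh[, c, ], c(V, d[5]))
          dxhat <- gc * ly$gamma[c]
          ggamma[c] <- sum(gc * xc)
          gbeta[c] <- sum(gc)
          # standard compact form: dx = inv/m * (m*dxhat - sum(dxhat)
          #                                      - xhat * sum(dxhat * xhat))
          dx[, c, ] <- (ca$inv[c] / m) *
            (m * dxhat - sum(dxhat) - xc * sum(dxhat * xc))
        }
        pgrads[[i]] <- list(gamma = ggamma, beta = gbeta)
        g <- array(dx, d)
      } else {
        g <- g * bcast_channel(ly$gamma / sqrt(ly$rvar + 1e-5), d)
      }
    } else if (ly$type == "conv") {
      # in train mode the gradient w.r.t. the network input itself is unused,
      # so the first conv layer skips its (largest) input-gradient pass
      need_gx <- !(mode == "train" && i == 1L)
      res <- cpp_conv3d_bwd(if (mode == "train") ca$x else numeric(0),
                            as.integer(ca$dims), g, ly$w, ly$k, ly$pad_lo,
                            need_gx, mode == "train")
      if (mode == "train") pgrads[[i]] <- list(w = res$gw, b = as.vector(res$gb))
      g <- if (need_gx) res$gx else NULL
    }
  }
  list(gx = g, pgrads = pgrads)
}
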