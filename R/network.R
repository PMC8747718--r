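#' Build an executable network from a model specification
#'
#' Instantiates seeded initial weights for every trainable layer: He-uniform
#' initialization for convolution and fully connected weights (appropriate for
#' ReLU stacks), zero biases, and unit-scale / zero-shift batch normalization
#' with zero-mean, unit-variance running statistics.
#'
#' @param spec a `leafcnn_model_spec`.
#' @param seed integer seed; identical seeds give bitwise-identical weights.
#' @return a `leafcnn_network` object holding the spec, parameters and state.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "leafcnn_model_spec"))
  shapes <- layer_shapes(spec)
  params <- vector("list", length(spec$layers))
  state <- vector("list", length(spec$layers))
  with_rng(mix_seed(seed, 101L), {
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      inp <- shapes[[i]]$input
      if (ly$kind == "conv2d") {
        fan_in <- prod(ly$filter_size) * inp$c
        lim <- sqrt(6 / fan_in)
        params[[i]] <- list(
          W = matrix(runif(fan_in * ly$num_filters, -lim, lim),
                     fan_in, ly$num_filters),
          b = numeric(ly$num_filters))
      } else if (ly$kind == "batchnorm") {
        params[[i]] <- list(gamma = rep(1, inp$c), beta = numeric(inp$c))
        state[[i]] <- list(run_mean = numeric(inp$c), run_var = rep(1, inp$c))
      } else if (ly$kind == "fully_connected") {
        fan_in <- inp$h * inp$w * inp$c
        lim <- sqrt(6 / fan_in)
        params[[i]] <- list(
          W = matrix(runif(fan_in * ly$out_units, -lim, lim),
                     fan_in, ly$out_units),
          b = numeric(ly$out_units))
      }
    }
  })
  structure(list(spec = spec, params = params, state = state, shapes = shapes),
            class = "leafcnn_network")
}

#' @export
print.leafcnn_network <- function(x, ...) {
  cat(sprintf("<leafcnn_network %s: %s trainable parameters>\n",
              x$spec$name,
              format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

# Activations flow in one of two layouts:
#   array: (H, W, C, N) tensor — needed by conv (im2col) and pooling
#   pix:   (H*W*N, C) matrix, row index h + w*H + n*H*W — convenient for
#          batchnorm/ReLU and produced directly by the im2col matmul
act_to_array <- function(a) {
  if (a$layout == "array") return(a)
  x <- a$data
  dim(x) <- c(a$h * a$w, a$n, a$c)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(a$h, a$w, a$c, a$n)
  list(layout = "array", data = x, h = a$h, w = a$w, c = a$c, n = a$n)
}
act_to_pix <- function(a) {
  if (a$layout == "pix") return(a)
  x <- aperm(a$data, c(1, 2, 4, 3))
  dim(x) <- c(a$h * a$w * a$n, a$c)
  list(layout = "pix", data = x, h = a$h, w = a$w, c = a$c, n = a$n)
}

bn_eps <- 1e-5
bn_momentum <- 0.9

# Forward pass. train = TRUE uses batch statistics, stores caches for the
# backward pass and updates running statistics (returned in `net`).
net_forward <- function(net, x, train = FALSE, labels = NULL) {
  spec <- net$spec
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L || !all(d[1:3] == spec$input_size))
    stop_leafcnn(sprintf("input shape %s does not match model input %s",
                         paste(d[1:3], collapse = "x"),
                         paste(spec$input_size, collapse = "x")))
  a <- list(layout = "array", data = x, h = d[1], w = d[2], c = d[3], n = d[4])
  caches <- vector("list", length(spec$layers))
  probs <- NULL
  loss <- NULL
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    p <- net$params[[i]]
    if (ly$kind == "conv2d") {
      a <- act_to_array(a)
      cols <- cpp_im2col(a$data, a$h, a$w, a$c, a$n,
                         ly$filter_size[1], ly$filter_size[2],
                         ly$padding, ly$stride)
      z <- cols %*% p$W
      z <- z + matrix(p$b, nrow(z), ncol(z), byrow = TRUE)
      ho <- (a$h + 2 * ly$padding - ly$filter_size[1]) %/% ly$stride + 1L
      wo <- (a$w + 2 * ly$padding - ly$filter_size[2]) %/% ly$stride + 1L
      if (train) caches[[i]] <- list(cols = cols, in_dims = c(a$h, a$w, a$c, a$n))
      a <- list(layout = "pix", data = z, h = ho, w = wo,
                c = ly$num_filters, n = a$n)
    } else if (ly$kind == "batchnorm") {
      a <- act_to_pix(a)
      xm <- a$data
      m <- nrow(xm)
      if (train) {
        mu <- colMeans(xm)
        xc <- xm - matrix(mu, m, a$c, byrow = TRUE)
        v <- colMeans(xc * xc)
        st <- net$state[[i]]
        st$run_mean <- bn_momentum * st$run_mean + (1 - bn_momentum) * mu
        st$run_var <- bn_momentum * st$run_var + (1 - bn_momentum) * v
        net$state[[i]] <- st
      } else {
        mu <- net$state[[i]]$run_mean
        v <- net$state[[i]]$run_var
        xc <- xm - matrix(mu, m, a$c, byrow = TRUE)
      }
      istd <- 1 / sqrt(v + bn_eps)
      xhat <- xc * matrix(istd, m, a$c, byrow = TRUE)
      y <- xhat * matrix(p$gamma, m, a$c, byrow = TRUE) +
        matrix(p$beta, m, a$c, byrow = TRUE)
      if (train) caches[[i]] <- list(xhat = xhat, istd = istd)
      a$data <- y
    } else if (ly$kind == "relu") {
      a <- act_to_pix(a)
      if (train) caches[[i]] <- list(mask = a$data > 0)
      a$data <- pmax(a$data, 0)
    } else if (ly$kind == "maxpool") {
      a <- act_to_array(a)
      pl <- cpp_maxpool_fwd(a$data, a$h, a$w, a$c, a$n, ly$window, ly$stride)
      ho <- (a$h - ly$window) %/% ly$stride + 1L
      wo <- (a$w - ly$window) %/% ly$stride + 1L
      out <- pl$out
      dim(out) <- c(ho, wo, a$c, a$n)
      if (train) caches[[i]] <- list(idx = pl$idx,
                                     in_len = length(a$data),
                                     in_dims = c(a$h, a$w, a$c, a$n))
      a <- list(layout = "array", data = out, h = ho, w = wo, c = a$c, n = a$n)
    } else if (ly$kind == "fully_connected") {
      if (a$h == 1L && a$w == 1L) {
        feat <- act_to_pix(a)$data           # already one row per sample
      } else {
        ap <- act_to_pix(a)
        v <- ap$data
        dim(v) <- c(ap$h * ap$w, ap$n, ap$c)
        v <- aperm(v, c(1, 3, 2))
        dim(v) <- c(ap$h * ap$w * ap$c, ap$n)
        feat <- t(v)
      }
      z <- feat %*% p$W
      z <- z + matrix(p$b, nrow(z), ncol(z), byrow = TRUE)
      if (train) caches[[i]] <- list(feat = feat,
                                     in_geom = c(a$h, a$w, a$c, a$n))
      a <- list(layout = "pix", data = z, h = 1L, w = 1L,
                c = ly$out_units, n = a$n)
    } else if (ly$kind == "softmax") {
      z <- a$data
      z <- z - apply(z, 1, max)
      e <- exp(z)
      probs <- e / rowSums(e)
      a$data <- probs
    } else if (ly$kind == "classification") {
      if (!is.null(labels)) {
        pick <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
        loss <- -mean(log(pmax(pick, 1e-12)))
      }
    }
  }
  list(probs = probs, loss = loss, caches = caches, net = net)
}

# Backward pass from softmax + cross-entropy. Returns per-layer gradients in
# the same structure as net$params.
net_backward <- function(net, fwd, labels) {
  spec <- net$spec
  probs <- fwd$probs
  n <- nrow(probs)
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  grads <- vector("list", length(spec$layers))
  # combined softmax/cross-entropy gradient wrt the FC scores
  d <- list(layout = "pix", data = (probs - Y) / n, h = 1L, w = 1L,
            c = ncol(probs), n = n)
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    p <- net$params[[i]]
    cache <- fwd$caches[[i]]
    if (ly$kind %in% c("classification", "softmax")) next
    if (ly$kind == "fully_connected") {
      grads[[i]] <- list(W = crossprod(cache$feat, d$data),
                         b = colSums(d$data))
      dfeat <- d$data %*% t(p$W)                       # n x in
      g <- cache$in_geom
      if (g[1] == 1L && g[2] == 1L) {
        d <- list(layout = "pix", data = dfeat, h = 1L, w = 1L,
                  c = g[3], n = g[4])
      } else {
        v <- t(dfeat)                                  # in x n
        dim(v) <- c(g[1] * g[2], g[3], g[4])
        v <- aperm(v, c(1, 3, 2))
        dim(v) <- c(g[1] * g[2] * g[4], g[3])
        d <- list(layout = "pix", data = v, h = g[1], w = g[2],
                  c = g[3], n = g[4])
      }
    } else if (ly$kind == "relu") {
      dd <- to_like(d, "pix")
      dd$data <- dd$data * cache$mask
      d <- dd
    } else if (ly$kind == "batchnorm") {
      dd <- to_like(d, "pix")
      dy <- dd$data
      m <- nrow(dy)
      xhat <- cache$xhat
      grads[[i]] <- list(gamma = colSums(dy * xhat), beta = colSums(dy))
      dxhat <- dy * matrix(p$gamma, m, ncol(dy), byrow = TRUE)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- (dxhat - matrix(s1 / m, m, ncol(dy), byrow = TRUE) -
               xhat * matrix(s2 / m, m, ncol(dy), byrow = TRUE)) *
        matrix(cache$istd, m, ncol(dy), byrow = TRUE)
      dd$data <- dx
      d <- dd
    } else if (ly$kind == "maxpool") {
      dd <- to_like(d, "array")
      dx <- cpp_maxpool_bwd(as.vector(dd$data), cache$idx, cache$in_len)
      dims <- cache$in_dims
      dim(dx) <- dims
      d <- list(layout = "array", data = dx, h = dims[1], w = dims[2],
                c = dims[3], n = dims[4])
    } else if (ly$kind == "conv2d") {
      dd <- to_like(d, "pix")
      grads[[i]] <- list(W = crossprod(cache$cols, dd$data),
                         b = colSums(dd$data))
      dcols <- dd$data %*% t(p$W)
      dims <- cache$in_dims
      dx <- cpp_col2im(dcols, dims[1], dims[2], dims[3], dims[4],
                       ly$filter_size[1], ly$filter_size[2],
                       ly$padding, ly$stride)
      dim(dx) <- dims
      d <- list(layout = "array", data = dx, h = dims[1], w = dims[2],
                c = dims[3], n = dims[4])
    }
  }
  grads
}

to_like <- function(d, layout) {
  if (d$layout == layout) return(d)
  if (layout == "pix") act_to_pix(d) else act_to_array(d)
}

# Forward in evaluation mode in manageable chunks; returns the probability
# matrix (n x C).
net_predict_probs <- function(net, x, chunk = 64L) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  n <- d[4]
  out <- matrix(0, n, net$spec$num_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- net_forward(net, x[, , , idx, drop = FALSE],
                              train = FALSE)$probs
  }
  out
}
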