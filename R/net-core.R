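# ---------------------------------------------------------------------------
# A small CNN engine. Tensors are R arrays with dim (H, W, B, C); batched 3x3
# same-padding convolutions are one BLAS matrix product over the im2col
# unrolling (src/convops.cpp). Every layer implements a forward pass that
# returns (output, cache) and a backward pass that maps the output gradient
# to parameter gradients plus the input gradient. Weights use He
# initialization; updates use Adam.
# ---------------------------------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

new_conv3 <- function(c_in, c_out, act = c("relu", "none"), trainable = TRUE) {
  act <- match.arg(act)
  list(type = "conv3", act = act, c_in = c_in, c_out = c_out,
       trainable = trainable,
       W = he_init(9 * c_in, c_out, 9 * c_in), b = numeric(c_out))
}

new_resblock <- function(c_in, c_out, trainable = TRUE) {
  list(type = "resblock", c_in = c_in, c_out = c_out, trainable = trainable,
       W1 = he_init(9 * c_in, c_out, 9 * c_in), b1 = numeric(c_out),
       W2 = he_init(9 * c_out, c_out, 9 * c_out), b2 = numeric(c_out),
       P = if (c_in != c_out) he_init(c_in, c_out, c_in) else NULL)
}

new_pool2 <- function() list(type = "pool2")
new_gap <- function() list(type = "gap")

new_dense <- function(d_in, d_out, act = c("relu", "none"), dropout = 0) {
  act <- match.arg(act)
  list(type = "dense", act = act, dropout = dropout, d_in = d_in,
       d_out = d_out, trainable = TRUE,
       W = he_init(d_in, d_out, d_in), b = numeric(d_out))
}

# Final 1-unit layer: sigmoid bounded, scaled to [0, output_scale].
new_head <- function(d_in, scale = 1) {
  list(type = "head", scale = scale, d_in = d_in, trainable = TRUE,
       W = he_init(d_in, 1, d_in), b = 0)
}

.conv_fwd <- function(l, x) {
  d <- dim(x)
  cols <- im2col3(x, d[1], d[2], d[3], d[4])
  z <- cols %*% l$W
  add_bias_ip(z, l$b)
  a <- if (l$act == "relu") z * (z > 0) else z
  mask <- if (l$act == "relu") z > 0
  dim(a) <- c(d[1], d[2], d[3], l$c_out)   # same storage order, no copy
  list(y = a, cache = list(cols = cols, mask = mask, d = d))
}

.conv_bwd <- function(l, cache, dy) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(prod(d[1:3]), l$c_out)
  if (l$act == "relu") dym <- dym * cache$mask
  list(grads = list(W = crossprod(cache$cols, dym), b = colSums(dym)),
       dx = col2im3(dym %*% t(l$W), d[1], d[2], d[3], d[4]))
}

.res_fwd <- function(l, x) {
  d <- dim(x)
  c1 <- .conv_fwd(list(type = "conv3", act = "relu", c_in = l$c_in,
                       c_out = l$c_out, W = l$W1, b = l$b1), x)
  c2 <- .conv_fwd(list(type = "conv3", act = "none", c_in = l$c_out,
                       c_out = l$c_out, W = l$W2, b = l$b2), c1$y)
  if (is.null(l$P)) {
    sc <- x
    xmat <- NULL
  } else {
    xmat <- x
    dim(xmat) <- c(prod(d[1:3]), d[4])
    sc <- xmat %*% l$P
    dim(sc) <- c(d[1], d[2], d[3], l$c_out)
  }
  z <- c2$y + sc
  list(y = z * (z > 0),
       cache = list(c1 = c1$cache, c2 = c2$cache, mask = z > 0, xmat = xmat,
                    d = d))
}

.res_bwd <- function(l, cache, dy) {
  d <- cache$d
  dz <- dy * cache$mask
  b2 <- .conv_bwd(list(act = "none", c_out = l$c_out, W = l$W2), cache$c2, dz)
  b1 <- .conv_bwd(list(act = "relu", c_out = l$c_out, W = l$W1), cache$c1,
                  b2$dx)
  grads <- list(W1 = b1$grads$W, b1 = b1$grads$b,
                W2 = b2$grads$W, b2 = b2$grads$b)
  if (is.null(l$P)) {
    dx <- b1$dx + dz
  } else {
    dzm <- dz
    dim(dzm) <- c(prod(d[1:3]), l$c_out)
    grads$P <- crossprod(cache$xmat, dzm)
    dsc <- dzm %*% t(l$P)
    dim(dsc) <- d
    dx <- b1$dx + dsc
  }
  list(grads = grads, dx = dx)
}

.pool_fwd <- function(l, x) {
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("pool2 needs even spatial dimensions")
  r <- pool2_fwd(x, d[1], d[2], d[3], d[4])
  list(y = r$y, cache = list(amax = r$amax, d = d))
}

.pool_bwd <- function(l, cache, dy) {
  d <- cache$d
  list(grads = NULL, dx = pool2_bwd(dy, cache$amax, d[1], d[2], d[3], d[4]))
}

.gap_fwd <- function(l, x) {
  d <- dim(x)
  y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(y = y, cache = list(d = d))
}

.gap_bwd <- function(l, cache, dy) {
  d <- cache$d
  np <- d[1] * d[2]
  list(grads = NULL,
       dx = array(rep(as.vector(dy), each = np) / np, d))
}

.dense_fwd <- function(l, x, train = FALSE) {
  z <- x %*% l$W
  add_bias_ip(z, l$b)
  a <- if (l$act == "relu") z * (z > 0) else z
  dmask <- NULL
  if (train && l$dropout > 0) {
    dmask <- matrix(runif(length(a)) >= l$dropout, nrow(a), ncol(a))
    a <- a * dmask / (1 - l$dropout)
  }
  list(y = a, cache = list(x = x, mask = if (l$act == "relu") z > 0,
                           dmask = dmask))
}

.dense_bwd <- function(l, cache, dy) {
  if (!is.null(cache$dmask)) dy <- dy * cache$dmask / (1 - l$dropout)
  if (l$act == "relu") dy <- dy * cache$mask
  list(grads = list(W = crossprod(cache$x, dy), b = colSums(dy)),
       dx = dy %*% t(l$W))
}

.head_fwd <- function(l, x) {
  z <- as.numeric(x %*% l$W + l$b)
  p <- 1 / (1 + exp(-z))
  list(y = l$scale * p, cache = list(x = x, p = p))
}

# The trainer supplies dz (gradient w.r.t. the pre-sigmoid logit) directly,
# so the binary cross-entropy shortcut (p - t)/B stays exact.
.head_bwd <- function(l, cache, dz) {
  dz <- matrix(dz, ncol = 1)
  list(grads = list(W = crossprod(cache$x, dz), b = sum(dz)),
       dx = dz %*% t(l$W))
}

# Forward pass through the whole network. Returns the output vector plus the
# per-layer caches needed for backprop (dropped when train = FALSE and
# keep_cache = FALSE).
net_forward <- function(net, x, train = FALSE, keep_cache = train) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    r <- switch(l$type,
      conv3 = .conv_fwd(l, x),
      resblock = .res_fwd(l, x),
      pool2 = .pool_fwd(l, x),
      gap = .gap_fwd(l, x),
      dense = .dense_fwd(l, x, train = train),
      head = .head_fwd(l, x))
    x <- r$y
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# Backward pass from the head logit gradient; returns per-layer grad lists.
net_backward <- function(net, caches, dz) {
  grads <- vector("list", length(net$layers))
  d <- dz
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    r <- switch(l$type,
      conv3 = .conv_bwd(l, caches[[i]], d),
      resblock = .res_bwd(l, caches[[i]], d),
      pool2 = .pool_bwd(l, caches[[i]], d),
      gap = .gap_bwd(l, caches[[i]], d),
      dense = .dense_bwd(l, caches[[i]], d),
      head = .head_bwd(l, caches[[i]], d))
    grads[i] <- list(r$grads)   # keep NULL entries for parameterless layers
    d <- r$dx
  }
  grads
}

.param_names <- function(l) {
  switch(l$type,
    conv3 = c("W", "b"),
    resblock = c("W1", "b1", "W2", "b2", if (!is.null(l$P)) "P"),
    dense = c("W", "b"),
    head = c("W", "b"),
    character(0))
}

# Total trainable parameter count (a pure function of the configuration).
#' Number of parameters of a network
#' @param net A network from [build_pds_network()] or
#'   [build_binary_network()].
#' @return Integer parameter count.
#' @export
net_n_params <- function(net) {
  sum(vapply(net$layers, function(l)
    sum(vapply(.param_names(l), function(nm) length(l[[nm]]), numeric(1))),
    numeric(1)))
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    nms <- .param_names(l)
    if (length(nms) == 0) return(NULL)
    st <- lapply(nms, function(nm) list(m = l[[nm]] * 0, v = l[[nm]] * 0))
    names(st) <- nms
    st
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (is.null(grads[[i]]) || isFALSE(l$trainable)) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]][[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
      l <- net$layers[[i]]
    }
  }
  list(net = net, state = state)
}

#' Predict scores for a batch of images
#'
#' Runs the network forward in evaluation mode (no dropout), in minibatches.
#'
#' @param net A built network.
#' @param x Image tensor, array `(H, W, N, 3)`, or a list of `H x W x 3`
#'   image arrays.
#' @param batch_size Forward minibatch size.
#' @return Numeric vector: PDS scores in \[0, output_scale\] for regression
#'   networks, severe-probabilities in (0, 1) for binary networks.
#' @export
net_predict <- function(net, x, batch_size = 64L) {
  if (is.list(x)) x <- images_to_tensor(x)
  n <- dim(x)[3]
  out <- numeric(n)
  for (st in seq(1, n, by = batch_size)) {
    en <- min(n, st + batch_size - 1L)
    out[st:en] <- net_forward(net, x[, , st:en, , drop = FALSE],
                              train = FALSE, keep_cache = FALSE)$out
  }
  out
}

#' Stack images into a batch tensor
#'
#' @param images List of `H x W x 3` arrays (or `leaf_image` objects).
#' @return Array with dim `(H, W, N, 3)`.
#' @export
images_to_tensor <- function(images) {
  imgs <- lapply(images, function(im) if (inherits(im, "leaf_image")) im$pixels else im)
  d <- dim(imgs[[1]])
  stopifnot(length(d) == 3, d[3] == 3)
  x <- array(0, c(d[1], d[2], length(imgs), 3))
  for (i in seq_along(imgs)) x[, , i, ] <- imgs[[i]]
  x
}
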