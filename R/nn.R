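# Minimal feed-forward network engine: 1-D/2-D convolutions (im2col +
# BLAS), batch normalization, max pooling, ReLU, dropout, dense layers,
# residual blocks, softmax cross-entropy, and plain SGD. Arrays are
# channels-last: (batch, length, channels) or (batch, rows, cols,
# channels). Everything is deterministic given the R RNG state.

# collapse all leading dims onto rows, channels on columns
.arr2mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(prod(d[-length(d)]), d[length(d)])
  a
}

.addbias <- function(m, b) m + rep(b, each = nrow(m))

# ---- convolution (im2col/col2im in compiled code) -------------------------

.conv1d_fwd <- function(x, W, b, k) {
  d <- dim(x)
  r <- .conv1d_fwd_cpp(x, d[1], d[2], d[3], W, b, k)
  out <- r$out
  dim(out) <- c(d[1], d[2], ncol(W))
  list(out = out, cache = list(M = r$M, d = d, k = k))
}

.conv1d_bwd <- function(dout, W, cache) {
  d <- cache$d
  r <- .conv1d_bwd_cpp(.arr2mat(dout), W, cache$M, d[1], d[2], d[3], cache$k)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dW = r$dW, db = as.numeric(r$db))
}

.conv2d_fwd <- function(x, W, b, k) {
  d <- dim(x)
  r <- .conv2d_fwd_cpp(x, d[1], d[2], d[3], d[4], W, b, k)
  out <- r$out
  dim(out) <- c(d[1], d[2], d[3], ncol(W))
  list(out = out, cache = list(M = r$M, d = d, k = k))
}

.conv2d_bwd <- function(dout, W, cache) {
  d <- cache$d
  r <- .conv2d_bwd_cpp(.arr2mat(dout), W, cache$M, d[1], d[2], d[3], d[4],
                       cache$k)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dW = r$dW, db = as.numeric(r$db))
}

# ---- pooling --------------------------------------------------------------

.pool1d_fwd <- function(x, s) {
  d <- dim(x)
  r <- .pool1d_fwd_cpp(x, d[1], d[2], d[3], s)
  out <- r$out; dim(out) <- c(d[1], r$L2, d[3])
  list(out = out, cache = list(arg = r$arg, d = d, s = s, L2 = r$L2))
}

.pool1d_bwd <- function(dout, cache) {
  d <- cache$d
  dx <- .pool1d_bwd_cpp(dout, cache$arg, d[1], d[2], d[3], cache$s)
  dim(dx) <- d
  dx
}

.pool2d_fwd <- function(x, s) {
  d <- dim(x)
  r <- .pool2d_fwd_cpp(x, d[1], d[2], d[3], d[4], s)
  out <- r$out; dim(out) <- c(d[1], r$H2, r$W2, d[4])
  list(out = out, cache = list(arg = r$arg, d = d, s = s))
}

.pool2d_bwd <- function(dout, cache) {
  d <- cache$d
  dx <- .pool2d_bwd_cpp(dout, cache$arg, d[1], d[2], d[3], d[4], cache$s)
  dim(dx) <- d
  dx
}

# ---- batch normalization --------------------------------------------------

.bn_fwd <- function(x, ly, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]; N <- as.integer(prod(d) / C)
  train <- train && N > 1L
  r <- .bn_fwd_cpp(x, N, C, ly$gamma, ly$beta, ly$run_mean, ly$run_var,
                   train, eps)
  if (train) {
    va_u <- as.numeric(r$va) * N / (N - 1L)
    if (!isTRUE(ly$bn_seen)) { # first batch seeds the running moments
      ly$run_mean <- as.numeric(r$mu)
      ly$run_var <- va_u
      ly$bn_seen <- TRUE
    } else {
      ly$run_mean <- momentum * ly$run_mean + (1 - momentum) * as.numeric(r$mu)
      ly$run_var <- momentum * ly$run_var + (1 - momentum) * va_u
    }
  }
  out <- r$out
  dim(out) <- d
  list(out = out, layer = ly,
       cache = list(xhat = r$xhat, ivar = as.numeric(r$ivar), d = d, N = N,
                    C = C, train = train))
}

.bn_bwd <- function(dout, ly, cache) {
  r <- .bn_bwd_cpp(dout, cache$xhat, cache$N, cache$C, ly$gamma, cache$ivar,
                   cache$train)
  dX <- r$dx
  dim(dX) <- cache$d
  list(dx = dX, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# ---- layer dispatch -------------------------------------------------------

.init_layer <- function(desc, shape) {
  ly <- desc
  switch(desc$kind,
    conv1d = {
      fan_in <- desc$k * shape[2]
      ly$W <- matrix(stats::rnorm(fan_in * desc$out_ch, 0, sqrt(2 / fan_in)),
                     fan_in, desc$out_ch)
      ly$b <- numeric(desc$out_ch)
      shape <- c(shape[1], desc$out_ch)
    },
    conv2d = {
      fan_in <- desc$k^2 * shape[3]
      ly$W <- matrix(stats::rnorm(fan_in * desc$out_ch, 0, sqrt(2 / fan_in)),
                     fan_in, desc$out_ch)
      ly$b <- numeric(desc$out_ch)
      shape <- c(shape[1:2], desc$out_ch)
    },
    bn = {
      ch <- shape[length(shape)]
      ly$gamma <- rep(1, ch); ly$beta <- numeric(ch)
      ly$run_mean <- numeric(ch); ly$run_var <- rep(1, ch)
    },
    pool1d = shape <- c(as.integer(ceiling(shape[1] / desc$s)), shape[2]),
    pool2d = shape <- c(as.integer(ceiling(shape[1] / desc$s)),
                        as.integer(ceiling(shape[2] / desc$s)), shape[3]),
    relu = NULL,
    dropout = NULL,
    flatten = shape <- prod(shape),
    dense = {
      fan_in <- shape[1]
      ly$W <- matrix(stats::rnorm(fan_in * desc$units, 0, sqrt(2 / fan_in)),
                     fan_in, desc$units)
      ly$b <- numeric(desc$units)
      shape <- desc$units
    },
    res1d = {
      in_ch <- shape[2]; ch <- desc$channels
      sub <- list()
      sh <- shape
      for (i in seq_len(desc$n_convs)) {
        r <- .init_layer(list(kind = "conv1d", k = 3L, out_ch = ch), sh)
        sub[[length(sub) + 1L]] <- r$layer; sh <- r$shape
        r <- .init_layer(list(kind = "bn"), sh)
        sub[[length(sub) + 1L]] <- r$layer
        if (i < desc$n_convs) sub[[length(sub) + 1L]] <- list(kind = "relu")
      }
      ly$branch <- sub
      if (in_ch != ch) {
        r <- .init_layer(list(kind = "conv1d", k = 1L, out_ch = ch), shape)
        ly$proj <- r$layer
      } else ly$proj <- NULL
      shape <- c(shape[1], ch)
    },
    stop("unknown layer kind: ", desc$kind)
  )
  list(layer = ly, shape = shape)
}

.layer_fwd <- function(ly, x, train) {
  switch(ly$kind,
    conv1d = { r <- .conv1d_fwd(x, ly$W, ly$b, ly$k)
               list(out = r$out, cache = r$cache, layer = ly) },
    conv2d = { r <- .conv2d_fwd(x, ly$W, ly$b, ly$k)
               list(out = r$out, cache = r$cache, layer = ly) },
    bn = { r <- .bn_fwd(x, ly, train)
           list(out = r$out, cache = r$cache, layer = r$layer) },
    pool1d = { r <- .pool1d_fwd(x, ly$s)
               list(out = r$out, cache = r$cache, layer = ly) },
    pool2d = { r <- .pool2d_fwd(x, ly$s)
               list(out = r$out, cache = r$cache, layer = ly) },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0), layer = ly),
    dropout = {
      if (train) {
        mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask), layer = ly)
      } else list(out = x, cache = list(mask = NULL), layer = ly)
    },
    flatten = {
      d <- dim(x)
      out <- x; dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(d = d), layer = ly)
    },
    dense = list(out = .addbias(x %*% ly$W, ly$b), cache = list(x = x),
                 layer = ly),
    res1d = {
      caches <- vector("list", length(ly$branch))
      h <- x
      for (i in seq_along(ly$branch)) {
        r <- .layer_fwd(ly$branch[[i]], h, train)
        ly$branch[[i]] <- r$layer; caches[[i]] <- r$cache; h <- r$out
      }
      if (!is.null(ly$proj)) {
        pr <- .conv1d_fwd(x, ly$proj$W, ly$proj$b, 1L)
        skip <- pr$out; pcache <- pr$cache
      } else { skip <- x; pcache <- NULL }
      z <- h + skip
      list(out = pmax(z, 0),
           cache = list(branch = caches, pcache = pcache, mask = z > 0),
           layer = ly)
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

.layer_bwd <- function(ly, dout, cache) {
  switch(ly$kind,
    conv1d = { r <- .conv1d_bwd(dout, ly$W, cache)
               list(dx = r$dx, grads = list(W = r$dW, b = r$db)) },
    conv2d = { r <- .conv2d_bwd(dout, ly$W, cache)
               list(dx = r$dx, grads = list(W = r$dW, b = r$db)) },
    bn = { r <- .bn_bwd(dout, ly, cache)
           list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta)) },
    pool1d = list(dx = .pool1d_bwd(dout, cache), grads = NULL),
    pool2d = list(dx = .pool2d_bwd(dout, cache), grads = NULL),
    relu = list(dx = dout * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = { dx <- dout; dim(dx) <- cache$d; list(dx = dx, grads = NULL) },
    dense = list(dx = tcrossprod(dout, ly$W),
                 grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    res1d = {
      dz <- dout * cache$mask
      grads <- list(branch = vector("list", length(ly$branch)), proj = NULL)
      dh <- dz
      for (i in rev(seq_along(ly$branch))) {
        r <- .layer_bwd(ly$branch[[i]], dh, cache$branch[[i]])
        grads$branch[[i]] <- r$grads; dh <- r$dx
      }
      if (!is.null(ly$proj)) {
        pr <- .conv1d_bwd(dz, ly$proj$W, cache$pcache)
        grads$proj <- list(W = pr$dW, b = pr$db)
        dx <- dh + pr$dx
      } else dx <- dh + dz
      list(dx = dx, grads = grads)
    },
    stop("unknown layer kind: ", ly$kind)
  )
}

# SGD with classical momentum (velocity kept on the layer) and L2
# weight decay applied to weight matrices only
.layer_update <- function(ly, grads, lr, momentum = 0.9, weight_decay = 0) {
  if (is.null(grads)) return(ly)
  if (ly$kind == "res1d") {
    for (i in seq_along(ly$branch)) {
      ly$branch[[i]] <- .layer_update(ly$branch[[i]], grads$branch[[i]], lr,
                                      momentum, weight_decay)
    }
    if (!is.null(ly$proj)) {
      ly$proj <- .layer_update(ly$proj, grads$proj, lr, momentum, weight_decay)
    }
    return(ly)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm == "W" && weight_decay > 0) g <- g + weight_decay * ly[[nm]]
    vnm <- paste0("v_", nm)
    v <- if (is.null(ly[[vnm]])) g else momentum * ly[[vnm]] + g
    ly[[vnm]] <- v
    ly[[nm]] <- ly[[nm]] - lr * v
  }
  ly
}

.n_layer_params <- function(ly) {
  if (ly$kind == "res1d") {
    n <- sum(vapply(ly$branch, .n_layer_params, numeric(1)))
    if (!is.null(ly$proj)) n <- n + length(ly$proj$W) + length(ly$proj$b)
    return(n)
  }
  sum(vapply(intersect(names(ly), c("W", "b", "gamma", "beta")),
             function(nm) length(ly[[nm]]), numeric(1)))
}

# ---- network --------------------------------------------------------------

# instantiate parameters for an architecture_spec; seeded, pure
nn_init <- function(spec, seed = 1L) {
  with_seed_local(seed, {
    shape <- spec$input_shape
    layers <- vector("list", length(spec$blocks))
    for (i in seq_along(spec$blocks)) {
      r <- .init_layer(spec$blocks[[i]], shape)
      layers[[i]] <- r$layer; shape <- r$shape
    }
    structure(list(layers = layers, spec = spec), class = "libspec_net")
  })
}

# forward pass; returns logits, per-layer caches, updated net (BN running
# stats), and named activations for layer inspection
nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  acts <- list()
  h <- x
  for (i in seq_along(net$layers)) {
    r <- .layer_fwd(net$layers[[i]], h, train)
    net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    h <- r$out
    nm <- net$layers[[i]]$name
    if (!is.null(nm)) acts[[nm]] <- h
  }
  list(logits = h, caches = caches, net = net, acts = acts)
}

# backward from logit gradients; returns per-layer grads and input gradient
nn_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  dh <- dlogits
  for (i in rev(seq_along(net$layers))) {
    r <- .layer_bwd(net$layers[[i]], dh, caches[[i]])
    grads[i] <- list(r$grads) # plain [[<- would drop NULL entries
    dh <- r$dx
  }
  list(grads = grads, dx = dh)
}

nn_sgd_step <- function(net, grads, lr, momentum = 0.9, weight_decay = 0) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]] <- .layer_update(net$layers[[i]], grads[[i]], lr,
                                     momentum, weight_decay)
  }
  net
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# total parameter count of an instantiated network
nn_param_count <- function(net) {
  sum(vapply(net$layers, .n_layer_params, numeric(1)))
}
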