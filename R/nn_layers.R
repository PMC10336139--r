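# Minimal feed-forward layer primitives with analytic gradients.
#
# Every *_fwd returns list(out, cache); every *_bwd consumes (dout, cache) and
# returns the gradient w.r.t. the layer input plus gradients for any weights.
# These back the encoder, decoder, technical-effect and critic networks; the
# full objective gradient assembled from them is verified against finite
# differences in the test suite.

# multiply/add a per-column vector across all rows
cmul <- function(x, v) x * rep(v, each = nrow(x))
cadd <- function(x, v) x + rep(v, each = nrow(x))

linear_fwd <- function(x, W, b) {
  list(out = cadd(x %*% W, b), cache = list(x = x, W = W))
}

linear_bwd <- function(dout, cache) {
  list(
    dx = dout %*% t(cache$W),
    dW = crossprod(cache$x, dout),
    db = colSums(dout)
  )
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dout, cache) dout * cache

# Inverted dropout; the 0/1 mask is drawn by the caller so that a fixed noise
# draw makes the whole objective a deterministic function (finite-difference
# checkable, reproducible under seeds).
dropout_fwd <- function(x, mask, p) {
  if (p <= 0) return(list(out = x, cache = NULL))
  sc <- mask / (1 - p)
  list(out = x * sc, cache = sc)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

new_batchnorm <- function(n_features, affine = TRUE) {
  list(
    gamma = if (affine) rep(1, n_features) else NULL,
    beta  = if (affine) rep(0, n_features) else NULL,
    rmean = rep(0, n_features),
    rvar  = rep(1, n_features),
    initialized = FALSE
  )
}

# Batch normalization over columns. In training mode minibatch statistics are
# used and exponential running averages (momentum 0.1) are stored for eval
# mode. gamma/beta live in the parameter list of the owning network; they are
# passed explicitly so the optimizer can see them.
bn_fwd <- function(x, gamma, beta, bn, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v <- pmax(v, 0)
    bn$rmean <- if (bn$initialized) (1 - momentum) * bn$rmean + momentum * mu else mu
    bn$rvar  <- if (bn$initialized) (1 - momentum) * bn$rvar + momentum * v else v
    bn$initialized <- TRUE
  } else {
    mu <- bn$rmean
    v <- bn$rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- cmul(x - rep(mu, each = n), inv)
  out <- if (is.null(gamma)) xhat else cadd(cmul(xhat, gamma), beta)
  list(out = out, bn = bn,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, n = n, training = training))
}

bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- if (is.null(cache$gamma)) NULL else colSums(dout * xhat)
  dbeta <- if (is.null(cache$gamma)) NULL else colSums(dout)
  dxhat <- if (is.null(cache$gamma)) dout else cmul(dout, cache$gamma)
  if (cache$training) {
    n <- cache$n
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- cmul(dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n), cache$inv)
  } else {
    dx <- cmul(dxhat, cache$inv)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_fwd <- function(x) {
  p <- softmax_rows(x)
  list(out = p, cache = p)
}

softmax_bwd <- function(dout, cache) {
  p <- cache
  p * (dout - rowSums(dout * p))
}

# ---- optimizers -------------------------------------------------------------

new_opt_state <- function() new.env(parent = emptyenv())

# One AdamW/Adam descent step over a named list of numeric arrays.
# `wd` = 0 gives plain Adam; weight decay is decoupled (applied to the
# parameter directly, not through the moment estimates).
adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 0, skip_decay = character()) {
  if (is.null(state$t)) {
    state$t <- 0L
    state$m <- lapply(par, function(p) p * 0)
    state$v <- lapply(par, function(p) p * 0)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (wd > 0 && !(nm %in% skip_decay)) upd <- upd + wd * par[[nm]]
    par[[nm]] <- par[[nm]] - lr * upd
  }
  par
}

# Global-norm gradient clipping (NaN guard during cyclical training).
clip_grads <- function(grads, max_norm = 10) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
    attr(grads, "clipped") <- TRUE
  }
  grads
}

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}
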