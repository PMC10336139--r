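# Amortized variational posterior: modality-specific encoder networks, the
# softmax-basis (Laplace-approximated Dirichlet) reparameterization, closed
# form KL to the prior, posterior summaries and the ILR latent space.

LOGVAR_MIN <- -10
LOGVAR_MAX <- 10

# ---- RNA encoder ------------------------------------------------------------

enc_rna_fwd <- function(Xres, C, par, rs, training, noise, hyper) {
  p <- hyper$encoder_dropout
  x <- cbind(Xres, C)
  l0 <- linear_fwd(x, par$enc_W0, par$enc_b0)
  b0 <- bn_fwd(l0$out, par$enc_g0, par$enc_be0, rs$enc0, training)
  r0 <- relu_fwd(b0$out)
  d0 <- dropout_fwd(r0$out, noise$enc_mask0, if (is.null(noise$enc_mask0)) 0 else p)
  l1 <- linear_fwd(d0$out, par$enc_W1, par$enc_b1)
  b1 <- bn_fwd(l1$out, par$enc_g1, par$enc_be1, rs$enc1, training)
  r1 <- relu_fwd(b1$out)
  d1 <- dropout_fwd(r1$out, noise$enc_mask1, if (is.null(noise$enc_mask1)) 0 else p)
  l2 <- linear_fwd(d1$out, par$enc_W2, par$enc_b2)
  b2 <- bn_fwd(l2$out, par$enc_g2, par$enc_be2, rs$enc2, training)
  out <- b2$out
  K <- hyper$n_topics
  lv_raw <- out[, (K + 1):(2 * K), drop = FALSE]
  dlv_raw <- out[, 2 * K + 2]
  post <- list(
    topic_mu = out[, 1:K, drop = FALSE],
    topic_logvar = clamp(lv_raw, LOGVAR_MIN, LOGVAR_MAX),
    depth_mu = out[, 2 * K + 1],
    depth_logvar = clamp(dlv_raw, LOGVAR_MIN, LOGVAR_MAX)
  )
  list(post = post,
       rs = list(enc0 = b0$bn, enc1 = b1$bn, enc2 = b2$bn),
       cache = list(l0 = l0$cache, b0 = b0$cache, r0 = r0$cache, d0 = d0$cache,
                    l1 = l1$cache, b1 = b1$cache, r1 = r1$cache, d1 = d1$cache,
                    l2 = l2$cache, b2 = b2$cache, K = K,
                    lv_ok = (lv_raw > LOGVAR_MIN & lv_raw < LOGVAR_MAX),
                    dlv_ok = (dlv_raw > LOGVAR_MIN & dlv_raw < LOGVAR_MAX)))
}

enc_rna_bwd <- function(dpost, cache) {
  K <- cache$K
  m <- nrow(dpost$topic_mu)
  dout <- matrix(0, m, 2 * K + 2)
  dout[, 1:K] <- dpost$topic_mu
  dout[, (K + 1):(2 * K)] <- dpost$topic_logvar * cache$lv_ok
  dout[, 2 * K + 1] <- dpost$depth_mu
  dout[, 2 * K + 2] <- dpost$depth_logvar * cache$dlv_ok
  b2 <- bn_bwd(dout, cache$b2)
  l2 <- linear_bwd(b2$dx, cache$l2)
  g <- dropout_bwd(l2$dx, cache$d1)
  g <- relu_bwd(g, cache$r1)
  b1 <- bn_bwd(g, cache$b1)
  l1 <- linear_bwd(b1$dx, cache$l1)
  g <- dropout_bwd(l1$dx, cache$d0)
  g <- relu_bwd(g, cache$r0)
  b0 <- bn_bwd(g, cache$b0)
  l0 <- linear_bwd(b0$dx, cache$l0)
  list(enc_W0 = l0$dW, enc_b0 = l0$db, enc_g0 = b0$dgamma, enc_be0 = b0$dbeta,
       enc_W1 = l1$dW, enc_b1 = l1$db, enc_g1 = b1$dgamma, enc_be1 = b1$dbeta,
       enc_W2 = l2$dW, enc_b2 = l2$db, enc_g2 = b2$dgamma, enc_be2 = b2$dbeta)
}

draw_enc_noise <- function(m, hyper, modality) {
  p <- hyper$encoder_dropout
  if (modality == "RNA") {
    H <- ENC_HIDDEN_RNA
    list(enc_mask0 = matrix(rbinom(m * H, 1L, 1 - p), m),
         enc_mask1 = matrix(rbinom(m * H, 1L, 1 - p), m))
  } else {
    H <- ENC_HIDDEN_ATAC
    list(enc_mask1 = matrix(rbinom(m * H, 1L, 1 - p), m))
  }
}

#' Encode expression profiles into posterior parameters
#'
#' Runs deviance residuals (concatenated with the covariate design) through
#' the expression encoder and returns the variational posterior parameters:
#' topic means/log-variances plus the log-normal posterior over the cell size
#' factor. Log-variances are clamped to `[-10, 10]`.
#'
#' @param model a `codal_model` with modality `"RNA"`.
#' @param residuals cells-by-genes deviance residual matrix.
#' @param C covariate design rows.
#' @param training logical; eval mode (default) is deterministic.
#' @param seed dropout seed in training mode.
#' @return list with `topic_mu`, `topic_logvar`, `depth_mu`, `depth_logvar`.
#' @export
encode_expression <- function(model, residuals, C, training = FALSE, seed = 0L) {
  stopifnot(model$modality == "RNA")
  residuals <- as_dense(residuals); C <- as.matrix(C)
  stopifnot_finite(residuals, "encoder input")
  noise <- list(enc_mask0 = NULL, enc_mask1 = NULL)
  if (training) {
    set.seed(derive_seed(seed, "enc"))
    noise <- draw_enc_noise(nrow(residuals), model$hyper, "RNA")
  }
  enc_rna_fwd(residuals, C, model$par, model$rs, training, noise, model$hyper)$post
}

# ---- ATAC encoder (deep averaging network) ----------------------------------

enc_atac_fwd <- function(X, C, par, rs, training, noise, hyper) {
  m <- nrow(X)
  Xr <- X
  if (training && !is.null(noise$peak_keep)) {
    Xr <- X * noise$peak_keep
    empty <- Matrix::rowSums(Xr) == 0
    if (any(empty)) Xr[empty, ] <- X[empty, , drop = FALSE] # fall back: keep all peaks
  }
  cnt <- Matrix::rowSums(Xr)
  if (any(cnt == 0)) stop("cell with no accessible peaks", call. = FALSE)
  v0 <- as.matrix(Xr %*% par$emb_W0) / cnt
  l1 <- linear_fwd(cbind(v0, C), par$enc_W1, par$enc_b1)
  b1 <- bn_fwd(l1$out, par$enc_g1, par$enc_be1, rs$enc1, training)
  r1 <- relu_fwd(b1$out)
  d1 <- dropout_fwd(r1$out, noise$enc_mask1, if (is.null(noise$enc_mask1)) 0 else hyper$encoder_dropout)
  l2 <- linear_fwd(d1$out + v0, par$enc_W2, par$enc_b2)
  b2 <- bn_fwd(l2$out, par$enc_g2, par$enc_be2, rs$enc2, training)
  out <- b2$out
  K <- hyper$n_topics
  lv_raw <- out[, (K + 1):(2 * K), drop = FALSE]
  post <- list(topic_mu = out[, 1:K, drop = FALSE],
               topic_logvar = clamp(lv_raw, LOGVAR_MIN, LOGVAR_MAX),
               depth_mu = NULL, depth_logvar = NULL)
  list(post = post, rs = list(enc1 = b1$bn, enc2 = b2$bn),
       cache = list(Xr = Xr, cnt = cnt, l1 = l1$cache, b1 = b1$cache,
                    r1 = r1$cache, d1 = d1$cache, l2 = l2$cache, b2 = b2$cache,
                    K = K, H = ncol(v0),
                    lv_ok = (lv_raw > LOGVAR_MIN & lv_raw < LOGVAR_MAX)))
}

enc_atac_bwd <- function(dpost, cache) {
  K <- cache$K
  m <- nrow(dpost$topic_mu)
  dout <- cbind(dpost$topic_mu, dpost$topic_logvar * cache$lv_ok)
  b2 <- bn_bwd(dout, cache$b2)
  l2 <- linear_bwd(b2$dx, cache$l2)
  dskip <- l2$dx # gradient into (v1 + v0)
  g <- dropout_bwd(dskip, cache$d1)
  g <- relu_bwd(g, cache$r1)
  b1 <- bn_bwd(g, cache$b1)
  l1 <- linear_bwd(b1$dx, cache$l1)
  H <- cache$H
  dv0 <- l1$dx[, seq_len(H), drop = FALSE] + dskip
  demb <- as.matrix(Matrix::crossprod(cache$Xr, dv0 / cache$cnt))
  list(emb_W0 = demb,
       enc_W1 = l1$dW, enc_b1 = l1$db, enc_g1 = b1$dgamma, enc_be1 = b1$dbeta,
       enc_W2 = l2$dW, enc_b2 = l2$db, enc_g2 = b2$dgamma, enc_be2 = b2$dbeta)
}

#' Encode accessibility profiles into posterior parameters
#'
#' Deep-averaging-network encoder: each cell is the mean of the embedding
#' vectors of its accessible peaks; covariates enter at the hidden layer and a
#' skip connection adds the embedding average to the output layer input. In
#' training mode accessible peaks are left out at rate 1/20 (cells that would
#' lose all peaks keep their full set).
#'
#' @param model a `codal_model` with modality `"ATAC"`.
#' @param X binary cells-by-peaks matrix (sparse accepted).
#' @param C covariate design rows.
#' @param training logical.
#' @param seed peak-dropout seed in training mode.
#' @return list with `topic_mu` and `topic_logvar`.
#' @export
encode_accessibility <- function(model, X, C, training = FALSE, seed = 0L) {
  stopifnot(model$modality == "ATAC")
  C <- as.matrix(C)
  noise <- list(peak_keep = NULL, enc_mask1 = NULL)
  if (training) {
    set.seed(derive_seed(seed, "enc-atac"))
    noise <- c(list(peak_keep = matrix(rbinom(nrow(X) * ncol(X), 1L, 1 - 1 / 20), nrow(X))),
               draw_enc_noise(nrow(X), model$hyper, "ATAC"))
  }
  enc_atac_fwd(X, C, model$par, model$rs, training, noise, model$hyper)$post
}

# ---- reparameterization and KL ----------------------------------------------

#' Sample topic compositions from the variational posterior
#'
#' Softmax-basis reparameterization: a diagonal Gaussian draw in the softmax
#' basis is pushed through the row-wise softmax, matching the Laplace
#' approximation of the Dirichlet used for the prior.
#'
#' @param post posterior parameter list (from an encoder).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return cells-by-topics composition matrix (rows sum to 1).
#' @export
reparameterized_sample <- function(post, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "repar"))
  eps <- matrix(rnorm(length(post$topic_mu)), nrow(post$topic_mu))
  softmax_rows(post$topic_mu + exp(0.5 * post$topic_logvar) * eps)
}

#' KL divergence from the variational posterior to the topic prior
#'
#' Closed-form Gaussian KL between the diagonal posterior and the Laplace
#' approximation of the Dirichlet prior in the softmax basis, with prior
#' moments `mean_k = log(a_k) - mean(log a)` and
#' `var_k = (1 - 2/K)/a_k + sum(1/a)/K^2`.
#'
#' @param post posterior parameter list.
#' @param alpha positive Dirichlet concentration vector.
#' @return per-cell KL (nonnegative).
#' @export
kl_to_prior <- function(post, alpha) {
  pr <- dirichlet_laplace_moments(alpha)
  mu <- post$topic_mu; lv <- post$topic_logvar
  m <- nrow(mu)
  pv <- rep(pr$var, each = m); pm <- rep(pr$mean, each = m)
  0.5 * rowSums(log(pv) - lv + (exp(lv) + (mu - pm)^2) / pv - 1)
}

# gradients of sum(kl) w.r.t. posterior params, and w.r.t. alpha
kl_grads <- function(post, alpha) {
  pr <- dirichlet_laplace_moments(alpha)
  mu <- post$topic_mu; lv <- post$topic_logvar
  m <- nrow(mu); K <- length(alpha)
  pv <- rep(pr$var, each = m); pm <- rep(pr$mean, each = m)
  dmu <- (mu - pm) / pv
  dlv <- 0.5 * (exp(lv) / pv - 1)
  # per-topic sums for prior-parameter gradients
  dpm <- -colSums((mu - pm) / pv)
  dpv <- 0.5 * colSums(1 / pv - (exp(lv) + (mu - pm)^2) / pv^2)
  # chain into log-alpha: pm_k = la_k - mean(la); pv_k = (1-2/K) e^-la_k + sum(e^-la)/K^2
  dla_from_pm <- dpm - rep(sum(dpm) / K, K)
  a <- alpha
  dla_from_pv <- -(1 - 2 / K) / a * dpv - (1 / a) * sum(dpv) / K^2
  list(dmu = dmu, dlv = dlv, dlog_alpha = dla_from_pm + dla_from_pv)
}

# Gaussian KL between the log-size-factor posterior and its LogNormal prior
# N(log(observed depth), 1): closed form, per cell.
depth_kl <- function(depth_mu, depth_logvar, log_depth, prior_sd = 1) {
  pv <- prior_sd^2
  0.5 * (log(pv) - depth_logvar + (exp(depth_logvar) + (depth_mu - log_depth)^2) / pv - 1)
}

depth_kl_grads <- function(depth_mu, depth_logvar, log_depth, prior_sd = 1) {
  pv <- prior_sd^2
  list(dmu = (depth_mu - log_depth) / pv,
       dlv = 0.5 * (exp(depth_logvar) / pv - 1))
}

#' Posterior mean topic compositions
#'
#' Averages reparameterized softmax samples from the variational posterior
#' (`n_samples = 0` returns the zero-noise composition `softmax(topic_mu)`).
#'
#' @param model a trained `codal_model`.
#' @param X counts (raw; residuals are computed internally for RNA).
#' @param C covariate design.
#' @param n_samples number of posterior draws to average (default 32).
#' @param seed integer seed.
#' @return cells-by-topics matrix with unit row sums.
#' @export
posterior_mean_topics <- function(model, X, C, n_samples = 32, seed = 0L) {
  post <- encode_cells(model, X, C)
  if (n_samples <= 0) return(softmax_rows(post$topic_mu))
  acc <- 0
  for (s in seq_len(n_samples)) {
    acc <- acc + reparameterized_sample(post, seed = derive_seed(seed, "pm", s))
  }
  acc / n_samples
}

# encoder entry point that accepts raw counts for either modality
encode_cells <- function(model, X, C) {
  if (model$modality == "RNA") {
    res <- deviance_residuals_matrix(X, pi_hat = model$pi_hat)
    encode_expression(model, res, C)
  } else {
    encode_accessibility(model, (X > 0) * 1, C)
  }
}

# ---- ILR latent space -------------------------------------------------------

# Orthonormal Helmert-like contrast basis (K x K-1), columns orthogonal to 1.
ilr_basis <- function(K) {
  V <- matrix(0, K, K - 1)
  for (j in seq_len(K - 1)) {
    V[seq_len(j), j] <- 1 / sqrt(j * (j + 1))
    V[j + 1, j] <- -j / sqrt(j * (j + 1))
  }
  V
}

#' Isometric log-ratio coordinates of compositions
#'
#' Maps strictly positive compositions (floored at 1e-8 and renormalized) to
#' Euclidean coordinates with a fixed orthonormal Helmert basis; an isometry
#' of the Aitchison geometry, so the uniform composition maps to the origin.
#'
#' @param Z cells-by-topics compositions.
#' @return cells-by-(topics-1) coordinate matrix.
#' @export
ilr_transform <- function(Z) {
  Z <- as_dense(Z)
  Z <- pmax(Z, 1e-8)
  Z <- Z / rowSums(Z)
  log(Z) %*% ilr_basis(ncol(Z))
}

#' ILR k-nearest-neighbor graph
#'
#' Transforms posterior-mean compositions to ILR coordinates and links each
#' cell to its `k` nearest neighbors under the Manhattan (L1) distance.
#'
#' @param Zbar cells-by-topics compositions.
#' @param k number of neighbors (must be `< nrow(Zbar)`).
#' @return list with `coords` (ILR coordinates), `index` (cells-by-k neighbor
#'   index matrix) and `dist` (matching distances).
#' @export
ilr_knn <- function(Zbar, k = 15) {
  n <- nrow(Zbar)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  coords <- ilr_transform(Zbar)
  D <- unname(as.matrix(dist(coords, method = "manhattan")))
  idx <- t(vapply(seq_len(n), function(i) {
    ord <- order(D[i, ])
    ord[ord != i][seq_len(k)]
  }, integer(k)))
  dst <- t(vapply(seq_len(n), function(i) D[i, idx[i, ]], numeric(k)))
  list(coords = coords, index = idx, dist = dst)
}
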