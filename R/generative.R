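# Generative side of the disentangling topic model: hierarchical Dirichlet
# topics, linear biological decoder with batch normalization, the state- and
# covariate-conditioned technical-effect network, and the per-modality count
# likelihoods.

TECH_HIDDEN <- 32L
ENC_HIDDEN_RNA <- 512L
ENC_HIDDEN_ATAC <- 256L

#' Create an untrained disentangling topic model
#'
#' Allocates all generative and variational parameters for a topic model of
#' one modality. Cells are Dirichlet-distributed mixtures over `n_topics`
#' latent programs; a linear decoder maps the mixture to per-feature
#' biological rates, while a small neural network maps (state, covariates) to
#' zero-centered technical effects. The two are summed and softmaxed into a
#' composition that parameterizes a negative binomial (RNA) or multinomial
#' (ATAC) observation distribution.
#'
#' @param n_features number of genes (RNA) or peaks (ATAC).
#' @param n_topics latent dimensionality (number of topics).
#' @param n_covariates number of columns of the technical covariate design.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param dropout decoder dropout rate; tuned in `[0.05, 0.1]`.
#' @param total_pseudocounts total Dirichlet pseudocount budget; the
#'   Gamma(2, 2 * n_topics / total_pseudocounts) hyperprior on each
#'   concentration entry has expected sum equal to this value (default 50).
#' @param corruption_prob probability that a cell's technical-effect row is
#'   zeroed during training (stabilizes cyclical training; default 0.05).
#' @param corruption_unit `"cell"` (default) zeroes whole rows; `"entry"`
#'   zeroes independent entries.
#' @param seed integer seed for weight initialization.
#' @return an object of class `codal_model`.
#' @export
new_codal_model <- function(n_features, n_topics, n_covariates,
                            modality = c("RNA", "ATAC"),
                            dropout = 0.05, total_pseudocounts = 50,
                            corruption_prob = 0.05,
                            corruption_unit = c("cell", "entry"),
                            seed = 0L) {
  modality <- match.arg(modality)
  corruption_unit <- match.arg(corruption_unit)
  stopifnot(n_topics >= 2, n_features >= 2, n_covariates >= 0)
  set.seed(derive_seed(seed, "init"))
  K <- as.integer(n_topics); G <- as.integer(n_features); Cn <- as.integer(n_covariates)

  par <- list(
    log_alpha = rep(log(total_pseudocounts / K), K),
    beta = glorot(K, G),
    dec_gamma = rep(1, G),
    dec_beta = rep(0, G),
    tech_W0 = glorot(K + Cn, TECH_HIDDEN),
    tech_b0 = rep(0, TECH_HIDDEN),
    tech_h_gamma = rep(1, TECH_HIDDEN),
    tech_h_beta = rep(0, TECH_HIDDEN),
    tech_W1 = glorot(TECH_HIDDEN, G),
    tech_b1 = rep(0, G),
    gamma_t = rep(1, G)
  )
  if (modality == "RNA") {
    H <- ENC_HIDDEN_RNA
    par <- c(par, list(
      log_theta = rep(log(5), G),
      enc_W0 = glorot(G + Cn, H), enc_b0 = rep(0, H),
      enc_g0 = rep(1, H), enc_be0 = rep(0, H),
      enc_W1 = glorot(H, H), enc_b1 = rep(0, H),
      enc_g1 = rep(1, H), enc_be1 = rep(0, H),
      enc_W2 = glorot(H, 2L * K + 2L), enc_b2 = rep(0, 2L * K + 2L),
      enc_g2 = rep(1, 2L * K + 2L), enc_be2 = rep(0, 2L * K + 2L)
    ))
  } else {
    H <- ENC_HIDDEN_ATAC
    par <- c(par, list(
      emb_W0 = glorot(G, H),
      enc_W1 = glorot(H + Cn, H), enc_b1 = rep(0, H),
      enc_g1 = rep(1, H), enc_be1 = rep(0, H),
      enc_W2 = glorot(H, 2L * K), enc_b2 = rep(0, 2L * K),
      enc_g2 = rep(1, 2L * K), enc_be2 = rep(0, 2L * K)
    ))
  }

  rs <- list(
    dec = new_batchnorm(G),
    tech_h = new_batchnorm(TECH_HIDDEN),
    tech_out = new_batchnorm(G, affine = FALSE),
    enc0 = new_batchnorm(if (modality == "RNA") ENC_HIDDEN_RNA else ENC_HIDDEN_ATAC),
    enc1 = new_batchnorm(if (modality == "RNA") ENC_HIDDEN_RNA else ENC_HIDDEN_ATAC),
    enc2 = new_batchnorm(length(par$enc_b2))
  )

  structure(
    list(
      par = par, rs = rs, modality = modality,
      hyper = list(
        n_topics = K, n_features = G, n_covariates = Cn,
        dropout = dropout, total_pseudocounts = total_pseudocounts,
        corruption_prob = corruption_prob, corruption_unit = corruption_unit,
        encoder_dropout = 0.05, tech_dropout = 0.05
      ),
      feature_ids = NULL, covariate_schema = NULL, log = NULL
    ),
    class = "codal_model"
  )
}

#' @export
print.codal_model <- function(x, ...) {
  cat(sprintf(
    "<codal_model> %s | %d topics x %d features, %d covariates%s\n",
    x$modality, x$hyper$n_topics, x$hyper$n_features, x$hyper$n_covariates,
    if (isTRUE(x$rs$dec$initialized)) " (trained)" else " (untrained)"
  ))
  invisible(x)
}

alpha_values <- function(model) exp(model$par$log_alpha)

# ---- decoder ----------------------------------------------------------------

decoder_fwd <- function(Z, par, rs, training, drop_mask = NULL, dropout = 0) {
  dp <- dropout_fwd(Z, drop_mask, if (is.null(drop_mask)) 0 else dropout)
  s <- dp$out %*% par$beta
  bn <- bn_fwd(s, par$dec_gamma, par$dec_beta, rs$dec, training)
  list(lambda = bn$out, rs_dec = bn$bn,
       cache = list(dp = dp, Zd = dp$out, bn = bn$cache))
}

decoder_bwd <- function(dlambda, cache, par) {
  b <- bn_bwd(dlambda, cache$bn)
  dbeta <- crossprod(cache$Zd, b$dx)
  dZd <- b$dx %*% t(par$beta)
  dZ <- dropout_bwd(dZd, cache$dp$cache)
  list(dZ = dZ, beta = dbeta, dec_gamma = b$dgamma, dec_beta = b$dbeta)
}

#' Biological rates from topic compositions
#'
#' Maps topic compositions through the linear decoder and its batch
#' normalization: the topic-by-feature loading matrix gives each cell's
#' log-scale biological rate, standardized per feature across the training
#' population and rescaled by learned per-feature variance/bias.
#'
#' @param model a `codal_model`.
#' @param Z cells-by-topics composition matrix (rows sum to 1).
#' @param training logical; training mode uses minibatch statistics and
#'   dropout, eval mode uses running statistics (requires a trained model).
#' @param seed seed for the dropout mask in training mode.
#' @return cells-by-features matrix of biological rates (lambda).
#' @export
biological_rates <- function(model, Z, training = FALSE, seed = 0L) {
  Z <- as_dense(Z)
  stopifnot(ncol(Z) == model$hyper$n_topics)
  if (!training && !isTRUE(model$rs$dec$initialized)) {
    stop("decoder running statistics not initialized; train the model first",
         call. = FALSE)
  }
  mask <- NULL
  if (training && model$hyper$dropout > 0) {
    set.seed(derive_seed(seed, "dec-drop"))
    mask <- matrix(rbinom(length(Z), 1L, 1 - model$hyper$dropout), nrow(Z))
  }
  decoder_fwd(Z, model$par, model$rs, training, mask, model$hyper$dropout)$lambda
}

# ---- technical-effect network ----------------------------------------------

tech_fwd <- function(Z, C, par, rs, training, noise, hyper) {
  dpz <- dropout_fwd(Z, noise$tech_zmask, if (is.null(noise$tech_zmask)) 0 else hyper$tech_dropout)
  x <- cbind(dpz$out, C)
  l0 <- linear_fwd(x, par$tech_W0, par$tech_b0)
  bnh <- bn_fwd(l0$out, par$tech_h_gamma, par$tech_h_beta, rs$tech_h, training)
  r <- relu_fwd(bnh$out)
  dph <- dropout_fwd(r$out, noise$tech_hmask, if (is.null(noise$tech_hmask)) 0 else hyper$tech_dropout)
  l1 <- linear_fwd(dph$out, par$tech_W1, par$tech_b1)
  bno <- bn_fwd(l1$out, NULL, NULL, rs$tech_out, training)
  t_out <- cmul(bno$out, par$gamma_t)
  corrupt <- NULL
  if (training && !is.null(noise$corrupt)) {
    corrupt <- noise$corrupt
    if (is.matrix(corrupt)) t_out <- t_out * corrupt else t_out <- t_out * (1 - corrupt)
  }
  list(t = t_out, rs_tech_h = bnh$bn, rs_tech_out = bno$bn,
       cache = list(dpz = dpz, l0 = l0$cache, bnh = bnh$cache, r = r$cache,
                    dph = dph$cache, l1 = l1$cache, bno = bno$cache,
                    xhat = bno$out, corrupt = corrupt, K = ncol(Z)))
}

tech_bwd <- function(dt, cache, par) {
  if (!is.null(cache$corrupt)) {
    dt <- if (is.matrix(cache$corrupt)) dt * cache$corrupt else dt * (1 - cache$corrupt)
  }
  dgamma_t <- colSums(dt * cache$xhat)
  dxhat <- cmul(dt, par$gamma_t)
  bo <- bn_bwd(dxhat, cache$bno)
  l1 <- linear_bwd(bo$dx, cache$l1)
  dr <- dropout_bwd(l1$dx, cache$dph)
  dr <- relu_bwd(dr, cache$r)
  bh <- bn_bwd(dr, cache$bnh)
  l0 <- linear_bwd(bh$dx, cache$l0)
  K <- cache$K
  dZd <- l0$dx[, seq_len(K), drop = FALSE]
  dZ <- dropout_bwd(dZd, cache$dpz$cache)
  list(dZ = dZ,
       tech_W0 = l0$dW, tech_b0 = l0$db,
       tech_h_gamma = bh$dgamma, tech_h_beta = bh$dbeta,
       tech_W1 = l1$dW, tech_b1 = l1$db,
       gamma_t = dgamma_t)
}

#' Technical effects from state and covariates
#'
#' Evaluates the technical-effect network on topic compositions and the
#' covariate design. Outputs are zero-centered per feature over the training
#' population (batch statistics in training mode, running statistics in eval
#' mode) and rescaled by the learned per-feature technical variance. In
#' training mode each cell's technical-effect row is zeroed with the model's
#' corruption probability.
#'
#' @inheritParams biological_rates
#' @param C covariate design rows matching `Z`.
#' @return cells-by-features matrix of technical effects.
#' @export
technical_effects <- function(model, Z, C, training = FALSE, seed = 0L) {
  Z <- as_dense(Z); C <- as.matrix(C)
  if (ncol(C) != model$hyper$n_covariates) {
    stop("covariate width mismatch: expected ", model$hyper$n_covariates,
         " columns, got ", ncol(C), call. = FALSE)
  }
  noise <- list(tech_zmask = NULL, tech_hmask = NULL, corrupt = NULL)
  if (training) {
    set.seed(derive_seed(seed, "tech"))
    noise <- draw_tech_noise(nrow(Z), model$hyper)
  }
  tech_fwd(Z, C, model$par, model$rs, training, noise, model$hyper)$t
}

draw_tech_noise <- function(m, hyper) {
  p <- hyper$tech_dropout
  zmask <- matrix(rbinom(m * hyper$n_topics, 1L, 1 - p), m)
  hmask <- matrix(rbinom(m * TECH_HIDDEN, 1L, 1 - p), m)
  corrupt <- if (hyper$corruption_unit == "cell") {
    rbinom(m, 1L, hyper$corruption_prob)
  } else {
    matrix(rbinom(m * hyper$n_features, 1L, 1 - hyper$corruption_prob), m)
  }
  list(tech_zmask = zmask, tech_hmask = hmask, corrupt = corrupt)
}

# ---- composition and likelihoods -------------------------------------------

#' Compose biological and technical effects into expression compositions
#'
#' Row-wise softmax of `lambda + t`; invariant to adding a per-cell constant
#' and guarded against overflow by max subtraction.
#'
#' @param lambda,t conformable cells-by-features matrices.
#' @return row-stochastic matrix of the same shape.
#' @export
compose_rates <- function(lambda, t = 0) {
  softmax_rows(lambda + t)
}

xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

#' Negative binomial log-likelihood of RNA counts
#'
#' Sum over genes of the negative binomial log-pmf with mean `n * rho` and
#' inverse-dispersion `theta` (variance `mu + mu^2 / theta`).
#'
#' @param X counts (vector for one cell, or cells-by-genes matrix).
#' @param rho row-stochastic composition(s), same shape as `X`.
#' @param n size factor(s), one per cell.
#' @param theta per-gene inverse-dispersion vector.
#' @return per-cell log-likelihood vector.
#' @export
rna_log_likelihood <- function(X, rho, n, theta) {
  if (is.null(dim(X))) { X <- matrix(X, 1); rho <- matrix(rho, 1) }
  X <- as_dense(X)
  if (any(X < 0)) stop("negative counts", call. = FALSE)
  stopifnot(all(n > 0), all(theta > 0))
  m <- nrow(X)
  mu <- rho * n
  th <- rep(theta, each = m)
  ll <- lgamma(X + th) - lgamma(th) - lgamma(X + 1) +
    th * log(th) - th * log(th + mu) + xlogy(X, mu) - X * log(th + mu)
  rowSums(ll)
}

# gradient of sum(rna_log_likelihood) w.r.t. mu (elementwise)
nb_dll_dmu <- function(X, mu, th) X / pmax(mu, 1e-12) - (X + th) / (th + mu)
# gradient w.r.t. theta (elementwise, before summing over cells)
nb_dll_dtheta <- function(X, mu, th) {
  digamma(X + th) - digamma(th) + log(th) + 1 - log(th + mu) - (X + th) / (th + mu)
}

#' Multinomial log-likelihood of binary accessibility profiles
#'
#' Log-probability of the observed accessible-peak indicator vector under a
#' multinomial with the cell's composition and trials equal to the number of
#' accessible peaks. The multinomial coefficient, constant in the parameters,
#' is omitted.
#'
#' @param X binary vector or cells-by-peaks matrix.
#' @param rho row-stochastic composition(s).
#' @return per-cell log-likelihood vector.
#' @export
atac_log_likelihood <- function(X, rho) {
  if (is.null(dim(X))) { X <- matrix(X, 1); rho <- matrix(rho, 1) }
  X <- as_dense(X)
  if (any(rowSums(X) == 0)) stop("zero-depth cell", call. = FALSE)
  rowSums(xlogy(X, rho))
}

#' Batch-free expression or accessibility predictions
#'
#' Softmax of the biological rates alone, evaluated from posterior-mean topic
#' compositions with running statistics: the technical-effect network is
#' zero-centered by construction, so dropping it yields the expected
#' composition free of batch-driven distortion. No covariate enters.
#'
#' @param model a trained `codal_model`.
#' @param Zbar cells-by-topics posterior mean compositions.
#' @return row-stochastic matrix of unconfounded compositions.
#' @export
disentangled_rates <- function(model, Zbar) {
  compose_rates(biological_rates(model, Zbar, training = FALSE))
}

# ---- Dirichlet prior --------------------------------------------------------

# Laplace approximation of Dirichlet(alpha) in the softmax basis:
# mean_k = log a_k - mean(log a); var_k = (1 - 2/K)/a_k + sum(1/a)/K^2.
dirichlet_laplace_moments <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  K <- length(alpha)
  la <- log(alpha)
  list(mean = la - mean(la),
       var = (1 - 2 / K) / alpha + sum(1 / alpha) / K^2)
}

# log of the Gamma(2, 2K/I) hyperprior density at alpha, in the log-alpha
# MAP parameterization (includes the log-Jacobian of the exp transform).
log_alpha_prior <- function(log_alpha, total_pseudocounts) {
  K <- length(log_alpha)
  shape <- 2; rate <- 2 * K / total_pseudocounts
  alpha <- exp(log_alpha)
  sum(shape * log_alpha - rate * alpha) # + const
}

grad_log_alpha_prior <- function(log_alpha, total_pseudocounts) {
  K <- length(log_alpha)
  rate <- 2 * K / total_pseudocounts
  2 - rate * exp(log_alpha)
}

# ---- forward sampling -------------------------------------------------------

#' Sample synthetic counts from the generative model
#'
#' Draws topic compositions from the Dirichlet prior (concentrations from the
#' Gamma hyperprior unless supplied), evaluates biological and technical
#' effects using whole-sample statistics, and samples counts from the
#' modality's noise distribution. The sampled truth (`Z`, `lambda`, `t`,
#' `rho`) is attached as attributes; the model's running statistics are
#' updated to the population values so eval-mode predictions line up with the
#' sampling distribution.
#'
#' @param model a `codal_model` (its current weights define the truth).
#' @param C covariate design (`n_cells` rows).
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @param alpha optional fixed Dirichlet concentration vector; default draws
#'   one from the Gamma(2, 2 * n_topics / total_pseudocounts) hyperprior.
#' @param depth_logmean,depth_logsd log-normal read-depth parameters.
#' @return list with `counts` (sparse dgCMatrix), updated `model`, and truth
#'   matrices `Z`, `lambda`, `t`, `rho`, `n`.
#' @export
sample_generative <- function(model, C, n_cells, seed = 0L, alpha = NULL,
                              depth_logmean = log(1500), depth_logsd = 0.3) {
  set.seed(derive_seed(seed, "gen"))
  K <- model$hyper$n_topics; G <- model$hyper$n_features
  C <- as.matrix(C)
  stopifnot(nrow(C) == n_cells)
  if (is.null(alpha)) {
    alpha <- rgamma(K, shape = 2, rate = 2 * K / model$hyper$total_pseudocounts)
    alpha <- pmax(alpha, 1e-3)
  }
  g <- matrix(rgamma(n_cells * K, shape = rep(alpha, each = n_cells)), n_cells)
  Z <- g / rowSums(g)

  dec <- decoder_fwd(Z, model$par, model$rs, training = TRUE)
  noise <- list(tech_zmask = NULL, tech_hmask = NULL, corrupt = NULL)
  tch <- tech_fwd(Z, C, model$par, model$rs, training = TRUE, noise, model$hyper)
  model$rs$dec <- dec$rs_dec
  model$rs$tech_h <- tch$rs_tech_h
  model$rs$tech_out <- tch$rs_tech_out
  # population stats == running stats for downstream eval-mode use
  model$rs$dec$rmean <- colMeans(Z %*% model$par$beta)
  model$rs$dec$rvar <- apply(Z %*% model$par$beta, 2, function(x) mean((x - mean(x))^2))

  lambda <- dec$lambda
  t_eff <- tch$t
  rho <- compose_rates(lambda, t_eff)
  if (model$modality == "RNA") {
    n <- rlnorm(n_cells, depth_logmean, depth_logsd)
    theta <- exp(model$par$log_theta)
    counts <- matrix(rnbinom(n_cells * G, size = rep(theta, each = n_cells),
                             mu = rho * n), n_cells)
  } else {
    n <- round(rlnorm(n_cells, depth_logmean, depth_logsd))
    counts <- t(vapply(seq_len(n_cells),
                       function(i) as.numeric(rmultinom(1, n[i], rho[i, ])),
                       numeric(G)))
    counts <- (counts > 0) * 1
  }
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  list(counts = counts, model = model, Z = Z, lambda = lambda, t = t_eff,
       rho = rho, n = n, alpha = alpha)
}
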