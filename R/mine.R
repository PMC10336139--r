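# Neural mutual-information estimation: a small critic network held
# 1-Lipschitz by spectral normalization, the Donsker-Varadhan minibatch lower
# bound computed over all m^2 cross-pairings, and the Wasserstein-form
# diagnostic. The critic scores pairs (lambda_i, t_j); because its first layer
# is linear in the concatenated input, all m^2 first-layer pre-activations are
# assembled from two m-by-64 products rather than an (m^2)-by-2G input.

CRITIC_HIDDEN <- 64L

#' Create a mutual-information critic
#'
#' @param n_features width of each of the two input blocks (genes/peaks).
#' @param input_dropout dropout rate on the critic input (default 0: off).
#' @param seed initialization seed.
#' @return an object of class `codal_critic`.
#' @export
new_critic <- function(n_features, input_dropout = 0, seed = 0L) {
  set.seed(derive_seed(seed, "critic"))
  H <- CRITIC_HIDDEN
  st <- list(
    par = list(
      W0 = glorot(2L * n_features, H), b0 = rep(0, H),
      W1 = glorot(H, H), b1 = rep(0, H),
      W2 = glorot(H, 1L), b2 = 0
    ),
    u = list(W0 = NULL, W1 = NULL, W2 = NULL),
    n_features = n_features,
    input_dropout = input_dropout
  )
  spectral_normalize(structure(st, class = "codal_critic"), n_iter = 20)
}

#' Spectrally normalize critic weights
#'
#' Divides each weight matrix by its leading singular value, estimated by
#' power iteration with persistent vectors (at least one iteration per call),
#' enforcing the 1-Lipschitz contract. Biases are untouched (they do not
#' affect the Lipschitz constant).
#'
#' @param critic a `codal_critic`.
#' @param n_iter power iterations per weight matrix (default 1).
#' @return the normalized critic.
#' @export
spectral_normalize <- function(critic, n_iter = 1) {
  for (nm in c("W0", "W1", "W2")) {
    W <- critic$par[[nm]]
    u <- critic$u[[nm]]
    if (is.null(u)) u <- rnorm(ncol(W))
    for (i in seq_len(max(1L, n_iter))) {
      v <- as.numeric(W %*% u)
      v <- v / max(sqrt(sum(v^2)), 1e-12)
      u <- as.numeric(crossprod(W, v))
      u <- u / max(sqrt(sum(u^2)), 1e-12)
    }
    sigma <- as.numeric(v %*% W %*% u)
    critic$par[[nm]] <- W / max(abs(sigma), 1e-12)
    critic$u[[nm]] <- u
  }
  critic
}

# Forward pass over all m x m pairings; returns the score matrix S (S[i,j] =
# T(lambda_i, t_j)) with caches for backprop. Dropout mask is drawn by the
# caller (NULL = off).
critic_pair_scores <- function(critic, lambda, t, drop_mask = NULL) {
  par <- critic$par
  m <- nrow(lambda)
  H <- CRITIC_HIDDEN
  G <- critic$n_features
  lam_in <- lambda; t_in <- t
  if (!is.null(drop_mask)) {
    p <- critic$input_dropout
    lam_in <- lambda * drop_mask$lam / (1 - p)
    t_in <- t * drop_mask$t / (1 - p)
  }
  A <- lam_in %*% par$W0[seq_len(G), , drop = FALSE]            # m x H
  B <- t_in %*% par$W0[G + seq_len(G), , drop = FALSE]          # m x H
  # pre-activation for pair (i,j): A[i,] + B[j,] + b0, laid out with i fastest
  pre0 <- A[rep(seq_len(m), times = m), , drop = FALSE] +
    B[rep(seq_len(m), each = m), , drop = FALSE]
  pre0 <- cadd(pre0, par$b0)
  h0 <- relu_fwd(pre0)
  pre1 <- cadd(h0$out %*% par$W1, par$b1)
  h1 <- relu_fwd(pre1)
  S <- matrix(as.numeric(h1$out %*% par$W2) + par$b2, m, m)
  list(S = S, cache = list(lam_in = lam_in, t_in = t_in, h0 = h0, h1 = h1,
                           m = m, G = G, drop_mask = drop_mask))
}

# Backward from dS (m x m) to critic parameters and to lambda/t rows.
critic_pair_bwd <- function(dS, cache, critic) {
  par <- critic$par
  m <- cache$m; G <- cache$G
  dvec <- as.numeric(dS) # pair (i,j) at index (j-1)*m + i
  dh1 <- outer(dvec, as.numeric(par$W2))
  db2 <- sum(dvec)
  dW2 <- crossprod(cache$h1$out, dvec)
  dpre1 <- relu_bwd(dh1, cache$h1$cache)
  dW1 <- crossprod(cache$h0$out, dpre1)
  db1 <- colSums(dpre1)
  dh0 <- dpre1 %*% t(par$W1)
  dpre0 <- relu_bwd(dh0, cache$h0$cache)
  db0 <- colSums(dpre0)
  # collapse the pair dimension back onto rows of lambda (i) and t (j)
  i_idx <- rep(seq_len(m), times = m)
  j_idx <- rep(seq_len(m), each = m)
  dA <- rowsum(dpre0, i_idx)                                    # m x H
  dB <- rowsum(dpre0, j_idx)
  Wl <- par$W0[seq_len(G), , drop = FALSE]
  Wt <- par$W0[G + seq_len(G), , drop = FALSE]
  dlam <- dA %*% t(Wl)
  dt <- dB %*% t(Wt)
  dW0 <- rbind(crossprod(cache$lam_in, dA), crossprod(cache$t_in, dB))
  if (!is.null(cache$drop_mask)) {
    p <- critic$input_dropout
    dlam <- dlam * cache$drop_mask$lam / (1 - p)
    dt <- dt * cache$drop_mask$t / (1 - p)
  }
  list(grads = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dlam = dlam, dt = dt)
}

#' Critic score for one (biological, technical) pair
#'
#' @param critic a `codal_critic`.
#' @param lambda,t numeric vectors (or single-row matrices) of matching width.
#' @return scalar score.
#' @export
critic_score <- function(critic, lambda, t) {
  lambda <- matrix(lambda, nrow = 1); t <- matrix(t, nrow = 1)
  if (ncol(lambda) != critic$n_features || ncol(t) != critic$n_features) {
    stop("critic input width mismatch", call. = FALSE)
  }
  critic_pair_scores(critic, lambda, t)$S[1, 1]
}

# core estimate + cache; exported wrappers below
mine_forward <- function(critic, lambda, t, drop_mask = NULL) {
  cs <- critic_pair_scores(critic, lambda, t, drop_mask)
  S <- cs$S
  m <- nrow(S)
  lme <- logsumexp(S) - log(m^2)        # log mean exp over all pairs
  est <- mean(diag(S)) - lme
  list(estimate = est, S = S, cache = cs$cache, lme = lme)
}

# dMINE/dS: diagonal paired term minus all-pairs softmax
mine_dS <- function(S) {
  m <- nrow(S)
  P <- exp(S - max(S))
  P <- P / sum(P)
  D <- -P
  diag(D) <- diag(D) + 1 / m
  D
}

#' Minibatch MINE lower bound on mutual information
#'
#' Donsker-Varadhan estimate over a minibatch of paired samples: the mean
#' paired critic score minus the log of the mean of `exp` scores over all
#' m-by-m cross-pairings, computed with log-sum-exp stabilization. A constant
#' critic gives exactly zero.
#'
#' @param critic a `codal_critic`.
#' @param lambda,t m-by-features matrices of paired samples (`m >= 2`).
#' @return scalar estimate.
#' @export
mine_estimate <- function(critic, lambda, t) {
  lambda <- as_dense(lambda); t <- as_dense(t)
  if (nrow(lambda) < 2) stop("need at least 2 samples", call. = FALSE)
  mine_forward(critic, lambda, t)$estimate
}

#' Wasserstein-form dependence diagnostic
#'
#' The Kantorovich-dual style minibatch bound: mean paired score minus the
#' mean over rows of `log sum_j exp` of the cross scores. For a constant
#' critic this equals `-log(m)`.
#'
#' @inheritParams mine_estimate
#' @return scalar diagnostic value.
#' @export
wasserstein_bound <- function(critic, lambda, t) {
  lambda <- as_dense(lambda); t <- as_dense(t)
  S <- critic_pair_scores(critic, lambda, t)$S
  m <- nrow(S)
  if (m == 1) return(0)
  mean(diag(S)) - mean(apply(S, 1, logsumexp))
}

#' One gradient-ascent update of the critic
#'
#' Takes one Adam ascent step on the MINE estimate (learning rate `1e-4` by
#' default, no weight decay) and re-applies spectral normalization, as done
#' once per training step.
#'
#' @param critic a `codal_critic`.
#' @param lambda,t detached m-by-features sample matrices.
#' @param opt_state optimizer state environment (`new_opt_state()`).
#' @param lr Adam learning rate.
#' @return updated critic (estimate in attribute `"estimate"`).
#' @export
update_critic <- function(critic, lambda, t, opt_state, lr = 1e-4) {
  fw <- mine_forward(critic, lambda, t)
  dS <- mine_dS(fw$S)
  bw <- critic_pair_bwd(dS, fw$cache, critic)
  grads <- lapply(bw$grads, function(g) -g) # ascent
  critic$par <- adam_step(critic$par, grads, opt_state, lr, wd = 0)
  critic <- spectral_normalize(critic)
  attr(critic, "estimate") <- fw$estimate
  critic
}

# Leading singular values of the (normalized) critic weights.
critic_spectral_norms <- function(critic) {
  vapply(critic$par[c("W0", "W1", "W2")],
         function(W) svd(W, nu = 0, nv = 0)$d[1], numeric(1))
}
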