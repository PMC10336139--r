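# The training objective (annealed ELBO minus the weighted mutual-information
# bound), its hand-derived gradient, the cyclical annealing and one-cycle
# optimizer schedules, the learning-rate range test, and the main fit loop.

#' Annealing weights for the objective terms
#'
#' Cyclic schedule over three cycles: the mutual-information weight follows
#' the sawtooth `r(s) = min(1, 2 * mod(s, L) / L)` with cycle length
#' `L = s_total / 3`, ramping to 1 by mid-cycle; the KL weight follows the
#' step-up variant `(1/3) * ceil(s / L) * r(s)`, so its cycle maxima are 1/3,
#' 2/3 and 1. Cycle boundaries are computed in real arithmetic.
#'
#' @param s current step (1-based).
#' @param s_total total number of steps.
#' @param n_cycles number of annealing cycles (default 3).
#' @return list with `eps1` (KL weight) and `eps2` (MI weight).
#' @export
anneal_weights <- function(s, s_total, n_cycles = 3) {
  L <- s_total / n_cycles
  r <- pmin(1, 2 * (s %% L) / L)
  list(eps1 = (1 / n_cycles) * ceiling(s / L) * r, eps2 = r)
}

# One-cycle learning-rate policy: cosine ramp lr_min -> lr_max over the first
# `pct` of steps, cosine decay back to lr_min after; momentum inversely
# annealed within [m_min, m_max].
one_cycle <- function(s, s_total, lr_min, lr_max, pct = 0.3,
                      m_min = 0.85, m_max = 0.95) {
  frac <- min(1, s / s_total)
  if (frac <= pct) {
    u <- (1 - cos(pi * frac / pct)) / 2
  } else {
    u <- (1 + cos(pi * (frac - pct) / (1 - pct))) / 2
  }
  list(lr = lr_min + (lr_max - lr_min) * u,
       momentum = m_max - (m_max - m_min) * u)
}

draw_step_noise <- function(m, hyper, modality, n_peaks = NULL) {
  noise <- draw_tech_noise(m, hyper)
  noise$dec_mask <- if (hyper$dropout > 0)
    matrix(rbinom(m * hyper$n_topics, 1L, 1 - hyper$dropout), m) else NULL
  noise <- c(noise, draw_enc_noise(m, hyper, modality))
  if (modality == "ATAC") {
    noise$peak_keep <- matrix(rbinom(m * n_peaks, 1L, 1 - 1 / 20), m)
  }
  noise$eps_topic <- NULL # drawn against matrix dims below
  noise
}

# Full objective forward + backward for one minibatch. `batch` carries dense
# counts X (m x G), covariates C, and (RNA) deviance residuals and observed
# log-depths. Returns the objective value (to be maximized), its components,
# gradients w.r.t. all model parameters, updated running statistics, and the
# detached (lambda, t) draws for the critic step.
objective_step <- function(par, rs, hyper, modality, batch, critic,
                           eps1, eps2, mi_weight, noise, training = TRUE,
                           n_total = nrow(batch$X), want_grads = TRUE) {
  m <- nrow(batch$X)
  K <- hyper$n_topics
  alpha <- exp(par$log_alpha)

  # --- encode ---
  if (modality == "RNA") {
    enc <- enc_rna_fwd(batch$Xres, batch$C, par, rs, training, noise, hyper)
  } else {
    enc <- enc_atac_fwd(batch$X, batch$C, par, rs, training, noise, hyper)
  }
  post <- enc$post

  # --- reparameterized draws ---
  y <- post$topic_mu + exp(0.5 * post$topic_logvar) * noise$eps_topic
  sm <- softmax_fwd(y)
  Z <- sm$out
  if (modality == "RNA") {
    dn <- post$depth_mu + exp(0.5 * post$depth_logvar) * noise$eps_depth
    n_i <- exp(clamp(dn, -30, 30))
  }

  # --- decode ---
  dec <- decoder_fwd(Z, par, rs, training, noise$dec_mask, hyper$dropout)
  tch <- tech_fwd(Z, batch$C, par, rs, training, noise, hyper)
  lambda <- dec$lambda
  t_eff <- tch$t
  logits <- lambda + t_eff
  rho_sm <- softmax_fwd(logits)
  rho <- rho_sm$out

  # --- likelihood ---
  if (modality == "RNA") {
    theta <- exp(par$log_theta)
    th <- rep(theta, each = m)
    mu <- rho * n_i
    recon <- sum(lgamma(batch$X + th) - lgamma(th) - lgamma(batch$X + 1) +
                   th * log(th) - th * log(th + mu) + xlogy(batch$X, mu) -
                   batch$X * log(th + mu)) / m
  } else {
    recon <- sum(xlogy(batch$X, rho)) / m
  }

  # --- KL terms and hyperprior ---
  klt <- sum(kl_to_prior(post, alpha)) / m
  kld <- if (modality == "RNA")
    sum(depth_kl(post$depth_mu, post$depth_logvar, batch$log_depth)) / m else 0
  lp_alpha <- log_alpha_prior(par$log_alpha, hyper$total_pseudocounts) / n_total

  # --- MINE term (one estimate per step, shared by model and critic grads) ---
  mine_fw <- if (mi_weight != 0) mine_forward(critic, lambda, t_eff) else NULL
  mine_val <- if (is.null(mine_fw)) 0 else mine_fw$estimate

  value <- recon - eps1 * (klt + kld) + eps1 * lp_alpha -
    eps2 * mi_weight * mine_val

  rs2 <- rs
  rs2$dec <- dec$rs_dec; rs2$tech_h <- tch$rs_tech_h; rs2$tech_out <- tch$rs_tech_out
  for (nm in names(enc$rs)) rs2[[nm]] <- enc$rs[[nm]]
  out <- list(value = value, recon = recon, kl = klt + kld, mine = mine_val,
              lambda = lambda, t = t_eff, rs = rs2)
  if (!want_grads) return(out)

  # ======== backward (gradient of `value`) ========
  grads <- list()

  # likelihood -> logits (and size factor / dispersion for RNA)
  if (modality == "RNA") {
    dll_dmu <- nb_dll_dmu(batch$X, mu, th) / m
    drho <- dll_dmu * n_i
    dlogits <- softmax_bwd(drho, rho_sm$cache)
    ddn <- rowSums(dll_dmu * rho) * n_i
    grads$log_theta <- colSums(nb_dll_dtheta(batch$X, mu, th)) * theta / m
  } else {
    dlogits <- (batch$X - Matrix::rowSums(batch$X) * rho) / m
    dlogits <- as.matrix(dlogits)
  }

  # MINE -> lambda, t (model side) and critic parameters (ascent side)
  dlam_mine <- 0; dt_mine <- 0
  if (!is.null(mine_fw)) {
    dS <- mine_dS(mine_fw$S)
    mb <- critic_pair_bwd(dS, mine_fw$cache, critic)
    out$critic_grads <- mb$grads
    coef <- -eps2 * mi_weight
    if (coef != 0) {
      dlam_mine <- coef * mb$dlam
      dt_mine <- coef * mb$dt
    }
  }

  dlambda <- dlogits + dlam_mine
  dt <- dlogits + dt_mine

  db <- decoder_bwd(dlambda, dec$cache, par)
  tb <- tech_bwd(dt, tch$cache, par)
  grads$beta <- db$beta; grads$dec_gamma <- db$dec_gamma; grads$dec_beta <- db$dec_beta
  for (nm in c("tech_W0", "tech_b0", "tech_h_gamma", "tech_h_beta",
               "tech_W1", "tech_b1", "gamma_t")) grads[[nm]] <- tb[[nm]]

  # through the reparameterized composition into posterior params
  dZ <- db$dZ + tb$dZ
  dy <- softmax_bwd(dZ, sm$cache)
  kg <- kl_grads(post, alpha)
  dpost <- list(
    topic_mu = dy - eps1 * kg$dmu / m,
    topic_logvar = dy * noise$eps_topic * 0.5 * exp(0.5 * post$topic_logvar) -
      eps1 * kg$dlv / m
  )
  grads$log_alpha <- -eps1 * kg$dlog_alpha / m +
    eps1 * grad_log_alpha_prior(par$log_alpha, hyper$total_pseudocounts) / n_total

  if (modality == "RNA") {
    dkg <- depth_kl_grads(post$depth_mu, post$depth_logvar, batch$log_depth)
    dpost$depth_mu <- ddn - eps1 * dkg$dmu / m
    dpost$depth_logvar <- ddn * noise$eps_depth * 0.5 * exp(0.5 * post$depth_logvar) -
      eps1 * dkg$dlv / m
    eb <- enc_rna_bwd(dpost, enc$cache)
  } else {
    eb <- enc_atac_bwd(dpost, enc$cache)
  }
  out$grads <- c(grads, eb)
  out
}

#' Evaluate the training objective on a batch of cells
#'
#' Deterministic given `seed`: draws one reparameterized sample per cell and
#' returns the annealed objective and its components. Training mode uses
#' minibatch statistics and dropout noise; eval mode (default) uses running
#' statistics.
#'
#' @param model a `codal_model`.
#' @param critic a `codal_critic` (may be `NULL` when `mi_weight = 0`).
#' @param X counts (`codal_counts` or matrix rows).
#' @param C covariate design (`codal_design` or matrix).
#' @param eps1,eps2 KL and MI term weights.
#' @param mi_weight multiplier on the MI term.
#' @param seed integer seed for the Monte Carlo draw.
#' @return list with `value`, `recon`, `kl`, `mine`.
#' @export
codal_objective <- function(model, critic, X, C, eps1 = 1, eps2 = 1,
                            mi_weight = 1, seed = 0L) {
  Xm <- if (inherits(X, "codal_counts")) X$counts else X
  Cm <- if (inherits(C, "codal_design")) C$matrix else as.matrix(C)
  batch <- make_batch(Xm, Cm, model)
  set.seed(derive_seed(seed, "obj"))
  m <- nrow(batch$X)
  noise <- list(eps_topic = matrix(rnorm(m * model$hyper$n_topics), m),
                eps_depth = rnorm(m))
  if (is.null(critic)) critic <- new_critic(model$hyper$n_features, seed = seed)
  res <- objective_step(model$par, model$rs, model$hyper, model$modality, batch,
                        critic, eps1, eps2, mi_weight, noise, training = FALSE,
                        want_grads = FALSE)
  res[c("value", "recon", "kl", "mine")]
}

make_batch <- function(Xm, Cm, model) {
  Xd <- as_dense(Xm)
  if (model$modality == "RNA") {
    list(X = Xd, C = Cm,
         Xres = deviance_residuals_matrix(Xd, pi_hat = model$pi_hat),
         log_depth = log(pmax(rowSums(Xd), 1)))
  } else {
    list(X = (Xd > 0) * 1, C = Cm)
  }
}

#' Learning-rate range test
#'
#' Sweeps the learning rate geometrically over `[1e-6, 1]` while taking real
#' optimizer steps on successive minibatches, tracking the smoothed objective.
#' The upper bound is the rate at the steepest improvement before divergence
#' (loss exceeding 4x the best seen); the lower bound is `lr_max / 25`. Falls
#' back to `(4e-5, 1e-3)` with a warning if no stable region is found.
#'
#' @param X,C counts and covariate design.
#' @param n_topics number of topics for the probe model.
#' @param n_steps number of sweep steps (default 30).
#' @param batch_size minibatch size.
#' @param seed integer seed.
#' @param dropout decoder dropout for the probe model.
#' @return list with `lr_min` and `lr_max`.
#' @export
lr_range_test <- function(X, C, n_topics, n_steps = 30, batch_size = 128,
                          seed = 0L, dropout = 0.05) {
  fit0 <- fit_codal(X, C, n_topics = n_topics, dropout = dropout,
                    epochs = 1, batch_size = batch_size, seed = seed,
                    mi_weight = 0, lr = "sweep", sweep_steps = n_steps)
  sw <- fit0$lr_sweep
  loss <- -sw$value
  sm <- loss
  for (i in seq_along(sm)[-1]) sm[i] <- 0.7 * sm[i - 1] + 0.3 * loss[i]
  i_min <- which.min(sm)
  # first step where the smoothed loss exceeds twice its running best
  running_best <- cummin(sm)
  diverged <- which(sm > 2 * abs(running_best) + running_best)
  last <- if (length(diverged)) max(2L, min(diverged) - 1L) else length(sm)
  if (i_min <= 2 || all(diff(sm) >= 0)) {
    warning("no stable learning-rate region found; using defaults", call. = FALSE)
    return(list(lr_min = 1e-3 / 25, lr_max = 1e-3))
  }
  lr_max <- min(sw$lr[i_min] / 10, sw$lr[last])
  list(lr_min = lr_max / 25, lr_max = lr_max)
}

#' Fit a disentangling topic model
#'
#' Cyclical annealed minibatch gradient ascent on the objective
#' `reconstruction - eps1 * KL - eps2 * mi_weight * MINE`: per step the
#' schedules set the optimizer and term weights, the topic-model parameters
#' take one AdamW step, and the critic takes one Adam ascent step on the same
#' mutual-information estimate followed by spectral normalization.
#'
#' @param X a `codal_counts` (or cells-by-features matrix).
#' @param C a `codal_design` (or covariate matrix).
#' @param n_topics latent dimensionality.
#' @param dropout decoder dropout in `[0.05, 0.1]`.
#' @param mi_weight multiplier on the mutual-information term (0 gives a
#'   plain annealed topic-model VAE).
#' @param epochs passes over the data (default 24).
#' @param batch_size minibatch size (default 128).
#' @param lr `NULL` to run the learning-rate range test, or a numeric vector
#'   `c(lr_min, lr_max)`.
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param critic_lr Adam learning rate for the critic (default 1e-4).
#' @param seed integer seed controlling initialization, shuffling and all
#'   stochastic draws; two runs with the same seed are identical.
#' @param modality `"RNA"` or `"ATAC"` (taken from `X` when it is a
#'   `codal_counts`).
#' @param verbose print progress every few epochs.
#' @param sweep_steps internal (learning-rate sweep length).
#' @param epoch_callback optional `function(model, critic, epoch)` invoked
#'   after every epoch; returning `TRUE` stops training (used for rung
#'   scoring and pruning during hyperparameter search).
#' @return a trained `codal_model` with a per-step `log` data frame.
#' @export
fit_codal <- function(X, C, n_topics, dropout = 0.05, mi_weight = 1,
                      epochs = 24, batch_size = 128, lr = NULL,
                      weight_decay = 0.01, critic_lr = 1e-4, seed = 0L,
                      modality = NULL, verbose = FALSE, sweep_steps = 30,
                      epoch_callback = NULL) {
  if (inherits(X, "codal_counts")) {
    modality <- X$modality
    Xm <- X$counts
    feature_ids <- X$feature_ids
  } else {
    modality <- modality %||% "RNA"
    Xm <- X
    feature_ids <- colnames(X)
  }
  schema <- NULL
  if (inherits(C, "codal_design")) { schema <- C$schema; Cm <- C$matrix } else Cm <- as.matrix(C)
  n_cells <- nrow(Xm)
  stopifnot(nrow(Cm) == n_cells)

  lr_sweep_mode <- identical(lr, "sweep")
  if (is.null(lr)) {
    rt <- lr_range_test(X, C, n_topics, n_steps = sweep_steps,
                        batch_size = batch_size, seed = seed, dropout = dropout)
    lr <- c(rt$lr_min, rt$lr_max)
  }

  model <- new_codal_model(ncol(Xm), n_topics, ncol(Cm), modality = modality,
                           dropout = dropout, seed = seed)
  model$feature_ids <- feature_ids
  model$covariate_schema <- schema
  if (modality == "RNA") {
    model$pi_hat <- pmax(Matrix::colSums(Xm) / sum(Xm), 1e-12)
  }
  critic <- new_critic(ncol(Xm), seed = derive_seed(seed, "crit-init"))
  opt_model <- new_opt_state()
  opt_critic <- new_opt_state()

  n_batches <- ceiling(n_cells / batch_size)
  s_total <- if (lr_sweep_mode) sweep_steps else epochs * n_batches
  sweep_lrs <- if (lr_sweep_mode) exp(seq(log(1e-6), log(1), length.out = sweep_steps))
  log_rows <- vector("list", s_total)
  s <- 0L
  done <- FALSE
  for (epoch in seq_len(if (lr_sweep_mode) 1e9 else epochs)) {
    set.seed(derive_seed(seed, "perm", epoch))
    perm <- sample(n_cells)
    for (b in seq_len(n_batches)) {
      s <- s + 1L
      idx <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, n_cells)]
      if (length(idx) < 2L) next
      batch <- make_batch(Xm[idx, , drop = FALSE], Cm[idx, , drop = FALSE], model)
      aw <- anneal_weights(s, s_total)
      if (lr_sweep_mode) {
        step_lr <- sweep_lrs[s]; step_mom <- 0.9
        aw <- list(eps1 = 1, eps2 = 0)
      } else {
        oc <- one_cycle(s, s_total, lr[1], lr[2])
        step_lr <- oc$lr; step_mom <- oc$momentum
      }
      set.seed(derive_seed(seed, "step", s))
      m <- length(idx)
      noise <- draw_step_noise(m, model$hyper, modality,
                               n_peaks = model$hyper$n_features)
      noise$eps_topic <- matrix(rnorm(m * n_topics), m)
      noise$eps_depth <- rnorm(m)

      res <- objective_step(model$par, model$rs, model$hyper, modality, batch,
                            critic, aw$eps1, aw$eps2, mi_weight, noise,
                            training = TRUE, n_total = n_cells)
      if (!is.finite(res$value)) {
        stop(sprintf("non-finite objective at step %d (recon=%.3g kl=%.3g mine=%.3g)",
                     s, res$recon, res$kl, res$mine), call. = FALSE)
      }
      model$rs <- res$rs
      grads <- lapply(res$grads, function(g) -g) # ascent via descent
      grads <- clip_grads(grads, 10)
      model$par <- adam_step(model$par, grads, opt_model, step_lr,
                             beta1 = step_mom, wd = weight_decay,
                             skip_decay = c("log_alpha", "log_theta", "dec_gamma",
                                            "dec_beta", "gamma_t", "tech_h_gamma",
                                            "tech_h_beta", "enc_g0", "enc_be0",
                                            "enc_g1", "enc_be1", "enc_g2", "enc_be2"))
      if (mi_weight != 0 && !is.null(res$critic_grads)) {
        critic$par <- adam_step(critic$par,
                                lapply(res$critic_grads, function(g) -g),
                                opt_critic, critic_lr, wd = 0)
        critic <- spectral_normalize(critic)
      }
      log_rows[[s]] <- data.frame(step = s, epoch = epoch, lr = step_lr,
                                  eps1 = aw$eps1, eps2 = aw$eps2,
                                  recon = res$recon, kl = res$kl,
                                  mine = res$mine, value = res$value)
      if (s >= s_total) { done <- TRUE; break }
    }
    if (!is.null(epoch_callback) && (b >= n_batches || done)) {
      tmp <- model
      tmp$train_config <- list(mi_weight = mi_weight)
      if (isTRUE(epoch_callback(tmp, critic, epoch))) done <- TRUE
    }
    if (done) break
    if (verbose && epoch %% 4 == 0) {
      message(sprintf("epoch %d/%d  objective %.2f", epoch, epochs, res$value))
    }
  }
  model$log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  model$critic <- critic
  model$mi_weight <- mi_weight
  model$train_config <- list(n_topics = n_topics, dropout = dropout,
                             mi_weight = mi_weight, epochs = epochs,
                             batch_size = batch_size, lr = lr, seed = seed)
  if (lr_sweep_mode) {
    model$lr_sweep <- data.frame(lr = sweep_lrs[seq_len(s)],
                                 value = model$log$value)
  }
  model
}

#' Evaluation-mode predictions from a trained model
#'
#' Convenience hook returning posterior-mean topics, biological rates,
#' technical effects, disentangled compositions, and the softmax denominator
#' (per-cell sum of `exp(lambda + t)`), all in eval mode.
#'
#' @param model a trained `codal_model`.
#' @param X,C counts and covariates.
#' @param n_samples posterior draws for the topic mean.
#' @param seed integer seed.
#' @return list with `Z`, `lambda`, `t`, `rho_bar`, `kappa`, `n`.
#' @export
predict_codal <- function(model, X, C, n_samples = 32, seed = 0L) {
  Xm <- if (inherits(X, "codal_counts")) X$counts else X
  Cm <- if (inherits(C, "codal_design")) C$matrix else as.matrix(C)
  Z <- posterior_mean_topics(model, Xm, Cm, n_samples = n_samples, seed = seed)
  lambda <- biological_rates(model, Z)
  t_eff <- technical_effects(model, Z, Cm)
  n <- if (model$modality == "RNA") {
    post <- encode_cells(model, Xm, Cm)
    exp(post$depth_mu + 0.5 * exp(post$depth_logvar))
  } else Matrix::rowSums(Xm > 0)
  list(Z = Z, lambda = lambda, t = t_eff,
       rho_bar = compose_rates(lambda),
       kappa = rowSums(exp(lambda + t_eff)), n = n)
}
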