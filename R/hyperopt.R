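# Bayesian hyperparameter search over (n_topics, dropout) with a Gaussian
# process surrogate over (hyperparameters, rung), percentile pruning at
# mid-training rungs, a pruning-aware expected-improvement acquisition, and
# constant-liar batched proposals for concurrent trials.

#' Create an empty trial ledger
#'
#' @param rung_epochs epochs at which trials are scored; the last entry is
#'   the final rung (default `c(8, 16, 24)`; pruning applies to earlier
#'   rungs only).
#' @param prune_quantile percentile (0-100) below which a trial is pruned at
#'   an intermediate rung (default 50).
#' @return an object of class `codal_ledger`.
#' @export
new_trial_ledger <- function(rung_epochs = c(8, 16, 24), prune_quantile = 50) {
  structure(list(trials = list(), rung_epochs = rung_epochs,
                 prune_quantile = prune_quantile),
            class = "codal_ledger")
}

#' Record a trial in the ledger
#'
#' @param ledger a `codal_ledger`.
#' @param H hyperparameter list (`n_topics`, `dropout`).
#' @param scores numeric vector of per-rung scores; `NA` beyond the rung at
#'   which the trial stopped.
#' @param status `"complete"`, `"pruned"`, `"running"` or `"failed"`.
#' @return the updated ledger.
#' @export
ledger_add <- function(ledger, H, scores, status) {
  n_rungs <- length(ledger$rung_epochs)
  sc <- rep(NA_real_, n_rungs)
  sc[seq_along(scores)] <- scores
  ledger$trials[[length(ledger$trials) + 1L]] <-
    list(H = H, scores = sc, status = status)
  ledger
}

#' @export
print.codal_ledger <- function(x, ...) {
  st <- vapply(x$trials, function(t) t$status, character(1))
  cat(sprintf("<codal_ledger> %d trials (%d complete, %d pruned), best %.4g\n",
              length(x$trials), sum(st == "complete"), sum(st == "pruned"),
              best_final_score(x)))
  invisible(x)
}

#' Tidy view of a trial ledger
#'
#' @param x a `codal_ledger`.
#' @param ... unused.
#' @return tibble with one row per trial.
#' @export
tidy.codal_ledger <- function(x, ...) {
  if (!length(x$trials)) return(tibble::tibble())
  tibble::tibble(
    trial = seq_along(x$trials),
    n_topics = vapply(x$trials, function(t) t$H$n_topics, numeric(1)),
    dropout = vapply(x$trials, function(t) t$H$dropout, numeric(1)),
    status = vapply(x$trials, function(t) t$status, character(1)),
    final_score = vapply(x$trials, function(t) tail(t$scores, 1), numeric(1))
  )
}

rung_scores <- function(ledger, r, statuses = c("complete", "pruned")) {
  sc <- vapply(ledger$trials, function(t)
    if (t$status %in% statuses) t$scores[r] else NA_real_, numeric(1))
  sc[!is.na(sc)]
}

best_final_score <- function(ledger) {
  n_rungs <- length(ledger$rung_epochs)
  sc <- rung_scores(ledger, n_rungs, statuses = "complete")
  if (length(sc)) return(max(sc))
  # bootstrap phase: best score seen at any rung minus one sd
  all_sc <- unlist(lapply(seq_len(n_rungs), function(r) rung_scores(ledger, r)))
  if (!length(all_sc)) return(-Inf)
  max(all_sc) - max(sd(all_sc), 1, na.rm = TRUE)
}

#' Pruning thresholds per intermediate rung
#'
#' The `q`-th percentile of all scores recorded at each rung before the
#' final one; `-Inf` (no pruning) where no score exists yet.
#'
#' @param ledger a `codal_ledger`.
#' @return numeric vector of length `n_rungs - 1`.
#' @export
pruning_thresholds <- function(ledger) {
  n_rungs <- length(ledger$rung_epochs)
  vapply(seq_len(n_rungs - 1L), function(r) {
    sc <- rung_scores(ledger, r)
    if (!length(sc)) -Inf else
      unname(quantile(sc, ledger$prune_quantile / 100, type = 7))
  }, numeric(1))
}

# ---- Gaussian process surrogate --------------------------------------------

matern52 <- function(X1, X2, ls) {
  X1s <- sweep(X1, 2, ls, "/"); X2s <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * X1s %*% t(X2s)
  r <- sqrt(pmax(d2, 0))
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

gp_nll <- function(theta, X, y) {
  d <- ncol(X)
  ls <- exp(theta[seq_len(d)]); s2 <- exp(theta[d + 1]); sn2 <- exp(theta[d + 2])
  K <- s2 * matern52(X, X, ls) + diag(sn2 + 1e-8, nrow(X))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

# Fit a GP with Matern-5/2 kernel (ARD lengthscales) by marginal likelihood.
gp_fit <- function(X, y, n_restarts = 2, seed = 0L) {
  d <- ncol(X)
  ymu <- mean(y); ysd <- max(sd(y), 1e-8)
  ys <- (y - ymu) / ysd
  set.seed(derive_seed(seed, "gp"))
  best <- NULL
  starts <- c(list(rep(0, d + 2)),
              lapply(seq_len(n_restarts), function(i) rnorm(d + 2, 0, 0.7)))
  for (th0 in starts) {
    op <- tryCatch(optim(th0, gp_nll, X = X, y = ys, method = "L-BFGS-B",
                         lower = rep(c(-4, -4, -9), c(d, 1, 1)),
                         upper = rep(c(4, 4, 2), c(d, 1, 1))),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  th <- best$par
  ls <- exp(th[seq_len(d)]); s2 <- exp(th[d + 1]); sn2 <- exp(th[d + 2])
  K <- s2 * matern52(X, X, ls) + diag(sn2 + 1e-8, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, ls = ls, s2 = s2, sn2 = sn2, chol = ch, alpha = alpha,
       ymu = ymu, ysd = ysd)
}

gp_predict <- function(gp, Xnew) {
  Ks <- gp$s2 * matern52(Xnew, gp$X, gp$ls)
  mu <- as.numeric(Ks %*% gp$alpha)
  w <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(gp$s2 - colSums(w^2), 1e-10)
  list(mean = mu * gp$ysd + gp$ymu, sd = sqrt(var) * gp$ysd)
}

scale_H <- function(H, box, rung, n_rungs) {
  c((H$n_topics - box$n_topics[1]) / max(1, diff(box$n_topics)),
    (H$dropout - box$dropout[1]) / max(1e-9, diff(box$dropout)),
    (rung - 1) / max(1, n_rungs - 1))
}

#' Fit the GP surrogate on a trial ledger
#'
#' All non-null (score, hyperparameters, rung) tuples are fitted jointly,
#' with inputs min-max scaled to `[0, 1]` and scores standardized. Running
#' trials are imputed at the final rung with the mean completed final score
#' (constant-liar strategy).
#'
#' @param ledger a `codal_ledger`.
#' @param box search box: list with `n_topics = c(lo, hi)` and
#'   `dropout = c(lo, hi)`.
#' @param seed integer seed for the hyperparameter restarts.
#' @return a `codal_surrogate` (GP state plus scaling info).
#' @export
fit_surrogate <- function(ledger, box, seed = 0L) {
  n_rungs <- length(ledger$rung_epochs)
  rows <- list(); ys <- numeric(0)
  comp_final <- rung_scores(ledger, n_rungs, statuses = "complete")
  liar <- if (length(comp_final)) mean(comp_final) else NA
  for (t in ledger$trials) {
    if (t$status == "failed") next
    for (r in seq_len(n_rungs)) {
      sc <- t$scores[r]
      if (is.na(sc) && t$status == "running" && r == n_rungs && !is.na(liar)) sc <- liar
      if (is.na(sc)) next
      rows[[length(rows) + 1L]] <- scale_H(t$H, box, r, n_rungs)
      ys <- c(ys, sc)
    }
  }
  if (length(ys) < 3) stop("not enough scores to fit the surrogate", call. = FALSE)
  X <- do.call(rbind, rows)
  structure(c(gp_fit(X, ys, seed = seed),
              list(box = box, n_rungs = n_rungs)),
            class = "codal_surrogate")
}

surrogate_moments <- function(surrogate, H, rung) {
  if (!is.null(surrogate$moments_fn)) return(surrogate$moments_fn(H, rung))
  x <- matrix(scale_H(H, surrogate$box, rung, surrogate$n_rungs), nrow = 1)
  p <- gp_predict(surrogate, x)
  list(mean = p$mean, sd = p$sd)
}

#' Pruning-aware expected improvement
#'
#' Classical expected improvement at the final rung, exploratory margin
#' `xi * |f_star|`, multiplied by the probability that the trial survives
#' every intermediate rung: the product over rungs of the GP probability of
#' scoring above that rung's pruning threshold (rungs treated as
#' independent).
#'
#' @param H hyperparameter list.
#' @param surrogate a fitted `codal_surrogate`.
#' @param thresholds intermediate-rung thresholds ([pruning_thresholds()]).
#' @param f_star incumbent best final score.
#' @param xi exploration margin (default 0.1).
#' @return nonnegative scalar.
#' @export
expected_improvement_pruned <- function(H, surrogate, thresholds, f_star,
                                        xi = 0.1) {
  n_rungs <- surrogate$n_rungs
  survival <- 1
  for (r in seq_len(n_rungs - 1L)) {
    if (!is.finite(thresholds[r])) next
    mom <- surrogate_moments(surrogate, H, r)
    survival <- survival * pnorm(-(thresholds[r] - mom$mean) / mom$sd)
  }
  momF <- surrogate_moments(surrogate, H, n_rungs)
  target <- f_star + xi * abs(f_star)
  if (momF$sd <= 0) {
    ei <- max(0, momF$mean - target)
  } else {
    u <- (momF$mean - target) / momF$sd
    ei <- momF$sd * (u * pnorm(u) + dnorm(u))
  }
  survival * ei
}

sample_box <- function(box, n, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "box"))
  lapply(seq_len(n), function(i) list(
    n_topics = sample(box$n_topics[1]:box$n_topics[2], 1),
    dropout = runif(1, box$dropout[1], box$dropout[2])
  ))
}

#' Propose the next hyperparameter set
#'
#' Before `n_startup` non-running trials exist, draws uniformly from the
#' search box; afterwards evaluates the pruning-aware expected improvement on
#' `n_candidates` uniform draws and returns the argmax. Deterministic given
#' the ledger and seed.
#'
#' @param ledger a `codal_ledger`.
#' @param box search box (see [fit_surrogate()]).
#' @param n_candidates candidate draws (default 300).
#' @param seed integer seed.
#' @param n_startup random startup trials (default 15).
#' @param surrogate optionally a pre-fitted surrogate (refit otherwise).
#' @param xi exploration margin.
#' @return hyperparameter list with attribute `"acquisition"`.
#' @export
propose_next <- function(ledger, box, n_candidates = 300, seed = 0L,
                         n_startup = 15, surrogate = NULL, xi = 0.1) {
  n_done <- sum(vapply(ledger$trials, function(t)
    t$status %in% c("complete", "pruned"), logical(1)))
  if (n_done < n_startup) {
    return(sample_box(box, 1, seed = derive_seed(seed, "startup", length(ledger$trials)))[[1]])
  }
  if (is.null(surrogate)) surrogate <- fit_surrogate(ledger, box, seed = seed)
  thresholds <- pruning_thresholds(ledger)
  f_star <- best_final_score(ledger)
  cands <- sample_box(box, n_candidates, seed = derive_seed(seed, "cand", length(ledger$trials)))
  eis <- vapply(cands, expected_improvement_pruned, numeric(1),
                surrogate = surrogate, thresholds = thresholds,
                f_star = f_star, xi = xi)
  H <- cands[[which.max(eis)]]
  attr(H, "acquisition") <- max(eis)
  H
}

# ---- trials -----------------------------------------------------------------

#' Run one hyperparameter trial
#'
#' Trains a model with the given hyperparameters on the train split,
#' evaluating the objective on the held-out split at each rung epoch; the
#' trial is pruned when an intermediate-rung score falls below the ledger's
#' current threshold.
#'
#' @param H hyperparameter list (`n_topics`, `dropout`).
#' @param X,C counts and design.
#' @param split list with `train`/`test` index vectors
#'   ([stratified_split()]).
#' @param ledger the current `codal_ledger` (for thresholds).
#' @param train_config list of [fit_codal()] arguments (`epochs` is taken
#'   from the final rung).
#' @param seed integer seed.
#' @return list with `scores`, `status`, and the fitted `model` (complete
#'   trials only).
#' @export
run_trial <- function(H, X, C, split, ledger, train_config = list(), seed = 0L) {
  Xm <- if (inherits(X, "codal_counts")) X$counts else X
  Cm <- if (inherits(C, "codal_design")) C$matrix else as.matrix(C)
  rungs <- ledger$rung_epochs
  thresholds <- pruning_thresholds(ledger)
  Xtr <- Xm[split$train, , drop = FALSE]; Ctr <- Cm[split$train, , drop = FALSE]
  Xte <- Xm[split$test, , drop = FALSE]; Cte <- Cm[split$test, , drop = FALSE]
  scores <- numeric(0); pruned <- FALSE
  mw <- train_config$mi_weight %||% 1
  cb <- function(model, critic, epoch) {
    ri <- match(epoch, rungs)
    if (is.na(ri)) return(FALSE)
    sc <- codal_objective(model, critic, Xte, Cte, mi_weight = mw,
                          seed = derive_seed(seed, "rung", ri))$value
    scores[ri] <<- sc
    if (ri < length(rungs) && is.finite(thresholds[ri]) && sc < thresholds[ri]) {
      pruned <<- TRUE
      return(TRUE)
    }
    FALSE
  }
  args <- c(list(X = Xtr, C = Ctr, n_topics = H$n_topics, dropout = H$dropout,
                 epochs = max(rungs), seed = seed, epoch_callback = cb),
            train_config)
  args <- args[!duplicated(names(args))]
  model <- tryCatch(do.call(fit_codal, args), error = function(e) e)
  if (inherits(model, "error")) {
    return(list(scores = scores, status = "failed", model = NULL,
                message = conditionMessage(model)))
  }
  list(scores = scores,
       status = if (pruned) "pruned" else "complete",
       model = if (pruned) NULL else model)
}

#' Tune hyperparameters with pruning-aware Bayesian optimization
#'
#' Splits the data 4:1 (stratified), runs `n_startup` random trials, then
#' proposes candidates by pruning-aware expected improvement in constant-liar
#' batches of `workers`. Stops after `min_trials` once `patience` consecutive
#' trials bring no improvement, or at `max_trials`.
#'
#' @param X,C counts and design.
#' @param topic_range integer range `c(lo, hi)` for the number of topics.
#' @param dropout_range decoder dropout box (default `c(0.05, 0.1)`).
#' @param min_trials,patience,max_trials stopping rule (defaults 48, 12, 128).
#' @param workers proposals per constant-liar batch (default 5).
#' @param n_startup random startup trials (default 15).
#' @param ratio train fraction for the split (default 0.8).
#' @param train_config extra [fit_codal()] arguments.
#' @param rung_epochs scoring epochs (default `c(8, 16, 24)`).
#' @param trainer optional function `(H, ledger, seed)` returning
#'   `list(scores, status, model)`; replaces real training (used for tuner
#'   benchmarking with synthetic objectives).
#' @param seed integer seed.
#' @return list with `best_H`, `best_model`, `best_score`, and the `ledger`.
#' @export
tune_codal <- function(X = NULL, C = NULL, topic_range, dropout_range = c(0.05, 0.1),
                       min_trials = 48, patience = 12, max_trials = 128,
                       workers = 5, n_startup = 15, ratio = 0.8,
                       train_config = list(), rung_epochs = c(8, 16, 24),
                       trainer = NULL, seed = 0L) {
  box <- list(n_topics = topic_range, dropout = dropout_range)
  ledger <- new_trial_ledger(rung_epochs = rung_epochs)
  if (is.null(trainer)) {
    stopifnot(!is.null(X), !is.null(C))
    Xc <- if (inherits(X, "codal_counts")) X else codal_counts(X)
    Cd <- if (inherits(C, "codal_design")) C else
      encode_covariates(data.frame(batch = rep("all", nrow(Xc$counts))), categorical = "batch")
    split <- stratified_split(Xc, Cd, ratio = ratio, seed = seed)
    trainer <- function(H, ledger, trial_seed) {
      run_trial(H, Xc, Cd, split, ledger, train_config = train_config,
                seed = trial_seed)
    }
  }
  best <- -Inf; best_H <- NULL; best_model <- NULL
  last_improve <- 0L
  n <- 0L
  while (n < max_trials) {
    batch_n <- min(workers, max_trials - n)
    proposals <- list()
    lhat <- ledger
    for (w in seq_len(batch_n)) {
      H <- propose_next(lhat, box, seed = derive_seed(seed, "prop", n + w))
      proposals[[w]] <- H
      lhat <- ledger_add(lhat, H, numeric(0), "running")
    }
    for (H in proposals) {
      n <- n + 1L
      res <- trainer(H, ledger, derive_seed(seed, "trial", n))
      ledger <- ledger_add(ledger, H, res$scores, res$status)
      if (res$status == "complete") {
        final <- tail(res$scores, 1)
        if (is.finite(final) && final > best) {
          best <- final; best_H <- H; best_model <- res$model
          last_improve <- n
        }
      }
      if (n >= max_trials) break
    }
    if (n >= min_trials && (n - last_improve) >= patience) break
  }
  if (is.null(best_H)) stop("all trials failed", call. = FALSE)
  list(best_H = best_H, best_model = best_model, best_score = best,
       ledger = ledger)
}

# ---- ledger serialization ---------------------------------------------------

#' Write / read a trial ledger as JSON
#'
#' @param ledger a `codal_ledger`.
#' @param path file path.
#' @return `path` invisibly; `read_trial_ledger` returns the ledger.
#' @export
write_trial_ledger <- function(ledger, path) {
  jsonlite::write_json(
    list(rung_epochs = ledger$rung_epochs,
         prune_quantile = ledger$prune_quantile,
         trials = lapply(ledger$trials, function(t)
           list(H = t$H, scores = t$scores, status = t$status))),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_trial_ledger
#' @export
read_trial_ledger <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  led <- new_trial_ledger(rung_epochs = unlist(j$rung_epochs),
                          prune_quantile = j$prune_quantile)
  for (t in j$trials) {
    sc <- vapply(t$scores, function(s) if (is.null(s)) NA_real_ else as.numeric(s), numeric(1))
    led <- ledger_add(led, list(n_topics = t$H$n_topics, dropout = t$H$dropout),
                      sc, t$status)
  }
  led
}
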