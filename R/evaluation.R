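# Diagnostics and benchmark metrics: silhouette widths on latent coordinates,
# per-gene entanglement correlations, the across-model variance
# decomposition, topic matching, and the MI-weight sweep harness.

#' Silhouette widths of labeled points
#'
#' Standard silhouette: for each point, `(b - a) / max(a, b)` where `a` is
#' the mean distance to its own cluster and `b` the smallest mean distance to
#' another cluster. Cells in singleton clusters score 0 with a warning.
#'
#' @param coords numeric matrix of coordinates (e.g. ILR).
#' @param labels cluster labels, one per row.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return list with per-cell `widths` and the mean `asw`.
#' @export
silhouette_widths <- function(coords, labels, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 labels", call. = FALSE)
  D <- as.matrix(dist(coords, method = metric))
  n <- nrow(D)
  sizes <- table(labels)
  if (any(sizes == 1)) warning("singleton cluster(s) scored 0", call. = FALSE)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[li]] == 1) { widths[i] <- 0; next }
    a <- sum(D[i, labels == li]) / (sizes[[li]] - 1)
    b <- min(vapply(setdiff(names(sizes), li),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(widths = widths, asw = mean(widths))
}

#' Per-gene correlation between biological and technical predictions
#'
#' Pearson correlation across cells, per gene, between predicted biological
#' rates and technical effects; the summary statistic is the median absolute
#' correlation (an entanglement measure: independent predictions give values
#' near 0). Genes with a constant column are reported as `NA`.
#'
#' @param lambda,t cells-by-genes matrices.
#' @return list with per-gene `r` and `median_abs_r`.
#' @export
disentanglement_correlation <- function(lambda, t) {
  stopifnot(all(dim(lambda) == dim(t)))
  r <- vapply(seq_len(ncol(lambda)), function(j) {
    lj <- lambda[, j]; tj <- t[, j]
    if (sd(lj) == 0 || sd(tj) == 0) return(NA_real_)
    cor(lj, tj)
  }, numeric(1))
  list(r = r, median_abs_r = median(abs(r), na.rm = TRUE))
}

#' Across-model variance decomposition
#'
#' Law of total variance over the model (seed) index of a cells-by-genes-by-
#' models array: per gene, the within term is the mean over cells of the
#' across-model (population) variance, the between term is the across-cell
#' variance of the across-model mean, and their sum equals the total variance
#' over all (cell, model) pairs exactly.
#'
#' @param stack 3-d array (cells x genes x models), models >= 2.
#' @return list with per-gene `within`, `between`, `total`, and the scalar
#'   `within_fraction` (sum within / sum total).
#' @export
variance_decomposition <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) stop("need a cells x genes x models array with >= 2 models", call. = FALSE)
  M <- d[3]
  mean_m <- apply(stack, c(1, 2), mean)             # across-model mean
  var_m <- apply(stack, c(1, 2), function(v) mean((v - mean(v))^2))
  within <- colMeans(var_m)
  between <- apply(mean_m, 2, function(v) mean((v - mean(v))^2))
  total <- within + between
  list(within = within, between = between, total = total,
       within_fraction = sum(within) / sum(total))
}

#' Match fitted topics to reference topics
#'
#' Correlates effective decoder loadings (loadings scaled by the per-feature
#' batchnorm gain over the population sd) row-by-row and finds the topic
#' permutation maximizing the mean correlation: exhaustive search for up to 8
#' topics (exact assignment), greedy matching beyond.
#'
#' @param ref,fit topics-by-features loading matrices (or `codal_model`s,
#'   from which effective loadings are taken).
#' @return list with `perm` (fit topic index for each reference topic),
#'   `cor` (matched per-topic correlations) and `mean_cor`.
#' @export
match_topics <- function(ref, fit) {
  B1 <- if (inherits(ref, "codal_model")) effective_loadings(ref) else ref
  B2 <- if (inherits(fit, "codal_model")) effective_loadings(fit) else fit
  K <- nrow(B1)
  stopifnot(nrow(B2) == K)
  R <- cor(t(B1), t(B2))
  if (K <= 8) {
    perms <- all_perms(K)
    sc <- apply(perms, 1, function(p) mean(R[cbind(seq_len(K), p)]))
    perm <- unname(perms[which.max(sc), ])
  } else {
    perm <- integer(K); taken <- logical(K)
    ord <- order(apply(R, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- order(R[i, ], decreasing = TRUE)
      j <- j[!taken[j]][1]
      perm[i] <- j; taken[j] <- TRUE
    }
  }
  matched <- R[cbind(seq_len(K), perm)]
  list(perm = perm, cor = matched, mean_cor = mean(matched))
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1))
  do.call(rbind, lapply(seq_len(k), function(i) {
    sub <- all_perms(k - 1)
    cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub)))
  }))
}

#' Effective decoder loadings
#'
#' Topic loadings on the per-feature standardized scale actually seen by the
#' softmax: `beta * gamma / sd`, using the decoder batchnorm's population
#' statistics. Comparable across models (raw loadings are only identified up
#' to the per-feature affine absorbed by batchnorm).
#'
#' @param model a trained `codal_model`.
#' @return topics-by-features matrix.
#' @export
effective_loadings <- function(model) {
  sc <- model$par$dec_gamma / sqrt(model$rs$dec$rvar + 1e-5)
  model$par$beta * rep(sc, each = model$hyper$n_topics)
}

#' Sweep the mutual-information weight
#'
#' Trains `n_models` models per MI weight on a fixed dataset (different
#' seeds, same split), collects biological and technical predictions into
#' repeat tensors, and reports per-weight variance decompositions, the
#' entanglement correlation, and a trajectory-quality proxy (adjusted Rand
#' index of k-means on ILR coordinates against true branch labels).
#'
#' @param X,C counts and design.
#' @param truth_branch true branch label per cell (for the ARI proxy), or
#'   `NULL` to skip.
#' @param weights MI weights to sweep (default `c(0, 0.5, 1, 2, 4, 8)`).
#' @param n_models fits per weight (default 10).
#' @param n_topics,epochs,lr,batch_size passed to [fit_codal()].
#' @param seed base seed; model `i` uses `seed + i`.
#' @return a `codal_sweep` list, one entry per weight, with fields
#'   `within_fraction_t`, `within_fraction_lambda`, `median_abs_r`, `ari`,
#'   plus the fold reduction of within-variance relative to weight 0.
#' @export
mi_weight_sweep <- function(X, C, truth_branch = NULL,
                            weights = c(0, 0.5, 1, 2, 4, 8), n_models = 10,
                            n_topics = 5, epochs = 24, lr = NULL,
                            batch_size = 128, seed = 0L) {
  Xm <- if (inherits(X, "codal_counts")) X$counts else X
  results <- list()
  if (is.null(lr)) {
    rt <- lr_range_test(X, C, n_topics, seed = seed)
    lr <- c(rt$lr_min, rt$lr_max)
  }
  for (w in weights) {
    lam_stack <- NULL; t_stack <- NULL; aris <- numeric(0); rmed <- numeric(0)
    for (i in seq_len(n_models)) {
      fit <- fit_codal(X, C, n_topics = n_topics, mi_weight = w,
                       epochs = epochs, batch_size = batch_size,
                       lr = lr, seed = derive_seed(seed, "sweep", w, i))
      pred <- predict_codal(fit, X, C, n_samples = 8,
                            seed = derive_seed(seed, "pred", w, i))
      if (is.null(lam_stack)) {
        lam_stack <- array(0, c(nrow(pred$lambda), ncol(pred$lambda), n_models))
        t_stack <- lam_stack
      }
      lam_stack[, , i] <- pred$lambda
      t_stack[, , i] <- pred$t
      rmed[i] <- disentanglement_correlation(pred$lambda, pred$t)$median_abs_r
      if (!is.null(truth_branch)) {
        co <- ilr_transform(pred$Z)
        km <- kmeans(co, centers = length(unique(truth_branch)), nstart = 10)
        aris[i] <- mclust::adjustedRandIndex(km$cluster, truth_branch)
      }
    }
    vd_t <- variance_decomposition(t_stack)
    vd_l <- variance_decomposition(lam_stack)
    results[[as.character(w)]] <- list(
      weight = w,
      within_t = sum(vd_t$within), within_fraction_t = vd_t$within_fraction,
      within_lambda = sum(vd_l$within),
      within_fraction_lambda = vd_l$within_fraction,
      within_t_gene = vd_t$within,
      median_abs_r = median(rmed), ari = if (length(aris)) aris else NA
    )
  }
  base_t <- results[[1]]$within_t
  for (w in names(results)) {
    results[[w]]$fold_reduction_t <- base_t / results[[w]]$within_t
  }
  structure(list(weights = weights, results = results,
                 config = list(n_models = n_models, n_topics = n_topics,
                               epochs = epochs, lr = lr, seed = seed)),
            class = "codal_sweep")
}

#' @export
print.codal_sweep <- function(x, ...) {
  cat("<codal_sweep>\n")
  for (r in x$results) {
    cat(sprintf("  weight %4.1f: within-var(t) %.4g (x%.1f vs 0), median |r| %.3f, ARI %s\n",
                r$weight, r$within_t, r$fold_reduction_t, r$median_abs_r,
                if (all(is.na(r$ari))) "-" else sprintf("%.2f", median(r$ari))))
  }
  invisible(x)
}

#' Serialize a sweep report to JSON
#'
#' @param x a `codal_sweep`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_report <- function(x, path) {
  jsonlite::write_json(
    list(weights = x$weights, config = x$config,
         results = lapply(x$results, function(r) r[setdiff(names(r), "within_t_gene")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy topic loadings of a fitted model
#'
#' @param x a `codal_model`.
#' @param ... unused.
#' @return tibble with columns `topic`, `feature`, `loading` (effective
#'   standardized loading).
#' @export
tidy.codal_model <- function(x, ...) {
  B <- effective_loadings(x)
  feats <- x$feature_ids %||% paste0("f", seq_len(ncol(B)))
  tibble::tibble(
    topic = rep(seq_len(nrow(B)), times = ncol(B)),
    feature = rep(feats, each = nrow(B)),
    loading = as.numeric(B)
  )
}

#' One-row fit summary
#'
#' @param x a `codal_model`.
#' @param ... unused.
#' @return tibble with the model dimensions and final objective components.
#' @export
glance.codal_model <- function(x, ...) {
  last <- tail(x$log, 1)
  tibble::tibble(
    modality = x$modality, n_topics = x$hyper$n_topics,
    n_features = x$hyper$n_features, mi_weight = x$mi_weight %||% NA_real_,
    steps = nrow(x$log), objective = last$value,
    recon = last$recon, kl = last$kl, mine = last$mine
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Training-trace plot
#'
#' Objective components and annealing weights per training step.
#'
#' @param model a fitted `codal_model`.
#' @return a ggplot object.
#' @export
plot_training <- function(model) {
  lg <- model$log
  df <- rbind(
    data.frame(step = lg$step, value = lg$recon, what = "reconstruction"),
    data.frame(step = lg$step, value = lg$kl, what = "KL"),
    data.frame(step = lg$step, value = lg$mine, what = "MINE"),
    data.frame(step = lg$step, value = lg$eps1, what = "eps1"),
    data.frame(step = lg$step, value = lg$eps2, what = "eps2")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}

#' MI-weight sweep plot
#'
#' Within-model technical-effect variance (log scale) and the entanglement
#' correlation against the MI weight.
#'
#' @param sweep a `codal_sweep`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  df <- do.call(rbind, lapply(sweep$results, function(r) {
    data.frame(weight = r$weight,
               value = c(r$within_t, r$median_abs_r),
               what = c("within-model variance of t",
                        "median |cor(lambda, t)|"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
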