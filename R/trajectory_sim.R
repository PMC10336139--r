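# Synthetic batch-confounded differentiation benchmarks: a tree-structured
# construction plan with k-parameterized cell-type mixing weights, Markov path
# sampling, sigmoidal interpolation along edges, and cell synthesis by
# hypergeometric read mixing from per-(batch, type) donor pools.

FC_TYPES <- c("HSC", "CD16+Mono", "B1B", "NK", "CD8+T", "pDC", "cDC2")

# Mixing weights stored symbolically as intercept + coefficient-of-k matrices
# so the unit-row-sum property can be checked algebraically for all k.
fc_weight_tables <- function() {
  nodes <- c("root", "1", "2", "3", "4", "5", "6", "7")
  W0 <- matrix(0, length(nodes), length(FC_TYPES),
               dimnames = list(nodes, FC_TYPES))
  Wk <- W0
  set_w <- function(node, type, const, coef = 0) {
    W0[node, type] <<- const; Wk[node, type] <<- coef
  }
  set_w("root", "HSC", 1)
  set_w("1", "HSC", 0.5)
  for (ty in c("CD16+Mono", "B1B", "NK", "CD8+T")) set_w("1", ty, 0.125)
  # monocyte/dendritic arm
  set_w("2", "HSC", 0.2, 1); set_w("2", "CD16+Mono", 0.4, -0.5)
  set_w("2", "pDC", 0.2, -0.25); set_w("2", "cDC2", 0.2, -0.25)
  # lymphoid arm (mirror structure)
  set_w("3", "HSC", 0.2, 1); set_w("3", "B1B", 0.4, -0.5)
  set_w("3", "NK", 0.2, -0.25); set_w("3", "CD8+T", 0.2, -0.25)
  set_w("4", "HSC", 0, 1); set_w("4", "CD16+Mono", 1, -2)
  set_w("4", "pDC", 0, 0.5); set_w("4", "cDC2", 0, 0.5)
  set_w("5", "HSC", 0, 1); set_w("5", "CD16+Mono", 0, 1)
  set_w("5", "pDC", 0.5, -1); set_w("5", "cDC2", 0.5, -1)
  set_w("6", "HSC", 0, 1); set_w("6", "B1B", 1, -2)
  set_w("6", "NK", 0, 0.5); set_w("6", "CD8+T", 0, 0.5)
  set_w("7", "HSC", 0, 1); set_w("7", "B1B", 0, 1)
  set_w("7", "NK", 0.5, -1); set_w("7", "CD8+T", 0.5, -1)
  list(W0 = W0, Wk = Wk)
}

#' Build a trajectory construction plan
#'
#' Tree of 8 nodes over 7 base cell types: a stem root, a branch point into
#' monocyte/dendritic and lymphoid arms, and four terminal states ("Mono",
#' "Dendritic", "B-cell", "T-cell"). `k` raises the baseline similarity of
#' all states (at `k = 0` terminal nodes are pure cell types); `p_tcell`
#' splits the lymphoid arm between the T-cell and B-cell terminals.
#'
#' @param k base cell-similarity parameter in `[0, 0.25]`.
#' @param p_tcell probability of the lymphoid arm terminating at "T-cell".
#' @return an object of class `codal_plan` with node weights (numeric and
#'   symbolic), edges and transition probabilities.
#' @export
build_plan <- function(k = 0.05, p_tcell = 0.5) {
  if (k < 0 || k > 0.25) stop("k must be in [0, 0.25]", call. = FALSE)
  if (p_tcell < 0 || p_tcell > 1) stop("p_tcell must be in [0, 1]", call. = FALSE)
  tb <- fc_weight_tables()
  W <- tb$W0 + k * tb$Wk
  if (any(W < -1e-12 | W > 1 + 1e-12)) {
    stop("mixing weights outside [0, 1] for k = ", k, call. = FALSE)
  }
  edges <- data.frame(
    from = c("root", "1", "1", "2", "2", "3", "3"),
    to = c("1", "2", "3", "4", "5", "6", "7"),
    prob = c(1, 0.4, 0.6, 0.5, 0.5, 1 - p_tcell, p_tcell),
    stringsAsFactors = FALSE
  )
  labels <- c(root = "HSC", `4` = "Mono", `5` = "Dendritic",
              `6` = "B-cell", `7` = "T-cell")
  structure(list(weights = W, sym = tb, edges = edges, k = k,
                 p_tcell = p_tcell, labels = labels,
                 terminals = c("4", "5", "6", "7"), types = FC_TYPES),
            class = "codal_plan")
}

#' @export
print.codal_plan <- function(x, ...) {
  cat(sprintf("<codal_plan> k=%.3g p_tcell=%.3g, %d nodes / %d base types\n",
              x$k, x$p_tcell, nrow(x$weights), length(x$types)))
  invisible(x)
}

#' Sample a root-to-terminal path and a progress value
#'
#' Follows the plan's Markov transition matrix from the root to a terminal
#' node and draws the cell's progress along that path from Beta(0.5, 1).
#'
#' @param plan a `codal_plan`.
#' @return list with `path` (node id vector) and `p` (progress in `[0, 1]`).
#' @export
sample_cell_path <- function(plan) {
  node <- "root"; path <- node
  while (!(node %in% plan$terminals)) {
    out <- plan$edges[plan$edges$from == node, ]
    node <- sample(out$to, 1, prob = out$prob)
    path <- c(path, node)
  }
  list(path = path, p = rbeta(1, 0.5, 1))
}

# Exact terminal-state probabilities by path enumeration (test oracle lives
# independently; this is the model's own account used for reporting).
terminal_probs <- function(plan) {
  c(`4` = 0.4 * 0.5, `5` = 0.4 * 0.5,
    `6` = 0.6 * (1 - plan$p_tcell), `7` = 0.6 * plan$p_tcell)
}

#' Interpolate mixing weights along a sampled path
#'
#' The progress fraction `p` locates the cell on one edge of its path (edges
#' split `[0, 1]` evenly); within the edge the start and end node weights are
#' blended with `delta = logistic(2 * p_edge - 1)`.
#'
#' @param plan a `codal_plan`.
#' @param path node id vector from [sample_cell_path()].
#' @param p progress in `[0, 1]`.
#' @return named mixing-weight vector over base cell types (sums to 1).
#' @export
interpolate_weights <- function(plan, path, p) {
  L <- length(path) - 1L
  e <- min(L, floor(p * L) + 1L)
  p_edge <- p * L - (e - 1L)
  delta <- 1 / (1 + exp(-(2 * p_edge - 1)))
  w <- plan$weights[path[e], ] * (1 - delta) + plan$weights[path[e + 1L], ] * delta
  w / sum(w)
}

# Largest-remainder rounding of N * pi to integer quotas summing to N.
round_quotas <- function(N, pi) {
  q <- N * pi
  fl <- floor(q)
  rem <- as.integer(round(N - sum(fl)))
  if (rem > 0) {
    add <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

# Multivariate hypergeometric draw: sample `k` reads without replacement from
# a donor's gene-count vector, by sequential conditional hypergeometrics.
mvhyper <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  left <- k
  nz <- which(counts > 0)
  for (j in nz) {
    if (left == 0) break
    x <- rhyper(1, counts[j], remaining - counts[j], left)
    out[j] <- x
    left <- left - x
    remaining <- remaining - counts[j]
  }
  out
}

#' Generate synthetic base cell-type populations
#'
#' Stand-in for pools of pure cells sampled from a real multi-batch dataset
#' (synthetic: no external reads required). Each type upregulates a disjoint
#' marker gene block over a shared baseline profile; batch 2 pools are
#' additionally distorted by gene-wise multiplicative log-normal technical
#' factors and a depth shift, emulating batch-specific technical effects.
#'
#' @param n_genes number of genes.
#' @param cells_per_pool donor cells per (batch, type) pool.
#' @param batch_effect_sd sd of the log-normal gene-wise batch-2 distortion.
#' @param depth_logmean,depth_logsd donor read-depth log-normal parameters.
#' @param depth_shift multiplicative batch-2 depth scale.
#' @param marker_fold fold-change of a type's marker block.
#' @param seed integer seed.
#' @param types base type names (default: the plan's 7 types).
#' @return an object of class `codal_basepops`: per-batch, per-type integer
#'   count matrices.
#' @export
synthetic_base_populations <- function(n_genes = 300, cells_per_pool = 60,
                                       batch_effect_sd = 0.3,
                                       depth_logmean = log(2500),
                                       depth_logsd = 0.25,
                                       depth_shift = 1.25, marker_fold = 8,
                                       seed = 0L, types = FC_TYPES) {
  set.seed(derive_seed(seed, "basepops"))
  n_types <- length(types)
  baseline <- exp(rnorm(n_genes, 0, 1))
  block <- floor(n_genes / n_types)
  profiles <- lapply(seq_len(n_types), function(ti) {
    r <- baseline
    idx <- ((ti - 1) * block + 1):(ti * block)
    r[idx] <- r[idx] * marker_fold
    r / sum(r)
  })
  names(profiles) <- types
  batch_factors <- exp(rnorm(n_genes, 0, batch_effect_sd))
  pools <- list()
  for (b in c("batch1", "batch2")) {
    pools[[b]] <- lapply(types, function(ty) {
      rate <- profiles[[ty]]
      if (b == "batch2") {
        rate <- rate * batch_factors
        rate <- rate / sum(rate)
      }
      dlm <- depth_logmean + if (b == "batch2") log(depth_shift) else 0
      depth <- pmax(50, round(rlnorm(cells_per_pool, dlm, depth_logsd)))
      mat <- t(vapply(depth, function(d) {
        as.integer(rnbinom(n_genes, size = 3, mu = d * rate))
      }, integer(n_genes)))
      mat
    })
    names(pools[[b]]) <- types
  }
  structure(list(pools = pools, types = types, n_genes = n_genes,
                 profiles = profiles, batch_factors = batch_factors),
            class = "codal_basepops")
}

#' Synthesize one cell by hypergeometric read mixing
#'
#' Draws a read depth from a log-normal, splits it into per-type quotas by
#' largest-remainder rounding of the mixing weights, picks one donor cell per
#' contributing type from the requested batch's pool, and samples each quota
#' from the donor's reads without replacement (falling back to sampling with
#' replacement only if 10 redrawn donors are all too shallow).
#'
#' @param pi_cell mixing weights over base types (sums to 1).
#' @param base a `codal_basepops`.
#' @param batch `"batch1"` or `"batch2"`.
#' @param depth_logmean,depth_logsd read-depth log-normal parameters.
#' @return integer gene-count vector; total reads equal the quota sum.
#' @export
synthesize_cell <- function(pi_cell, base, batch = "batch1",
                            depth_logmean = log(2000), depth_logsd = 0.3) {
  N <- max(20, round(rlnorm(1, depth_logmean, depth_logsd)))
  quotas <- round_quotas(N, pi_cell)
  out <- integer(base$n_genes)
  for (ti in which(quotas > 0)) {
    pool <- base$pools[[batch]][[base$types[ti]]]
    q <- quotas[ti]
    donor <- NULL
    for (try in seq_len(10)) {
      cand <- pool[sample(nrow(pool), 1), ]
      if (sum(cand) >= q) { donor <- cand; break }
    }
    if (is.null(donor)) {
      # donor too shallow after 10 tries: sample reads with replacement
      reads <- sample.int(base$n_genes, q, replace = TRUE, prob = cand / sum(cand))
      out <- out + tabulate(reads, nbins = base$n_genes)
    } else {
      out <- out + mvhyper(donor, q)
    }
  }
  out
}

#' Generate a two-batch confounded trajectory dataset
#'
#' Each batch contributes `n_per_batch` cells sampled exclusively from that
#' batch's donor pools, following its own plan. Confounding is introduced by
#' giving the two plans different terminal probabilities (e.g. `p_tcell = 1`
#' in batch 1 and `0` in batch 2 makes the T-cell branch batch-1-exclusive
#' and the B-cell branch batch-2-exclusive: "completely confounded").
#'
#' @param plan_batch1,plan_batch2 `codal_plan`s sharing `k`.
#' @param base a `codal_basepops`.
#' @param n_per_batch cells per batch (default 2000).
#' @param seed integer seed.
#' @param depth_logmean,depth_logsd synthesized cell depth parameters.
#' @return list with `counts` (`codal_counts`), `design` (`codal_design` with
#'   one-hot batch), and `truth` (tibble: batch, path, progress, branch,
#'   mixing weights).
#' @export
generate_dataset <- function(plan_batch1, plan_batch2, base,
                             n_per_batch = 2000, seed = 0L,
                             depth_logmean = log(2000), depth_logsd = 0.3) {
  if (plan_batch1$k != plan_batch2$k) {
    stop("plans must share the base-similarity parameter k", call. = FALSE)
  }
  set.seed(derive_seed(seed, "dataset"))
  plans <- list(batch1 = plan_batch1, batch2 = plan_batch2)
  n_total <- 2L * n_per_batch
  counts <- matrix(0L, n_total, base$n_genes)
  truth <- vector("list", n_total)
  i <- 0L
  for (b in names(plans)) {
    plan <- plans[[b]]
    for (ci in seq_len(n_per_batch)) {
      i <- i + 1L
      sp <- sample_cell_path(plan)
      w <- interpolate_weights(plan, sp$path, sp$p)
      counts[i, ] <- synthesize_cell(w, base, batch = b,
                                     depth_logmean = depth_logmean,
                                     depth_logsd = depth_logsd)
      terminal <- sp$path[length(sp$path)]
      L <- length(sp$path) - 1L
      e <- min(L, floor(sp$p * L) + 1L)
      truth[[i]] <- data.frame(
        cell = sprintf("%s_cell%04d", b, ci), batch = b,
        path = paste(sp$path, collapse = ">"), progress = sp$p,
        terminal = terminal,
        branch = unname(plan$labels[terminal]),
        # tree segment (edge) the cell lies on: the trajectory-level branch
        segment = paste(sp$path[e], sp$path[e + 1L], sep = "-"),
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, truth)
  X <- codal_counts(counts, cell_ids = truth$cell,
                    feature_ids = paste0("gene", seq_len(base$n_genes)),
                    modality = "RNA", drop_empty = FALSE)
  design <- encode_covariates(truth["batch"], categorical = "batch")
  list(counts = X, design = design, truth = tibble::as_tibble(truth))
}
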