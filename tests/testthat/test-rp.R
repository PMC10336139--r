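test_that("regulatory potential follows the exponential distance decay", {
  # a peak at one decay distance contributes half its accessibility
  c1 <- regulatory_potential(matrix(0.4), delta_kb = 10, compartment = "U",
                             a = c(U = 1, D = 1, P = 1), decay = c(U = 10, D = 5))
  expect_equal(c1, 0.4 * 0.5, tolerance = 1e-12)
  # promoter peaks never decay
  c2 <- regulatory_potential(matrix(0.4), delta_kb = 1.2, compartment = "P",
                             a = c(U = 1, D = 1, P = 3), decay = c(U = 10, D = 5))
  expect_equal(c2, 3 * 0.4, tolerance = 1e-12)
  # worked example: a_U = 2, A = 0.01, delta = 10, Delta = 5 -> 0.005
  c3 <- regulatory_potential(matrix(0.01), 10, "U",
                             a = c(U = 2, D = 1, P = 1), decay = c(U = 5, D = 5))
  expect_equal(c3, 0.005, tolerance = 1e-12)
  # linearity in accessibility
  A <- matrix(runif(8), 2)
  d <- c(3, 50, 1, 200); comp <- c("U", "D", "P", "D")
  a <- c(U = 1.5, D = 0.7, P = 2); dec <- c(U = 20, D = 40)
  expect_equal(regulatory_potential(2 * A, d, comp, a, dec),
               2 * regulatory_potential(A, d, comp, a, dec), tolerance = 1e-12)
  expect_error(regulatory_potential(A, c(-1, 2, 3, 4), comp, a, dec), "negative")
})

test_that("peak assignment is strand-aware with promoter and window rules", {
  asg <- assign_peaks(tss = 100000, strand = "+",
                      peak_start = c(98000, 99400, 150000, 900000),
                      peak_end = c(98500, 100400, 150500, 900500))
  expect_equal(nrow(asg), 3) # the 800 kb peak is outside the window
  expect_equal(asg$compartment, c("U", "P", "D"))
  asg_m <- assign_peaks(tss = 100000, strand = "-",
                        peak_start = c(98000, 150000),
                        peak_end = c(98500, 150500))
  expect_equal(asg_m$compartment, c("D", "U")) # flipped on the minus strand
})

test_that("the RP likelihood matches a scalar oracle and absorbs shifts in kappa", {
  set.seed(1)
  n <- 3
  cvec <- c(0.2, 0.5, 0.9)
  params <- list(gamma = 1.2, b = 0.5, theta = 4,
                 c_mean = mean(cvec), c_sd = sd(cvec))
  ctx <- list(n = c(100, 150, 120), t = c(0.1, -0.2, 0), kappa = c(50, 60, 55))
  x <- c(3, 1, 7)
  lam <- params$gamma * (cvec - params$c_mean) / params$c_sd + params$b
  mu <- ctx$n * exp(lam + ctx$t) / ctx$kappa
  oracle <- sum(dnbinom(x, size = params$theta, mu = mu, log = TRUE))
  expect_equal(rp_log_likelihood(x, cvec, params, ctx), oracle, tolerance = 1e-10)

  # t = 0 reduces exactly to the unaugmented model
  ctx0 <- ctx; ctx0$t <- c(0, 0, 0)
  mu0 <- ctx$n * exp(lam) / ctx$kappa
  expect_equal(rp_log_likelihood(x, cvec, params, ctx0),
               sum(dnbinom(x, size = params$theta, mu = mu0, log = TRUE)),
               tolerance = 1e-10)

  # a constant added to t is absorbed by scaling kappa accordingly
  ctx_shift <- ctx; ctx_shift$t <- ctx$t + 0.7; ctx_shift$kappa <- ctx$kappa * exp(0.7)
  expect_equal(rp_log_likelihood(x, cvec, params, ctx_shift),
               rp_log_likelihood(x, cvec, params, ctx), tolerance = 1e-10)
  expect_error(rp_log_likelihood(x, cvec, params,
                                 list(n = ctx$n, t = ctx$t, kappa = c(-1, 1, 1))),
               "kappa")
})

simulate_rp_gene <- function(n_cells = 2000, seed = 3, decay_U = 10,
                             t_shift = NULL) {
  set.seed(seed)
  P <- 14
  comp <- rep(c("U", "D", "P"), c(6, 6, 2))
  delta <- c(runif(6, 1, 60), runif(6, 1, 60), runif(2, 0, 1.4))
  A <- matrix(rexp(n_cells * P), n_cells)
  A <- A / rowSums(A) * 0.1
  a <- c(U = 3, D = 0.8, P = 2)
  dec <- c(U = decay_U, D = 25)
  cvec <- regulatory_potential(A, delta, comp, a, dec)
  lam <- 1.5 * (cvec - mean(cvec)) / sd(cvec) - 0.5
  t <- if (is.null(t_shift)) rep(0, n_cells) else t_shift
  n <- rep(2000, n_cells)
  kappa <- rep(400, n_cells)
  mu <- n * exp(lam + t) / kappa
  x <- rnbinom(n_cells, size = 5, mu = mu)
  list(x = x, A = A, delta = delta, comp = comp, lam = lam,
       ctx = list(n = n, t = t, kappa = kappa))
}

test_that("MAP fitting recovers decay distances and per-cell rates", {
  g <- simulate_rp_gene(n_cells = 2000, seed = 3, decay_U = 10)
  fit <- fit_rp(g$x, g$A, g$delta, g$comp, g$ctx, seed = 1)
  expect_gt(fit$params$decay[["U"]], 5)
  expect_lt(fit$params$decay[["U"]], 20)
  cv <- regulatory_potential(g$A, g$delta, g$comp, fit$params$a, fit$params$decay)
  lam_hat <- codal:::rp_lambda(cv, fit$params$gamma, fit$params$b,
                               fit$params$c_mean, fit$params$c_sd)
  expect_gt(cor(lam_hat, g$lam), 0.8)
  # deterministic given the seed
  fit2 <- fit_rp(g$x, g$A, g$delta, g$comp, g$ctx, seed = 1)
  expect_identical(fit$par_raw, fit2$par_raw)
  expect_error(fit_rp(g$x, g$A, numeric(0), character(0), g$ctx), "no assigned")
})

test_that("technical-effect augmentation improves held-out likelihood under batch shifts", {
  set.seed(5)
  n <- 1200
  batch <- rep(c(0, 1), each = n / 2)
  wins <- 0L
  for (gene in 1:6) {
    shift <- (2 * batch - 1) * 0.6 # per-batch expression distortion
    g <- simulate_rp_gene(n_cells = n, seed = 10 + gene, t_shift = shift)
    train <- c(seq(1, n / 2, by = 2), seq(n / 2 + 1, n, by = 2))
    test <- setdiff(seq_len(n), train)
    sub <- function(ctx, idx) list(n = ctx$n[idx], t = ctx$t[idx], kappa = ctx$kappa[idx])
    ctx0 <- g$ctx; ctx0$t <- rep(0, n) # unaugmented: no technical vector
    f_aug <- fit_rp(g$x[train], g$A[train, ], g$delta, g$comp, sub(g$ctx, train), seed = 1)
    f_un <- fit_rp(g$x[train], g$A[train, ], g$delta, g$comp, sub(ctx0, train), seed = 1)
    ll_aug <- rp_log_likelihood(g$x[test],
                                regulatory_potential(g$A[test, ], g$delta, g$comp,
                                                     f_aug$params$a, f_aug$params$decay),
                                f_aug$params, sub(g$ctx, test))
    ll_un <- rp_log_likelihood(g$x[test],
                               regulatory_potential(g$A[test, ], g$delta, g$comp,
                                                    f_un$params$a, f_un$params$decay),
                               f_un$params, sub(ctx0, test))
    if (ll_aug > ll_un) wins <- wins + 1L
  }
  expect_gte(wins, 4L) # majority of genes
})

test_that("in-silico deletion scores dominant regulatory arms above chance", {
  # gene driven almost entirely by close upstream peaks
  set.seed(7)
  n <- 800; P <- 14
  comp <- rep(c("U", "D", "P"), c(6, 6, 2))
  delta <- c(runif(6, 1, 8), runif(6, 20, 60), runif(2, 0, 1.4))
  A <- matrix(rexp(n * P), n); A <- A / rowSums(A) * 0.1
  a <- c(U = 6, D = 0.1, P = 0.1); dec <- c(U = 15, D = 25)
  cvec <- regulatory_potential(A, delta, comp, a, dec)
  lam <- 1.5 * (cvec - mean(cvec)) / sd(cvec) - 0.5
  ctx <- list(n = rep(2000, n), t = rep(0, n), kappa = rep(400, n))
  x <- rnbinom(n, size = 5, mu = ctx$n * exp(lam) / ctx$kappa)
  g <- list(x = x, A = A, delta = delta, comp = comp, ctx = ctx)
  fit <- fit_rp(g$x, g$A, g$delta, g$comp, g$ctx, seed = 2)
  expect_equal(in_silico_deletion(fit, g$x, g$A, g$ctx, integer(0)), 0)
  # zero-accessibility peaks do not move the association
  A0 <- g$A; A0[, 3] <- 0
  fit0 <- fit_rp(g$x, A0, g$delta, g$comp, g$ctx, seed = 2)
  base <- in_silico_deletion(fit0, g$x, A0, g$ctx, c(5, 6))
  expect_equal(in_silico_deletion(fit0, g$x, A0, g$ctx, c(5, 6, 3)), base,
               tolerance = 1e-9)
  # masking the upstream arm (large effects) beats random same-size masks
  up <- which(g$comp == "U")
  assoc_up <- in_silico_deletion(fit, g$x, g$A, g$ctx, up)
  set.seed(8)
  null_assoc <- replicate(40, {
    in_silico_deletion(fit, g$x, g$A, g$ctx, sample(length(g$delta), length(up)))
  })
  expect_gt(assoc_up, quantile(null_assoc, 0.95))
})

test_that("motif enrichment is calibrated and matches exact rank statistics", {
  set.seed(9)
  # shifted alternative: detected
  assoc <- c(rnorm(30, 2), rnorm(120, 0))
  names(assoc) <- paste0("g", seq_along(assoc))
  expect_lt(motif_enrichment(assoc, paste0("g", 1:30)), 0.05)
  # null calibration: p-values uniform across repeated simulations
  ps <- replicate(200, {
    a <- rnorm(60); names(a) <- paste0("g", 1:60)
    motif_enrichment(a, paste0("g", sample(60, 20)))
  })
  expect_gt(suppressWarnings(ks.test(ps, punif)$p.value), 0.01)
  # singleton set: matches exact enumeration of the rank-sum null
  a <- c(gA = 3.2, b1 = 1, b2 = 2, b3 = 2.5, b4 = 4, b5 = 0.5)
  r <- rank(a)["gA"]
  # P(singleton rank >= observed) under exchangeability
  p_manual <- (length(a) - r + 1) / length(a)
  expect_equal(motif_enrichment(a, "gA"), unname(p_manual), tolerance = 1e-9)
  expect_error(motif_enrichment(a, character(0)), "nonempty")
  # Bonferroni table
  M <- matrix(rnorm(300), 50, dimnames = list(paste0("g", 1:50), paste0("m", 1:6)))
  tab <- motif_enrichment_table(M, paste0("g", 1:10))
  expect_equal(tab$p_adjusted, pmin(1, tab$p_value * 6))
})
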