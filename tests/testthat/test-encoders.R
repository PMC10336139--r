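test_that("expression encoder output has the contracted shape and is row-wise", {
  s <- small_simulation()
  model <- s$sim$model
  res <- deviance_residuals(as.matrix(s$sim$counts))
  post <- encode_expression(model, res, s$C)
  K <- model$hyper$n_topics
  expect_equal(dim(post$topic_mu), c(200L, K))
  expect_equal(dim(post$topic_logvar), c(200L, K))
  expect_length(post$depth_mu, 200L)
  # deterministic in eval mode
  post2 <- encode_expression(model, res, s$C)
  expect_identical(post, post2)
  # permuting cells permutes outputs identically (eval mode is row-wise)
  perm <- sample(200)
  postp <- encode_expression(model, res[perm, ], s$C[perm, ])
  expect_equal(postp$topic_mu, post$topic_mu[perm, ], tolerance = 1e-12)
  resN <- res; resN[1, 1] <- NA
  expect_error(encode_expression(model, resN, s$C), "non-finite")
})

test_that("accessibility encoder averages embeddings over accessible peaks", {
  P <- 12; K <- 3
  model <- new_codal_model(P, K, 2, modality = "ATAC", seed = 2)
  # one accessible peak: the embedding average is that peak's embedding row
  X <- matrix(0, 2, P); X[1, 5] <- 1; X[2, c(2, 9)] <- 1
  C <- rbind(c(1, 0), c(0, 1))
  post <- encode_accessibility(model, X, C)
  expect_equal(dim(post$topic_mu), c(2L, K))
  # mean invariance: scaling the indicator doesn't change the average
  post_dup <- encode_accessibility(model, X * 3, C) # binarized upstream in practice
  expect_equal(post$topic_mu, post_dup$topic_mu, tolerance = 1e-9)
  # eval mode uses all accessible peaks (no corruption): deterministic
  expect_identical(post, encode_accessibility(model, X, C))
})

test_that("reparameterized samples are compositional and collapse at zero noise", {
  post <- list(topic_mu = matrix(c(0, log(3), 1, 1), 2, byrow = TRUE),
               topic_logvar = matrix(-40, 2, 2))
  Z <- reparameterized_sample(post, seed = 1)
  expect_equal(Z, softmax_rows(post$topic_mu), tolerance = 1e-8)
  post$topic_logvar <- matrix(0.3, 2, 2)
  Z1 <- reparameterized_sample(post, seed = 5)
  Z2 <- reparameterized_sample(post, seed = 5)
  expect_identical(Z1, Z2)
  expect_equal(rowSums(Z1), c(1, 1), tolerance = 1e-12)
})

test_that("KL to the Dirichlet-Laplace prior is exact against Monte Carlo", {
  # zero when the posterior equals the prior moments
  alpha <- c(2, 1, 0.5)
  pr <- codal:::dirichlet_laplace_moments(alpha)
  post <- list(topic_mu = matrix(pr$mean, 1), topic_logvar = matrix(log(pr$var), 1))
  expect_equal(kl_to_prior(post, alpha), 0, tolerance = 1e-10)

  # nonnegative on random instances; matches MC within 1%
  set.seed(3)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    alpha <- exp(rnorm(K, 0, 0.5))
    mu <- rnorm(K, 0, 1); lv <- rnorm(K, -0.5, 0.4)
    post <- list(topic_mu = matrix(mu, 1), topic_logvar = matrix(lv, 1))
    kl <- kl_to_prior(post, alpha)
    expect_gte(kl, 0)
    pr <- codal:::dirichlet_laplace_moments(alpha)
    n <- 4e5
    z <- matrix(rnorm(n * K), n) * rep(exp(0.5 * lv), each = n) +
      rep(mu, each = n)
    lq <- rowSums(dnorm(z, rep(mu, each = n), rep(exp(0.5 * lv), each = n), log = TRUE))
    lp <- rowSums(dnorm(z, rep(pr$mean, each = n), rep(sqrt(pr$var), each = n), log = TRUE))
    mc <- mean(lq - lp)
    se <- sd(lq - lp) / sqrt(n)
    expect_lt(abs(kl - mc), 0.01 * max(kl, 0.05) + 4 * se)
  }
  expect_error(kl_to_prior(post, c(-1, 1)), "positive")
})

test_that("posterior means are compositional and collapse when n_samples = 0", {
  s <- small_simulation()
  model <- s$sim$model
  Zbar <- posterior_mean_topics(model, s$sim$counts, s$C, n_samples = 4, seed = 2)
  expect_equal(rowSums(Zbar), rep(1, 200), tolerance = 1e-9)
  Z0 <- posterior_mean_topics(model, s$sim$counts, s$C, n_samples = 0)
  post <- codal:::encode_cells(model, s$sim$counts, s$C)
  expect_equal(Z0, softmax_rows(post$topic_mu), tolerance = 1e-12)
})

test_that("posterior-mean averaging variance shrinks like 1/n_samples", {
  post <- list(topic_mu = matrix(c(0.5, -0.2, 0.1), 1),
               topic_logvar = matrix(0, 1, 3))
  draw_mean <- function(n_samples, seed) {
    acc <- 0
    for (s in seq_len(n_samples))
      acc <- acc + reparameterized_sample(post, seed = derive_seed(seed, s))
    (acc / n_samples)[1, 1]
  }
  v1 <- var(vapply(1:300, function(s) draw_mean(1, s), numeric(1)))
  v8 <- var(vapply(1:300, function(s) draw_mean(8, 1000 + s), numeric(1)))
  expect_lt(v8, v1 / 4) # ~1/8, with slack for sampling noise
})

test_that("ILR maps the simplex isometrically with the barycenter at origin", {
  K <- 4
  unif <- matrix(1 / K, 2, K)
  expect_equal(ilr_transform(unif), matrix(0, 2, K - 1), tolerance = 1e-10,
               ignore_attr = TRUE)
  # Aitchison isometry: perturbation by a constant composition preserves
  # distances
  set.seed(9)
  Z <- matrix(rexp(5 * K), 5); Z <- Z / rowSums(Z)
  p <- rexp(K); p <- p / sum(p)
  Zp <- sweep(Z, 2, p, `*`); Zp <- Zp / rowSums(Zp)
  expect_equal(as.numeric(dist(ilr_transform(Z))),
               as.numeric(dist(ilr_transform(Zp))), tolerance = 1e-8)
})

test_that("ILR kNN graph uses L1 distance and respects permutations", {
  set.seed(4)
  Z <- matrix(rexp(30 * 3), 30); Z <- Z / rowSums(Z)
  Z[2, ] <- Z[1, ] # identical pair
  g <- ilr_knn(Z, k = 3)
  expect_equal(dim(g$index), c(30L, 3L))
  expect_equal(g$index[1, 1], 2L)
  expect_equal(g$index[2, 1], 1L)
  expect_equal(g$dist[1, 1], 0, tolerance = 1e-12)
  expect_error(ilr_knn(Z, k = 30), "smaller")
  # relabeling cells permutes the graph consistently
  perm <- sample(30)
  g2 <- ilr_knn(Z[perm, ], k = 3)
  inv <- order(perm)
  expect_equal(g2$dist[inv[1], ], g$dist[1, ], tolerance = 1e-10)
})
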