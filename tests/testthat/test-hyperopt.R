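fake_surrogate <- function(n_rungs, moments) {
  structure(list(n_rungs = n_rungs,
                 moments_fn = function(H, r) moments[[r]]),
            class = "codal_surrogate")
}

test_that("pruning thresholds are rung percentiles with sane edge cases", {
  led <- new_trial_ledger(rung_epochs = c(8, 16, 24))
  expect_equal(pruning_thresholds(led), c(-Inf, -Inf))
  for (s in 1:4) led <- ledger_add(led, list(n_topics = s, dropout = 0.05),
                                   c(s, NA, NA), "pruned")
  expect_equal(pruning_thresholds(led)[1], 2.5)
  led$prune_quantile <- 0
  expect_equal(pruning_thresholds(led)[1], 1)
  # failed trials never enter the percentile
  led$prune_quantile <- 50
  led <- ledger_add(led, list(n_topics = 9, dropout = 0.05), c(100), "failed")
  expect_equal(pruning_thresholds(led)[1], 2.5)
})

test_that("best final score uses complete trials, with a bootstrap fallback", {
  led <- new_trial_ledger()
  led <- ledger_add(led, list(n_topics = 3, dropout = 0.05), c(1, 2, NA), "pruned")
  # no complete trials: best observed anywhere minus one sd
  expect_lt(codal:::best_final_score(led), 2)
  led <- ledger_add(led, list(n_topics = 4, dropout = 0.05), c(1, 2, 5), "complete")
  led <- ledger_add(led, list(n_topics = 5, dropout = 0.05), c(1, 2, 3), "complete")
  expect_equal(codal:::best_final_score(led), 5)
})

test_that("pruned expected improvement reduces to classical EI and hits landmarks", {
  f_star <- 2; xi <- 0.1
  # no pruning rungs: the survival product is empty (single-rung search)
  sur1 <- fake_surrogate(1, list(list(mean = f_star * (1 + xi), sd = 1)))
  ei <- expected_improvement_pruned(list(n_topics = 5, dropout = 0.07), sur1,
                                    thresholds = numeric(0), f_star = f_star)
  expect_equal(ei, dnorm(0), tolerance = 1e-12)

  # intermediate-rung means equal to thresholds halve the acquisition twice
  sur3 <- fake_surrogate(3, list(list(mean = 0, sd = 1), list(mean = 0, sd = 1),
                                 list(mean = f_star * (1 + xi), sd = 1)))
  ei3 <- expected_improvement_pruned(list(n_topics = 5, dropout = 0.07), sur3,
                                     thresholds = c(0, 0), f_star = f_star)
  expect_equal(ei3, 0.25 * dnorm(0), tolerance = 1e-12)

  # -Inf thresholds recover the unpruned acquisition exactly
  ei_inf <- expected_improvement_pruned(list(n_topics = 5, dropout = 0.07), sur3,
                                        thresholds = c(-Inf, -Inf), f_star = f_star)
  expect_equal(ei_inf, dnorm(0), tolerance = 1e-12)
})

test_that("pruned expected improvement matches a Monte-Carlo oracle within 2%", {
  set.seed(13)
  for (rep in 1:10) {
    mom <- lapply(1:3, function(r) list(mean = rnorm(1, 1, 1),
                                        sd = runif(1, 0.4, 1.5)))
    thr <- rnorm(2, 0.5, 0.5)
    f_star <- rnorm(1, 1, 0.5)
    xi <- 0.1
    sur <- fake_surrogate(3, mom)
    ei <- expected_improvement_pruned(list(n_topics = 5, dropout = 0.07), sur,
                                      thresholds = thr, f_star = f_star, xi = xi)
    # oracle: simulate rung scores independently, apply the improvement
    # definition literally (positive improvement only at the final rung for
    # trials that survive every earlier rung)
    n <- 2e5
    f1 <- rnorm(n, mom[[1]]$mean, mom[[1]]$sd)
    f2 <- rnorm(n, mom[[2]]$mean, mom[[2]]$sd)
    f3 <- rnorm(n, mom[[3]]$mean, mom[[3]]$sd)
    surv <- (f1 >= thr[1]) & (f2 >= thr[2])
    target <- f_star + xi * abs(f_star)
    imp <- ifelse(surv & f3 > target, f3 - target, 0)
    mc <- mean(imp)
    se <- sd(imp) / sqrt(n)
    expect_lt(abs(ei - mc), 0.02 * max(ei, 0.02) + 4 * se)
  }
})

test_that("proposals are random during startup then maximize the acquisition", {
  box <- list(n_topics = c(3L, 20L), dropout = c(0.05, 0.1))
  led <- new_trial_ledger()
  H1 <- propose_next(led, box, seed = 5)
  expect_true(H1$n_topics >= 3 && H1$n_topics <= 20)
  expect_true(H1$dropout >= 0.05 && H1$dropout <= 0.1)
  expect_identical(H1, propose_next(led, box, seed = 5))

  # past startup: deterministic argmax over the candidate draw
  set.seed(21)
  for (i in 1:16) {
    led <- ledger_add(led, list(n_topics = sample(3:20, 1), dropout = 0.07),
                      cumsum(runif(3)), "complete")
  }
  H2 <- propose_next(led, box, seed = 6)
  expect_identical(H2, propose_next(led, box, seed = 6))
  expect_gt(attr(H2, "acquisition"), 0)
})

test_that("the GP surrogate interpolates rung-structured scores", {
  led <- new_trial_ledger()
  set.seed(2)
  for (i in 1:20) {
    K <- sample(3:20, 1)
    f <- -((K - 12)^2) / 20
    led <- ledger_add(led, list(n_topics = K, dropout = 0.07),
                      f + c(-0.2, -0.1, 0) + rnorm(3, 0, 0.02), "complete")
  }
  sur <- fit_surrogate(led, list(n_topics = c(3L, 20L), dropout = c(0.05, 0.1)))
  m12 <- codal:::surrogate_moments(sur, list(n_topics = 12, dropout = 0.07), 3)
  m3 <- codal:::surrogate_moments(sur, list(n_topics = 3, dropout = 0.07), 3)
  expect_gt(m12$mean, m3$mean)
  expect_gt(m3$sd, 0)
})

test_that("tuning locates a noisy quadratic optimum and obeys stopping rules", {
  # synthetic objective benchmark with a mock trainer
  hits <- 0L
  for (sd_ in 1:10) {
    mock <- local({
      s <- sd_
      function(H, ledger, trial_seed) {
        set.seed(derive_seed(s, "mock", trial_seed))
        f <- -(H$n_topics - 12)^2 + rnorm(1, 0, 0.5)
        list(scores = f + c(-2, -1, 0), status = "complete", model = NULL)
      }
    })
    res <- tune_codal(topic_range = c(3L, 25L), trainer = mock,
                      min_trials = 30, patience = 30, max_trials = 30,
                      n_startup = 10, workers = 5, seed = sd_)
    if (abs(res$best_H$n_topics - 12) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)

  # stops once no improvement in `patience` recent trials past the minimum
  flat <- function(H, ledger, trial_seed) {
    list(scores = c(0, 0, 0), status = "complete", model = NULL)
  }
  res <- tune_codal(topic_range = c(3L, 25L), trainer = flat,
                    min_trials = 48, patience = 12, max_trials = 128,
                    n_startup = 5, workers = 5, seed = 1)
  n_tr <- length(res$ledger$trials)
  expect_gte(n_tr, 48L)
  expect_lte(n_tr, 55L) # stop checked at the next batch boundary

  # never exceeds the trial ceiling even when improving steadily
  rising <- local({
    i <- 0
    function(H, ledger, trial_seed) {
      i <<- i + 1
      list(scores = c(i, i, i), status = "complete", model = NULL)
    }
  })
  res2 <- tune_codal(topic_range = c(3L, 25L), trainer = rising,
                     min_trials = 10, patience = 5, max_trials = 20,
                     n_startup = 3, workers = 5, seed = 2)
  expect_lte(length(res2$ledger$trials), 20L)
})

test_that("trial ledgers round-trip through JSON", {
  led <- new_trial_ledger(rung_epochs = c(2, 4, 6), prune_quantile = 40)
  led <- ledger_add(led, list(n_topics = 7, dropout = 0.061), c(1.5, NA, NA), "pruned")
  led <- ledger_add(led, list(n_topics = 9, dropout = 0.09), c(1, 2, 3), "complete")
  path <- withr::local_tempfile(fileext = ".json")
  write_trial_ledger(led, path)
  back <- read_trial_ledger(path)
  expect_equal(back$rung_epochs, led$rung_epochs)
  expect_equal(back$prune_quantile, led$prune_quantile)
  expect_equal(back$trials, led$trials, tolerance = 1e-12)
  # resumed proposals continue identically
  box <- list(n_topics = c(3L, 12L), dropout = c(0.05, 0.1))
  expect_identical(propose_next(led, box, seed = 3),
                   propose_next(back, box, seed = 3))
})

test_that("real trials score rungs on held-out cells and can be pruned", {
  s <- small_simulation(n = 100, G = 12)
  X <- codal_counts(s$sim$counts)
  d <- two_batch_design(100)
  sp <- stratified_split(X, d, seed = 1)
  led <- new_trial_ledger(rung_epochs = c(1, 2, 3))
  cfg <- list(batch_size = 32, lr = c(0.002, 0.05), mi_weight = 0)
  res <- run_trial(list(n_topics = 3, dropout = 0.05), X, d, sp, led,
                   train_config = cfg, seed = 2)
  expect_equal(res$status, "complete")
  expect_length(res$scores, 3)
  expect_s3_class(res$model, "codal_model")

  # an impossible threshold at rung 1 prunes immediately
  led2 <- led
  for (i in 1:2) led2 <- ledger_add(led2, list(n_topics = 3, dropout = 0.05),
                                    c(1e9, 1e9, 1e9), "complete")
  res2 <- run_trial(list(n_topics = 3, dropout = 0.05), X, d, sp, led2,
                    train_config = cfg, seed = 2)
  expect_equal(res2$status, "pruned")
  expect_length(res2$scores, 1)
  expect_null(res2$model)
})
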