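test_that("construction plan mixing weights sum to one symbolically", {
  tb <- codal:::fc_weight_tables()
  # intercepts sum to 1 and k-coefficients to 0 in every node row, so the
  # unit-sum property holds for every admissible k
  expect_equal(unname(rowSums(tb$W0)), rep(1, nrow(tb$W0)))
  expect_equal(unname(rowSums(tb$Wk)), rep(0, nrow(tb$Wk)))
  # k = 0 gives pure terminal types
  p0 <- build_plan(k = 0, p_tcell = 0.5)
  expect_equal(p0$weights["4", "CD16+Mono"], 1)
  expect_equal(p0$weights["6", "B1B"], 1)
  # transition probabilities out of each node sum to 1
  pl <- build_plan(k = 0.05, p_tcell = 0.3)
  for (nd in unique(pl$edges$from)) {
    expect_equal(sum(pl$edges$prob[pl$edges$from == nd]), 1)
  }
  expect_error(build_plan(k = 0.3), "k must be")
  expect_error(build_plan(k = 0.05, p_tcell = 2), "p_tcell")
})

test_that("terminal frequencies match path enumeration and progress is Beta(0.5, 1)", {
  plan <- build_plan(k = 0.05, p_tcell = 1)
  set.seed(11)
  n <- 1e4
  draws <- replicate(n, {
    sp <- sample_cell_path(plan)
    c(terminal = tail(sp$path, 1), p = sp$p)
  })
  term <- draws[1, ]; p <- as.numeric(draws[2, ])
  # exact enumeration oracle: P(4) = .4 * .5, P(5) = .4 * .5, P(7) = .6 * 1
  expected <- c(`4` = 0.2, `5` = 0.2, `7` = 0.6)
  obs <- table(factor(term, levels = names(expected)))
  chi <- chisq.test(obs, p = expected)
  expect_gt(chi$p.value, 0.01)
  expect_equal(sum(term == "6"), 0) # no B-cells at p_tcell = 1
  ks <- ks.test(p, pbeta, 0.5, 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("edge interpolation blends node weights sigmoidally", {
  plan <- build_plan(k = 0.05, p_tcell = 0.5)
  path <- c("root", "1", "3", "7")
  # p at the midpoint of edge 2 gives the exact 50:50 node mixture
  w_mid <- interpolate_weights(plan, path, p = 0.5) # edge 2, p_edge = 0.5
  expect_equal(unname(w_mid),
               unname((plan$weights["1", ] + plan$weights["3", ]) / 2),
               tolerance = 1e-12)
  # start of an edge blends at the logistic floor sigma(-1)
  d0 <- 1 / (1 + exp(1))
  w0 <- interpolate_weights(plan, path, p = 0)
  expect_equal(unname(w0),
               unname(plan$weights["root", ] * (1 - d0) + plan$weights["1", ] * d0),
               tolerance = 1e-12)
  for (p in seq(0, 1, by = 0.1)) {
    expect_equal(sum(interpolate_weights(plan, path, p)), 1, tolerance = 1e-12)
  }
})

test_that("pseudotime moves compositions away from the root monotonically", {
  plan <- build_plan(k = 0.05, p_tcell = 1)
  path <- c("root", "1", "3", "7")
  ps <- seq(0.05, 0.95, by = 0.05)
  dists <- vapply(ps, function(p)
    sum(abs(interpolate_weights(plan, path, p) - plan$weights["root", ])),
    numeric(1))
  expect_gt(cor(ps, dists, method = "spearman"), 0.9)
})

test_that("cell synthesis conserves reads and matches hypergeometric margins", {
  base <- synthetic_base_populations(n_genes = 60, cells_per_pool = 8,
                                     depth_logmean = log(1200), seed = 3)
  plan <- build_plan(k = 0.05, p_tcell = 1)
  set.seed(4)
  w <- interpolate_weights(plan, c("root", "1", "3", "7"), 0.4)
  for (i in 1:5) {
    x <- synthesize_cell(w, base, "batch1", depth_logmean = log(500))
    expect_true(sum(x) > 0)
  }
  # concentrated weights: reads drawn from a single donor follow the
  # multivariate hypergeometric mean quota * donor_count / donor_total
  pure <- setNames(c(1, rep(0, 6)), base$types)
  set.seed(5)
  pool1 <- base$pools$batch1$HSC
  # single-donor pool isolates the donor marginal
  base1 <- base; base1$pools$batch1$HSC <- pool1[1, , drop = FALSE]
  donor <- pool1[1, ]
  reps <- t(replicate(300, synthesize_cell(pure, base1, "batch1",
                                           depth_logmean = log(500),
                                           depth_logsd = 0)))
  q <- sum(reps[1, ])
  expect_true(all(rowSums(reps) == q)) # exact conservation at fixed depth
  expectation <- q * donor / sum(donor)
  hyper_var <- q * (donor / sum(donor)) * (1 - donor / sum(donor)) *
    (sum(donor) - q) / (sum(donor) - 1)
  se <- sqrt(hyper_var / 300)
  ok <- abs(colMeans(reps) - expectation) <= 3 * se + 1e-9
  expect_gt(mean(ok), 0.95)

  # seeded determinism
  set.seed(9); a <- synthesize_cell(w, base, "batch2")
  set.seed(9); b <- synthesize_cell(w, base, "batch2")
  expect_identical(a, b)
})

test_that("confounded datasets deplete terminal states per batch", {
  base <- synthetic_base_populations(n_genes = 50, cells_per_pool = 10, seed = 6)
  p1 <- build_plan(k = 0.05, p_tcell = 1)
  p2 <- build_plan(k = 0.05, p_tcell = 0)
  ds <- generate_dataset(p1, p2, base, n_per_batch = 120, seed = 7,
                         depth_logmean = log(400))
  tr <- ds$truth
  expect_equal(nrow(tr), 240)
  expect_equal(sum(tr$batch == "batch1" & tr$branch == "B-cell"), 0)
  expect_equal(sum(tr$batch == "batch2" & tr$branch == "T-cell"), 0)
  expect_gt(sum(tr$batch == "batch1" & tr$branch == "T-cell"), 0)
  # branch labels consistent with sampled paths
  expect_true(all(mapply(function(path, br) {
    term <- tail(strsplit(path, ">")[[1]], 1)
    unname(p1$labels[term]) == br
  }, tr$path, tr$branch)))
  # default dataset size is two trajectories of 2000 cells
  expect_equal(formals(generate_dataset)$n_per_batch, 2000)
  # design carries the batch one-hot
  expect_equal(colnames(ds$design$matrix), c("batch=batch1", "batch=batch2"))
  expect_error(generate_dataset(p1, build_plan(k = 0.1), base, 10, 1),
               "share")
})

test_that("base populations express their marker blocks and honor batch knobs", {
  base <- synthetic_base_populations(n_genes = 70, cells_per_pool = 15,
                                     batch_effect_sd = 0.4, seed = 8)
  block <- floor(70 / 7)
  for (ti in c(1, 4)) {
    idx <- ((ti - 1) * block + 1):(ti * block)
    own <- colMeans(base$pools$batch1[[base$types[ti]]])
    other <- colMeans(base$pools$batch1[[base$types[ti %% 7 + 1]]])
    expect_gt(mean(own[idx]), 2 * mean(other[idx]))
  }
  # no batch distortion: per-gene pool means agree across batches
  flat <- synthetic_base_populations(n_genes = 70, cells_per_pool = 200,
                                     batch_effect_sd = 0, depth_shift = 1,
                                     seed = 9)
  m1 <- colMeans(flat$pools$batch1$HSC); m2 <- colMeans(flat$pools$batch2$HSC)
  expect_gt(cor(m1, m2), 0.98)
  expect_lt(abs(log(sum(m1) / sum(m2))), 0.1)
  # determinism
  again <- synthetic_base_populations(n_genes = 70, cells_per_pool = 15,
                                      batch_effect_sd = 0.4, seed = 8)
  expect_identical(base$pools$batch1$HSC, again$pools$batch1$HSC)
})
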