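# Shared fixture builders: tiny models and datasets constructed in code.

tiny_rna_model <- function(G = 7, K = 3, Cn = 2, seed = 3) {
  new_codal_model(G, K, Cn, modality = "RNA", seed = seed)
}

tiny_counts <- function(n = 12, G = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * G, 5) + 1, n)
  codal_counts(m, modality = "RNA")
}

two_batch_design <- function(n) {
  encode_covariates(
    data.frame(batch = rep(c("A", "B"), length.out = n)),
    categorical = "batch"
  )
}

# small generative-model dataset with known truth
small_simulation <- function(n = 200, G = 40, K = 3, seed = 5) {
  truth <- new_codal_model(G, K, 2, modality = "RNA", seed = seed)
  truth$par$beta <- matrix(rnorm(K * G, sd = 2), K)
  Cm <- cbind(rep(c(1, 0), each = n / 2), rep(c(0, 1), each = n / 2))
  sim <- sample_generative(truth, Cm, n, seed = seed + 1,
                           alpha = rep(0.5, K), depth_logmean = log(800))
  list(truth = truth, sim = sim, C = Cm)
}
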