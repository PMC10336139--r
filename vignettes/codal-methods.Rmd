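---
title: "Disentangling biological and technical variation in multi-batch single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling biological and technical variation in multi-batch single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(codal)
```

## The model

Single-cell RNA-seq and ATAC-seq experiments collected across batches mix two
sources of variation: the biology of cell state, and batch-driven technical
distortion. `codal` models observed counts as the composition of both. Cell
state is a Dirichlet-distributed mixture over `K` *topics*,

$$Z_i \sim \mathrm{Dirichlet}(\alpha), \qquad
\alpha_d \sim \mathrm{Gamma}\!\left(2, \tfrac{2K}{\mathcal I}\right),$$

with the total pseudocount budget fixed at $\mathcal I = 50$ so prior
sparsity does not depend on the latent dimension. A linear decoder maps the
mixture to per-gene biological rates,
$\lambda_{ij} = \mathrm{batchnorm}(\mathrm{dropout}(Z_{i\cdot})\beta_{\cdot j})$,
while a small neural network $h_\phi(Z_{i\cdot}, C_{i\cdot})$ maps state plus
technical covariates (one-hot batch indicators, standardized QC metrics) to a
technical effect $t_{ij}$ that is zero-centered per gene and rescaled by a
learned per-gene technical variance $\gamma_t$. Counts follow

$$X_{ij} \sim \mathrm{NB}\!\left(n_i\,\rho_{ij},\, \vartheta_j\right),
\qquad \rho_{ij} = \frac{e^{\lambda_{ij}+t_{ij}}}{\sum_l e^{\lambda_{il}+t_{il}}},$$

with a log-normal latent size factor $n_i$ centered at the observed depth
(RNA), or a multinomial over accessible peaks (ATAC). Because $t$ is
zero-centered by construction, dropping it and softmaxing $\lambda$ alone
yields the *disentangled* (batch-free) composition `disentangled_rates()`.

Nothing in the likelihood prevents the technical network from absorbing
biological signal, so the objective penalizes the mutual information between
$\lambda$ and $t$ with a neural lower bound (Donsker–Varadhan form, estimated
on all $m^2$ cross-pairings of a minibatch). The critic is a 64-unit two-layer
network held 1-Lipschitz by spectral normalization — without the constraint
the bound decouples from the strength of dependence and destabilizes
training. The full objective per minibatch is

$$\hat{\mathcal V} = \text{reconstruction} - \varepsilon_1 D_{KL}
  - \varepsilon_2\, w\, \mathrm{MINE}(\lambda, t),$$

where $w$ is the user-facing MI weight (`mi_weight`, default 1; 0 gives a
plain annealed topic-model VAE used as the baseline in all comparisons).

## Inference and training

The posterior over topics is amortized: a two-block 512-unit encoder for
RNA (fed deviance residuals concatenated with covariates), a deep-averaging
("bag of peaks") encoder with a skip connection for ATAC. Gaussian posteriors
in the softmax basis are pushed through the row-softmax, matching a Laplace
approximation of the Dirichlet prior whose moments are
$\mu_k = \log\alpha_k - \overline{\log\alpha}$ and
$\sigma^2_k = (1-2/K)/\alpha_k + \sum_l \alpha_l^{-1}/K^2$.

Training is cyclical minibatch gradient ascent (AdamW for the model, Adam
plus spectral normalization for the critic, both once per step; the MI
estimate is computed once per step and shared between the model and critic
gradients). The KL weight follows a step-up cyclic schedule (cycle maxima
1/3, 2/3, 1 over three cycles) and the MI weight a cyclic sawtooth reaching 1
by mid-cycle. Learning-rate bounds come from a geometric range test
(`lr_range_test()`): the upper bound is a tenth of the rate at the smoothed
loss minimum, capped before divergence, and the lower bound is 1/25 of that;
a one-cycle cosine schedule runs between them with momentum inversely
annealed in [0.85, 0.95].

All forward and backward passes are implemented directly in R on matrix
primitives. Every gradient path (both encoders, the decoder batchnorm, the
technical network's centering layer, the negative binomial and multinomial
likelihoods, the KL and its Dirichlet hyperprior, and the pairwise critic) is
verified against central finite differences in the test suite; this is the
package's substitute for trusting an autodiff engine.

Key defaults and their origins: minibatch 128 cells; 24 epochs; corruption
of the technical-effect row per cell with probability 0.05 (the corruption
unit is configurable; per-entry corruption is a defensible alternative and
is exposed as an option); decoder dropout tuned in [0.05, 0.1]; critic learning rate
1e-4 with no weight decay; AdamW weight decay 0.01 (the optimizer is named
without parameters; 0.01 is its conventional default, batchnorm/scale
parameters excluded from decay); gradient clipping at global norm 10 as a
NaN guard. The Dirichlet concentration $\alpha$ is a MAP point estimate in
log space; its Gamma hyperprior enters the objective scaled per cell and
annealed with the KL weight.

## Latent space

Posterior-mean compositions live on the simplex; distances are taken after
an isometric log-ratio transform with a fixed orthonormal Helmert-like basis
(any orthonormal basis gives the same geometry; the uniform composition maps
to the origin). Neighbor graphs use the Manhattan distance on these
coordinates (`ilr_knn()`).

## Hyperparameter tuning

`tune_codal()` searches `(n_topics, dropout)` with a Gaussian-process
surrogate (Matérn 5/2, ARD lengthscales, inputs min–max scaled, scores
standardized) fitted jointly over *(hyperparameters, rung)* tuples, where
rungs are scores on a stratified 4:1 held-out split after epochs 8, 16 and
24. Trials below the median of their rung are pruned. The acquisition is
expected improvement at the final rung with an exploratory margin
$\xi |f^*|$ ($\xi = 0.1$), multiplied by the probability of surviving every
intermediate rung — rungs treated as independent, a documented
approximation, since successive rung scores are in truth correlated.
Proposals are drawn in constant-liar batches of five (running trials imputed
at the mean completed score); 15 random startup trials precede the
surrogate; stopping follows min 48 trials / patience 12 / ceiling 128. The
final epoch's score feeds only the incumbent, never a pruning threshold.

## Regulatory-potential models

For multimodal data, per-gene models tie expression to local accessibility:
$c_{ij} = \sum_\eta a_{j\eta} \sum_{k \in \mathfrak D_{j\eta}} A_{ik}
2^{-\delta_{jk}/\Delta_{j\eta}}$ over upstream/downstream/promoter
compartments (promoter decay infinite; peaks assigned within ±600 kb of the
TSS, promoter ±1.5 kb, strand-aware, distances in kb). The standardized
potential enters a negative binomial through the same softmax-denominator
construction as the topic model; fixing the per-cell technical vectors $t$
and denominators $\kappa_i$ from a trained topic model augments the gene
model with batch awareness *without adding trainable parameters*. MAP
fitting uses softplus transforms for positivity, normal(0, 2) priors on the
unconstrained scale, and BFGS from three random restarts. Probabilistic
in-silico deletion scores a motif by the likelihood drop when its peaks are
masked; enrichment over a gene set is a one-sided rank-sum test with
Bonferroni correction across motifs.

## The synthetic confounded-trajectory generator

The simulator emulates benchmarks built by mixing reads from pure
cell-type populations along a differentiation tree: a stem root, myeloid
(monocyte/dendritic) and lymphoid (B/T) arms, with mixing weights linear in
a base-similarity parameter `k` (rows sum to one identically in `k`). Cells
sample a root-to-terminal path from a Markov chain in which `p_tcell`
splits the lymphoid arm; a Beta(0.5, 1) progress value places the cell along
the path (interpreted as the fractional position over the whole path and
mapped to an edge plus a within-edge fraction — the construction leaves this
mapping open; note the logistic blend $\sigma(2p_{\text{edge}}-1)$ spans
only [0.27, 0.73], so states hug the nodes), and the cell's reads are drawn
without replacement (multivariate hypergeometric) from one donor per
contributing population, with largest-remainder quota rounding so read
conservation is exact. Giving the two batches different `p_tcell` (1 vs 0)
makes the T branch exclusive to batch 1 and the B branch to batch 2 — the
"completely confounded" configuration.

Because no external reads can be assumed, donor pools are themselves
synthetic (`synthetic_base_populations()`): each of 7 types upregulates a
disjoint marker block (8-fold) over a shared log-normal baseline profile,
negative binomial counts (dispersion 3) at log-normal depths
(median 2500); batch 2 is distorted by gene-wise log-normal factors
(sd 0.3) and a 1.25× depth shift. These values were fixed once as a
moderate, realistic batch effect; they are deliberately *not* tuned. What
the generator does not emulate: ambient RNA, doublets, per-cell quality
gradients, or batch effects that interact with cell state nonlinearly — so
passing benchmarks here bounds behavior on clean confounding, not on every
real-data pathology.

## What the scaled-down experiments show — and what they do not

The package's validation experiments run at desk scale (hundreds to a few
thousand cells, hundreds of genes, minutes of CPU), a couple of orders of
magnitude below the scale at which the modeling approach was designed to
operate (tens of thousands of cells, thousands of genes, ~17k optimizer
steps). Three effects of this gap are visible and documented here because
they shape the validation results:

- **Parameter recovery** (500 cells, 100 genes, 4 topics, 24 epochs):
  permutation-matched effective loadings correlate with truth at ~0.7 on
  average. Loadings are compared on the standardized scale
  (`effective_loadings()`), since raw loadings are only identified up to the
  per-gene affine absorbed by batchnorm.
- **Entanglement** (2×1000-cell completely confounded benchmark, 300 genes,
  10 topics — one per base type plus slack, the top of the tuning range used
  for such benchmarks): the median per-gene correlation between biological
  and technical predictions drops consistently when the MI penalty is on.
  This is the regularizer's first-order effect and it survives scaling down.
- **Across-seed stability of technical-effect estimates**: at full scale the
  MI penalty collapses the seed-to-seed variance of $\hat t$ by an order of
  magnitude. At desk scale the across-seed variance is dominated by
  *topic-allocation multimodality* — with ~100-200 cells per terminal
  branch, different seeds allocate topics differently (occasionally merging
  the two batch-exclusive terminals), at MI weight 0 and 1 alike. The
  regularizer cannot remove that mode of variance, and with only ~384
  critic updates the bound stays loose; the measured fold-reduction is
  ~1.1–1.3×, far below the full-scale effect. We report this honestly
  rather than re-tuning the generator to manufacture the contrast.
- **Branch recovery by clustering**: k-means with one center per tree
  segment against segment labels reaches ARI ~0.5–0.65. The latent clusters
  are essentially pure (confusion tables are block-structured); the ARI
  ceiling comes from k-means splitting the dominant stem continuum (over
  half the cells, by the Beta(0.5, 1) progress law) before resolving
  ~80-cell terminal branches. A trajectory-aware metric would be the right
  instrument; it is outside this package's scope.

## Numerical choices

Log-variances clamped to [−10, 10]; softmax with max subtraction; the MI
bound's log-mean-exp stabilized the same way; batchnorm eval statistics are
exponential running averages (momentum 0.1); power iteration uses one step
per normalization call with persistent vectors (so the spectral-norm bound
is tight at the training operating point, not after a single cold call);
topic matching is exact (exhaustive) up to 8 topics and greedy beyond; ties
in k-nearest-neighbor distances exclude self-matches explicitly. Problem
sizes in the test suite (e.g. 3 seeds × 2 weights in the scripted
experiment, 5 × 2 in the test suite) were chosen as the smallest that
leave the comparisons interpretable.
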