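---
title: "Predicting risk perception from semantic embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting risk perception from semantic embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riskembed` implements a pipeline for predicting mean human risk ratings
from semantic representations and for interpreting what those predictions
do and do not capture. This vignette documents the statistical model, every
tunable parameter that matters, the numerical conventions, the design
decisions that were genuinely open, and the limits of what the synthetic
validation shows.

## 1. The model

The response variable is a per-term mean risk rating on a −100..100 scale
(negative = safe, positive = risky). Predictors are one or more *feature
blocks* over the same terms:

* the nine psychometric item means (1..7 scale: voluntariness, immediacy,
  knowledge to the exposed, knowledge to science, controllability, novelty,
  catastrophic potential, dread, fatality);
* word-embedding vectors, either pretrained (read from word2vec text
  format) or trained in the package from free-association data.

The association embedding follows a three-step procedure. A long table of
(cue, response, count) records is arranged into a sparse cue × response
count matrix **M**, keeping only responses whose total count is strictly
greater than a cutoff (default 5 — the conventional noise floor for
association norms). **M** is transformed to positive pointwise mutual
information,
$$M'_{cr} = \max\!\Big(0,\ \log\frac{n_{cr}\,N}{n_{c\cdot}\,n_{\cdot r}}\Big),$$
which removes marginal frequency effects, and the rank-\(k\) truncated SVD
\(M' \approx U \Sigma V^*\) yields the cue vectors \(U\Sigma\) (the
response-side vectors \(V\) are discarded).

Prediction uses elastic-net regression: squared-error loss with penalty
\(\alpha\,[\,l_1\|\beta\|_1 + \tfrac{1-l_1}{2}\|\beta\|_2^2\,]\). The
fitting itself is delegated to `glmnet` (with `lambda` = \(\alpha\) and
glmnet's `alpha` = the mixing ratio \(l_1\)); the package owns the
evaluation protocol around it:

* **Nested CV.** 10 outer folds × 10 repeats, each repeat reshuffling rows
  with a seed derived deterministically from the master seed. On each outer
  training set, the hyperparameter pair is chosen by inner 10-fold CV over
  the full 11 × 8 grid (mixing ratio in 11 even steps on [0, 1]; penalty
  magnitude in 8 exponential steps, `10^seq(-5, 2, length.out = 8)`); the
  winner is refit on the outer training set and scored on the held-out fold
  by \(R^2 = 1 - SS_{res}/SS_{tot}\) around the held-out mean. The grand
  mean over all 100 fold scores is the headline performance estimate. Ties
  on the grid resolve to the first grid position (mixing ratio varying
  slowest), deterministically.
* **No standardization.** Predictors are not standardized inside the
  elastic net (a flag exists). SVD-based embeddings concentrate variance in
  leading dimensions by construction; per-column standardization destroys
  that structure and measurably hurts them. Instead, *groupwise scaling*
  multiplies each block by one scalar so its mean column SD (sample, n−1
  denominator) equals the psychometric block's. The average penalty per
  dimension is then comparable across blocks while within-block anisotropy
  is preserved. The psychometric block is never rescaled.
* **Confidence intervals.** For comparing models evaluated on the same
  folds, `adjusted_ci()` removes the shared fold effect (centering each
  fold's scores across models), applies the \(\sqrt{m/(m-1)}\)
  small-sample correction for \(m\) models, and forms a normal-theory 95%
  interval — the standard within-design adjustment for repeated-measures
  comparisons.

## 2. Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_response_freq` | 5 | total count per response | responses at or below it are dropped (strictly-greater rule); matches the conventional cutoff for association norms |
| `k` (SVD rank) | — | dimensions | chosen by the analyst; must not exceed min(n cues, n responses) |
| `l1_ratio_grid` | 11 even steps on [0, 1] | — | spans ridge to lasso |
| `alpha_grid` | `10^seq(-5, 2, 8)` | penalty magnitude | log-uniform; covers effectively-unpenalized to fully-shrunk |
| `outer_folds`, `repeats` | 10, 10 | — | 100 fold scores stabilize the grand mean |
| `inner_folds` | 10 | — | the inner fold count is a free protocol choice; exposed in `cv_config()` |
| `bigram_policy` | `mean_of_words` | — | bigram risks average constituent word vectors; `strict` reproduces vocabulary-intersection behaviour |
| `similarity_stat` | `max` | — | a word close to *any* known risk is risk-like; `mean` available |
| `temperature` | 0.1 | softmax units of cosine | association generator concentration; see §3 |
| `responses_per_cue` | 300 | tokens per cue | ≈ 100 participants × 3 responses, the scale of large association studies |

Thresholds with no principled default (the "very low frequency" cutoff in
vocabulary filtering) are required arguments rather than defaults.

## 3. What the synthetic generator emulates — and what it does not

`make_world()` draws standard-normal latent vectors \(z_i \in
\mathbb{R}^{k}\) per word and builds every observable as a noisy linear
function of them: risk means as \(z_i^\top w + \varepsilon\) mapped
affinely onto [−100, 100], the nine psychometric items likewise onto
[1, 7], and each word norm from its own loading vector. Noise is calibrated
in closed form so the population R² of the best linear predictor equals a
chosen ceiling: \(\sigma^2_\varepsilon = \sigma^2_{signal}(1-R^2)/R^2\).
The affine maps place 3.29 population SDs at the scale bounds, so clipping
touches ~0.1% of draws and the ceiling calculation stays valid. By default
affect norms load on the risk-weight direction (mirroring the empirical
primacy of affect in risk perception) while frequency and concreteness
norms load on orthogonal directions; any loading pattern can be planted
explicitly.

Associations are drawn per cue from a softmax over latent cosine
similarity divided by a temperature. At the default temperature 0.1 the
modal response takes ≈ 11% of the mass and a cue elicits ≈ 100 distinct
responses out of 300 draws — the concentration profile of real association
norms. The generator is deliberately minimal: it does not model
participant-level response chaining, cue-dependent response availability,
or any nonlinearity between meaning and ratings.

Two structural gaps between generator and reality bound what passing tests
show. First, the cosine channel transmits only the *direction* of each
latent vector; since the ratings also depend on vector *magnitude*, the
variance recoverable from associations alone is capped at roughly
\((1 - 1/(2k))\) of the ceiling before any estimation loss — an inherent
property of this generator family, not of the pipeline. Second, real
association data reflect retrieval processes that are not a similarity
softmax, so high recovery here does not certify accuracy on real norms; it
certifies that the implementation extracts planted linear structure
correctly.

## 4. Numerical conventions and degenerate inputs

* PPMI uses the natural logarithm; the base only rescales all dimensions
  uniformly and is absorbed by the regression, but one base must be fixed.
  Zero-count cells map to zero without evaluating the log, preserving
  sparsity. No context-distribution smoothing and no shifted PPMI.
* SVD sign indeterminacy is fixed by forcing the largest-magnitude entry of
  each left singular vector positive; ties among singular values retain
  backend order (a residual nondeterminism risk across LAPACK builds,
  irrelevant for generic matrices).
* Token policy: Unicode NFC, surrounding whitespace stripped, lowercasing
  off by default (association cues are case-preserving) and applied
  uniformly by every reader when requested.
* The machine-vote threshold is the empirical type-1 quantile of candidate
  scores at (1 − human rate), so the positive rate matches the human rate
  exactly up to ties.
* Degenerate scoring rules are declared, not inferred: all-equal document
  means scale to 0; documents with no scorable word are flagged unscored;
  a constant norm is flagged and excluded from its group mean; a constant
  response is an error (R² undefined).
* Lemma deduplication keeps the most frequent word per lemma, ties broken
  lexicographically; filter order is frequency → lemma → sensitive.

## 5. Open design choices

* **Residuals for interpretability** default to out-of-fold (each term
  predicted only by models that never saw it; residual = observed − mean
  out-of-fold prediction across repeats). In-sample residuals shrink
  optimistically toward zero and would understate missing signal; they
  remain available for comparison via `residuals` on a `risk_enet` fit.
* **Shared variance of the norms** is reported as cross-validated R² under
  the same protocol as every other model, with an `in_sample` flag,
  keeping all variance-explained numbers on one scale.
* **Groupwise scaling before CV** (on the full matrix) follows the
  pipeline ordering of ensemble construction before evaluation; only scale
  information can leak, and a fold-wise variant is a one-line change in
  user code since blocks are plain matrices.
* **Per-norm correlation CIs** use the Fisher z transform, with the |r|
  interval floored at 0 when the r interval straddles zero.
* **Association table dialects**: both a long (cue, response, count) triple
  format and a wide participant-level format are accepted, since
  association exports vary; both funnel into one aggregated, deterministic
  representation.
* **Machine-vote seed lists** are pooled across source studies rather than
  voted per list; per-list voting would need a second combination rule with
  no evident benefit.

## 6. Problem sizes used in validation

The shipped tests validate exact contracts (PPMI formula, SVD Gram
reconstruction, scaling idempotence, vote truth tables, coverage and
scaling arithmetic) at small sizes, and statistical contracts at moderate
ones chosen to keep the full suite within a few minutes: the no-leakage
null at n = 300, p = 50; ceiling recovery at n = 1000, p = 50; the
end-to-end association pipeline at 800 cues over a 1000-word world with a
0.80 ceiling; the planted missing-dimension interpretability analysis at
n = 600. `scripts/acceptance.R` re-runs the full synthetic study (800
rated cues, full 10×10 nested CV for three models, interpretability,
curation and corpus scoring) from one master seed.

## 7. Known limitations

* The elastic-net hyperparameter search is exhaustive over a fixed grid;
  no warm-started path tricks across folds, by design (determinism and
  faithfulness to the protocol above raw speed).
* `svd_embed()` densifies its input; for count matrices in the tens of
  thousands of rows a sparse truncated solver would be preferable.
* Bigram handling by word-vector averaging is a crude composition model;
  phrase vectors, where available, are preferred via `phrase_then_mean`.
* The 2-D corpus projection (UMAP in typical use) is intentionally not
  bundled: `tfidf_matrix()` returns the matrix and any reducer can consume
  it.
* Coverage counts distinct vocabulary types per document; a headline
  repeating one risk word still counts 1. Token-level counting would
  overstate coverage of repetitive headlines.
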