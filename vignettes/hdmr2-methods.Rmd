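---
title: "Methods: second-order HDMR classification and the MTM interaction test"
author: "hdmr2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-order HDMR classification and the MTM interaction test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmr2)
```

## The model

`hdmr2` addresses small-sample binary classification of (log-)expression
data under two constraints that rule out most black-box learners: the
decision rule must be interpretable gene by gene, and gene–gene
interactions must be allowed to carry information that no single gene
carries. The framework rests on the high dimensional model representation
(HDMR) of the log-likelihood ratio
$L(X) = \log \frac{P(y = 1 \mid X)}{P(y = 0 \mid X)}$:
the second-order expansion approximates $L(X)$ by a constant plus a sum of
one-dimensional terms $S(X_f)$ and two-dimensional interaction terms
$S(X_{f_i, f_j})$. Computing the exact expansion would require the full
joint distribution, so the package instead builds a *linear approximation*
from plug-in log-likelihood-ratio estimates of partial observations:

- an **LLR machine** per feature and per feature pair: a regularized
  Gaussian discriminant estimator returning
  $L(x_u) = \log N(x_u;\hat\mu_1, \hat\Sigma_1) -
  \log N(x_u;\hat\mu_0, \hat\Sigma_0)$ for $|u| \le 2$;
- the **interaction term** of a pair is its excess over the marginals,
  $S(X_{f_i,f_j}) = L(x_{f_i,f_j}) - S(X_{f_i}) - S(X_{f_j})$, which is
  identically zero whenever the fitted pair density factorizes into the two
  fitted marginals;
- a **risk** per feature, $r^f$, and per pair, $r^{f_i,f_j}$: the
  between-class difference of the mean training-set term. Risks are on the
  log-likelihood-ratio scale for every coordinate, which is what makes the
  model a glass box: each selected gene or pair reports how much it moves
  the decision statistic on average.

Weak coordinates are screened out (`r^f > T1` keeps a feature,
`|r^{f_i,f_j}| > T2` keeps a pair, both strict, and a pair dies with either
member). The surviving terms form the feature vector $V(x)$, and the weights
are the closed-form maximizer of the between-class gap of the projected
training points over the unit sphere,
$b^* = d / \lVert d \rVert_2$ with $d$ the between-class mean difference of
$V$ — the 1-bit compressed-sensing style surrogate for the intractable
regression onto the true HDMR coefficients. The score is
$R(X) = b^* \cdot V(X)$ and the label is $\mathbf{1}\{R(X) > T\}$.
This is **LAS-HDMR** (`train_las_hdmr()`).

**LABS-HDMR** (`train_labs_hdmr()`) replaces the individual pair
coordinates by per-feature blocks: $P^{f_i}$ collects the partners with pair
risk above $T2$, $N^{f_i}$ those below $-T2$; block risks are the means of
the member-pair risks; blocks weaker than $T3$ (strict) are pruned, and each
surviving block contributes one coordinate equal to the mean of its member
pairs' $S$ terms. A surviving pair belongs to the block of *each* member, so
it is deliberately counted twice in $V$ — that is what the printed set
definitions imply, and we keep it (documented rather than "fixed") because
it preserves the per-feature reading of every block.

There is no intercept term in the fitted model: the expansion's constant is
absorbed by the decision threshold $T$, as is the class-prior log-ratio,
which the machines deliberately exclude. $T$ defaults to the midpoint of the
class means of the training scores and is swept when ROC curves are
reported.

## The LLR machines

`fit_gaussian_llr()` estimates class means and unbiased class covariances,
then shrinks toward the scaled identity,
$\hat\Sigma^{reg}_y = (1-\lambda)\hat\Sigma_y +
\lambda\,\frac{\mathrm{tr}(\hat\Sigma_y)}{|u|} I$, $\lambda \in [0,1]$.
With `kind = "linear"` the raw covariances are pooled with weights
$(n_y - 1)/(n_0 + n_1 - 2)$ *before* shrinkage and shared by both classes
(RLDA-style); `kind = "quadratic"` keeps per-class covariances
(RQDA-style). The convex-shrinkage convention was chosen because it keeps
the published endpoint semantics — $\lambda = 0$ is the plain LDA/QDA
plug-in, $\lambda = 1$ a spherical per-class model — and guarantees
positive-definiteness in between. Resubstitution LLRs (machines fitted on
the full training set, evaluated on it) are used for the risks, exactly as
the risk definitions are written; an out-of-fold variant would be easy but
would no longer match them.

Numerical safeguards, in order of application: diagonal covariance entries
are floored at $10^{-8}\times$ the feature's overall sample variance (or
$10^{-8}$ absolute for a constant feature); the implied pair correlation is
capped at $1 - 10^{-6}$ in magnitude so the $2\times 2$ matrix stays
strictly positive definite even for perfectly collinear features at
$\lambda = 0$. An all-constant feature subset is an error, not a silent
fallback.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `T1` | feature risk cut (LLR units) | `-Inf` | keep everything until tuned |
| `T2` | pair risk magnitude cut | `0` | any nonzero interaction enters |
| `T3` | block risk cut (LABS) | `0` | all non-empty blocks kept |
| `T`  | decision threshold on `R(X)` | training midpoint | absorbs prior + intercept |
| `lambda` | covariance shrinkage | `0.5` | mid-grid; tune over `0:0.1:1` |
| `kind` | pooled vs per-class covariance | `quadratic` | interactions need class-specific covariance |
| `pairs_over` | pair candidate set | `survivors` | all-pairs is quadratic in features |

`tune_hdmr()` grid-searches these by stratified k-fold cross-validation
(default 5 folds, fold assignment from an explicit seed), scoring each grid
point by mean out-of-fold AUC; a grid point whose screening empties the
model scores 0.5 instead of aborting. Ties break toward fewer selected
coordinates, then the smaller `(T1, T2, T3)`. `default_risk_grids()`
proposes `T1`/`T2` candidates at the 0/25/50/75th percentiles of the
observed risk distributions. Outside of cross-validation an empty selection
is a hard error: in a glass-box tool surprises should be loud.

## The MTM interaction test

A pair's interaction is *class-differential* — a second-order term is
genuinely needed — exactly when (the features are dependent in at least one
class) **and** (the two class covariance matrices differ). For jointly
Gaussian pairs `run_mtm()` tests this composite null by multiple test
mixing:

1. per-class Pearson correlation tests
   ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, $n-2$ df, two-sided);
2. Fisher's method across the two classes:
   $C = -2(\ln p_0 + \ln p_1) \sim \chi^2_4$ under the null (p-values
   clamped at $10^{-300}$ before the logs);
3. covariance equality by the likelihood-ratio (Box's M) test with the
   chi-square adjustment — for $p = 2$ features and $g = 2$ groups the
   reference distribution has $p(p+1)(g-1)/2 = 3$ df and scale factor
   $c_1 = \frac{13}{18}\left(\frac{1}{n_0-1} + \frac{1}{n_1-1} -
   \frac{1}{N-2}\right)$;
4. union-bound combination $p = \min(1, p_{\text{Fisher}} + p_{\text{cov}})$
   — a deliberate overestimate, so the test is conservative by
   construction (the suite verifies the empirical rejection rate never
   exceeds the nominal level);
5. Benjamini–Hochberg adjustment across pairs, with the denominator equal
   to the number of *performed* tests: pairs left with fewer than 4 usable
   samples in a class, a constant member, or a singular class covariance
   are flagged untestable, logged, and excluded.

Before testing, outliers are removed per feature and per class by the
3-scaled-MAD rule (scaled MAD $= 1.4826 \times$ median absolute deviation;
zero MAD removes nothing). The default policy is *pairwise deletion*: a
sample flagged in either member is dropped from that pair's tests only,
avoiding global sample loss; `outlier_policy = "global"` drops flagged
samples everywhere, `"none"` disables removal.

The sweep is fully vectorized (pairwise-deletion counts, means, variances
and covariances come from masked cross-products), and the test suite pins
it exactly to the scalar per-pair route `mtm_pair_test()`. `pair_graph()`
summarizes the result as a weighted gene graph: each gene scored by its
minimum incident combined p-value, edges weighted $-\ln p$.

## Feature ranking and probe collapsing

`lrt_score()` is the classical two-sample Gaussian generalized
likelihood-ratio statistic on mean and variance with MLE variances,
$N\ln\hat\sigma^2_{H_0} - n_0\ln\hat\sigma^2_0 - n_1\ln\hat\sigma^2_1$.
Only the induced ranking is consumed downstream (`top_k()`, then probe
collapsing by highest score per gene with lexicographic tie-breaks in
`collapse_probes()`), so any order-preserving variant of the statistic
yields the identical pipeline; we use the affine-invariant GLRT because it
is the canonical such score under independent Gaussian models.

## The synthetic generator

`generate_expression()` draws the population the classifiers and MTM are
validated on. It emulates four feature types of expression data:

- **global markers** in correlated blocks of `k`: class 0
  $N(0, \sigma_0^2\Sigma_0)$, class 1 $N(\mu, \sigma_1^2\Sigma_1)$ with
  equicorrelation matrices ($\rho_y$ off-diagonal) and mean
  $[1, 1/2, \dots, 1/k]$ (*synergetic*) or $[1, 0, \dots, 0]$
  (*marginal*);
- **heterogeneous markers**: class-0-like blocks that are dysregulated only
  in one of `c` class-1 subclasses. Class-1 samples are assigned a subclass
  uniformly at random; blocks cycle through the subclasses so every
  subclass drives some blocks. The source description ("certain points
  follow a distribution similar to class 1") leaves the
  block-to-subclass map open; one subclass per block with uniform sample
  assignment is the simplest reading consistent with `c = 2` and is fixed
  here once;
- **low-variance non-markers**: the class-0 marker distribution in both
  classes, in blocks of `k`;
- **high-variance non-markers**: independent features, each a mixture
  $pN(0, \sigma_0^2) + (1-p)N(1, \sigma_1^2)$ with $p$ drawn once per
  feature (not per sample — the weight is a property of the feature).

Defaults follow the published benchmark conditions:
$\sigma_0^2 = 0.25$, $\sigma_1^2 = 0.64$, $k = 10$, $c = 2$, and the four
`scenario()` presets pair synergetic/marginal means with equal
($\rho_0 = \rho_1 = 0.5$) or unequal ($\rho_0 = 0.1$, $\rho_1 = 0.9$)
correlations. The classifier preset uses 60 features, all heterogeneous
(the hardest marker type); the MTM preset uses 5000 features with 20 global
and 80 heterogeneous markers, 2000 high-variance non-markers and — since
only three of the four counts are stated — the remaining 2900 as
low-variance background. When the MTM preset is rescaled
(`total_features`), the 100 marker features are kept, the high-variance
share stays at 40% of the total, and low-variance features absorb the rest.

Ground truth for detection benchmarks: the interacting pairs are the
within-block marker pairs whenever the class-conditional bivariate
covariances differ ($\sigma_0^2 \ne \sigma_1^2$ or $\rho_0 \ne \rho_1$) and
the correlations are not both zero. Equicorrelation validity
($\rho > -1/(k-1)$), exact per-class stratification, and bit-level seed
determinism are enforced/tested.

What the generator does *not* emulate: technical noise and normalization
artifacts, heavy tails, probe-level redundancy, or imbalanced subclass
proportions. Tests passing on this population therefore certify the
algorithms' behavior under their own modeling assumptions — Gaussian blocks
with class-dependent covariance — not performance on any particular
clinical dataset.

## Evaluation

`roc_auc()` computes AUC by the Mann–Whitney rank statistic with midrank
ties, and the threshold-sweep curve whose trapezoidal area equals it
(pinned to `1e-12` in the suite, and cross-checked against an established
ROC implementation). Balanced accuracy at an operating point is
$1 - (P_I + P_{II})/2$. `repeated_experiment()` drives learning curves:
per repetition a fresh stratified training sample and an independent
stratified test sample are drawn, with per-repetition seeds derived
deterministically from the master seed so results are independent of
execution order. `mtm_detection_experiment()` does the same for MTM,
reporting per-repetition detection AUCs and a vertically averaged ROC (mean
TPR on a fixed 101-point FPR grid).

Problem sizes used by the shipped tests are deliberately desk-scale — 20
repetitions and 500–1000 test samples per class for learning curves, a
500-feature reduction of the MTM population, 50 repetitions of the 200-gene
null sweep — chosen so the whole suite certifies the claimed orderings
(more data helps; unequal correlations are easier to detect; the null is
conserved) within minutes. Full-scale runs are one argument away
(`reps`, `n_test`, `total_features`).

## Known limitations

- The expansion stops at order two; three-way interactions fold into pairs
  or vanish. Higher orders are a stated open direction, not implemented.
- Only Gaussian LLR machines ship. The machine interface is pluggable by
  construction (anything with `llr_score()` semantics), but mixing machine
  families per feature is untested territory.
- MTM's union-bound combination overestimates the p-value; power is traded
  for validity, and the test is anti-conservative nowhere but conservative
  everywhere (most visibly at small $n$).
- Pair screening over `T1` survivors (the default) can miss a pair whose
  members are individually uninformative; `pairs_over = "all"` restores
  them at quadratic cost.
- The risk statistics are resubstitution quantities; with very small
  classes they are optimistic, which is why thresholds should come from
  cross-validation rather than be interpreted absolutely.
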