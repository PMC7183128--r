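# hdmr2 — glass-box classification and differential co-expression for binary expression data

Small-sample, high-dimensional binary classification — relapse vs.
relapse-free from a few dozen transcriptomes — needs models that say *why*
they decide, gene by gene, and that can exploit gene–gene interactions
without estimating a full joint distribution. `hdmr2` implements a
framework built on the second-order high dimensional model representation
(HDMR) of the log-likelihood ratio
L(X) = log P(y=1|X)/P(y=0|X):

- **LAS-HDMR** — per-gene and per-gene-pair regularized Gaussian
  discriminant LLR machines produce S(X_f) and the interaction excess
  S(X_{fi,fj}) = L(x_{fi,fj}) − S(X_fi) − S(X_fj); features and pairs are
  screened by their *risks* (between-class differences of the mean training
  LLR, r^f > T1 and |r^{fi,fj}| > T2); the survivors form V(x) and are
  combined with the unit-norm weights b\* = d/‖d‖₂ maximizing the
  between-class gap of the projected training points; the score is
  R(X) = b\*·V(X), the label **1**{R(X) > T}.
- **LABS-HDMR** — the block variant: surviving pairs merge into per-feature
  risk-increasing/decreasing blocks P^f = {f′ : r^{f,f′} > T2},
  N^f = {f′ : r^{f,f′} < −T2}; weak blocks (mean member risk below T3) are
  pruned and each block contributes the mean of its members' S terms.
- **MTM** (multiple test mixing) — a test for *class-differential* pairwise
  co-expression: per-class Pearson independence tests combined by Fisher's
  method (C = −2(ln p₀ + ln p₁) ~ χ²₄ under the null), a covariance-equality
  likelihood-ratio (Box's M) test with the χ² adjustment (3 df for a
  bivariate two-group problem), union-bound combination
  p = min(1, p_Fisher + p_cov), 3-scaled-MAD outlier screening, and
  Benjamini–Hochberg FDR control over the testable pairs.
- A two-sample Gaussian **LRT gene ranking** with highest-scoring-probe
  collapse, a **block-covariance expression simulator** (global /
  heterogeneous markers, low- and high-variance non-markers, with ground
  truth for detection benchmarks), and **ROC/AUC experiment drivers**.

Everything is driven by plain TSV/CSV matrices and is deterministic given a
seed. The methods vignette (`vignettes/hdmr2-methods.Rmd`) documents the
model, the defaults, and the numerical choices.

## Worked example

Train LAS-HDMR on a hard synthetic population (60 heterogeneous marker
features in correlated blocks; class correlations 0.1 vs 0.9) and test MTM
on a 500-feature screen:

```r
library(hdmr2)

cfg <- scenario(2, seed = 42)         # synergetic markers, rho0 = 0.1, rho1 = 0.9
sim <- generate_expression(cfg, n0 = 20, n1 = 20)
sim$data
#> expr_matrix: 40 samples x 60 features; labels: 20 class-0 / 20 class-1

model <- train_las_hdmr(sim$data, hdmr_params(T1 = 0, T2 = 0.05, lambda = 0.5))
model
#> LAS-HDMR model: 60 features, 1151 pairs; T1 = 0, T2 = 0.05, T = 4.587
round(head(sort(model$risks$r_pair, decreasing = TRUE), 3), 2)
#> F0011|F0031 F0012|F0031 F0025|F0029
#>        1.11        0.97        0.92

test <- generate_expression(cfg, 1000, 1000, seed = 43)$data
roc_auc(hdmr_score(model, test$values), test$labels)
#> ROC: AUC = 0.8100 (2001 curve points)

mtm_cfg <- scenario(2, preset = "mtm", total_features = 500, seed = 42)
msim <- generate_expression(mtm_cfg, 40, 40)
res <- run_mtm(msim$data, fdr = 0.05)
res
#> MTM sweep: 124750 pairs enumerated, 124750 testable, 88 significant at BH 0.05
mtm_roc(res, msim$truth)
#> ROC: AUC = 0.9631 (77231 curve points)
```

Reading the numbers: from 40 training samples the model holds a test-set
AUC of 0.81, and every selected coordinate is interpretable — the top pair
risks (≈ 1 on the log-likelihood-ratio scale) say how much those gene pairs
move the decision statistic between classes on average. On the 500-gene
screen MTM flags 88 of 124,750 pairs at 5% FDR and ranks the truly
interacting within-block marker pairs near the top (detection AUC 0.96).

A command-line surface over the same functions ships in `inst/cli/hdmr2`
with subcommands `simulate`, `rank`, `train`, `predict`, `mtm` and
`evaluate`, e.g.

```sh
Rscript inst/cli/hdmr2 simulate --scenario 2 --n0 20 --n1 20 --seed 5 --out-prefix sim
Rscript inst/cli/hdmr2 train --matrix sim_matrix.tsv --labels sim_labels.tsv \
    --T1 0 --T2 0.05 --model-out model.json
Rscript inst/cli/hdmr2 predict --model model.json --matrix sim_matrix.tsv --out scores.tsv
```

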