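---
title: "Heritability estimation by regularized regression: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability estimation by regularized regression: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimand and the model

Narrow-sense heritability $h^2$ is the share of phenotypic variance
explained by additive genetic effects. For a continuous trait the working
model is

$$ Y_i = \mu + \sum_{j=1}^{p} X_{ij} u_j + e_i, \qquad
   e_i \sim N(0, \sigma^2_e), $$

with $X_{ij}$ the standardized additive genotype (mean 0, variance 1) at
the $j$-th of $p$ unknown causal variants among $M \gg p$ genotyped SNPs,
so that $\sigma^2_g = \sum_j u_j^2$, $\sigma^2_Y = \sigma^2_g + \sigma^2_e$
and $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.

Rather than estimating $\sigma^2_g$ directly — which requires estimating
thousands of small, LD-confounded coefficients or a random-effects
approximation over mostly-null markers — the package estimates the pair
$(\sigma^2_Y, \sigma^2_e)$ and uses the identity

$$ h^2 = 1 - \sigma^2_e / \sigma^2_Y. $$

$\sigma^2_Y$ is trivial to estimate well (the $N-1$ empirical variance).
The work is in $\sigma^2_e$, estimated by a screening + refitted
cross-validation (RCV) pipeline:

1. **Screening** reduces $M$ below $N$: either SIS (rank SNPs by absolute
   marginal correlation with the outcome, keep a fixed top fraction) or
   ITRRS (iterate ridge fits within each chromosome, keeping the
   top fraction by absolute coefficient each round). ITRRS accounts for LD
   between SNPs and is preferred once $M$ is large (tens of thousands or
   more); SIS is adequate below roughly ten thousand SNPs.
2. **Selection**: the sample is split into random halves; a 10-fold
   cross-validated lasso on one half picks a parsimonious SNP set.
3. **Refit**: ordinary least squares of the outcome on the selected SNPs
   in the *other* half gives a residual-variance estimate that is
   conditionally unbiased, because the selection never saw that half's
   noise. The degrees-of-freedom correction is $n/2 - k - 1$ for a
   support of size $k$.
4. Roles are switched and the two estimates averaged.

Cross-fitting is what makes the estimate nearly unbiased: selected-but-null
SNPs cost only degrees of freedom in the refit, while a causal SNP (or a
good LD proxy of one) that is *missed* leaves its variance in the residual
and biases $\hat\sigma^2_e$ upward. This asymmetry drives several defaults
below.

## Binary outcomes and the liability scale

For a 0/1 outcome $D$ the same pipeline runs on the linear working model
$D_i = \alpha + X_i^T v + \epsilon_i$, with total variance
$\hat\sigma^2_D = \bar D (1 - \bar D)$, giving an observed-scale estimate
$\hat h^2_o$. The Robertson transform maps it to the liability scale,

$$ \hat h^2_l = \hat h^2_o \, K (1 - K) / z^2, $$

where $K$ is the population prevalence and $z = \varphi(\Phi^{-1}(1-K))$
is the standard-normal density at the threshold truncating the upper
proportion $K$. For case-control data ascertained to a sample case
fraction $P \ne K$ the corrected transform

$$ \hat h^2_l = \hat h^2_o \, K^2 (1 - K)^2 / \{P (1 - P) z^2\} $$

is used; the two coincide at $P = K$. `estimate_heritability()` defaults
$P$ to the sample case fraction, and $K$ must be supplied by the user —
disease prevalence is external epidemiological knowledge. With
$\hat h^2_o = 0.244$, $K = 0.004$ and $P = 4312/8668$ the corrected
transform gives $0.110$, the package's worked example.

## Censored age-at-onset outcomes

For failure times the model is a log-normal accelerated failure time
model, $Y^o_i = \log T_i = \mu + X_i^T u + e_i$, observed as
$Y_i = \min(Y^o_i, C_i)$ with event indicator $\delta_i$. The package uses
inverse-probability-of-censoring weighting (IPCW): with $\hat S_c$ the
Kaplan–Meier estimator of the *censoring* survival function (censorings
treated as events), each observation gets weight
$W_i = \delta_i / \hat S_c(Y_i^-)$. Censored rows get weight zero; events
are up-weighted by the inverse probability of having remained uncensored.
Evaluation uses the left limit — an event at $t$ never uses censoring
information at its own time — with event-before-censoring tie handling,
the standard IPCW convention.

Screening, lasso and refit all run weighted, and the outcome variance is

$$ \hat\sigma^2_{Y^o} =
   V_1 \sum_i W_i (Y_i - \bar Y_w)^2 / (V_1^2 - V_2), \qquad
   V_1 = \sum_i W_i,\; V_2 = \sum_i W_i^2 . $$

The $(V_1^2 - V_2)$ denominator is chosen so that with unit weights the
estimator reduces exactly to the usual $n-1$ sample variance (a
$(V_2 - V_1)$ denominator would be identically zero there). The same
logic extends to the weighted refit, whose denominator
$V_1 - (k+1) V_2 / V_1$ equals $n - k - 1$ under unit weights and matches
the $(V_1^2 - V_2)$ form at $k = 0$. A package invariant, enforced by
test, is that the zero-censoring survival path reproduces the continuous
path *bit for bit*.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `keep_fraction` | 0.3 (SIS), 0.5/iteration (ITRRS) | fraction of SNPs kept; moderate cutoffs with more iterations beat aggressive single cuts |
| `n_iterations` | 6 | ITRRS rounds; 5–6 with keep 0.5 reduces ~250K SNPs to a workable set |
| `shrinkage` | 0.01 | ridge penalty, applied as $\lambda N$ on standardized genotypes so sensitivity grids transfer across sample sizes |
| `cv_folds` | 10 | lasso cross-validation folds |
| `penalty_rule` | `"min"` | see below |
| `split_seed` | user | the whole estimate is deterministic given it |
| `n_calibration`, `n_replicates` | 100, 100 | weighted-bootstrap batches |
| `K` | user-supplied | population prevalence for the liability scale |

**Penalty rule.** The CV-minimum rule is the default for *every* outcome,
including censored ones. The one-SE rule is attractive when selection
stability is the goal, but here under-selection is the asymmetric risk:
the cross-fitted refit neutralizes over-selection, while every missed
causal effect inflates $\hat\sigma^2_e$. In desk-scale censored
experiments (N = 3000, ~750 events per half-sample) the one-SE rule
biased the mean heritability estimate by roughly $-0.09$ at a truth of
0.1, against $-0.04$ for CV-min, with a correspondingly inflated
$\hat\sigma^2_e$. One-SE remains available via
`rcv_config(penalty_rule = "one_se")`, and is the rule used inside
bootstrap penalty calibration, where weight noise argues for extra
regularization.

**Screening is deliberately outside the data split.** It uses the full
sample, which is justified asymptotically by the selection stage's oracle
property, and is also why the weighted bootstrap can hold the screen
fixed across replicates (its main cost saver). The practical cost is that
aggressive screening (many ITRRS iterations on a small sample) can leak
full-sample noise into the retained set; the refit then looks slightly
too good. Moderate keep-fractions at desk scales keep this negligible.

## The weighted bootstrap

Standard errors come from perturbing every observation's loss
contribution with i.i.d. positive mean-1, variance-1 weights — standard
exponential draws. (The weight law is this package's choice; any mean-1,
variance-1 positive law qualifies.) The penalty is first calibrated: over
`n_calibration` weighted datasets, the one-SE penalty is recorded for
both half-samples and averaged on the natural scale; this average is then
frozen and `n_replicates` weighted re-estimations of Steps 2–4 (selection,
refit, averaging — plus the weighted total variance) yield the SE as the
standard deviation of the replicate estimates. With degenerate unit
weights every replicate is identical and the SE is exactly zero, which is
enforced by test.

## The synthetic-data generator

`simulate_dataset()` emulates the benchmark designs end to end:

* **Genotypes** come from a pool of haplotypes (default 200) with local
  LD from a first-order copying process: the allele at locus $j+1$ copies
  locus $j$ with probability `ld_decay`, otherwise it is drawn fresh at
  that locus's target frequency (drawn from `maf_range`). Adjacent-allele
  correlation is ≈ `ld_decay`, decaying geometrically with distance, and
  chromosomes are independent. Haplotypes are drawn with replacement and
  paired into diploids. The default `ld_decay = 0.5` represents a
  moderately dense genotyping array; 0.9–0.95 emulates the dense-platform,
  high-LD regime of real haplotype panels.
* **Effects**: $p$ causal SNPs drawn uniformly (optionally restricted to
  MAF ≤ θ), with $u_j \sim N(0, \sigma^2_g / p)$ and
  $\sigma^2_g = h^2 \sigma^2_e / (1 - h^2)$ — so $h^2 \in \{0.1, 0.6\}$
  with $\sigma^2_e = 1$ gives $\sigma^2_g \in \{1/9, 1.5\}$. By default
  $\sum u_j^2$ matches $\sigma^2_g$ only in expectation; the
  exact-normalization mode rescales to equality, which recovery tests use
  so that every replicate has the same true $h^2$. $\mu = 0$ throughout.
* **Outcomes**: continuous $Y = X u + e$; binary via a liability threshold
  at the upper-$K$ theoretical quantile (exactly 0 at $K = 0.5$; the
  theoretical rather than empirical quantile keeps replicates
  independent); survival with log-scale censoring
  $C \sim N(0, \texttt{censor\_sd}^2)$, where the default sd of 2 yields
  ≈50% censoring.
* **Untyped-causal scenario**: causal SNPs and (default) 5 flanking SNPs
  per side are removed from the analysis set, leaving only LD proxies —
  the regime separating regression-based estimation from
  similarity-matrix methods.

What the generator does *not* emulate: realistic recombination maps,
population structure and relatedness, genotyping/imputation error, and
MAF-dependent LD (the copying process gives correlations that are nearly
MAF-free). Passing recovery tests therefore demonstrates correctness of
the estimator under its own model assumptions, not robustness to
confounding in real cohorts.

## Numerical choices

* Standardization uses the sample mean and $N-1$ standard deviation, so
  the mean-0/variance-1 invariant is exact and testable; allele-frequency
  based scaling ($2q(1-q)$) would differ only by $O_p(N^{-1/2})$ and the
  estimate is invariant to allele flips after standardization.
* Missing genotypes are mean-imputed per SNP at load (imputed entries
  standardize to exactly 0); monomorphic SNPs are dropped.
* Ridge fits solve the exact penalized normal equations — primal when
  columns ≤ rows, dual (kernel) form otherwise — with an unpenalized
  intercept.
* All rank ties (screening correlations, ridge/lasso coefficient
  magnitudes) break toward the lower SNP index, so screening is
  reproducible without a seed.
* Empty lasso support degenerates to the (weighted) sample variance of
  the outcome, keeping the estimator defined under $h^2 = 0$.
* The lasso path uses 40 penalties down to 2% of the maximum; the CV
  choice is made once per half-sample run, with folds assigned
  deterministically from `split_seed`.
* $\hat h^2$ is reported unclipped with a range flag; clipping to
  $[0, 1]$ is opt-in, because bias assessment needs the raw value.

## Desk-scale test sizes

The test suite and acceptance script run scaled-down analogues of the
published designs, chosen to finish in minutes on one CPU: five
pseudo-chromosome runs at $N = 3000$, $M = 3000$, $p = 100$ (survival,
both $h^2 = 0.1$ and $0.6$, ≈50% censoring, `ld_decay = 0.9`);
the untyped-causal scenario at $N = 3000$, $M = 3000$, $p = 60$,
`ld_decay = 0.95`; binary at $N = 6000$, $M = 1000$, $K = 0.5$; and an
asymptotic-variance check at $N = 2000$ with $p = 5$ strong causals.
Full-scale replications ($N$ up to 20{,}000, $M$ = 35{,}760) use the same
code paths and are supported but not run by default.

## Known limitations

* **Censored outcomes need large samples.** With ≈50% censoring only half
  the observations carry outcome information into each half-sample fit.
  At $N = 3000$ and $h^2 = 0.6$ the selected SNP set cannot span enough
  of the genetic variance and $\hat\sigma^2_e$ retains an upward bias of
  ≈0.2 (hence $\hat h^2$ biased low by ≈0.1) across every screener and
  penalty configuration we profiled; the effect shrinks with $N$ and is
  absent in the continuous analogue at the same size. This is a genuine
  finite-sample property of the estimator, not an implementation artifact.
* **The asymptotic variance $4h^2(1-h^2)^2/N$ is oracle-premised.** It is
  approached only when the selection stage effectively recovers the
  support (few, strong causals). With many weak causals the replicate
  variance of $\hat h^2$ sits several-fold above the formula because the
  two half-sample estimates share missed-variance and lose their
  near-independence. Variance reporting should therefore rely on the
  weighted bootstrap, not the formula.
* IPCW assumes censoring independent of genotype and covariates
  (Kaplan–Meier); covariate-dependent censoring would need a survival
  model for the weights, which is out of scope.
* The estimator can return values outside $[0, 1]$ in small samples or
  under $h^2 \approx 0$; this is by design (unbiasedness near the
  boundary requires it).
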