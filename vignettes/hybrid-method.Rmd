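---
title: "Correcting a significant original study with its replication: the hybrid method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting a significant original study with its replication: the hybrid method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmeta)
```

## Model and assumptions

Two studies estimate a common true effect θ on an analysis scale where
sampling distributions are tractable: Hedges' *g* for mean differences
(noncentral-t sampling model) or Fisher's *z* for correlations (normal
model with known variance 1/(n − 3)).  The model is

* y~O~: the original study's effect, *observed only because it was
  statistically significant* — a one-tailed selection at level α/2
  (default .025, i.e. a two-tailed test at .05 of which only the expected
  direction is publishable);
* y~R~: the replication's effect, observed unconditionally.

The key identity is that of p-uniform: the conditional probability
q~O~(θ) = P(y ≥ y~O~; θ) / P(y ≥ y~O~^CV^; θ) is Uniform(0,1) at the true
θ, exactly as the replication's tail probability q~R~(θ) = P(y ≥ y~R~; θ)
is.  The combined statistic x(θ) = q~O~ + q~R~ therefore follows the
two-term Irwin–Hall (triangular) distribution at the truth, with CDF
F(x) = x²/2 on [0, 1] and −x²/2 + 2x − 1 on [1, 2].  Both q's — and hence
x — are increasing in θ, which makes x a pivot:

* **estimate**: solve x(θ̂) = 1 (equivalently F = .5);
* **confidence interval**: solve x(θ) = F⁻¹((1 ± level)/2);
* **test of θ = 0**: refer x(0) to F (one-tailed) or to the folded
  G(x) = 2·min(F, 1 − F) (two-tailed).

Since x(θ) is increasing, the *lower* confidence bound solves
F(x) = .025 and the *upper* solves F(x) = .975; this orientation
reproduces the worked example in `README.md` and is asserted by the test
suite.

Two variants temper the estimator's left tail, which can be strongly
negative when the original study is only marginally significant (q~O~
then barely responds to θ):

* **hybrid⁰** sets θ̂ = 0 whenever x(0) > 1 (combined evidence pointing
  negative), keeping hybrid's CI and p value;
* **hybridᴿ** returns the plain replication result whenever the
  original's two-tailed p exceeds α/2 (.025), because such an original
  implies a negative corrected effect that contradicts its own claim;
  ties at exactly .025 take the replication branch (the switching rule is
  stated with strict inequalities, and the boundary case already implies
  a non-positive corrected estimate).

Fixed-effect meta-analysis and replication-only estimation complete the
method set; both are standard normal-theory procedures with known
variances and make no selection correction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | .05 | two-tailed level of the original's selection test; the effective one-tailed selection level is `alpha/2` |
| `direction` | positive | expected sign; `negative` mirrors effects in and out |
| `ci_level` | .95 | level of all confidence intervals |
| `backend` | auto | `nct` (exact noncentral t) for mean designs, `normal` for correlations |
| `grid_n` | 1000 | evaluation-grid resolution per margin |

The `alpha/2` selection threshold and the hybridᴿ switching threshold are
the same number by construction: both mark the point where the corrected
effect estimate changes sign.

## Numerical choices

**Noncentral-t tails.** The conditional probability is a ratio of two
upper-tail probabilities.  For hypothesized effects far below the
observations (the region the CI lower bound lives in) both tails are of
order 10⁻¹⁰ or smaller, while `stats::pt()`'s noncentral algorithm only
guarantees ~10⁻¹² *absolute* accuracy — the computed ratio there is pure
noise.  `log_nct_sf()` therefore evaluates log P(T > t; df, ncp) by
Gauss–Legendre quadrature (400 nodes) over the chi mixing distribution of
T = (Z + ncp)/(S/√df), accumulated in log space.  This retains full
relative accuracy at any ncp; the test suite checks it against `pt()`
where `pt()` is reliable and against monotonicity where it is not.  A
consequence worth knowing: a published lower bound for the worked example
obtained with unstable tail arithmetic differs from the exact value
(−1.222) by about 0.11; the upper bound and point estimate are unaffected
to three decimals.

**Root finding.** Scalar fits bracket x(θ) = target on [−6, 6] (analysis
scale), doubling the bracket up to four times before declaring failure,
then call `uniroot()` with tolerance 10⁻¹⁰; the fitted estimate satisfies
|x(θ̂) − 1| < 10⁻⁸.  The evaluation grid instead uses a fixed 60-iteration
vectorized bisection on [−10, 10] across all cells simultaneously —
deterministic, seed-free, and bit-reproducible.  Cells whose true root
lies beyond the bracket saturate at ±10, which is indistinguishable from
±∞ after the tanh back-transform (|tanh(10)| differs from 1 by 4·10⁻⁹,
far below grid resolution).

**Clipping.** q values are clipped to [10⁻³⁰⁰, 1] and x to [0, 2] before
Irwin–Hall evaluation, absorbing floating-point underflow at extreme θ.

**Degenerate inputs.** An original exactly at its critical value has
q~O~ ≡ 1 for every θ; construction of a `study_pair` rejects
non-significant originals (the model conditions on selection) unless
`force = TRUE`, which tags results as outside the model's assumptions.

## The evaluation framework

`evaluate_condition()` reproduces estimator performance *analytically*
rather than by simulation: the marginal distribution of a significant
original is discretized into `grid_n` evenly spaced cumulative
probabilities P^O^~i~ = 1 − π + iπ/(grid_n + 1) (π = selection power),
the replication into P^R^~i~ = i/(grid_n + 1), and every method is applied
to each of the grid_n² equally weighted combinations on the Fisher-z
scale.  Mean, median, SD and RMSE are reported after back-transforming to
correlations; coverage and rejection use the z scale (the transform is
monotone, so the events are identical).  Hybrid coverage and rejection
are computed through the test-inversion identity — the CI contains ρ
exactly when x(atanh ρ) lies between the Irwin–Hall reference quantiles —
which avoids per-cell CI root-finding without any approximation.  SD uses
the population (1/N) denominator, so RMSE² = bias² + SD² holds exactly on
every cell; with a 10⁶-cell grid the distinction from the sample
denominator is far below reporting precision.

Default conditions mirror the published design: ρ ∈ {0, .1, .3, .5},
sample sizes from the quartiles of original-study sizes in the
Reproducibility Project: Psychology (31, 55, 96; 783 as the
powered-replication case), selection at one-tailed α = .025, and a
1000 × 1000 grid.  Rejection rates are one-tailed at .025 for every
method including fixed-effect meta-analysis — the reading under which the
replication's Type I error is exactly .025; it is configurable via
`alpha_one_tailed`.  The test suite exercises reduced grids (≥ 120 per
margin after a convergence check showed refinement changes the
reproduced means by < .003); the acceptance script uses the full
1000 × 1000 grid where the quantity is cheap (error rates) and a 300-point
grid where per-cell root-finding is involved.

`simulate_pair()`/`simulate_pairs()` are the seeded Monte-Carlo
counterpart (rejection sampling of significant originals), used for the
uniformity property tests and for user experiments.  The generator
emulates the analytic model exactly — normal Fisher-z sampling, known
variances, a single common effect, clean one-tailed selection.  It does
not emulate heterogeneity in true effects, p-hacking or questionable
research practices, approximate effect-size conversions, or partial
publication of non-significant results; passing tests therefore certify
the methods under their stated assumptions, not robustness to violations
of them.

## Design decisions that were genuinely open

* **Backend split.** The worked example's printed probabilities (q~O~ =
  .015/.025, two-tailed p ≈ .56) are only consistent with noncentral-t
  sampling distributions, while the analytic performance study and the
  prose assume normal ones.  Both backends are provided: `auto` uses t
  for mean designs and normal for correlations; either can be forced.
* **One-sample variance.** No published formula exists for the one-sample
  design's unbiased g variance in this context; the symmetric analogue
  1/n + [1 − (n−3)/((n−1)J²)]g² of the two-sample estimator is used.
* **Two-sample g variance.** The unbiased estimator is implemented as
  1/n₁ + 1/n₂ + [1 − (m−2)/(mJ²)]g², m = n₁ + n₂ − 2, which reproduces
  the reference weights (19.390, 39.863) to three decimals.
* **Observed power** follows the convention of the worked example: a
  one-tailed t test at the original's two-tailed α (.05), evaluated at
  the replication's estimate converted to Cohen's d.
* **hybrid⁰ truncation** applies to the point estimate only; interval and
  p value are those of hybrid, so the variant changes what you report,
  not what you can rule out.

## Limitations

* Exactly two studies; no random-effects extension (with k = 2 the
  heterogeneity variance is not estimable in practice) and no Irwin–Hall
  combination of more than two uniform summands.
* Effect measures are limited to standardized mean differences and
  correlations.
* The selection model is a sharp one-tailed threshold; graded or
  two-sided publication selection is not modeled.
* Conditional probabilities lose sensitivity to θ when the original's
  p value is close to its selection threshold; estimates and lower
  confidence bounds can then be extremely negative.  That is a property
  of the method — hybrid⁰ and hybridᴿ exist to manage it.
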