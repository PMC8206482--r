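---
title: "Simulating wording effects and their impact on categorical factor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating wording effects and their impact on categorical factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Balanced self-report scales mix positively worded (PW) and negatively worded
(NW) items that tap opposite poles of one construct. Some respondents answer
the two item types in logically inconsistent ways — the *wording (keying)
effect*. `wordingsim` implements a Monte Carlo laboratory for studying what
that inconsistency does to unidimensional categorical factor models: it
generates ordinal questionnaire data from a known population model,
contaminates a fraction of respondents with one of three mechanisms, fits two
structural models, and measures what survives.

The two fitted models are:

* **1F** (the "do-nothing" approach): one substantive factor measured by all
  items, with an external continuous criterion regressed on it.
* **RIIFA** (random intercept item factor analysis): the same model plus an
  orthogonal method factor whose unstandardized loadings are all fixed to 1
  and whose variance $\omega$ is free. The random intercept absorbs
  consistent individual shifts in response-scale use; the criterion is
  regressed on both factors.

In the correlation (delta) metric the implied structures are
$\Sigma_{1F} = \Lambda\Lambda' + \Theta$ and
$\Sigma_{RIIFA} = \mathbf{1}\omega\mathbf{1}' + \Lambda\Lambda' + \Theta$,
with unit diagonal, the substantive factor variance fixed to 1, and
uniquenesses $\theta_{ii} = 1 - \lambda_i^2 - \omega$ defined as remainders.
With the criterion path included, RIIFA spends two more parameters than 1F
($\omega$ and the wording-factor regression); the method factor alone costs
exactly one degree of freedom.

## The generating model

`generate_sample()` builds each uncontaminated data set as follows.

* **Loadings.** $k$ signed loadings drawn from $U(0.60, 0.80)$ (mean 0.70),
  with exactly $k/2$ random positions negated — the NW items. Loadings are
  redrawn for every replicate, so items have variable loadings across data
  sets.
* **Criterion.** A continuous variable loading 1.0 on a second factor that
  correlates 0.50 with the substantive factor (a strong criterion relation),
  giving population item-criterion correlations $0.5\,\lambda_i$.
* **Sampling.** The population correlation matrix
  $R_P = \Lambda\Phi\Lambda'$ (unities inserted on the diagonal) is
  Cholesky-factored, $R_P = U'U$, and samples are $X = ZU$ with $Z$ standard
  normal.
* **Categorization.** Item columns are cut at thresholds $-1.5, 0, 1.5$ into
  four symmetric categories (expected proportions 0.067/0.433/0.433/0.067);
  the criterion stays continuous. A value falling exactly on a threshold
  goes to the lower category — a measure-zero convention fixed for test
  determinism.
* **Inconsistency flags.** 40% of respondents (round-half-up) are flagged;
  only they are touched by contamination.

## The three contamination mechanisms

Each inconsistent respondent misresponds to `round(perc/100 * k)` items
(round-half-up, minimum one item when the percentage is positive).

* **Carelessness** (`apply_carelessness`): a random subset of NW items has
  its responses reversed ($1{=}4, 2{=}3$) — the respondent answers NW items
  as if they were PW. Carelessness is applied to NW items specifically; at
  50% of a balanced test this reverses every NW item.
* **Item verification difficulty** (`apply_ivd`): trait-conditional
  reversal. Respondents with an uncontaminated substantive factor score
  below 0 reverse PW items (false affirmations), those at or above 0 reverse
  NW items (false negations). The classification uses the 1F scores
  estimated on the uncontaminated matrix; a score of exactly 0 takes the
  high-trait branch (arbitrary, fixed).
* **Acquiescence** (`apply_acquiescence`): probabilistic upward switching.
  Items are drawn sequentially without replacement with selection weights
  0.50/0.33/0.17 for current categories 1/2/3 (category 4 is never changed),
  and remapped $1 \to 3$, $2 \to 3$ or $4$ (fair coin), $3 \to 4$, until the
  target count is reached or no eligible items remain (exhaustion is
  recorded, not re-drawn). We read the weights as per-draw selection
  probabilities; an item changed once becomes ineligible and the remaining
  weights follow the current (possibly updated) categories.

All three mechanisms leave consistent respondents' rows bit-identical, and
push reverse-coded sum scores of low-trait respondents up and of high-trait
respondents down.

## Estimation

`mixed_cor()` estimates the latent correlation matrix: two-step maximum
likelihood polychorics (thresholds fixed at the inverse-normal cumulative
proportions, the correlation maximizing the bivariate-normal cell
likelihood over $[-0.999, 0.999]$ with a 1e-8 optimizer tolerance), two-step
polyserials for the item-criterion column, per-correlation asymptotic
variances from the observed information, and per-observation influence
scores used by the robust test statistic. The bivariate normal CDF is
Genz's algorithm (compiled; accurate to ~1e-15). If the assembled matrix is
not positive definite it is repaired by eigenvalue clipping at 1e-6 and
re-normalization (flagged; never triggered on clean data of realistic
size). Cells with zero probability cannot occur inside the correlation
bracket, so log-likelihood floors (1e-12 per cell) are effectively dormant.

`fit_dwls()` fits either model by least squares on the non-redundant latent
correlations, from three deterministic starts seeded by the first
eigenvector of the item block. Two estimator flavors exist:

* `estimator = "uls"` (default): unweighted residuals. This is the
  package's estimator of record. We chose it after a calibration
  experiment: inverse-variance weighting systematically *under-shrinks* the
  1F loadings on heavily contaminated data, which contradicts the
  well-replicated behavior of robust WLS software on this design — under
  50% carelessness the contaminated structure implies
  $|\lambda| = \sqrt{0.294} \approx 0.54$ for a model that absorbs the
  block structure, and the unweighted compromise reproduces exactly that,
  along with its characteristic downstream pattern in loading error and
  score recovery. The weighted flavor remains available as
  `estimator = "dwls"`.
* The test statistic in the ULS flavor is the robust mean-and-variance
  adjusted (scaled-and-shifted) form $T = aF + b$ with
  $a = \sqrt{df/\mathrm{tr}((U\Gamma)^2)}$ and
  $b = df - a\,\mathrm{tr}(U\Gamma)$, where $\Gamma$ is the empirical
  asymptotic covariance of the correlation vector assembled from the
  influence scores and $U$ the residual projector at the solution. Traces
  are exact for up to 600 moments and estimated with 16 fixed-seed
  Rademacher probes above that (the probe seed is fixed, so results are
  bit-reproducible). The baseline model for CFI/TLI is the
  zero-correlation model with free thresholds. A known limitation: the
  correction internals of commercial WLSMV implementations are not public,
  and of the two indices CFI — which depends on the baseline statistic as
  well — is the more sensitive to that choice; cross-software comparisons
  of CFI under heavy misfit should be made with care.

**Identification and convergence.** The substantive factor variance is
fixed to 1; loadings, regressions and $\omega$ (parameterized as
$\sqrt\omega$ so box constraints keep it nonnegative) are free. A solution
counts as converged when the optimizer succeeds, all uniquenesses are
nonnegative, and — for RIIFA — $\omega \ge 10^{-6}$ *and* constraining
$\omega = 0$ genuinely worsens the fit (a plateau where it does not is a
boundary case, mirroring the empirical finding that the random intercept is
unidentified when wording variance is scarce). Boundary and Heywood cases
are reported with reason codes and excluded from downstream aggregation.

**Factor scores.** `eap_scores()` computes expected a posteriori scores
under the normal-ogive graded-response reparameterization
($a_i = \lambda_i/\sqrt{\theta_{ii}}$, category bounds from the estimated
thresholds), with 21-point Gauss–Hermite quadrature per dimension (two
dimensions for RIIFA, the wording dimension scaled by $\sqrt{\hat\omega}$).
When the fitted model contains the criterion regression, the standardized
criterion enters the posterior as a normal outcome with mean
$\beta_{sf}\eta + \beta_{wf}\zeta$ and residual variance $1 - R^2$: factor
scores condition on *every* observed variable of the model, exactly as SEM
software does. This choice is load-bearing — with items-only scores the
inconsistent respondents lose the one uncontaminated signal (the criterion)
and their recovery correlations drop far below the values this design is
known to produce. `use_criterion = FALSE` restores items-only scoring. The
21-node rule is accurate to about 2e-3 in score units against a dense-grid
oracle (4e-6 at 41 nodes); scoring precision at that level is immaterial
for the recovery correlations studied here, and one-dimensional users can
simply raise `n_quad`.

## Assessment and the factorial study

`run_replicate()` chains the steps for one (N, k) cell: generate, fit 1F to
the clean matrix (reference scores, reused for IVD classification), then for
each contamination percentage derive a contaminated matrix *from the same
clean sample*, fit both models, score, and assess. `run_study()` maps this
over the design. Every cell × replicate × purpose combination draws its own
substream seed (`substream_seed()`), so results are independent of execution
order and bit-reproducible.

Assessment per replicate (`loading_error`, `score_recovery`,
`wording_score_diagnostics`): mean bias error and mean absolute error of the
estimated substantive loadings per item polarity; Pearson correlations
between uncontaminated and contaminated scores over all / consistent /
inconsistent respondents; fit indices; structural coefficients and $R^2$.

`mixed_anova_eta()` computes the split-plot ANOVA effect sizes
($\eta_p^2$): the fitted model (1F vs RIIFA) is the two-level repeated
factor on each replicate, the design factors are between. With two within
levels the within stratum reduces to a between-factor ANOVA on the
difference scores, whose intercept is the model main effect — each effect
is tested against the model × replicate error, the standard split-plot
convention. Replicates missing either model (non-convergence) are dropped
pairwise; unbalanced cells use Type-III sums of squares under sum-to-zero
contrasts. The 10% contamination level, where RIIFA convergence is
structurally poor, is excluded from the ANOVA.

## Problem sizes and defaults

The canonical factorial design crosses contamination percentage (0–50%),
sample size (200/500/1000) and test length (12/24/60) with 100 replicates
per cell. The package's desk-scale default (`scale_factor = 0.1`, i.e. 10
replicates per cell) reproduces the headline aggregates of the full design
within Monte Carlo tolerance and is the problem size used by the test suite
and the acceptance script; `scale_factor = 1` runs the full design.

```{r, eval = FALSE}
library(wordingsim)
cfg <- study_config("carelessness", perc_levels = c(20, 30, 40, 50),
                    reps = 100, scale_factor = 0.1, master_seed = 1)
st <- run_study(cfg, verbose = TRUE)
print(st)
```

## What the generator does and does not emulate

The synthetic data embody the stated study conditions: a unidimensional
substantive construct, balanced scales, symmetric 4-category items,
normally distributed latent responses, one contamination mechanism per data
set, and an uncontaminated criterion. Passing tests therefore say nothing
about non-normal latent distributions, asymmetric thresholds, unbalanced
scales, scales with more categories, mixed within-respondent wording
effects, straight-lining, or missing data — all outside the generator's
scope. Known limitations worth repeating: the fit-statistic reconstruction
is approximate (CFI above), the acquiescence selection rule is one
defensible reading of "probabilities of being selected", and IVD
classification inherits the estimation error of the uncontaminated factor
scores near the trait median.
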