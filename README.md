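# wordingsim

Monte Carlo evaluation of item wording (keying) effects in unidimensional
categorical factor models.

Balanced questionnaires mix positively worded (PW) and negatively worded
(NW) items. When some respondents answer the two item types inconsistently —
by **carelessness** (reversing NW answers), **item verification difficulty**
(trait-conditional reversal of the "hard" item type), or **acquiescence**
(content-independent agreement) — the factor structure, the fit, and the
person scores of the usual models are all at risk. `wordingsim` is a
simulation-and-estimation pipeline for quantifying that risk, built for
psychometricians and methodologists who want a controlled laboratory with a
known ground truth.

The package

* generates 4-category ordinal data from a known model: loadings
  $\lambda_i \sim U(0.60, 0.80)$ with half the signs flipped (balanced
  scale), symmetric thresholds $(-1.5, 0, 1.5)$, and a continuous criterion
  correlating $0.50$ with the substantive factor;
* contaminates 40% of respondents with one of the three mechanisms, at a
  configurable percentage of misresponded items;
* estimates polychoric/polyserial correlation matrices (two-step ML, Genz's
  bivariate normal CDF in compiled code) and fits two structural models by
  least squares with a robust mean-and-variance-adjusted test statistic:
  **1F** ($\Sigma = \Lambda\Lambda' + \Theta$, the "do-nothing" approach)
  and **RIIFA** ($\Sigma = \mathbf{1}\omega\mathbf{1}' + \Lambda\Lambda' +
  \Theta$, a random-intercept method factor with loadings fixed to 1 and
  variance $\omega$ free);
* scores respondents by EAP quadrature and measures loading recovery
  (MBE/MAE per polarity), person-score recovery (correlations with the
  uncontaminated scores, overall and by respondent consistency), structural
  validity ($\beta$, $R^2$), fit (CFI/TLI/RMSEA), and split-plot ANOVA
  effect sizes ($\eta_p^2$) across a factorial design.

## Worked example

One replicate at heavy contamination: N = 1000, k = 24, carelessness on 50%
of the items for the 40% inconsistent respondents.

```r
library(wordingsim)
cell <- design_cell("carelessness", 50, 1000, 24)
gs <- generate_sample(cell, spec_seed = 101, sample_seed = 102)
gs$data
#> <sample_data> 1000 respondents x 24 items (12 PW, 12 NW), 400 flagged inconsistent

ref_fit <- fit_dwls(mixed_cor(gs$data), model_spec("onefactor", 24),
                    orient = gs$data$item_polarity)
ref <- eap_scores(gs$data, ref_fit)$sf      # uncontaminated reference scores

set.seed(42)
contaminated <- contaminate(gs$data, "carelessness", 50)
fit_1f <- fit_dwls(mixed_cor(contaminated), model_spec("onefactor", 24),
                   orient = gs$data$item_polarity)
fit_ri <- fit_dwls(mixed_cor(contaminated), model_spec("riifa", 24),
                   orient = gs$data$item_polarity)
fit_1f
#> <wefa_fit> onefactor model, k = 24, converged = TRUE (ok)
#>   chi2 = 5316.89 (df 275), CFI = 0.400, RMSEA = 0.135
#>   beta_sf = 0.384, R2 = 0.147
fit_ri
#> <wefa_fit> riifa model, k = 24, converged = TRUE (ok)
#>   chi2 = 475.13 (df 273), CFI = 0.976, RMSEA = 0.027
#>   omega = 0.200
#>   beta_sf = 0.389, beta_wf = 0.320, R2 = 0.254

rbind(`1F`  = score_recovery(ref, eap_scores(contaminated, fit_1f)$sf,
                             contaminated$inconsistent_flags),
      RIIFA = score_recovery(ref, eap_scores(contaminated, fit_ri)$sf,
                             contaminated$inconsistent_flags))
#>       r_total r_consistent r_inconsistent
#> 1F      0.714        0.997         -0.289
#> RIIFA   0.733        0.997         -0.139
```

Reading the output: the 1F model's fit collapses under 50% carelessness
(CFI 0.40, RMSEA 0.135) while RIIFA absorbs the contamination almost
perfectly (CFI 0.98) at the cost of two degrees of freedom, estimating a
large wording variance ($\omega = 0.20$). Yet the *person scores* tell a
different story: consistent respondents are recovered essentially perfectly
by both models (r = 0.997), and for the inconsistent 40% **neither** model
recovers the true scores — modeling the wording effect does not purge it
from the scores. Aggregated over a full factorial design the two models'
total recovery differs only slightly; `run_study()` produces those
aggregates, convergence tables and $\eta_p^2$ effect sizes:

```r
cfg <- study_config("carelessness", perc_levels = c(20, 30, 40, 50),
                    reps = 100, scale_factor = 0.1, master_seed = 1)
st <- run_study(cfg)
print(st)
```

A command-line wrapper is at `inst/scripts/run_study.R`. See the vignette
(`vignettes/wording-effects-simulation.Rmd`) for the model, the three
contamination mechanisms, the estimator and its design decisions.

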