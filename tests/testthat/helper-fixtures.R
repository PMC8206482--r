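# Response-pattern fixtures for a 10-item balanced scale (5 PW then 5 NW),
# for a hypothetical low-trait and high-trait examinee misresponding to 50%
# of the items under each wording effect. Sums are computed on reverse-coded
# responses (NW reversed).
tbl1 <- list(
  polarity = rep(c("PW", "NW"), each = 5),
  low = list(
    none         = c(1, 1, 1, 2, 2, 3, 3, 4, 4, 4),
    carelessness = c(1, 1, 1, 2, 2, 2, 2, 1, 1, 1),
    ivd          = c(4, 4, 4, 3, 3, 3, 3, 4, 4, 4),
    acquiescence = c(3, 3, 3, 4, 4, 3, 3, 4, 4, 4)
  ),
  high = list(
    none         = c(4, 4, 4, 3, 3, 2, 2, 1, 1, 1),
    carelessness = c(4, 4, 4, 3, 3, 3, 3, 4, 4, 4),
    ivd          = c(4, 4, 4, 3, 3, 3, 3, 4, 4, 4),
    acquiescence = c(4, 4, 4, 3, 3, 4, 4, 3, 3, 3)
  )
)

# reverse-coded sum score (NW items recoded 5 - x before summing)
recoded_sum <- function(resp, polarity = tbl1$polarity) {
  sum(ifelse(polarity == "NW", 5 - resp, resp))
}

# wrap a bare response matrix in a sample_data with given flags/polarity
make_sample <- function(responses, polarity, flags,
                        criterion = rnorm(nrow(responses))) {
  sample_data(responses, criterion, polarity, flags)
}

# a mixed_cor-shaped object holding an exact population matrix, for
# zero-residual fitting tests (constant weights, no influence scores so the
# fitter falls back to the unscaled statistic)
population_mixed_cor <- function(spec, n = 1e5) {
  R <- population_matrix(spec)
  k <- spec$n_items
  structure(list(corr = R,
                 thresholds = matrix(rep(spec$thresholds, each = k), k),
                 avar = matrix(1e-4, k + 1, k + 1), n = n, repaired = FALSE,
                 n_items = k, has_criterion = TRUE, scores = NULL),
            class = "mixed_cor")
}

# memoised desk-scale study runs shared across acceptance tests
.study_cache <- new.env(parent = emptyenv())
acceptance_study <- function(effect) {
  if (is.null(.study_cache[[effect]])) {
    cfg <- study_config(effect, perc_levels = c(20, 30, 40, 50),
                        reps = 100, scale_factor = 0.1, master_seed = 1)
    .study_cache[[effect]] <- run_study(cfg)
  }
  .study_cache[[effect]]
}
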