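test_that("implied correlations follow the 1F and RIIFA covariance structure", {
  sp1 <- model_spec("onefactor", 2, criterion_included = FALSE)
  M1 <- implied_correlations(list(loadings = c(0.7, -0.7)), sp1)
  expect_equal(M1[1, 2], -0.49)
  spr <- model_spec("riifa", 2, criterion_included = FALSE)
  Mr <- implied_correlations(list(loadings = c(0.7, -0.7), omega = 0.1), spr)
  expect_equal(Mr[1, 2], -0.39)
  expect_equal(unname(diag(Mr)), c(1, 1))
  # criterion column: lambda*beta_sf + sqrt(omega)*beta_wf
  spc <- model_spec("riifa", 2)
  Mc <- implied_correlations(
    list(loadings = c(0.7, -0.7), omega = 0.09, beta_sf = 0.5, beta_wf = 0.2),
    spc)
  expect_equal(unname(Mc[1, 3]), 0.7 * 0.5 + 0.3 * 0.2)
})

test_that("degrees of freedom: the method factor costs 1, the criterion path 1 more", {
  for (k in c(4, 12, 60)) {
    expect_equal(model_df(model_spec("onefactor", k, FALSE)) -
                   model_df(model_spec("riifa", k, FALSE)), 1L)
    expect_equal(model_df(model_spec("onefactor", k)) -
                   model_df(model_spec("riifa", k)), 2L)
  }
  # a 4-item scale with a criterion: 10 moments, 5 vs 7 parameters
  expect_equal(model_df(model_spec("onefactor", 4)), 5L)
  expect_equal(model_df(model_spec("riifa", 4)), 3L)
})

test_that("fitting the exact population matrix recovers the generating model", {
  set.seed(71)
  lam <- draw_loadings(12)
  spec <- population_spec(lam)
  fake <- population_mixed_cor(spec)
  pol <- ifelse(lam < 0, "NW", "PW")
  f1 <- fit_dwls(fake, model_spec("onefactor", 12), orient = pol)
  expect_true(f1$converged)
  expect_equal(f1$loadings, lam, tolerance = 1e-6)
  expect_equal(f1$beta_sf, 0.5, tolerance = 1e-6)  # 0.50 * 1.0 path product
  expect_lt(f1$chi2, 1e-8)
  expect_equal(f1$cfi, 1)
  expect_equal(f1$rmsea, 0)
  # RIIFA on data without wording variance hits the omega boundary
  fr <- fit_dwls(fake, model_spec("riifa", 12), orient = pol)
  expect_false(fr$converged)
  expect_equal(fr$reason, "omega_boundary")
})

test_that("fit indices follow their definitions and clamps", {
  fi <- fit_indices(100, 10, 1000, 45, 101)
  expect_equal(fi[["cfi"]], 1 - 90 / 955)
  expect_equal(fi[["rmsea"]], sqrt(90 / (10 * 100)))
  perfect <- fit_indices(8, 10, 1000, 45, 101)
  expect_equal(perfect[["cfi"]], 1)
  expect_equal(perfect[["rmsea"]], 0)
  expect_equal(perfect[["tli"]], 1)
  # baseline no worse than the model: CFI clamps at 1
  expect_equal(fit_indices(50, 10, 20, 45, 101)[["cfi"]], 1)
  expect_error(fit_indices(10, 0, 20, 45, 101), "positive")
})

test_that("RIIFA never fits worse than 1F and scores agree on clean data", {
  gs <- generate_sample(design_cell("none", 0, 1000, 24, custom = TRUE), 81, 82)
  pol <- gs$data$item_polarity
  mc <- mixed_cor(gs$data)
  f1 <- fit_dwls(mc, model_spec("onefactor", 24), orient = pol)
  fr <- fit_dwls(mc, model_spec("riifa", 24), orient = pol)
  expect_lte(fr$fmin, f1$fmin + 1e-10)   # nested: one extra parameter
  expect_true(f1$converged)
  s1 <- eap_scores(gs$data, f1)
  if (fr$converged) {
    sr <- eap_scores(gs$data, fr)
    expect_gt(cor(s1$sf, sr$sf), 0.99)
  }
  # uncontaminated fit is excellent
  expect_gt(f1$cfi, 0.95)
  expect_lt(f1$rmsea, 0.05)
})

test_that("parameters are recovered without bias on clean replicates", {
  # mean loading and structural-coefficient bias across replicates
  nrep <- 50
  bias_l <- bias_b <- numeric(nrep)
  for (r in seq_len(nrep)) {
    gs <- generate_sample(design_cell("none", 0, 1000, 24, custom = TRUE),
                          substream_seed(9, r, "spec"),
                          substream_seed(9, r, "sample"))
    mc <- mixed_cor(gs$data)
    f <- fit_dwls(mc, model_spec("onefactor", 24),
                  orient = gs$data$item_polarity)
    bias_l[r] <- mean(f$loadings - gs$spec$loadings)
    bias_b[r] <- f$beta_sf - 0.5
  }
  expect_lt(abs(mean(bias_l)), 0.02)
  expect_lt(abs(mean(bias_b)), 0.02)
})
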