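test_that("drawn loadings form a balanced scale with U(0.60, 0.80) magnitudes", {
  set.seed(11)
  lam <- draw_loadings(12)
  expect_length(lam, 12)
  expect_equal(sum(lam < 0), 6)
  expect_true(all(abs(lam) >= 0.60 & abs(lam) <= 0.80))
  expect_error(draw_loadings(5), "even")
  # Monte Carlo oracle: mean magnitude of U(0.60, 0.80) is 0.70
  set.seed(12)
  many <- replicate(500, mean(abs(draw_loadings(20))))
  expect_equal(mean(many), 0.70, tolerance = 0.005 / 0.70)
})

test_that("population matrix is Lambda Phi Lambda-prime with unit diagonal", {
  spec <- population_spec(c(0.7, -0.7))
  R <- population_matrix(spec)
  expect_equal(R[1, 2], -0.49)
  expect_equal(R[1, 3], 0.35)   # item-criterion: 0.7 * 0.5 * 1.0
  expect_equal(R[2, 3], -0.35)
  expect_equal(unname(diag(R)), rep(1, 3))
  # orthogonal factors: item-criterion correlations vanish
  R0 <- population_matrix(population_spec(c(0.7, -0.7), factor_corr = 0))
  expect_equal(unname(R0[1:2, 3]), c(0, 0))
})

test_that("population spec enforces its invariants", {
  expect_error(population_spec(c(0.7, 0.7)), "negative")
  expect_error(population_spec(c(0.9, -0.9)), "0.60, 0.80")
  expect_error(population_spec(c(0.7, -0.7), thresholds = c(0, 0, 1)),
               "increasing")
})

test_that("simulated continuous data matches the target correlations", {
  spec <- population_spec(c(0.7, -0.7))
  R <- population_matrix(spec)
  set.seed(21)
  X <- simulate_continuous(R, 50000)
  expect_equal(cor(X[, 1], X[, 2]), -0.49, tolerance = 0.01 / 0.49)
  expect_equal(cor(X[, 1], X[, 3]), 0.35, tolerance = 0.015 / 0.35)
  expect_lt(max(abs(colMeans(X))), 3 / sqrt(50000))
  set.seed(22)
  Xi <- simulate_continuous(diag(3), 20000)
  expect_lt(max(abs(cor(Xi)[upper.tri(diag(3))])), 3 / sqrt(20000))
})

test_that("categorization assigns threshold boundaries to the lower category", {
  expect_equal(categorize(c(-2, 0.5, 1.5, 0, -1.5, 2)),
               c(1L, 3L, 3L, 2L, 1L, 4L))
  # expected proportions under a standard normal
  set.seed(31)
  x <- qnorm((1:99999) / 1e5)
  p <- tabulate(categorize(x), 4) / length(x)
  expect_equal(p, c(0.0668, 0.4332, 0.4332, 0.0668), tolerance = 0.001)
  expect_error(categorize(1, thresholds = c(1, 0)), "increasing")
})

test_that("generate_sample composes the pipeline reproducibly", {
  cell <- design_cell("carelessness", 30, 200, 12)
  gs1 <- generate_sample(cell, 101, 202)
  gs2 <- generate_sample(cell, 101, 202)
  expect_identical(gs1, gs2)
  expect_equal(sum(gs1$data$inconsistent_flags), 80)
  expect_equal(dim(gs1$data$responses), c(200L, 12L))
  expect_true(all(gs1$data$responses %in% 1:4))
  expect_equal(gs1$data$item_polarity, ifelse(gs1$spec$loadings < 0, "NW", "PW"))
  big <- generate_sample(design_cell("none", 0, 1000, 60), 1, 2)
  expect_equal(dim(big$data$responses), c(1000L, 60L))
  expect_length(big$data$criterion, 1000)
})

test_that("item margins are symmetric in expectation", {
  gs <- generate_sample(design_cell("none", 0, 1000, 12, custom = TRUE), 7, 8)
  p <- unname(rowMeans(apply(gs$data$responses, 2,
                             function(x) tabulate(x, 4) / 1000)))
  # proportion(1) ~ proportion(4), proportion(2) ~ proportion(3)
  expect_equal(p[1], p[4], tolerance = 0.15)
  expect_equal(p[2], p[3], tolerance = 0.08)
})

test_that("sample CSV round-trips the responses and flags", {
  gs <- generate_sample(design_cell("none", 0, 50, 12, custom = TRUE), 3, 4)
  f <- tempfile(fileext = ".csv")
  write_sample_csv(gs, f)
  df <- read.csv(f)
  expect_equal(as.matrix(df[, 1:12]), gs$data$responses,
               ignore_attr = TRUE)
  expect_equal(df$inconsistent, as.integer(gs$data$inconsistent_flags))
  unlink(c(f, sub("\\.csv$", ".json", f)))
})

test_that("substream seeds are deterministic and distinct", {
  a <- substream_seed(1, "carelessness", 200, 12, 3, "spec")
  expect_identical(a, substream_seed(1, "carelessness", 200, 12, 3, "spec"))
  b <- substream_seed(1, "carelessness", 200, 12, 3, "sample")
  expect_false(a == b)
  expect_true(a >= 1 && a < 2^31)
})
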