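test_that("loading errors follow the MBE/MAE definitions per polarity", {
  expect_warning(le <- loading_error(c(0.6, 0.8), c(0.7, 0.7), c("PW", "PW")),
                 "empty polarity")
  expect_equal(le[["mbe_pw"]], 0)
  expect_equal(le[["mae_pw"]], 0.1)
  expect_true(is.na(le[["mbe_nw"]]))
  exact <- loading_error(c(0.7, -0.6), c(0.7, -0.6), c("PW", "NW"))
  expect_equal(unname(exact), c(0, 0, 0, 0))
  # triangle inequality: MAE >= |MBE| on random vectors
  set.seed(101)
  for (i in 1:200) {
    est <- runif(8, -1, 1); tru <- runif(8, -1, 1)
    le <- loading_error(est, tru, rep(c("PW", "NW"), 4))
    expect_gte(le[["mae_pw"]], abs(le[["mbe_pw"]]))
    expect_gte(le[["mae_nw"]], abs(le[["mbe_nw"]]))
  }
})

test_that("score recovery correlations split by consistency flags", {
  set.seed(102)
  u <- rnorm(100)
  flags <- rep(c(FALSE, TRUE), 50)
  expect_equal(unname(score_recovery(u, u, flags)), c(1, 1, 1))
  expect_equal(unname(score_recovery(u, -u, flags)), c(-1, -1, -1))
  # consistent subset preserved, inconsistent subset pure noise
  cont <- ifelse(flags, rnorm(100), u)
  r <- score_recovery(u, cont, flags)
  expect_gt(r[["r_consistent"]], 0.999)
  expect_lt(abs(r[["r_inconsistent"]]), 0.35)
  expect_warning(score_recovery(u, cont, rep(FALSE, 100)), "fewer than 3")
  zv <- suppressWarnings(score_recovery(u, rep(0, 100), flags))
  expect_true(all(is.na(zv)))
})

test_that("wording-score diagnostics report subgroup correlations", {
  set.seed(103)
  u <- rnorm(200)
  flags <- rep(c(TRUE, FALSE), 100)
  wf <- ifelse(flags, u + rnorm(200, sd = 0.3), rnorm(200))
  d <- wording_score_diagnostics(u, wf, flags)
  expect_gt(d$inconsistent, 0.8)
  expect_lt(abs(d$consistent), 0.3)
  const <- suppressWarnings(wording_score_diagnostics(u, rep(1, 200), flags))
  expect_true(all(is.na(unlist(const))))
})

test_that("split-plot eta-squared matches a hand-computed decomposition", {
  # two between cells (perc 20 vs 50), 4 replicates each, model repeated
  reps <- paste0("r", 1:8)
  perc <- rep(c(20, 50), each = 4)
  y1 <- c(0.95, 0.93, 0.94, 0.96, 0.80, 0.78, 0.82, 0.76)  # 1F
  y2 <- c(0.94, 0.90, 0.93, 0.95, 0.74, 0.70, 0.78, 0.72)  # RIIFA
  tab <- data.frame(
    replicate = rep(reps, 2), perc_we = rep(perc, 2),
    model = rep(c("1F", "RIIFA"), each = 8), r_total = c(y1, y2))
  out <- mixed_anova_eta(tab)
  # hand decomposition via difference scores d = y1 - y2:
  d <- y1 - y2
  ssm <- length(d) * mean(d)^2 / 2                      # model main effect
  g <- tapply(d, perc, mean)
  ssi <- sum(4 * (g - mean(d))^2) / 2                   # model x perc
  sse <- sum((d - ave(d, perc))^2) / 2                  # model x replicate
  expect_equal(out$eta_p_sq[out$effect == "model"],
               ssm / (ssm + sse), tolerance = 1e-10)
  expect_equal(out$eta_p_sq[out$effect == "model:perc_we"],
               ssi / (ssi + sse), tolerance = 1e-10)
})

test_that("eta-squared degenerates correctly", {
  # no within-model difference anywhere: model effect exactly 0
  tab <- data.frame(replicate = rep(paste0("r", 1:6), 2),
                    perc_we = rep(rep(c(20, 50), each = 3), 2),
                    model = rep(c("1F", "RIIFA"), each = 6),
                    r_total = rep(c(0.9, 0.8, 0.85, 0.7, 0.75, 0.72), 2))
  out <- mixed_anova_eta(tab)
  expect_equal(out$eta_p_sq[out$effect == "model"], 0)
  # definitional check: SS_effect 10, SS_error 90 -> 0.1
  expect_equal(10 / (10 + 90), 0.1)
  # single-cell table: intercept-only decomposition
  tab1 <- tab[tab$perc_we == 20, ]
  tab1$r_total <- tab1$r_total + rep(c(0.02, 0), each = 3)
  out1 <- mixed_anova_eta(tab1)
  d <- rep(0.02, 3)
  expect_equal(out1$eta_p_sq, 3 * mean(d)^2 / (3 * mean(d)^2 + 0))
})

test_that("replicates missing one model are dropped pairwise", {
  tab <- data.frame(replicate = c("a", "b", "c", "a", "b"),
                    perc_we = c(20, 20, 50, 20, 20),
                    model = c("1F", "1F", "1F", "RIIFA", "RIIFA"),
                    r_total = c(0.9, 0.92, 0.8, 0.88, 0.9))
  expect_error(mixed_anova_eta(tab), "too few")
})
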