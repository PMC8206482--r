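test_that("category reversal matches the reference patterns and is an involution", {
  expect_equal(reverse_categories(c(3L, 3L, 4L, 4L, 4L), 1:5),
               c(2L, 2L, 1L, 1L, 1L))
  set.seed(1)
  x <- sample(1:4, 30, replace = TRUE)
  expect_identical(reverse_categories(reverse_categories(x, 1:30), 1:30), x)
  expect_identical(reverse_categories(x, integer(0)), x)
  expect_error(reverse_categories(c(0L, 5L), 1), "out of range")
})

test_that("target item count uses round-half-up with a floor of one", {
  expect_equal(contamination_spec("carelessness", 10, 12)$target_item_count, 1L)
  expect_equal(contamination_spec("carelessness", 50, 10)$target_item_count, 5L)
  expect_equal(contamination_spec("carelessness", 30, 12)$target_item_count, 4L)
  expect_equal(contamination_spec("carelessness", 0, 12)$target_item_count, 0L)
  expect_equal(contamination_spec("acquiescence", 20, 12)$switch_probs,
               c("1" = 0.50, "2" = 0.33, "3" = 0.17))
  expect_null(contamination_spec("carelessness", 20, 12)$switch_probs)
})

test_that("carelessness reverses NW items of flagged respondents only", {
  resp <- rbind(tbl1$low$none, tbl1$high$none, tbl1$low$none)
  d <- make_sample(resp, tbl1$polarity, c(TRUE, TRUE, FALSE))
  set.seed(5)
  out <- apply_carelessness(d, contamination_spec("carelessness", 50, 10))
  # at 50% of a 10-item test all five NW items are reversed
  expect_equal(unname(out$responses[1, ]), tbl1$low$carelessness)
  expect_equal(unname(out$responses[2, ]), tbl1$high$carelessness)
  expect_identical(out$responses[3, ], d$responses[3, ])
  expect_identical(out$criterion, d$criterion)
  # reversal distance on changed cells is 1 or 3
  ch <- attr(out, "changes")
  expect_true(all(abs(ch$new - ch$old) %in% c(1, 3)))
  # 0% leaves everything untouched
  same <- apply_carelessness(d, contamination_spec("carelessness", 0, 10))
  expect_identical(same$responses, d$responses)
  expect_error(
    apply_carelessness(d, contamination_spec("carelessness", 80, 10)),
    "infeasible")
})

test_that("carelessness picks a random NW subset of the right size", {
  set.seed(9)
  gs <- generate_sample(design_cell("carelessness", 10, 200, 12), 1, 2)
  out <- apply_carelessness(gs$data, contamination_spec("carelessness", 10, 12))
  ch <- attr(out, "changes")
  nflag <- sum(gs$data$inconsistent_flags)
  expect_equal(nrow(ch), nflag)  # one item per flagged respondent at 10%
  expect_true(all(gs$data$item_polarity[ch$item] == "NW"))
  ndiff <- rowSums(out$responses != gs$data$responses)
  expect_equal(sort(unique(ndiff[gs$data$inconsistent_flags])), 1)
  expect_true(all(ndiff[!gs$data$inconsistent_flags] == 0))
})

test_that("IVD reverses PW items for low-trait and NW items for high-trait", {
  resp <- rbind(tbl1$low$none, tbl1$high$none, tbl1$high$none, tbl1$low$none)
  d <- make_sample(resp, tbl1$polarity, c(TRUE, TRUE, TRUE, FALSE))
  traits <- c(-1.2, 1.4, 0, -2)  # a score of exactly 0 counts as high-trait
  set.seed(6)
  out <- apply_ivd(d, contamination_spec("ivd", 50, 10), traits)
  expect_equal(unname(out$responses[1, ]), tbl1$low$ivd)
  expect_equal(unname(out$responses[2, ]), tbl1$high$ivd)
  # boundary respondent got its NW block reversed
  expect_identical(out$responses[3, 1:5], d$responses[3, 1:5])
  expect_equal(unname(out$responses[3, 6:10]), 5 - tbl1$high$none[6:10])
  expect_identical(out$responses[4, ], d$responses[4, ])
  same <- apply_ivd(d, contamination_spec("ivd", 0, 10), traits)
  expect_identical(same$responses, d$responses)
})

test_that("acquiescence switches categories upward with the stated mapping", {
  # all-4 respondent: no eligible items, exhaustion recorded
  d4 <- make_sample(matrix(4L, 1, 10), tbl1$polarity, TRUE)
  set.seed(7)
  out4 <- apply_acquiescence(d4, contamination_spec("acquiescence", 50, 10))
  expect_identical(out4$responses, d4$responses)
  expect_equal(attr(out4, "exhausted"), 1L)
  expect_equal(nrow(attr(out4, "changes")), 0)
  # mapping: 1 -> 3, 2 -> 3 or 4, 3 -> 4; strictly increasing
  set.seed(8)
  resp <- matrix(sample(1:4, 50 * 10, replace = TRUE), 50, 10)
  d <- make_sample(resp, tbl1$polarity, rep(TRUE, 50))
  out <- apply_acquiescence(d, contamination_spec("acquiescence", 50, 10))
  ch <- attr(out, "changes")
  expect_true(all(ch$new > ch$old))
  expect_true(all(ch$new[ch$old == 1] == 3))
  expect_true(all(ch$new[ch$old == 2] %in% c(3, 4)))
  expect_true(all(ch$new[ch$old == 3] == 4))
  # per-respondent change counts never exceed the target
  expect_true(all(table(factor(ch$respondent, levels = 1:50)) <= 5))
  # mean response can only go up
  expect_true(all(rowMeans(out$responses) >= rowMeans(d$responses)))
})

test_that("every effect moves reverse-coded sums toward the middle", {
  # low-trait sums increase, high-trait sums decrease (reference patterns)
  s_low <- recoded_sum(tbl1$low$none)
  s_high <- recoded_sum(tbl1$high$none)
  for (eff in c("carelessness", "ivd", "acquiescence")) {
    expect_gt(recoded_sum(tbl1$low[[eff]]), s_low)
    expect_lt(recoded_sum(tbl1$high[[eff]]), s_high)
  }
  # the reference sums themselves
  expect_equal(s_low, 14)
  expect_equal(s_high, 36)
  expect_equal(recoded_sum(tbl1$low$carelessness), 25)
  expect_equal(recoded_sum(tbl1$high$acquiescence), 26)
})

test_that("contaminate dispatches and validates", {
  gs <- generate_sample(design_cell("ivd", 20, 200, 12), 1, 2)
  expect_identical(contaminate(gs$data, "none", 30), gs$data)
  expect_identical(contaminate(gs$data, "carelessness", 0), gs$data)
  expect_error(contaminate(gs$data, "ivd", 30), "trait scores")
})
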