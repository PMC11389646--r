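test_that("standardized domain scores reproduce the published appraisals", {
  it <- aecopd_agree_items()
  expect_equal(round_half_up(standardized_domain_score(
    it$GOLD_2021[1:3], n_appraisers = 3)), 96)
  expect_equal(round_half_up(standardized_domain_score(
    it$GOLD_2021[4:6], n_appraisers = 3)), 59)
  expect_equal(round_half_up(standardized_domain_score(
    it$AAFP_guideline[7:14], n_appraisers = 3)), 85)
  # scale endpoints
  expect_equal(standardized_domain_score(matrix(7, 3, 5)), 100)
  expect_equal(standardized_domain_score(matrix(1, 3, 5)), 0)
  expect_equal(standardized_domain_score(matrix(4, 4, 8)), 50)
  expect_error(standardized_domain_score(matrix(8, 2, 2)), "outside")
  expect_error(standardized_domain_score(numeric(0), n_appraisers = 3))
})

test_that("domain score equals the brute-force oracle and is rater-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    block <- matrix(sample(1:7, 3 * 8, replace = TRUE), 3, 8)
    expect_equal(standardized_domain_score(block), oracle_domain_score(block))
    # appraiser permutation
    expect_equal(standardized_domain_score(block[sample(3), ]),
                 standardized_domain_score(block))
    # raw block and item means give identical results pre-rounding
    expect_equal(standardized_domain_score(colMeans(block), n_appraisers = 3),
                 standardized_domain_score(block))
  }
})

test_that("appraise_document scores all six domains and grades the document", {
  m <- gen_appraisals(quality = rep(1, 6), noise_sd = 0, seed = 1)
  res <- appraise_document(m)
  expect_equal(unname(res$domain_scores), rep(100, 6))
  expect_equal(res$recommendation_level, "A")
  m0 <- gen_appraisals(quality = rep(0, 6), noise_sd = 0, seed = 1)
  expect_equal(unname(appraise_document(m0)$domain_scores), rep(0, 6))
  mid <- appraisal_matrix(matrix(4L, 3, 23))
  expect_equal(unname(appraise_document(mid)$domain_scores), rep(50, 6))
  # aggregated mode: no ICC, same scores
  agg <- appraisal_matrix(matrix(colMeans(m$item_scores), 1, 23),
                          n_appraisers = 3, aggregated = TRUE)
  res_agg <- appraise_document(agg)
  expect_null(res_agg$icc)
  expect_equal(res_agg$domain_scores, res$domain_scores)
})

test_that("cross-document domain means reproduce the published summary row", {
  dm <- aecopd_agree_domains()
  expect_equal(round_half_up(domain_mean(dm$scores["Scope and Purpose", ])), 69)
  expect_equal(round_half_up(domain_mean(dm$scores["Clarity of Presentation", ])), 74)
  expect_equal(domain_mean(55), 55)
  expect_error(domain_mean(numeric(0)))
})

test_that("the default grading rule reproduces all nine published levels", {
  dm <- aecopd_agree_domains()
  got <- apply(dm$scores, 2, recommendation_level)
  expect_equal(got, dm$levels)
  expect_equal(recommendation_level(rep(100, 6)), "A")
  expect_error(recommendation_level(c(50, 50)), "6 domain scores")
  expect_error(recommendation_level(c(120, 1, 1, 1, 1, 1)))
})

test_that("ICC behaves like an agreement statistic", {
  # duplicated raters over varying subjects -> perfect agreement
  subj <- c(1, 3, 5, 7, 2, 6)
  expect_equal(icc(rbind(subj, subj))$icc, 1)
  # matches the ANOVA mean-squares hand computation on a small matrix
  set.seed(41)
  m <- matrix(rnorm(18, rep(1:6, each = 3)), nrow = 3)
  res <- icc(m, model = "ICC2_1")
  k <- 3; n <- 6
  row_m <- colMeans(m); col_m <- rowMeans(m); g <- mean(m)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  sse <- sum((m - outer(col_m, row_m, "+") + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  expect_equal(res$icc,
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  expect_equal(res$p_value, pf(msr / mse, n - 1, (n - 1) * (k - 1),
                               lower.tail = FALSE))
  # consistency variant
  res3 <- icc(m, model = "ICC3_1")
  expect_equal(res3$icc, (msr - mse) / (msr + (k - 1) * mse))
  # degenerate matrix reports an explicit status, not NaN
  dg <- icc(matrix(5, 3, 4))
  expect_equal(dg$status, "degenerate")
  expect_true(is.na(dg$icc))
  expect_error(icc(matrix(1:4, 1, 4)), "2 raters")
})

test_that("ICC is near zero for pure noise and decreases as noise grows", {
  set.seed(51)
  # no subject effect: expected ICC ~ 0
  vals <- replicate(30, icc(matrix(rnorm(3 * 20), 3, 20))$icc)
  expect_lt(abs(mean(vals)), 0.1)
  # monotone trend over noise levels added to a fixed subject signal
  subject <- rnorm(20, sd = 2)
  mean_icc <- sapply(c(0.2, 1, 3), function(ns) {
    mean(replicate(20, {
      m <- rbind(subject + rnorm(20, sd = ns),
                 subject + rnorm(20, sd = ns),
                 subject + rnorm(20, sd = ns))
      icc(m)$icc
    }))
  })
  expect_true(all(diff(mean_icc) < 0))
})
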