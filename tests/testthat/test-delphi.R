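test_that("band counts split the 1-9 scale at the configured edges", {
  expect_equal(unname(band_counts(rep(8, 15))), c(15, 0, 0))
  expect_equal(unname(band_counts(c(8, 8, 4, 4, 2))), c(2, 2, 1))
  # custom edges
  expect_equal(unname(band_counts(c(2, 3, 9), band_edges = c(2, 8))),
               c(1, 1, 1))
  expect_error(band_counts(c(5, 10)), "1\\.\\.9")
  expect_error(band_counts(c(5, 6.5)), "integer")
  expect_error(band_counts(integer(0)))
})

test_that("band counts match a brute-force tally on random panels", {
  set.seed(101)
  for (rep in 1:5) {
    scores <- sample(1:9, 1000, replace = TRUE)
    expect_equal(unname(band_counts(scores)), oracle_bands(scores))
  }
})

test_that("agreement coefficients reproduce the published consensus cells", {
  expect_equal(round_half_up(agreement_coefficients(c(12, 2, 1), 15), 2),
               c(agreement_importance = 80, agreement_selection = 93.33))
  expect_equal(round_half_up(agreement_coefficients(c(5, 6, 4), 15), 2),
               c(agreement_importance = 33.33, agreement_selection = 73.33))
  expect_equal(unname(agreement_coefficients(c(0, 0, 7), 7)), c(0, 0))
  expect_error(agreement_coefficients(c(1, 1, 1), 4), "sum")
  expect_error(agreement_coefficients(c(0, 0, 0), 0))
})

test_that("descriptives use the sample SD and guard the degenerate cases", {
  expect_equal(unname(rating_descriptives(rep(7, 10))), c(7, 0, 0))
  expect_equal(unname(rating_descriptives(c(9, 8, 7))), c(8, 1, 0.125))
  # n denominator option
  d <- rating_descriptives(c(9, 8, 7), sd_denominator = "n")
  expect_equal(unname(d[["sd"]]), sqrt(2/3))
  set.seed(7)
  for (rep in 1:5) {
    sc <- sample(1:9, 15, replace = TRUE)
    expect_equal(rating_descriptives(sc)[["cv"]], oracle_cv(sc))
  }
})

test_that("judgement coefficient follows the weighted-frequency formula", {
  prof <- aecopd_authority_profiles()
  # hand application of the formula to the marginal counts:
  # (0.3*7+0.2*8)/15 + (0.5*11+0.4*3+0.3*1)/15 + 0.1 + 0.1
  expect_equal(judgement_coefficient(prof), 3.7/15 + 7/15 + 0.2)
  all_high <- prof
  for (b in c("theoretical_analysis", "practical_experience",
              "literature", "intuition")) all_high[[b]] <- "high"
  expect_equal(judgement_coefficient(all_high), 1.0)
  all_low <- prof
  for (b in c("theoretical_analysis", "practical_experience",
              "literature", "intuition")) all_low[[b]] <- "low"
  expect_equal(judgement_coefficient(all_low), 0.6)
  bad <- prof; bad$intuition[3] <- "extreme"
  expect_error(judgement_coefficient(bad), "unknown")
})

test_that("familiarity and authority coefficients hit the published values", {
  prof <- aecopd_authority_profiles()
  expect_equal(round_half_up(familiarity_coefficient(prof), 2), 0.83)
  expect_equal(familiarity_coefficient(prof), 12.4 / 15)
  ac <- authority_coefficient(0.92, 0.83)
  expect_equal(ac$Cr, 0.875)
  expect_true(ac$acceptable)
  expect_equal(authority_coefficient(1, 1)$Cr, 1)
  low <- authority_coefficient(0.6, 0.2)
  expect_equal(low$Cr, 0.4)
  expect_false(low$acceptable)
  expect_error(authority_coefficient(1.2, 0.5), "out of")
})

test_that("response rate is a guarded percentage", {
  expect_equal(response_rate(15, 15), 100)
  expect_equal(response_rate(0, 10), 0)
  expect_equal(response_rate(7, 14), 50)
  expect_error(response_rate(1, 0))
  expect_error(response_rate(5, 4))
})

test_that("delphi_round composes the per-outcome statistics correctly", {
  set.seed(11)
  m <- rating_matrix(matrix(sample(1:9, 15 * 6, replace = TRUE), 15, 6,
                            dimnames = list(NULL, paste0("out", 1:6))))
  rd <- delphi_round(m)
  expect_s3_class(rd, "delphi_round")
  expect_equal(nrow(rd$stats), 6)
  # rows ordered by importance agreement, desc
  expect_true(all(diff(rd$stats$agreement_importance) <= 0))
  for (i in seq_len(nrow(rd$stats))) {
    o <- rd$stats$outcome_id[i]
    b <- band_counts(m[, o])
    expect_equal(rd$stats$n_critical[i], b[["n_critical"]])
    expect_equal(sum(rd$stats[i, c("n_critical", "n_important",
                                   "n_unimportant")]), 15)
    a <- agreement_coefficients(b, 15)
    expect_equal(rd$stats$agreement_importance[i], a[[1]])
    expect_equal(rd$stats$agreement_selection[i], a[[2]])
    expect_gte(a[[2]], a[[1]])
    expect_equal(rd$stats$cv[i], rating_descriptives(m[, o])[["cv"]])
  }
  # constant ratings: cv 0, agreements 100/100
  m2 <- rating_matrix(matrix(8L, 15, 1, dimnames = list(NULL, "A")))
  rd2 <- delphi_round(m2)
  expect_equal(rd2$stats$cv, 0)
  expect_equal(rd2$stats$agreement_importance, 100)
})

test_that("statistics are invariant under expert permutation", {
  set.seed(21)
  m <- rating_matrix(matrix(sample(1:9, 10 * 4, replace = TRUE), 10, 4))
  rd1 <- delphi_round(m)
  perm <- sample(nrow(m))
  m2 <- rating_matrix(m[perm, , drop = FALSE])
  rd2 <- delphi_round(m2)
  expect_equal(rd1$stats[, -1], rd2$stats[, -1])
})

test_that("selection rules partition outcomes and respect overrides", {
  st <- delphi_stats_from_bands(aecopd_consensus_bands(), 15)
  cfg <- selection_config(override_set = aecopd_overrides())
  dec <- apply_selection_rules(st, cfg)
  expect_setequal(dec$outcome_id[dec$flagged],
                  c("White blood cell count", "Interleukin-6 (IL-6) level",
                    "Procalcitonin (PCT) level",
                    "Prevalence of drug-resistant bacteria",
                    "Number of drug-resistant bacteria",
                    "Interleukin-8 (IL-8) level"))
  expect_setequal(dec$outcome_id[dec$decision == "excluded"],
                  c("Prevalence of drug-resistant bacteria",
                    "Number of drug-resistant bacteria"))
  expect_setequal(dec$outcome_id[dec$decision == "retained_by_override"],
                  aecopd_overrides())
  # every outcome receives exactly one decision
  expect_equal(sort(dec$outcome_id), sort(st$outcome_id))
  expect_equal(sum(attr(dec, "counts")), nrow(st))
  # agreement exactly at the threshold with high CV is NOT flagged
  crp <- dec[dec$outcome_id == "C-reactive protein level", ]
  expect_equal(crp$decision, "selected")
  # idempotence: re-applying to the same stats yields identical decisions
  expect_identical(apply_selection_rules(st, cfg), dec)
  # empty input
  empty <- apply_selection_rules(st[0, ], selection_config())
  expect_equal(nrow(empty), 0)
  expect_error(apply_selection_rules(st, selection_config(
    override_set = "nonexistent outcome")), "override")
})

test_that("rating matrices reject malformed input", {
  expect_error(rating_matrix(matrix(5, 1, 3)), "2 experts")
  expect_error(rating_matrix(matrix(c(1, 10), 2, 1)), "1\\.\\.9")
  expect_error(rating_matrix(matrix(c(1, NA), 2, 1)), "missing")
})
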