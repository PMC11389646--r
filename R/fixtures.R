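# Bundled example data for the AECOPD outcome-selection workflow:
# a 15-expert Delphi panel (authority profiles and per-outcome consensus
# summaries) and AGREE II appraisals of nine AECOPD guidelines /
# consensus documents by three appraisers. Used in examples, tests and
# the reproduction script.

#' Example expert authority profiles (15-expert AECOPD panel)
#'
#' Judgement-basis impact levels and familiarity for a 15-expert panel.
#' The level frequencies are: theoretical analysis 7 high / 8 medium;
#' practical experience 11 high / 3 medium / 1 low; literature 9 high /
#' 6 medium; intuition 4 medium / 11 low; familiarity 5 very / 7 quite /
#' 3 moderately familiar. Any per-expert assignment with these margins
#' yields the same Ca and Cs; this one is a fixed deterministic filling.
#'
#' @return an [expert_profiles] data frame of 15 rows.
#' @examples
#' p <- aecopd_authority_profiles()
#' round_half_up(familiarity_coefficient(p), 2)  # 0.83
#' @export
aecopd_authority_profiles <- function() {
  fill <- function(counts) {  # counts over levels, most to least
    rep(names(counts), times = counts)
  }
  expert_profiles(data.frame(
    expert_id = paste0("E", 1:15),
    theoretical_analysis = fill(c(high = 7, medium = 8, low = 0)),
    practical_experience = fill(c(high = 11, medium = 3, low = 1)),
    literature = fill(c(high = 9, medium = 6, low = 0)),
    intuition = fill(c(high = 0, medium = 4, low = 11)),
    familiarity = fill(c(very_familiar = 5, quite_familiar = 7,
                         moderately_familiar = 3, not_very_familiar = 0,
                         unfamiliar = 0)),
    stringsAsFactors = FALSE))
}

#' Example per-outcome Delphi consensus summaries (AECOPD, 15 experts)
#'
#' Band frequencies (important-and-critical / important-but-not-critical
#' / unimportant), coefficient of variation and mean importance score
#' for 43 candidate outcomes rated by a 15-expert panel. One published
#' health-economics row (cost-effectiveness ratio) is omitted because
#' its frequency layout is garbled in the source table.
#'
#' @return data frame `outcome_id, domain, n_critical, n_important,
#'   n_unimportant, cv, mean`.
#' @export
aecopd_consensus_bands <- function() {
  e <- "efficacy"; s <- "safety"; h <- "health_economics"
  rows <- list(
    list("The treatment failure rate", e, 15, 0, 0, 0.09, 8.40),
    list("Hospital readmission rate", e, 12, 3, 0, 0.15, 7.27),
    list("CAT score (The COPD Assessment Test)", e, 12, 2, 1, 0.19, 6.80),
    list("AECOPD-STES score", e, 12, 3, 0, 0.15, 7.33),
    list("Length of hospital stay", e, 11, 4, 0, 0.18, 7.20),
    list("Proportion of patients requiring ICU treatment", e, 11, 4, 0, 0.17, 7.27),
    list("Frequency of AECOPD", e, 10, 5, 0, 0.20, 7.20),
    list("Proportion of patients receiving invasive mechanical ventilation", e, 10, 5, 0, 0.19, 6.93),
    list("Proportion of patients with AECOPD-related complications", e, 10, 5, 0, 0.19, 7.07),
    list("Duration of recurrent AECOPD", e, 9, 5, 1, 0.26, 6.33),
    list("Duration of fever", e, 9, 5, 1, 0.31, 6.60),
    list("HRQOL-5 scale score", e, 9, 5, 1, 0.24, 6.33),
    list("Score of Chinese version of EQ-5D Quality of Life Scale", e, 8, 6, 1, 0.26, 6.40),
    list("Forced expiratory volume in one second predicted (FEV1%)", e, 8, 7, 0, 0.22, 6.53),
    list("FEV1/FVC", e, 7, 7, 1, 0.25, 6.40),
    list("Forced vital capacity (FVC)", e, 6, 9, 0, 0.19, 6.20),
    list("Duration of ICU treatment", e, 5, 9, 1, 0.25, 6.00),
    list("White blood cell count", e, 5, 6, 4, 0.38, 5.07),
    list("C-reactive protein level", e, 5, 7, 3, 0.41, 5.27),
    list("Interleukin-6 (IL-6) level", e, 3, 8, 4, 0.37, 4.80),
    list("Procalcitonin (PCT) level", e, 3, 8, 4, 0.39, 4.93),
    list("Prevalence of drug-resistant bacteria", e, 3, 8, 4, 0.37, 5.13),
    list("PaO2 level", e, 2, 11, 2, 0.26, 5.20),
    list("PaCO2 level", e, 2, 11, 2, 0.29, 5.47),
    list("Number of drug-resistant bacteria", e, 2, 7, 6, 0.45, 4.60),
    list("Interleukin-8 (IL-8) level", e, 2, 7, 6, 0.38, 4.40),
    list("Proportion of patients with serious adverse events", s, 15, 0, 0, 0.11, 8.20),
    list("Proportion of patients with non-serious adverse events", s, 11, 3, 1, 0.22, 6.87),
    list("Proportion of patients with abnormal renal function", s, 11, 3, 1, 0.26, 6.93),
    list("Proportion of patients with abnormal liver function", s, 10, 4, 1, 0.26, 6.87),
    list("Proportion of patients with pneumonia progression", s, 9, 6, 0, 0.24, 6.60),
    list("Proportion of patients with abnormal urinalysis", s, 7, 5, 3, 0.43, 5.40),
    list("Proportion of patients with abnormal coagulation function", s, 6, 6, 3, 0.42, 5.60),
    list("Duration of antibiotic use", s, 4, 10, 1, 0.31, 5.87),
    list("Transition time from intravenous to oral antibiotics", s, 4, 9, 2, 0.36, 5.33),
    list("Cumulative dose of antibiotics", s, 4, 9, 2, 0.35, 5.33),
    list("Cumulative dose of corticosteroids", s, 4, 10, 1, 0.30, 5.73),
    list("Duration of corticosteroid use", s, 4, 10, 1, 0.30, 5.73),
    list("Transition time from broad-spectrum to narrow-spectrum antibiotics", s, 3, 11, 1, 0.33, 5.33),
    list("Incremental cost-effectiveness ratio", h, 14, 1, 0, 0.11, 7.60),
    list("Effectiveness outcomes", h, 13, 2, 0, 0.14, 7.33),
    list("Quality-adjusted life years (QALY)", h, 12, 3, 0, 0.17, 7.13),
    list("Health utility value", h, 9, 5, 1, 0.29, 6.33))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(outcome_id = r[[1]], domain = r[[2]], n_critical = r[[3]],
               n_important = r[[4]], n_unimportant = r[[5]],
               cv = r[[6]], mean = r[[7]], stringsAsFactors = FALSE)
  }))
  out
}

#' Outcomes retained by external override in the AECOPD example
#'
#' The four inflammation-marker outcomes flagged by the Delphi rules but
#' retained on network-meta-analysis evidence of treatment sensitivity.
#'
#' @return character vector of outcome ids.
#' @export
aecopd_overrides <- function() {
  c("White blood cell count", "Interleukin-6 (IL-6) level",
    "Procalcitonin (PCT) level", "Interleukin-8 (IL-8) level")
}

#' Build a consensus-statistics table from band counts
#'
#' For settings where the per-expert ratings are unavailable but the
#' band frequencies (and optionally CV and mean) are published: computes
#' the agreement coefficients from the bands so the selection rules can
#' be applied with [apply_selection_rules()].
#'
#' @param bands data frame with `outcome_id, n_critical, n_important,
#'   n_unimportant` and optionally `cv`, `mean`.
#' @param n_experts panel size; every row's bands must sum to it.
#' @return data frame in the [delphi_round()] `stats` layout.
#' @export
delphi_stats_from_bands <- function(bands, n_experts) {
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    b <- c(bands$n_critical[i], bands$n_important[i], bands$n_unimportant[i])
    a <- agreement_coefficients(b, n_experts)
    data.frame(outcome_id = bands$outcome_id[i],
               n_critical = b[1L], n_important = b[2L], n_unimportant = b[3L],
               agreement_importance = a[[1L]], agreement_selection = a[[2L]],
               mean = bands$mean[i] %||% NA_real_,
               sd = NA_real_, cv = bands$cv[i] %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$agreement_importance, out$outcome_id), , drop = FALSE]
}

#' Example AGREE II item means for nine AECOPD guidance documents
#'
#' Mean item scores of three appraisers on the 23 AGREE II items for
#' nine guidelines / expert consensus documents on AECOPD management.
#' A few published item means fall slightly below the 1--7 item scale
#' (an artifact of the source table); the standardized domain score
#' tolerates them.
#'
#' @return data frame: `item` (1--23) plus one column per document.
#' @examples
#' it <- aecopd_agree_items()
#' round_half_up(standardized_domain_score(it$GOLD_2021[1:3], n_appraisers = 3))
#' @export
aecopd_agree_items <- function() {
  m <- matrix(c(
    7.00, 6.67, 5.33, 1.67, 1.67, 5.33, 7.00, 7.00, 7.00,
    7.00, 6.67, 5.33, 5.33, 3.33, 6.00, 6.33, 6.00, 5.33,
    6.33, 6.33, 4.00, 2.00, 1.67, 2.67, 6.00, 6.33, 6.00,
    6.67, 6.33, 3.33, 2.33, 2.67, 5.67, 7.00, 6.67, 7.00,
    1.33, 6.33, 0.67, 1.00, 1.33, 1.00, 1.33, 1.33, 1.33,
    5.67, 6.00, 5.33, 1.00, 1.67, 5.00, 6.67, 6.00, 6.67,
    6.33, 5.67, 2.33, 2.00, 1.33, 6.33, 6.67, 2.00, 2.00,
    2.67, 5.33, 2.00, 2.00, 1.67, 6.67, 6.67, 7.00, 2.67,
    2.67, 6.67, 1.00, 2.33, 1.33, 6.00, 6.33, 1.33, 1.33,
    5.67, 5.67, 6.67, 1.33, 1.67, 6.33, 6.67, 5.67, 2.67,
    6.67, 5.67, 2.33, 2.33, 1.33, 4.33, 6.00, 2.33, 2.00,
    7.00, 6.67, 2.33, 3.33, 2.33, 6.00, 6.00, 2.33, 2.00,
    1.67, 6.33, 1.33, 2.00, 2.67, 5.33, 5.67, 2.33, 1.00,
    6.00, 6.67, 1.00, 1.67, 5.33, 6.33, 5.67, 1.33, 4.33,
    6.67, 6.33, 5.00, 2.67, 2.00, 5.67, 7.00, 6.33, 6.33,
    7.00, 5.67, 5.33, 3.00, 5.33, 6.00, 7.00, 4.67, 5.00,
    7.00, 6.67, 5.00, 3.00, 4.67, 5.67, 7.00, 6.00, 5.33,
    2.33, 6.33, 3.33, 1.00, 0.67, 1.00, 4.33, 4.33, 3.33,
    3.00, 5.33, 4.67, 2.33, 4.67, 1.67, 5.00, 1.33, 1.67,
    5.33, 3.67, 2.33, 1.33, 2.33, 1.33, 3.33, 2.33, 3.00,
    6.67, 2.33, 1.33, 5.00, 5.00, 1.00, 4.00, 5.00, 2.33,
    3.00, 4.00, 2.33, 2.33, 3.00, 6.00, 6.33, 5.33, 5.33,
    1.67, 6.67, 5.33, 1.00, 2.00, 6.33, 6.67, 7.00, 7.00),
    nrow = 23, byrow = TRUE)
  out <- data.frame(item = 1:23, m)
  names(out)[-1L] <- c("GOLD_2021", "AAFP_guideline",
                       "European_Expert_Consensus_2021",
                       "Chinese_Expert_Consensus_2017",
                       "Chinese_Guideline_2021", "TCM_guideline_2018",
                       "European_American_Society_Guideline_2017",
                       "American_Canadian_Society_Guideline_2022",
                       "Swiss_Guideline_2018")
  out
}

#' Example published AGREE II domain scores for the nine documents
#'
#' The standardized domain percentages and recommendation levels as
#' published for the nine documents of [aecopd_agree_items()]. Kept
#' separately because one published cell (Domain 1 of the American /
#' Canadian guideline, 80%) is inconsistent with its own item means
#' (which give 91%).
#'
#' @return list: `scores` (6 x 9 matrix, domains x documents) and
#'   `levels` (published recommendation grades).
#' @export
aecopd_agree_domains <- function() {
  docs <- names(aecopd_agree_items())[-1L]
  scores <- matrix(c(
    96, 93, 65, 33, 20, 61, 91, 80, 85,
    59, 87, 35,  7, 15, 48, 67, 61, 67,
    64, 85, 23, 19, 20, 82, 87, 34, 21,
    98, 87, 69, 31, 50, 80, 100, 78, 76,
    56, 57, 32, 24, 36,  4, 53, 38, 26,
    22, 72, 47, 11, 25, 86, 92, 86, 86),
    nrow = 6, byrow = TRUE,
    dimnames = list(names(agree_domains()), docs))
  levels <- c("B", "B", "B", "C", "C", "B", "B", "B", "B")
  names(levels) <- docs
  list(scores = scores, levels = levels)
}

#' Example outcome-reporting counts from 499 AECOPD trials
#'
#' A representative subset of per-outcome reporting counts from a pool
#' of 499 randomized trials of herbal injections in AECOPD, spanning
#' frequently reported outcomes (arterial blood gases, composite
#' efficiency), the 6%-borderline region, and rarely reported ones.
#'
#' @return data frame `outcome_name, domain, report_count` with
#'   attribute `total_trials = 499`.
#' @export
aecopd_rct_counts <- function() {
  rows <- list(
    list("Efficiency (customized composite outcome)", "treatment_success", 361),
    list("PaCO2", "laboratory", 195),
    list("PaO2", "laboratory", 190),
    list("FEV1/FVC", "disease_progression", 111),
    list("C-reactive protein (CRP)", "laboratory", 109),
    list("FEV1", "airway_limitation", 108),
    list("pH", "laboratory", 88),
    list("FVC", "disease_progression", 79),
    list("WBCC", "laboratory", 63),
    list("Tumor necrosis factor-alpha (TNF-a)", "laboratory", 63),
    list("FEV1%", "disease_progression", 52),
    list("Interleukin-8 (IL-8)", "laboratory", 46),
    list("Procalcitonin (PCT)", "laboratory", 42),
    list("Length of hospital stay", "symptoms", 39),
    list("Granulocyte percentage (GR%)", "laboratory", 39),
    list("Interleukin-6 (IL-6)", "laboratory", 32),
    list("Score of symptoms and signs assessment", "symptoms", 32),
    list("Oxygen saturation (SaO2)", "laboratory", 28),
    list("Time for clinical symptoms and signs to resolve", "symptoms", 25),
    list("CAT score", "quality_of_life", 16),
    list("Interleukin-10 (IL-10)", "laboratory", 16),
    list("Fibrinogen (FBG)", "laboratory", 13),
    list("Length of stay in the ICU", "higher_level_care", 8),
    list("All-cause mortality", "death", 6),
    list("Superoxide dismutase (SOD)", "laboratory", 6),
    list("6-minute walk test (6-minute walking distance)", "exercise_capacity", 5),
    list("Duration of fever", "symptoms", 5),
    list("Incidence of complications", "complication", 3),
    list("Readmission rate (within 3 months)", "treatment_success", 2),
    list("BODE score", "symptoms", 1))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(outcome_name = r[[1]], domain = r[[2]],
               report_count = r[[3]], stringsAsFactors = FALSE)
  }))
  attr(out, "total_trials") <- 499L
  out
}
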