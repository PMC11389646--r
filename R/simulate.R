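#' Simulate a Delphi expert panel
#'
#' Ratings are drawn per expert and outcome as a truncated-rounded
#' normal, `round(clip(N(mu_o, sigma_o), 1, 9))`, around a latent
#' per-outcome importance; judgement-basis and familiarity profiles are
#' drawn from the supplied categoricals. Defaults mirror a 15-expert
#' panel with a mostly experienced, mostly familiar composition.
#'
#' @param n_experts panel size (default 15).
#' @param mu latent importance per outcome, in \[1, 9\] (named vector;
#'   names become outcome ids).
#' @param sigma rater noise SD per outcome (recycled).
#' @param basis_probs named list of length-3 probability vectors
#'   (high, medium, low) per judgement basis.
#' @param familiarity_probs length-5 probability vector over the
#'   familiarity levels, most to least familiar.
#' @param seed integer seed; the generator is deterministic under it.
#' @return list with a [rating_matrix] (`ratings`) and an
#'   [expert_profiles] data frame (`profiles`).
#' @examples
#' p <- gen_panel(mu = c(failure_rate = 8.4, WBCC = 5), sigma = 1, seed = 3)
#' delphi_round(p$ratings, p$profiles)
#' @export
gen_panel <- function(n_experts = 15L, mu, sigma = 1,
                      basis_probs = list(
                        theoretical_analysis = c(0.5, 0.5, 0.0),
                        practical_experience = c(0.7, 0.2, 0.1),
                        literature           = c(0.6, 0.4, 0.0),
                        intuition            = c(0.0, 0.3, 0.7)),
                      familiarity_probs = c(0.35, 0.45, 0.2, 0, 0),
                      seed = 1L) {
  if (any(mu < 1 | mu > 9)) fail("latent importances must lie in [1, 9]")
  sigma <- rep_len(sigma, length(mu))
  if (any(sigma <= 0)) fail("rater noise sd must be positive")
  for (b in names(basis_probs)) {
    if (abs(sum(basis_probs[[b]]) - 1) > 1e-8 || any(basis_probs[[b]] < 0)) {
      fail("basis '%s': probabilities must be non-negative and sum to 1", b)
    }
  }
  if (abs(sum(familiarity_probs) - 1) > 1e-8 || any(familiarity_probs < 0)) {
    fail("familiarity probabilities must be non-negative and sum to 1")
  }
  set.seed(seed)
  outcome_ids <- names(mu) %||% paste0("O", seq_along(mu))
  ratings <- sapply(seq_along(mu), function(j) {
    pmin(pmax(round(stats::rnorm(n_experts, mu[j], sigma[j])), 1), 9)
  })
  ratings <- matrix(as.integer(ratings), nrow = n_experts,
                    dimnames = list(paste0("E", seq_len(n_experts)),
                                    outcome_ids))
  prof <- data.frame(expert_id = rownames(ratings),
                     stringsAsFactors = FALSE)
  for (b in basis_names) {
    prof[[b]] <- sample(basis_levels, n_experts, replace = TRUE,
                        prob = basis_probs[[b]])
  }
  prof$familiarity <- sample(familiarity_levels, n_experts, replace = TRUE,
                             prob = familiarity_probs)
  list(ratings = rating_matrix(ratings), profiles = expert_profiles(prof))
}

#' Simulate an AGREE II appraiser matrix
#'
#' Item scores are `round(clip(1 + 6 * q_domain + N(0, noise_sd), 1, 7))`
#' where `q_domain` is the latent quality of the item's domain in
#' \[0, 1\].
#'
#' @param quality six latent domain qualities in \[0, 1\].
#' @param n_appraisers number of appraisers (default 3).
#' @param noise_sd appraiser noise SD on the 1-7 item scale.
#' @param document_id label for the generated document.
#' @param seed integer seed.
#' @return an [appraisal_matrix] (per-rater mode).
#' @export
gen_appraisals <- function(quality, n_appraisers = 3L, noise_sd = 0.5,
                           document_id = "synthetic", seed = 1L) {
  if (length(quality) != 6L || any(quality < 0 | quality > 1)) {
    fail("quality must be six values in [0, 1]")
  }
  if (noise_sd < 0) fail("noise_sd must be non-negative")
  set.seed(seed)
  dom <- agree_domains()
  q_item <- numeric(23L)
  for (i in seq_along(dom)) q_item[dom[[i]]] <- quality[i]
  scores <- matrix(0L, n_appraisers, 23L)
  for (a in seq_len(n_appraisers)) {
    raw <- 1 + 6 * q_item + stats::rnorm(23L, 0, noise_sd)
    scores[a, ] <- as.integer(pmin(pmax(round(raw), 1), 7))
  }
  appraisal_matrix(scores, document_id = document_id)
}

#' Simulate trial outcome-extraction records
#'
#' Each of `n_trials` trials reports outcome `o` independently with
#' probability `reporting_probs[o]`.
#'
#' @param n_trials number of trials (default 500, the scale of a large
#'   systematic review).
#' @param reporting_probs named vector of per-outcome reporting
#'   probabilities in \[0, 1\].
#' @param domains optional named vector outcome -> evaluation domain.
#' @param seed integer seed.
#' @return an [extraction_records] data frame.
#' @export
gen_extraction <- function(n_trials = 500L, reporting_probs,
                           domains = NULL, seed = 1L) {
  if (any(reporting_probs < 0 | reporting_probs > 1)) {
    fail("reporting probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  outcome_ids <- names(reporting_probs) %||%
    paste0("outcome", seq_along(reporting_probs))
  rows <- list()
  for (j in seq_along(reporting_probs)) {
    hit <- which(stats::runif(n_trials) < reporting_probs[j])
    if (length(hit)) {
      rows[[j]] <- data.frame(
        trial_id = paste0("T", hit),
        outcome_name = outcome_ids[j],
        domain = if (is.null(domains)) NA_character_
                 else unname(domains[outcome_ids[j]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(trial_id = character(), outcome_name = character(),
                     domain = character(), stringsAsFactors = FALSE)
  }
  extraction_records(df)
}

#' Simulate a multi-treatment trial network from the NMA model
#'
#' Trial-level true contrasts are `d[treatment] - d[baseline] +
#' N(0, tau)`. Continuous arms report the sample mean and SD of `n`
#' normal observations around `baseline_mean + contrast`; binary arms
#' report binomial event counts with log-link risks
#' `baseline_risk * exp(contrast)` (clipped at 0.99 with a warning, or
#' rejected, per `risk_overflow`).
#'
#' @param d named numeric vector of true basic parameters; the first
#'   element is the reference and must be 0.
#' @param tau between-trial heterogeneity SD (>= 0).
#' @param comparisons two-column matrix (or list of pairs) of treatment
#'   labels, one row per trial design; default: every non-reference
#'   treatment versus the reference.
#' @param trials_per_comparison number of trials per design.
#' @param n_per_arm arm sample size.
#' @param measure `"md"` or `"rr"`.
#' @param baseline_mean,arm_sd continuous baseline and within-arm SD.
#' @param baseline_risk binary reference-arm risk in (0, 1).
#' @param risk_overflow `"clip"` (default) or `"error"` when a simulated
#'   risk reaches 1.
#' @param seed integer seed.
#' @return an [nma_network].
#' @export
gen_network <- function(d, tau = 0.1, comparisons = NULL,
                        trials_per_comparison = 4L, n_per_arm = 100L,
                        measure = c("md", "rr"),
                        baseline_mean = 0, arm_sd = 1,
                        baseline_risk = 0.2,
                        risk_overflow = c("clip", "error"), seed = 1L) {
  measure <- match.arg(measure)
  risk_overflow <- match.arg(risk_overflow)
  if (tau < 0) fail("tau must be non-negative")
  if (n_per_arm < 2L) fail("n_per_arm must be >= 2")
  if (baseline_risk <= 0 || baseline_risk >= 1) fail("baseline_risk must be in (0, 1)")
  trts <- names(d) %||% fail("d must be a named vector of treatment effects")
  if (d[[1L]] != 0) fail("the first element of d is the reference and must be 0")
  if (is.null(comparisons)) {
    comparisons <- cbind(trts[1L], trts[-1L])
  }
  comparisons <- as.matrix(comparisons)
  set.seed(seed)
  rows <- list()
  trial <- 0L
  for (i in seq_len(nrow(comparisons))) {
    for (r in seq_len(trials_per_comparison)) {
      trial <- trial + 1L
      ta <- comparisons[i, 1L]; tb <- comparisons[i, 2L]
      contrast <- d[[tb]] - d[[ta]] + stats::rnorm(1L, 0, tau)
      if (measure == "md") {
        ya <- stats::rnorm(n_per_arm, baseline_mean, arm_sd)
        yb <- stats::rnorm(n_per_arm, baseline_mean + contrast, arm_sd)
        rows[[trial]] <- data.frame(
          trial_id = rep(paste0("S", trial), 2L),
          treatment = c(ta, tb), n = n_per_arm,
          mean = c(mean(ya), mean(yb)), sd = c(stats::sd(ya), stats::sd(yb)),
          stringsAsFactors = FALSE)
      } else {
        pa <- baseline_risk
        pb <- pa * exp(contrast)
        if (pb >= 1) {
          if (risk_overflow == "error") {
            fail("simulated risk %.3f >= 1 for trial %d; lower baseline_risk or effects",
                 pb, trial)
          }
          warning(sprintf("simulated risk %.3f clipped to 0.99 (trial %d)",
                          pb, trial), call. = FALSE)
          pb <- 0.99
        }
        rows[[trial]] <- data.frame(
          trial_id = rep(paste0("S", trial), 2L),
          treatment = c(ta, tb), n = n_per_arm,
          events = c(stats::rbinom(1L, n_per_arm, pa),
                     stats::rbinom(1L, n_per_arm, pb)),
          stringsAsFactors = FALSE)
      }
    }
  }
  nma_network(do.call(rbind, rows), measure = measure, reference = trts[1L])
}
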