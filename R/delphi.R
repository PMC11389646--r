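#' Expert rating matrix for a Delphi consensus round
#'
#' Validates and packages an experts-by-outcomes matrix of importance
#' scores on the 1--9 scale used in Delphi outcome-selection surveys
#' (1--3 unimportant, 4--6 important but not critical, 7--9 important
#' and critical).
#'
#' @param ratings integer matrix (or coercible) with one row per expert
#'   and one column per outcome; every entry an integer in 1..9.
#' @param expert_ids,outcome_ids optional identifier vectors; default to
#'   the dimnames of `ratings` or generated labels.
#' @return an object of class `rating_matrix`: the validated integer
#'   matrix with `expert_ids` as rownames and `outcome_ids` as colnames.
#' @examples
#' m <- rating_matrix(matrix(c(8, 9, 7, 4, 5, 6), nrow = 3,
#'                    dimnames = list(NULL, c("mortality", "CAT"))))
#' band_counts(m[, "mortality"])
#' @export
rating_matrix <- function(ratings, expert_ids = NULL, outcome_ids = NULL) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) fail("a rating matrix needs at least 2 experts")
  if (ncol(ratings) < 1L) fail("a rating matrix needs at least 1 outcome")
  expert_ids <- expert_ids %||% rownames(ratings) %||%
    paste0("E", seq_len(nrow(ratings)))
  outcome_ids <- outcome_ids %||% colnames(ratings) %||%
    paste0("O", seq_len(ncol(ratings)))
  if (anyDuplicated(expert_ids)) fail("duplicate expert ids")
  if (anyDuplicated(outcome_ids)) fail("duplicate outcome ids")
  for (j in seq_len(ncol(ratings))) {
    sc <- ratings[, j]
    if (anyNA(sc)) {
      fail("missing rating for outcome '%s' (expert '%s')",
           outcome_ids[j], expert_ids[which(is.na(sc))[1L]])
    }
    bad <- which(sc != floor(sc) | sc < 1 | sc > 9)
    if (length(bad)) {
      fail("rating for expert '%s', outcome '%s' is %s; must be an integer in 1..9",
           expert_ids[bad[1L]], outcome_ids[j], format(sc[bad[1L]]))
    }
  }
  storage.mode(ratings) <- "integer"
  dimnames(ratings) <- list(expert_ids, outcome_ids)
  structure(ratings, class = c("rating_matrix", "matrix", "array"))
}

#' Count ratings per importance band
#'
#' Splits the 1--9 importance scale into three bands at the configured
#' edges (default 3 and 6): scores above the upper edge are "important
#' and critical", scores in between are "important but not critical",
#' and scores at or below the lower edge are "unimportant".
#'
#' @param scores integer scores in 1..9 for one outcome.
#' @param band_edges two strictly increasing integers inside 1..9
#'   (default `c(3, 6)`).
#' @return named integer vector `(n_critical, n_important, n_unimportant)`
#'   summing to `length(scores)`.
#' @export
band_counts <- function(scores, band_edges = c(3L, 6L)) {
  scores <- check_scores_1_9(scores)
  if (length(band_edges) != 2L || band_edges[1] >= band_edges[2] ||
      band_edges[1] < 1 || band_edges[2] > 8) {
    fail("band_edges must be two increasing integers inside [1, 9)")
  }
  c(n_critical    = sum(scores >  band_edges[2]),
    n_important   = sum(scores >  band_edges[1] & scores <= band_edges[2]),
    n_unimportant = sum(scores <= band_edges[1]))
}

#' Expert agreement coefficients from band counts
#'
#' The importance agreement is the percentage of the panel voting in the
#' critical band (7--9); the selection agreement adds the middle band
#' (4--6 plus 7--9). Values are returned unrounded; display rounding is
#' half-up to two decimals.
#'
#' @param bands integer vector `(n_critical, n_important, n_unimportant)`.
#' @param n panel size; bands must sum to `n`.
#' @return named numeric vector
#'   `(agreement_importance, agreement_selection)` in percent.
#' @export
agreement_coefficients <- function(bands, n) {
  if (length(n) != 1L || n < 1) fail("panel size n must be >= 1")
  if (length(bands) != 3L || any(bands < 0)) fail("bands must be 3 non-negative counts")
  if (sum(bands) != n) {
    fail("band counts sum to %d but panel size is %d", sum(bands), n)
  }
  c(agreement_importance = 100 * bands[[1L]] / n,
    agreement_selection  = 100 * (bands[[1L]] + bands[[2L]]) / n)
}

#' Per-outcome descriptive statistics
#'
#' Mean, sample standard deviation (denominator n-1 unless configured
#' otherwise) and coefficient of variation CV = SD/mean of one outcome's
#' expert scores. CV <= 0.3 is the conventional coordination threshold.
#'
#' @param scores integer scores in 1..9.
#' @param sd_denominator `"n-1"` (sample SD, the default) or `"n"`.
#' @return named numeric vector `(mean, sd, cv)`.
#' @export
rating_descriptives <- function(scores, sd_denominator = c("n-1", "n")) {
  scores <- check_scores_1_9(scores)
  sd_denominator <- match.arg(sd_denominator)
  m <- mean(scores)
  n <- length(scores)
  s <- if (n == 1L) 0 else stats::sd(scores)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  cv <- if (m == 0) 0 else s / m
  c(mean = m, sd = s, cv = cv)
}

#' Default authority weights for the judgement and familiarity coefficients
#'
#' Judgement-basis weights per impact level (high, medium, low):
#' theoretical analysis 0.3/0.2/0.1, practical experience 0.5/0.4/0.3,
#' literature 0.1/0.1/0.1, intuition 0.1/0.1/0.1. Familiarity weights
#' 1.0/0.8/0.6/0.4/0.2 for very familiar through unfamiliar.
#'
#' @param basis_weights named list of length-3 numeric vectors
#'   (high, medium, low) for the four bases.
#' @param familiarity_weights length-5 numeric vector for the five
#'   familiarity levels, most to least familiar.
#' @return list of class `authority_weights`.
#' @export
authority_weights <- function(
    basis_weights = list(
      theoretical_analysis = c(high = 0.3, medium = 0.2, low = 0.1),
      practical_experience = c(high = 0.5, medium = 0.4, low = 0.3),
      literature           = c(high = 0.1, medium = 0.1, low = 0.1),
      intuition            = c(high = 0.1, medium = 0.1, low = 0.1)),
    familiarity_weights = c(very_familiar = 1.0, quite_familiar = 0.8,
                            moderately_familiar = 0.6,
                            not_very_familiar = 0.4, unfamiliar = 0.2)) {
  for (b in names(basis_weights)) {
    w <- basis_weights[[b]]
    if (length(w) != 3L || any(w < 0)) fail("basis '%s': need 3 non-negative weights", b)
    if (w[1] < w[2] || w[2] < w[3]) {
      fail("basis '%s': weights must satisfy high >= medium >= low", b)
    }
  }
  if (length(familiarity_weights) != 5L || any(familiarity_weights < 0)) {
    fail("need 5 non-negative familiarity weights")
  }
  structure(list(basis_weights = basis_weights,
                 familiarity_weights = familiarity_weights),
            class = "authority_weights")
}

basis_names <- c("theoretical_analysis", "practical_experience",
                 "literature", "intuition")
basis_levels <- c("high", "medium", "low")
familiarity_levels <- c("very_familiar", "quite_familiar",
                        "moderately_familiar", "not_very_familiar",
                        "unfamiliar")

#' Expert judgement-basis and familiarity profiles
#'
#' @param df data frame with columns `expert_id`,
#'   `theoretical_analysis`, `practical_experience`, `literature`,
#'   `intuition` (each `high`/`medium`/`low`) and `familiarity`
#'   (`very_familiar` .. `unfamiliar`).
#' @return the validated data frame, class `expert_profiles`.
#' @export
expert_profiles <- function(df) {
  need <- c("expert_id", basis_names, "familiarity")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("profiles missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$expert_id)) fail("duplicate expert_id in profiles")
  for (b in basis_names) {
    bad <- which(!df[[b]] %in% basis_levels)
    if (length(bad)) {
      fail("expert '%s': unknown %s level '%s'",
           df$expert_id[bad[1L]], b, df[[b]][bad[1L]])
    }
  }
  bad <- which(!df$familiarity %in% familiarity_levels)
  if (length(bad)) {
    fail("expert '%s': unknown familiarity level '%s'",
         df$expert_id[bad[1L]], df$familiarity[bad[1L]])
  }
  structure(as.data.frame(df), class = c("expert_profiles", "data.frame"))
}

#' Judgement coefficient Ca of an expert panel
#'
#' Weighted sum, over the four judgement bases, of the frequencies of
#' high/medium/low self-rated impact, divided by the panel size. Under
#' the default weights Ca lies in \[0.6, 1\].
#'
#' @param profiles an [expert_profiles] data frame.
#' @param weights an [authority_weights] object.
#' @return unrounded Ca.
#' @export
judgement_coefficient <- function(profiles, weights = authority_weights()) {
  profiles <- expert_profiles(profiles)
  n <- nrow(profiles)
  ca <- 0
  for (b in basis_names) {
    counts <- vapply(basis_levels, function(l) sum(profiles[[b]] == l), 0L)
    ca <- ca + sum(weights$basis_weights[[b]] * counts) / n
  }
  ca
}

#' Familiarity coefficient Cs of an expert panel
#'
#' Weighted mean of the panel's self-rated familiarity: 1.0 for very
#' familiar down to 0.2 for unfamiliar.
#'
#' @inheritParams judgement_coefficient
#' @return unrounded Cs in \[0.2, 1\].
#' @export
familiarity_coefficient <- function(profiles, weights = authority_weights()) {
  profiles <- expert_profiles(profiles)
  counts <- vapply(familiarity_levels, function(l) sum(profiles$familiarity == l), 0L)
  sum(weights$familiarity_weights * counts) / nrow(profiles)
}

#' Authority coefficient Cr = (Ca + Cs)/2
#'
#' Cr above 0.7 is conventionally read as acceptable panel reliability.
#'
#' @param Ca judgement coefficient in (0, 1].
#' @param Cs familiarity coefficient in (0, 1].
#' @return list with `Cr` and logical `acceptable` (`Cr > 0.7`).
#' @export
authority_coefficient <- function(Ca, Cs) {
  if (Ca <= 0 || Ca > 1) fail("Ca = %s out of (0, 1]", format(Ca))
  if (Cs <= 0 || Cs > 1) fail("Cs = %s out of (0, 1]", format(Cs))
  cr <- (Ca + Cs) / 2
  list(Cr = cr, acceptable = cr > 0.7)
}

#' Questionnaire response rate
#'
#' @param n_returned,n_distributed questionnaire counts.
#' @return percentage returned.
#' @export
response_rate <- function(n_returned, n_distributed) {
  if (n_distributed <= 0) fail("n_distributed must be positive")
  if (n_returned < 0 || n_returned > n_distributed) {
    fail("n_returned must be in [0, n_distributed]")
  }
  100 * n_returned / n_distributed
}

#' Selection-rule configuration for a Delphi round
#'
#' The default rule flags an outcome when its selection agreement
#' (votes in bands 4--6 plus 7--9) is strictly below
#' `agreement_threshold` percent AND its coefficient of variation is at
#' or above `cv_threshold`. Flagged outcomes named in `override_set`
#' (e.g. retained on external evidence such as a network meta-analysis)
#' become `retained_by_override`; other flagged outcomes are `excluded`;
#' everything else is `selected`.
#'
#' @param agreement_threshold percent, default 80; comparison is strict
#'   (an outcome at exactly the threshold is not flagged).
#' @param cv_threshold default 0.3; comparison is non-strict (CV exactly
#'   at the threshold flags).
#' @param band_edges passed to [band_counts()].
#' @param override_set character vector of outcome ids to retain despite
#'   flagging; optionally named, names holding a free-text justification.
#' @param agreement_driver which agreement coefficient drives the rule:
#'   `"selection"` (default) or `"importance"`.
#' @param flag_low_agreement_high_cv logical; `FALSE` inverts the rule's
#'   polarity (flag high-agreement/low-CV), provided for completeness.
#' @param sd_denominator passed to [rating_descriptives()].
#' @return list of class `selection_config`.
#' @export
selection_config <- function(agreement_threshold = 80, cv_threshold = 0.3,
                             band_edges = c(3L, 6L),
                             override_set = character(),
                             agreement_driver = c("selection", "importance"),
                             flag_low_agreement_high_cv = TRUE,
                             sd_denominator = c("n-1", "n")) {
  if (agreement_threshold <= 0 || agreement_threshold > 100) {
    fail("agreement_threshold must be in (0, 100]")
  }
  if (cv_threshold <= 0) fail("cv_threshold must be positive")
  structure(list(agreement_threshold = agreement_threshold,
                 cv_threshold = cv_threshold,
                 band_edges = band_edges,
                 override_set = override_set,
                 agreement_driver = match.arg(agreement_driver),
                 flag_low_agreement_high_cv = flag_low_agreement_high_cv,
                 sd_denominator = match.arg(sd_denominator)),
            class = "selection_config")
}

#' Evaluate one Delphi consensus round
#'
#' Computes, for every outcome, the band frequencies, the two agreement
#' coefficients, mean, SD and CV, applies the selection rules, and (when
#' profiles are supplied) the panel authority coefficients and response
#' rate. Rows are ordered by importance agreement (descending), ties by
#' outcome id, mirroring the conventional presentation of consensus
#' tables.
#'
#' @param ratings a [rating_matrix] (or coercible matrix).
#' @param profiles optional [expert_profiles] for Ca/Cs/Cr.
#' @param config a [selection_config].
#' @param weights an [authority_weights].
#' @param n_distributed number of questionnaires sent out; defaults to
#'   the panel size (100% response).
#' @return object of class `delphi_round` with components `stats`
#'   (per-outcome data frame), `decisions`, `authority`, `response_rate`,
#'   `config`, `n_experts`.
#' @examples
#' set.seed(1)
#' m <- rating_matrix(matrix(sample(6:9, 30, TRUE), 15, 2,
#'                    dimnames = list(NULL, c("mortality", "CAT"))))
#' delphi_round(m)
#' @export
delphi_round <- function(ratings, profiles = NULL,
                         config = selection_config(),
                         weights = authority_weights(),
                         n_distributed = NULL) {
  ratings <- if (inherits(ratings, "rating_matrix")) ratings else rating_matrix(ratings)
  n <- nrow(ratings)
  rows <- lapply(colnames(ratings), function(o) {
    b <- band_counts(ratings[, o], config$band_edges)
    a <- agreement_coefficients(b, n)
    d <- rating_descriptives(ratings[, o], config$sd_denominator)
    data.frame(outcome_id = o,
               n_critical = b[[1L]], n_important = b[[2L]],
               n_unimportant = b[[3L]],
               agreement_importance = a[[1L]], agreement_selection = a[[2L]],
               mean = d[[1L]], sd = d[[2L]], cv = d[[3L]],
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  stats <- stats[order(-stats$agreement_importance, stats$outcome_id), ,
                 drop = FALSE]
  rownames(stats) <- NULL
  dec <- apply_selection_rules(stats, config)
  stats$decision <- dec$decision[match(stats$outcome_id, dec$outcome_id)]

  authority <- NULL
  if (!is.null(profiles)) {
    ca <- judgement_coefficient(profiles, weights)
    cs <- familiarity_coefficient(profiles, weights)
    authority <- c(list(Ca = ca, Cs = cs), authority_coefficient(ca, cs))
  }
  n_distributed <- n_distributed %||% n
  structure(list(stats = stats,
                 decisions = dec,
                 authority = authority,
                 response_rate = response_rate(n, n_distributed),
                 config = config,
                 n_experts = n),
            class = "delphi_round")
}

#' Apply the Delphi selection/exclusion rules
#'
#' @param stats data frame with columns `outcome_id`,
#'   `agreement_selection`, `agreement_importance`, `cv` (as produced by
#'   [delphi_round()]).
#' @param config a [selection_config].
#' @return data frame with `outcome_id`, logical `flagged`, and
#'   `decision` in `selected`/`retained_by_override`/`excluded`, plus a
#'   `counts` attribute tabulating the decisions.
#' @export
apply_selection_rules <- function(stats, config = selection_config()) {
  if (nrow(stats) == 0L) {
    out <- data.frame(outcome_id = character(), flagged = logical(),
                      decision = character(), stringsAsFactors = FALSE)
    attr(out, "counts") <- c(selected = 0L, retained_by_override = 0L,
                             excluded = 0L)
    return(out)
  }
  ov <- config$override_set
  bad <- setdiff(ov, stats$outcome_id)
  if (length(bad)) {
    fail("override outcome(s) not present in stats: %s",
         paste(bad, collapse = ", "))
  }
  agree <- switch(config$agreement_driver,
                  selection = stats$agreement_selection,
                  importance = stats$agreement_importance)
  flagged <- (agree < config$agreement_threshold) & (stats$cv >= config$cv_threshold)
  if (!config$flag_low_agreement_high_cv) flagged <- !flagged
  decision <- ifelse(!flagged, "selected",
                     ifelse(stats$outcome_id %in% ov,
                            "retained_by_override", "excluded"))
  out <- data.frame(outcome_id = stats$outcome_id, flagged = flagged,
                    decision = decision, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    selected = sum(decision == "selected"),
    retained_by_override = sum(decision == "retained_by_override"),
    excluded = sum(decision == "excluded"))
  out
}

#' @export
print.delphi_round <- function(x, ...) {
  cat(sprintf("Delphi consensus round: %d experts, %d outcomes\n",
              x$n_experts, nrow(x$stats)))
  cat(sprintf("Response rate: %s%%\n", format(round_half_up(x$response_rate, 2))))
  if (!is.null(x$authority)) {
    cat(sprintf("Authority: Ca = %.2f, Cs = %.2f, Cr = %.3f (%s)\n",
                round_half_up(x$authority$Ca, 2),
                round_half_up(x$authority$Cs, 2),
                round_half_up(x$authority$Cr, 3),
                if (x$authority$acceptable) "acceptable, Cr > 0.7"
                else "below the 0.7 reliability bar"))
  }
  cnt <- attr(x$decisions, "counts")
  cat(sprintf("Decisions: %d selected, %d retained by override, %d excluded\n",
              cnt[["selected"]], cnt[["retained_by_override"]],
              cnt[["excluded"]]))
  invisible(x)
}

#' @export
summary.delphi_round <- function(object, ...) {
  s <- object$stats
  s$agreement_importance <- round_half_up(s$agreement_importance, 2)
  s$agreement_selection <- round_half_up(s$agreement_selection, 2)
  s$mean <- round_half_up(s$mean, 2)
  s$sd <- round_half_up(s$sd, 2)
  s$cv <- round_half_up(s$cv, 2)
  s
}
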