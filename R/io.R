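# Readers and writers for the CSV/JSON schemas of the pipeline.
# CSV dialect everywhere: UTF-8, comma separator, mandatory header row,
# "." decimal mark. Rounding happens only here, at the serialization
# boundary; in-memory statistics stay unrounded.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) fail("empty file: %s", path)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    fail("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  }
  df
}

#' Read a long-format expert ratings CSV
#'
#' Schema: `expert_id,outcome_id,score` with integer scores 1--9; every
#' (expert, outcome) cell must be present exactly once.
#'
#' @param path CSV file path.
#' @return a [rating_matrix].
#' @export
read_ratings_csv <- function(path) {
  df <- read_csv_checked(path, c("expert_id", "outcome_id", "score"))
  experts <- unique(df$expert_id)
  outcomes <- unique(df$outcome_id)
  key <- paste(df$expert_id, df$outcome_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    fail("%s: duplicate rating for expert '%s', outcome '%s'",
         path, df$expert_id[i], df$outcome_id[i])
  }
  m <- matrix(NA_real_, length(experts), length(outcomes),
              dimnames = list(experts, outcomes))
  m[cbind(match(df$expert_id, experts), match(df$outcome_id, outcomes))] <-
    df$score
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    fail("%s: no rating for expert '%s', outcome '%s'",
         path, experts[idx[1L]], outcomes[idx[2L]])
  }
  rating_matrix(m)
}

#' Read an expert profiles CSV
#'
#' Schema: `expert_id,theoretical_analysis,practical_experience,
#' literature,intuition,familiarity` with the level tokens documented in
#' [expert_profiles()].
#'
#' @param path CSV file path.
#' @return an [expert_profiles] data frame.
#' @export
read_profiles_csv <- function(path) {
  expert_profiles(read_csv_checked(
    path, c("expert_id", basis_names, "familiarity")))
}

#' Read AGREE II appraisals from CSV
#'
#' Per-rater mode: `document_id,appraiser_id,item,score`; aggregated
#' mode: `document_id,item,mean_score,n_appraisers`.
#'
#' @param path CSV file path.
#' @param mode `"per-rater"` or `"aggregated"`.
#' @return named list of [appraisal_matrix] objects, one per document.
#' @export
read_appraisals_csv <- function(path, mode = c("per-rater", "aggregated")) {
  mode <- match.arg(mode)
  if (mode == "per-rater") {
    df <- read_csv_checked(path, c("document_id", "appraiser_id", "item", "score"))
    out <- lapply(split(df, df$document_id), function(d) {
      raters <- unique(d$appraiser_id)
      m <- matrix(NA_real_, length(raters), 23L)
      m[cbind(match(d$appraiser_id, raters), d$item)] <- d$score
      appraisal_matrix(m, document_id = d$document_id[1L],
                       appraiser_ids = raters)
    })
  } else {
    df <- read_csv_checked(path, c("document_id", "item", "mean_score",
                                   "n_appraisers"))
    out <- lapply(split(df, df$document_id), function(d) {
      m <- matrix(NA_real_, 1L, 23L)
      m[1L, d$item] <- d$mean_score
      appraisal_matrix(m, document_id = d$document_id[1L],
                       n_appraisers = d$n_appraisers[1L], aggregated = TRUE)
    })
  }
  out
}

#' Read trial outcome-extraction records from CSV
#'
#' Schema: `trial_id,outcome_name[,domain]`.
#'
#' @param path CSV file path.
#' @return an [extraction_records] data frame.
#' @export
read_extractions_csv <- function(path) {
  extraction_records(read_csv_checked(path, c("trial_id", "outcome_name")))
}

#' Read arm-level trial data from CSV
#'
#' Continuous schema: `trial_id,treatment,n,mean,sd`; binary schema:
#' `trial_id,treatment,n,events`.
#'
#' @param path CSV file path.
#' @param measure `"md"` or `"rr"`.
#' @param reference optional reference treatment.
#' @return an [nma_network].
#' @export
read_arms_csv <- function(path, measure = c("md", "rr"), reference = NULL) {
  measure <- match.arg(measure)
  need <- c("trial_id", "treatment", "n",
            if (measure == "md") c("mean", "sd") else "events")
  nma_network(read_csv_checked(path, need), measure = measure,
              reference = reference)
}

#' Write a Delphi round report
#'
#' Emits a per-outcome CSV (band counts, agreement coefficients, mean,
#' SD, CV, decision; percentages and CV rounded half-up to 2 decimals)
#' and a JSON summary (panel size, response rate, authority
#' coefficients, decision counts). Output is deterministic: identical
#' inputs give byte-identical files.
#'
#' @param round a [delphi_round()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_delphi_report <- function(round, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "delphi_outcomes.csv")
  json_path <- file.path(dir, "delphi_summary.json")
  utils::write.csv(summary(round), csv_path, row.names = FALSE, quote = TRUE)
  cnt <- attr(round$decisions, "counts")
  summ <- list(n_experts = round$n_experts,
               response_rate = round_half_up(round$response_rate, 2),
               decisions = as.list(cnt))
  if (!is.null(round$authority)) {
    summ$authority <- list(Ca = round_half_up(round$authority$Ca, 2),
                           Cs = round_half_up(round$authority$Cs, 2),
                           Cr = round_half_up(round$authority$Cr, 3),
                           acceptable = round$authority$acceptable)
  }
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), json_path)
  invisible(c(csv_path, json_path))
}

#' Write an outcome-pool report
#'
#' CSV mirroring the reporting-frequency table:
#' `domain,outcome,count,frequency_percent,retained`.
#'
#' @param pool an [outcome_pool()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_pool_report <- function(pool, path) {
  t <- pool$tally
  t$retained <- t$outcome_name %in% pool$filter$retained$outcome_name
  out <- data.frame(domain = t$domain, outcome = t$outcome_name,
                    count = t$report_count,
                    frequency_percent = round_half_up(t$frequency_percent, 2),
                    retained = t$retained, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an NMA report
#'
#' Emits the relative-effect table with SUCRA and rank
#' (`nma_effects.csv`), the per-parameter convergence report
#' (`nma_psrf.csv`) and the pooled posterior draws as a plain-text
#' columnar file (`nma_draws.csv`).
#'
#' @param fit an [nma()] result.
#' @param dir output directory.
#' @param direction ranking direction, see [sucra()].
#' @return invisibly, the paths written.
#' @export
write_nma_report <- function(fit, dir, direction = "higher") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eff <- relative_effects(fit)
  rk <- sucra(fit, direction)
  eff$sucra <- round_half_up(100 * rk$sucra[eff$treatment], 2)
  eff$rank <- rank(-rk$sucra, ties.method = "min")[eff$treatment]
  eff$estimate <- round_half_up(eff$estimate, 4)
  eff$lower <- round_half_up(eff$lower, 4)
  eff$upper <- round_half_up(eff$upper, 4)
  p1 <- file.path(dir, "nma_effects.csv")
  p2 <- file.path(dir, "nma_psrf.csv")
  p3 <- file.path(dir, "nma_draws.csv")
  utils::write.csv(eff, p1, row.names = FALSE, quote = TRUE)
  psrf_out <- fit$psrf
  psrf_out$psrf <- round_half_up(psrf_out$psrf, 4)
  psrf_out$converged <- fit$converged
  utils::write.csv(psrf_out, p2, row.names = FALSE, quote = TRUE)
  draws <- do.call(rbind, fit$draws)
  utils::write.csv(as.data.frame(draws), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
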