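#' Trial outcome-extraction records
#'
#' @param df data frame with columns `trial_id`, `outcome_name` and
#'   optionally `domain` (evaluation domain). Duplicate
#'   (trial, outcome) pairs collapse to one (a trial reports an outcome
#'   or it does not).
#' @return validated data frame of class `extraction_records`.
#' @export
extraction_records <- function(df) {
  need <- c("trial_id", "outcome_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("extraction records missing column(s): %s",
                         paste(miss, collapse = ", "))
  if (!"domain" %in% names(df)) df$domain <- NA_character_
  df$outcome_name <- normalize_outcome(df$outcome_name)
  if (any(!nzchar(df$outcome_name))) fail("empty outcome name")
  df <- unique(df[, c("trial_id", "outcome_name", "domain")])
  # one domain per outcome name across the whole record set
  dmap <- unique(df[!is.na(df$domain), c("outcome_name", "domain")])
  dup <- dmap$outcome_name[duplicated(dmap$outcome_name)]
  if (length(dup)) {
    both <- dmap[dmap$outcome_name == dup[1L], "domain"]
    fail("outcome '%s' assigned to conflicting domains: %s",
         dup[1L], paste(both, collapse = " vs "))
  }
  structure(df, class = c("extraction_records", "data.frame"))
}

# trim + case-fold; exact matching after that (synonyms are the user's job,
# optionally via the synonym_map arguments below)
normalize_outcome <- function(x) tolower(trimws(x))

apply_synonyms <- function(x, synonym_map) {
  if (is.null(synonym_map)) return(x)
  key <- normalize_outcome(names(synonym_map))
  val <- normalize_outcome(unlist(synonym_map, use.names = FALSE))
  hit <- match(x, key)
  ifelse(is.na(hit), x, val[hit])
}

#' Tally outcome reporting across trials
#'
#' Counts, per outcome, the number of distinct trials reporting it and
#' the corresponding reporting frequency in percent.
#'
#' @param records an [extraction_records] data frame (or coercible).
#' @param total_trials denominator for frequencies; defaults to the
#'   number of distinct trial ids in `records` (pass the full trial
#'   count when some trials report none of the outcomes of interest).
#' @param synonym_map optional named character vector mapping reported
#'   names to canonical ones, applied before tallying.
#' @return data frame of class `outcome_tally`: `outcome_name`,
#'   `domain`, `report_count`, `frequency_percent`, sorted by count
#'   (descending) then name; `total_trials` attached as an attribute.
#' @export
tally_outcomes <- function(records, total_trials = NULL, synonym_map = NULL) {
  records <- extraction_records(as.data.frame(records))
  records$outcome_name <- apply_synonyms(records$outcome_name, synonym_map)
  records <- unique(records[, c("trial_id", "outcome_name", "domain")])
  total_trials <- total_trials %||% length(unique(records$trial_id))
  if (total_trials <= 0) fail("total_trials must be positive")
  counts <- tapply(records$trial_id, records$outcome_name,
                   function(x) length(unique(x)))
  dmap <- records[!duplicated(records$outcome_name),
                  c("outcome_name", "domain")]
  out <- data.frame(outcome_name = names(counts),
                    domain = dmap$domain[match(names(counts), dmap$outcome_name)],
                    report_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (any(out$report_count > total_trials)) {
    fail("an outcome is reported by more trials than total_trials = %d",
         total_trials)
  }
  out$frequency_percent <- 100 * out$report_count / total_trials
  out <- out[order(-out$report_count, out$outcome_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_trials") <- total_trials
  class(out) <- c("outcome_tally", "data.frame")
  out
}

#' Frequency filter for core-outcome candidacy
#'
#' Retains outcomes reported in strictly more than `threshold_percent`
#' of trials (the conventional "more than 6% of RCTs" screen; the
#' strictness is configurable).
#'
#' @param tally an [tally_outcomes()] result.
#' @param threshold_percent default 6.
#' @param strict logical; `TRUE` (default) keeps only frequencies
#'   strictly above the threshold.
#' @return list with data frames `retained` and `dropped` (each with the
#'   tally columns) and the `threshold_percent` used.
#' @export
frequency_filter <- function(tally, threshold_percent = 6, strict = TRUE) {
  if (threshold_percent < 0 || threshold_percent > 100) {
    fail("threshold_percent must be in [0, 100]")
  }
  keep <- if (strict) tally$frequency_percent > threshold_percent
          else tally$frequency_percent >= threshold_percent
  list(retained = tally[keep, , drop = FALSE],
       dropped = tally[!keep, , drop = FALSE],
       threshold_percent = threshold_percent)
}

#' Merge outcome candidates from multiple recommendation sources
#'
#' Unions outcome sets proposed by different sources (core outcome set
#' studies, regulatory guidance, guidelines, ...) with the
#' frequency-filtered trial-reported core set, annotating every
#' candidate with the full set of sources that proposed it.
#'
#' @param sources named list of character vectors of outcome names; the
#'   names are the source tags (e.g. `COS`, `guideline`, `regulatory`).
#' @param tally_core optional retained data frame from
#'   [frequency_filter()]; its outcomes are tagged `RCT_frequency`.
#' @param domains optional named character vector outcome -> evaluation
#'   domain; conflicting assignments raise an error.
#' @return data frame of class `candidate_list`: `outcome_name`,
#'   `domain`, `provenance` (comma-joined source tags), `included`;
#'   ordered by (domain, name).
#' @export
merge_candidates <- function(sources = list(), tally_core = NULL,
                             domains = NULL) {
  if (length(sources) && anyDuplicated(names(sources))) {
    fail("duplicate source tags")
  }
  prov <- list()
  add <- function(outs, tag) {
    for (o in normalize_outcome(outs)) {
      prov[[o]] <<- union(prov[[o]], tag)
    }
  }
  for (tag in names(sources)) add(sources[[tag]], tag)
  dom <- list()
  if (!is.null(tally_core)) {
    add(tally_core$outcome_name, "RCT_frequency")
    for (i in seq_len(nrow(tally_core))) {
      if (!is.na(tally_core$domain[i])) {
        dom[[tally_core$outcome_name[i]]] <- tally_core$domain[i]
      }
    }
  }
  if (!is.null(domains)) {
    for (o in names(domains)) {
      key <- normalize_outcome(o)
      if (!is.null(dom[[key]]) && dom[[key]] != domains[[o]]) {
        fail("outcome '%s' assigned to conflicting domains: %s vs %s",
             key, dom[[key]], domains[[o]])
      }
      dom[[key]] <- domains[[o]]
    }
  }
  if (length(prov) == 0L) {
    out <- data.frame(outcome_name = character(), domain = character(),
                      provenance = character(), included = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_list", "data.frame")
    return(out)
  }
  nm <- names(prov)
  out <- data.frame(
    outcome_name = nm,
    domain = vapply(nm, function(o) dom[[o]] %||% NA_character_, ""),
    provenance = vapply(nm, function(o) paste(sort(prov[[o]]), collapse = ","), ""),
    included = TRUE,
    stringsAsFactors = FALSE)
  out <- out[order(out$domain, out$outcome_name, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Run the outcome-pooling stage in one call
#'
#' @param records an [extraction_records] data frame.
#' @param sources named list of recommendation-source outcome sets.
#' @param total_trials,threshold_percent,synonym_map see
#'   [tally_outcomes()] and [frequency_filter()].
#' @return list of class `outcome_pool`: `tally`, `filter`
#'   (retained/dropped) and `candidates`.
#' @export
outcome_pool <- function(records, sources = list(), total_trials = NULL,
                         threshold_percent = 6, synonym_map = NULL) {
  tally <- tally_outcomes(records, total_trials, synonym_map)
  filt <- frequency_filter(tally, threshold_percent)
  cand <- merge_candidates(sources, filt$retained)
  structure(list(tally = tally, filter = filt, candidates = cand),
            class = "outcome_pool")
}

#' @export
print.outcome_pool <- function(x, ...) {
  cat(sprintf("Outcome pool: %d outcomes over %d trials; %d above %.3g%% reporting, %d candidates\n",
              nrow(x$tally), attr(x$tally, "total_trials"),
              nrow(x$filter$retained), x$filter$threshold_percent,
              nrow(x$candidates)))
  invisible(x)
}
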