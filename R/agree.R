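#' AGREE II item-to-domain mapping
#'
#' The 23 appraisal items partition into six domains: Scope and Purpose
#' (items 1-3), Stakeholder Involvement (4-6), Rigor of Development
#' (7-14), Clarity of Presentation (15-17), Applicability (18-21) and
#' Editorial Independence (22-23).
#'
#' @return named list of item-index vectors, one per domain.
#' @export
agree_domains <- function() {
  list(`Scope and Purpose`       = 1:3,
       `Stakeholder Involvement` = 4:6,
       `Rigor of Development`    = 7:14,
       `Clarity of Presentation` = 15:17,
       `Applicability`           = 18:21,
       `Editorial Independence`  = 22:23)
}

#' Standardized AGREE II domain score
#'
#' `100 * (obtained - minimum possible) / (maximum possible - minimum
#' possible)` where obtained is the total score over appraisers and
#' items of the domain on the 1--7 item scale. Identical whether
#' computed from the raw appraiser-by-item block or from item means
#' (obtained = n_appraisers * sum of item means).
#'
#' @param scores either a numeric matrix (appraisers x items of one
#'   domain) or, with `n_appraisers` given, a vector of per-item mean
#'   scores.
#' @param n_appraisers required when `scores` is a vector of item means.
#' @param scale item scale bounds, default `c(1, 7)`.
#' @return unrounded percent in \[0, 100\]; display rounding is half-up
#'   to integer percent.
#' @examples
#' standardized_domain_score(c(7, 7, 6.33), n_appraisers = 3)  # ~96.3
#' @export
standardized_domain_score <- function(scores, n_appraisers = NULL,
                                      scale = c(1, 7)) {
  if (is.matrix(scores)) {
    n_app <- nrow(scores)
    n_items <- ncol(scores)
    obtained <- sum(scores)
  } else {
    if (is.null(n_appraisers)) {
      fail("supply n_appraisers when scoring from item means")
    }
    n_app <- n_appraisers
    n_items <- length(scores)
    obtained <- n_app * sum(scores)
  }
  if (n_items < 1L || n_app < 1L) fail("need at least one appraiser and one item")
  # item means ingested from published tables occasionally dip below the
  # scale minimum; tolerate down to 0, never above the maximum
  if (any(scores < 0 | scores > scale[2])) {
    fail("item score outside the [0, %g] range", scale[2])
  }
  min_possible <- n_app * n_items * scale[1]
  max_possible <- n_app * n_items * scale[2]
  100 * (obtained - min_possible) / (max_possible - min_possible)
}

#' Appraisal matrix for one document
#'
#' @param item_scores appraisers x 23 numeric matrix of AGREE II item
#'   scores; integers 1--7 in per-rater mode, possibly fractional item
#'   means (a 1 x 23 matrix) in aggregated mode.
#' @param document_id document label.
#' @param appraiser_ids optional labels.
#' @param n_appraisers actual number of appraisers behind the scores;
#'   defaults to `nrow(item_scores)`. Set this in aggregated mode, where
#'   `item_scores` has a single row of item means.
#' @param aggregated logical; `TRUE` when `item_scores` holds item means
#'   rather than raw per-rater integers (ICC is then unavailable).
#' @return object of class `appraisal_matrix`.
#' @export
appraisal_matrix <- function(item_scores, document_id = "document",
                             appraiser_ids = NULL, n_appraisers = NULL,
                             aggregated = FALSE) {
  item_scores <- as.matrix(item_scores)
  if (ncol(item_scores) != 23L) fail("AGREE II has 23 items; got %d columns",
                                     ncol(item_scores))
  if (any(is.na(item_scores))) fail("missing item score in '%s'", document_id)
  if (any(item_scores < 0 | item_scores > 7)) {
    fail("item score outside [0, 7] in '%s'", document_id)
  }
  if (!aggregated && any(item_scores != floor(item_scores))) {
    fail("per-rater scores must be integers; use aggregated = TRUE for item means")
  }
  structure(list(item_scores = item_scores,
                 document_id = document_id,
                 appraiser_ids = appraiser_ids %||%
                   paste0("A", seq_len(nrow(item_scores))),
                 n_appraisers = n_appraisers %||% nrow(item_scores),
                 aggregated = aggregated),
            class = "appraisal_matrix")
}

#' Score one document on all six AGREE II domains
#'
#' @param matrix an [appraisal_matrix].
#' @param thresholds recommendation-grading thresholds, see
#'   [recommendation_level()].
#' @param icc_model ICC variant for rater consistency, see [icc()].
#' @return list of class `agree_appraisal`: `document_id`,
#'   `domain_scores` (six unrounded percents), `recommendation_level`,
#'   and `icc` (`NULL` in aggregated mode, where per-rater data are
#'   absent).
#' @export
appraise_document <- function(matrix,
                              thresholds = recommendation_thresholds(),
                              icc_model = c("ICC2_1", "ICC3_1")) {
  dom <- agree_domains()
  scores <- vapply(dom, function(items) {
    block <- matrix$item_scores[, items, drop = FALSE]
    if (matrix$aggregated) {
      standardized_domain_score(colMeans(block),
                                n_appraisers = matrix$n_appraisers)
    } else {
      standardized_domain_score(block)
    }
  }, 0)
  icc_res <- NULL
  if (!matrix$aggregated && nrow(matrix$item_scores) >= 2L) {
    icc_res <- icc(matrix$item_scores, model = match.arg(icc_model))
  }
  structure(list(document_id = matrix$document_id,
                 domain_scores = scores,
                 recommendation_level = recommendation_level(scores, thresholds),
                 icc = icc_res),
            class = "agree_appraisal")
}

#' @export
print.agree_appraisal <- function(x, ...) {
  cat(sprintf("AGREE II appraisal of '%s'\n", x$document_id))
  sc <- round_half_up(x$domain_scores)
  for (i in seq_along(sc)) {
    cat(sprintf("  %-24s %3d%%\n", names(sc)[i], as.integer(sc[i])))
  }
  cat(sprintf("  Recommendation level: %s\n", x$recommendation_level))
  if (!is.null(x$icc)) {
    cat(sprintf("  Rater ICC: %.3f (p = %.3g)\n", x$icc$icc, x$icc$p_value))
  }
  invisible(x)
}

#' Mean domain score across documents
#'
#' @param scores numeric vector of per-document standardized percentages
#'   for one domain.
#' @return unrounded mean percent (display rounding: half-up to integer).
#' @export
domain_mean <- function(scores) {
  if (length(scores) == 0L) fail("no domain scores supplied")
  mean(scores)
}

#' Intra-class correlation coefficient for rater consistency
#'
#' Two-way ANOVA-based ICC over a raters x subjects score matrix.
#' `ICC2_1` (the default) is the two-way random-effects,
#' absolute-agreement, single-measures coefficient; `ICC3_1` is the
#' two-way mixed consistency variant. The p-value is from the ANOVA
#' F-test of the subject effect (F = MSR/MSE on n-1 and (n-1)(k-1)
#' degrees of freedom).
#'
#' @param ratings numeric matrix, raters in rows, subjects in columns.
#' @param model `"ICC2_1"` or `"ICC3_1"`.
#' @return list `icc`, `p_value`, `model`, `status` (`"ok"` or
#'   `"degenerate"` when all scores are identical, in which case `icc`
#'   is `NA`).
#' @export
icc <- function(ratings, model = c("ICC2_1", "ICC3_1")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  k <- nrow(ratings)  # raters
  n <- ncol(ratings)  # subjects
  if (k < 2L || n < 2L) fail("ICC needs at least 2 raters and 2 subjects")
  if (anyNA(ratings)) fail("ICC requires a complete matrix")
  if (stats::var(as.vector(ratings)) == 0) {
    return(list(icc = NA_real_, p_value = NA_real_, model = model,
                status = "degenerate"))
  }
  d <- data.frame(score = as.vector(ratings),
                  rater = factor(rep(seq_len(k), times = n)),
                  subject = factor(rep(seq_len(n), each = k)))
  # perfect agreement gives a zero residual MS; the F-test warning is
  # expected there and the ICC itself (1) is well defined
  ms <- suppressWarnings(
    stats::anova(stats::aov(score ~ subject + rater, data = d)))
  msr <- ms["subject", "Mean Sq"]   # between-subject
  msc <- ms["rater", "Mean Sq"]     # between-rater
  mse <- ms["Residuals", "Mean Sq"]
  est <- switch(model,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse))
  f <- msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = est, p_value = p, model = model, status = "ok")
}

#' Recommendation-grading thresholds
#'
#' Defaults: level A when every domain scores at least `a_min` (60%);
#' level C when fewer than `c_domains` (3) domains reach `c_min` (30%);
#' level B otherwise.
#'
#' @param a_min,c_min percent cut-offs.
#' @param c_domains minimum number of domains at `c_min` to escape C.
#' @return named list.
#' @export
recommendation_thresholds <- function(a_min = 60, c_min = 30, c_domains = 3L) {
  list(a_min = a_min, c_min = c_min, c_domains = c_domains)
}

#' Grade a document from its six domain scores
#'
#' @param domain_scores six standardized percentages.
#' @param thresholds a [recommendation_thresholds()] list.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
recommendation_level <- function(domain_scores,
                                 thresholds = recommendation_thresholds()) {
  if (length(domain_scores) != 6L) {
    fail("need exactly 6 domain scores, got %d", length(domain_scores))
  }
  if (any(domain_scores < 0 | domain_scores > 100)) {
    fail("domain scores must lie in [0, 100]")
  }
  if (all(domain_scores >= thresholds$a_min)) return("A")
  if (sum(domain_scores >= thresholds$c_min) < thresholds$c_domains) return("C")
  "B"
}
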