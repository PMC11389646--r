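#' Assemble arm-level trial data into a treatment network
#'
#' @param arms data frame of arm records. Continuous outcomes (mean
#'   difference scale) need columns `trial_id, treatment, n, mean, sd`;
#'   binary outcomes (relative-risk scale) need
#'   `trial_id, treatment, n, events`.
#' @param measure `"md"` (continuous, mean difference) or `"rr"`
#'   (binary, relative risk modelled on the log scale).
#' @param reference reference treatment; defaults to `"CI"`
#'   (conventional-intervention control) when present, else the first
#'   treatment label in sort order.
#' @return object of class `nma_network`: the validated arm table plus
#'   `treatments`, `reference`, `measure`, `trials`.
#' @examples
#' arms <- data.frame(trial_id = c(1, 1, 2, 2),
#'                    treatment = c("A", "B", "B", "C"),
#'                    n = 50, mean = c(0, 1, 1, 2), sd = 1)
#' nma_network(arms, measure = "md", reference = "A")
#' @export
nma_network <- function(arms, measure = c("md", "rr"), reference = NULL) {
  measure <- match.arg(measure)
  arms <- as.data.frame(arms)
  need <- c("trial_id", "treatment", "n",
            if (measure == "md") c("mean", "sd") else "events")
  miss <- setdiff(need, names(arms))
  if (length(miss)) fail("arm data missing column(s): %s",
                         paste(miss, collapse = ", "))
  if (any(arms$n < 1)) fail("arm sample size must be >= 1")
  if (measure == "md" && any(arms$sd <= 0)) fail("arm sd must be positive")
  if (measure == "rr" && any(arms$events < 0 | arms$events > arms$n)) {
    fail("events must lie in [0, n]")
  }
  key <- paste(arms$trial_id, arms$treatment)
  if (anyDuplicated(key)) {
    fail("duplicate (trial, treatment) arm: %s", key[duplicated(key)][1L])
  }
  by_trial <- split(arms$treatment, arms$trial_id)
  single <- names(by_trial)[vapply(by_trial, length, 0L) < 2L]
  if (length(single)) fail("trial '%s' has fewer than 2 arms", single[1L])

  treatments <- sort(unique(arms$treatment))
  reference <- reference %||% if ("CI" %in% treatments) "CI" else treatments[1L]
  if (!reference %in% treatments) {
    fail("reference treatment '%s' not present in the data", reference)
  }
  treatments <- c(reference, setdiff(treatments, reference))

  # connectivity by breadth-first traversal over trial co-membership
  reached <- treatments[1L]
  repeat {
    grow <- unique(unlist(by_trial[vapply(by_trial, function(tr)
      any(tr %in% reached), TRUE)]))
    if (all(grow %in% reached)) break
    reached <- union(reached, grow)
  }
  if (!setequal(reached, treatments)) {
    fail("network is disconnected: treatment(s) %s unreachable from '%s'",
         paste(setdiff(treatments, reached), collapse = ", "), reference)
  }
  arms <- arms[order(arms$trial_id, match(arms$treatment, treatments)), ,
               drop = FALSE]
  rownames(arms) <- NULL
  structure(list(arms = arms, treatments = treatments,
                 reference = reference, measure = measure,
                 trials = unique(arms$trial_id)),
            class = "nma_network")
}

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("Treatment network: %d treatments, %d trials, %d arms (%s)\n",
              length(x$treatments), length(x$trials), nrow(x$arms),
              if (x$measure == "md") "continuous, MD"
              else "binary, RR (log link)"))
  cat(sprintf("Reference: %s\n", x$reference))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from between- and within-chain variances of one scalar
#' parameter: with m chains of length n, `W` the mean within-chain
#' variance and `B/n` the variance of the chain means, the pooled
#' variance estimate is `(n-1)/n W + B/n` and the PSRF is the square
#' root of its ratio to `W`. Values inside \[1.00, 1.05\] indicate
#' satisfactory convergence.
#'
#' @param chains list of equal-length numeric vectors (one per chain),
#'   or a matrix with one column per chain; at least 2 chains of length
#'   at least 10.
#' @return list `psrf` and `status` (`"ok"`, or `"degenerate"` with
#'   `psrf = NA` when the within-chain variance is zero).
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) fail("PSRF needs at least 2 chains")
  n <- unique(vapply(chains, length, 0L))
  if (length(n) != 1L) fail("chains must have equal length")
  if (n < 10L) fail("chains must have length >= 10")
  w <- mean(vapply(chains, stats::var, 0))
  if (w == 0) return(list(psrf = NA_real_, status = "degenerate"))
  b_over_n <- stats::var(vapply(chains, mean, 0))
  var_hat <- (n - 1) / n * w + b_over_n
  list(psrf = sqrt(var_hat / w), status = "ok")
}
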