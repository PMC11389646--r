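# pairwise random-effects pooling (DerSimonian-Laird via metafor) of the
# contrast a-vs-b over a set of trials that contain both treatments
pairwise_pool <- function(network, a, b, trial_ids) {
  arms <- network$arms[network$arms$trial_id %in% trial_ids, , drop = FALSE]
  ga <- arms[arms$treatment == a, , drop = FALSE]
  gb <- arms[arms$treatment == b, , drop = FALSE]
  gb <- gb[match(ga$trial_id, gb$trial_id), , drop = FALSE]
  es <- if (network$measure == "md") {
    metafor::escalc(measure = "MD",
                    m1i = ga$mean, sd1i = ga$sd, n1i = ga$n,
                    m2i = gb$mean, sd2i = gb$sd, n2i = gb$n)
  } else {
    metafor::escalc(measure = "RR",
                    ai = ga$events, n1i = ga$n,
                    ci = gb$events, n2i = gb$n)
  }
  fit <- metafor::rma(yi, vi, data = es, method = "DL")
  c(estimate = as.numeric(fit$beta), se = fit$se)
}

trials_with <- function(network, trts) {
  by_trial <- split(network$arms$treatment, network$arms$trial_id)
  names(by_trial)[vapply(by_trial, function(x) all(trts %in% x), TRUE)]
}

#' Bucher direct-versus-indirect consistency check
#'
#' First-order-loop check of the consistency assumption for one
#' treatment pair: the direct estimate pools the trials containing both
#' treatments (pairwise random effects, DerSimonian-Laird); the
#' indirect estimate chains the two legs through a common comparator
#' (`d_ab = d_ac - d_bc`, variance the sum of the leg variances), using
#' only trials independent of the direct evidence. The difference is
#' tested with a two-sided normal z-test. This is a declared
#' simplification of full node-splitting: only first-order loops are
#' examined.
#'
#' @param network an [nma_network].
#' @param pair character vector `c(a, b)`.
#' @return list of class `node_split`: `pair`, `comparator`, `direct`
#'   and `indirect` (estimate, se), `difference`, `z`, `p_value`.
#' @export
bucher_node_split <- function(network, pair) {
  if (length(pair) != 2L || !all(pair %in% network$treatments)) {
    fail("pair must name two treatments in the network")
  }
  a <- pair[1L]; b <- pair[2L]
  direct_trials <- trials_with(network, c(a, b))
  if (length(direct_trials) == 0L) {
    fail("no direct evidence for %s vs %s", a, b)
  }
  # candidate comparators with independent a-c and b-c legs
  others <- setdiff(network$treatments, pair)
  legs <- lapply(others, function(cc) {
    ta <- setdiff(trials_with(network, c(a, cc)), direct_trials)
    tb <- setdiff(trials_with(network, c(b, cc)), direct_trials)
    list(comparator = cc, ta = ta, tb = tb,
         strength = min(length(ta), length(tb)))
  })
  strengths <- vapply(legs, function(l) l$strength, 0L)
  if (all(strengths == 0L)) {
    fail("no independent first-order indirect path for %s vs %s", a, b)
  }
  leg <- legs[[which.max(strengths)]]
  direct <- pairwise_pool(network, a, b, direct_trials)
  d_ac <- pairwise_pool(network, a, leg$comparator, leg$ta)
  d_bc <- pairwise_pool(network, b, leg$comparator, leg$tb)
  indirect <- c(estimate = d_ac[["estimate"]] - d_bc[["estimate"]],
                se = sqrt(d_ac[["se"]]^2 + d_bc[["se"]]^2))
  diff <- direct[["estimate"]] - indirect[["estimate"]]
  se_diff <- sqrt(direct[["se"]]^2 + indirect[["se"]]^2)
  z <- diff / se_diff
  structure(list(pair = pair, comparator = leg$comparator,
                 direct = direct, indirect = indirect,
                 difference = diff, se_difference = se_diff,
                 z = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "node_split")
}

#' @export
print.node_split <- function(x, ...) {
  cat(sprintf("Consistency check (first-order Bucher loop) %s vs %s via %s\n",
              x$pair[1L], x$pair[2L], x$comparator))
  cat(sprintf("  direct   %8.4f (se %.4f)\n", x$direct[["estimate"]],
              x$direct[["se"]]))
  cat(sprintf("  indirect %8.4f (se %.4f)\n", x$indirect[["estimate"]],
              x$indirect[["se"]]))
  cat(sprintf("  difference %.4f, z = %.3f, p = %.4f (%s)\n",
              x$difference, x$z, x$p_value,
              if (x$p_value >= 0.05) "consistent at the 5% level"
              else "inconsistency signal"))
  invisible(x)
}
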