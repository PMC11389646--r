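#' MCMC configuration for the Bayesian network meta-analysis
#'
#' @param n_chains number of Markov chains (default 3; at least 2 so
#'   the PSRF is defined).
#' @param n_iter iterations per chain after burn-in (default 10,000).
#' @param n_burnin burn-in iterations discarded per chain (default
#'   1,000); step sizes adapt only during burn-in, so the retained
#'   draws come from a fixed transition kernel.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; chain `c` uses `seed + c - 1`, making
#'   runs bit-reproducible.
#' @param prior_d_sd prior standard deviation of the basic parameters
#'   (normal, mean 0) on the model scale (MD, or log RR).
#' @param tau_upper upper bound of the uniform prior on the
#'   between-trial heterogeneity SD; `NULL` sets it from the data scale
#'   (continuous: 5 x pooled arm SD; log RR: 2).
#' @param psrf_limits acceptable PSRF band, default `c(1, 1.05)`.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 10000L, n_burnin = 1000L,
                        thin = 1L, seed = 1L, prior_d_sd = 100,
                        tau_upper = NULL, psrf_limits = c(1, 1.05)) {
  if (n_chains < 2L) fail("need at least 2 chains for the PSRF")
  if (n_burnin < 0L || n_iter < 10L) fail("invalid iteration counts")
  if (thin < 1L) fail("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), prior_d_sd = prior_d_sd,
                 tau_upper = tau_upper, psrf_limits = psrf_limits),
            class = "mcmc_config")
}

# per-arm log likelihood given linear predictor eta
# md: eta is the arm mean; rr: eta is the arm log risk
arm_loglik <- function(eta, dat, measure) {
  if (measure == "md") {
    stats::dnorm(dat$y, eta, dat$se, log = TRUE)
  } else {
    p <- exp(eta)
    ll <- ifelse(p >= 1 | p <= 0, -Inf,
                 dat$r * eta + (dat$n - dat$r) * log1p(-pmin(p, 1 - 1e-12)))
    ll
  }
}

#' Fit a Bayesian random-effects consistency network meta-analysis
#'
#' Arm-based model: each trial has its own baseline parameter; each
#' non-baseline arm has a trial-specific deviation, exchangeable around
#' the consistency contrast `d[treatment] - d[baseline]` with
#' between-trial SD `tau`. Continuous arms use a normal likelihood for
#' the observed arm mean (SE = sd/sqrt(n)); binary arms a binomial
#' likelihood with log link, so `d` is a log relative risk (proposals
#' implying risk >= 1 are rejected). Sampling is adaptive random-walk
#' Metropolis-within-Gibbs: baselines and deviations by Metropolis
#' steps, the basic parameters by exact Gibbs draws from their normal
#' full conditionals, `tau` by Metropolis under a uniform prior.
#'
#' @param network an [nma_network].
#' @param config an [mcmc_config].
#' @return object of class `nma_fit`: per-chain draw matrices
#'   (`draws`, columns `d[...]` and `tau`), PSRF table (`psrf`),
#'   `converged` flag, the network and config.
#' @examples
#' arms <- data.frame(trial_id = rep(1:4, each = 2),
#'                    treatment = c("CI", "A", "CI", "A", "CI", "B", "A", "B"),
#'                    n = 100,
#'                    mean = c(0, 1, 0.2, 1.1, 0, 2, 1, 2.2), sd = 2)
#' net <- nma_network(arms, "md")
#' fit <- nma(net, mcmc_config(n_iter = 500, n_burnin = 200, seed = 7))
#' coef(fit)
#' @export
nma <- function(network, config = mcmc_config()) {
  stopifnot(inherits(network, "nma_network"))
  measure <- network$measure
  arms <- network$arms
  trt <- network$treatments
  k_trt <- length(trt)
  trial_idx <- match(arms$trial_id, network$trials)
  n_trials <- length(network$trials)
  t_arm <- match(arms$treatment, trt)
  # baseline arm = first arm of each trial (lowest treatment order)
  is_base <- !duplicated(trial_idx)
  base_t <- t_arm[is_base][trial_idx]          # baseline treatment per arm
  nb <- which(!is_base)                        # non-baseline arm rows

  dat <- if (measure == "md") {
    list(y = arms$mean, se = arms$sd / sqrt(arms$n))
  } else {
    list(r = arms$events, n = arms$n)
  }
  tau_upper <- config$tau_upper %||%
    if (measure == "md") 5 * sqrt(mean(arms$sd^2)) else 2

  # data-based initial values, jittered per chain
  init_mu <- if (measure == "md") {
    arms$mean[is_base]
  } else {
    log((arms$events[is_base] + 0.5) / (arms$n[is_base] + 1))
  }
  obs_arm <- if (measure == "md") {
    arms$mean
  } else {
    log((arms$events + 0.5) / (arms$n + 1))
  }
  init_delta <- obs_arm[nb] - init_mu[trial_idx[nb]]

  n_keep <- config$n_iter %/% config$thin
  d_cols <- paste0("d[", trt[-1L], "]")
  draws <- vector("list", config$n_chains)

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    mu <- init_mu + stats::rnorm(n_trials, 0, 0.1)
    delta <- init_delta + stats::rnorm(length(nb), 0, 0.1)
    d <- c(0, stats::rnorm(k_trt - 1L, 0, 0.5))
    tau <- tau_upper * (0.05 + 0.1 * chain / config$n_chains)
    step_mu <- rep(0.5, n_trials)
    step_delta <- rep(0.5, length(nb))
    step_tau <- tau_upper / 10
    acc_mu <- acc_delta <- acc_tau <- 0
    adapt_every <- 50L

    delta_full <- numeric(nrow(arms))
    out <- matrix(NA_real_, n_keep, k_trt)  # d[2..K], tau
    kept <- 0L
    total_iter <- config$n_burnin + config$n_iter

    for (it in seq_len(total_iter)) {
      delta_full[nb] <- delta
      eta <- mu[trial_idx] + delta_full

      ## baselines: elementwise Metropolis per trial
      mu_prop <- mu + stats::rnorm(n_trials, 0, step_mu)
      eta_prop <- mu_prop[trial_idx] + delta_full
      ll_cur <- arm_loglik(eta, dat, measure)
      ll_prop <- arm_loglik(eta_prop, dat, measure)
      dll <- rowsum(ll_prop - ll_cur, trial_idx)[, 1L] +
        stats::dnorm(mu_prop, 0, 100, log = TRUE) -
        stats::dnorm(mu, 0, 100, log = TRUE)
      acc <- log(stats::runif(n_trials)) < dll
      mu[acc] <- mu_prop[acc]
      acc_mu <- acc_mu + mean(acc)

      ## deviations: elementwise Metropolis per non-baseline arm
      delta_full[nb] <- delta
      eta <- mu[trial_idx] + delta_full
      dmean <- d[t_arm[nb]] - d[base_t[nb]]
      delta_prop <- delta + stats::rnorm(length(nb), 0, step_delta)
      eta_nb <- eta[nb]
      eta_nb_prop <- mu[trial_idx[nb]] + delta_prop
      dat_nb <- if (measure == "md") {
        list(y = dat$y[nb], se = dat$se[nb])
      } else {
        list(r = dat$r[nb], n = dat$n[nb])
      }
      dll <- arm_loglik(eta_nb_prop, dat_nb, measure) -
        arm_loglik(eta_nb, dat_nb, measure) +
        stats::dnorm(delta_prop, dmean, tau, log = TRUE) -
        stats::dnorm(delta, dmean, tau, log = TRUE)
      acc <- log(stats::runif(length(nb))) < dll
      delta[acc] <- delta_prop[acc]
      acc_delta <- acc_delta + mean(acc)

      ## basic parameters: exact Gibbs from the normal full conditional
      for (k in 2:k_trt) {
        as_t <- which(t_arm[nb] == k)  # arms where treatment k is the arm
        as_b <- which(base_t[nb] == k) # arms where k is the trial baseline
        prec <- (length(as_t) + length(as_b)) / tau^2 + 1 / config$prior_d_sd^2
        num <- (sum(delta[as_t] + d[base_t[nb][as_t]]) +
                sum(d[t_arm[nb][as_b]] - delta[as_b])) / tau^2
        d[k] <- stats::rnorm(1L, num / prec, sqrt(1 / prec))
      }

      ## heterogeneity SD: Metropolis under the uniform prior
      dmean <- d[t_arm[nb]] - d[base_t[nb]]
      tau_prop <- tau + stats::rnorm(1L, 0, step_tau)
      if (tau_prop > 0 && tau_prop < tau_upper) {
        dll <- sum(stats::dnorm(delta, dmean, tau_prop, log = TRUE)) -
          sum(stats::dnorm(delta, dmean, tau, log = TRUE))
        if (log(stats::runif(1L)) < dll) {
          tau <- tau_prop
          acc_tau <- acc_tau + 1
        }
      }

      ## step-size adaptation, burn-in only
      if (it <= config$n_burnin && it %% adapt_every == 0L) {
        rate_mu <- acc_mu / adapt_every
        rate_delta <- acc_delta / adapt_every
        rate_tau <- acc_tau / adapt_every
        step_mu <- step_mu * exp(rate_mu - 0.44)
        step_delta <- step_delta * exp(rate_delta - 0.44)
        step_tau <- step_tau * exp(rate_tau - 0.44)
        acc_mu <- acc_delta <- acc_tau <- 0
      }

      if (it > config$n_burnin &&
          (it - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- c(d[-1L], tau)
      }
    }
    colnames(out) <- c(d_cols, "tau")
    draws[[chain]] <- out
  }

  psrf_tab <- data.frame(
    parameter = c(d_cols, "tau"),
    psrf = vapply(seq_len(k_trt), function(j)
      psrf(lapply(draws, function(m) m[, j]))$psrf, 0),
    stringsAsFactors = FALSE)
  # estimates marginally below 1 are sampling noise, not non-convergence;
  # only the upper limit can fail the check
  converged <- all(!is.na(psrf_tab$psrf) &
                   psrf_tab$psrf <= config$psrf_limits[2])

  structure(list(draws = draws, psrf = psrf_tab, converged = converged,
                 network = network, config = config,
                 d_names = trt),
            class = "nma_fit")
}

# all post-burn-in draws of basic parameters, pooled over chains,
# with the reference's structural zero column prepended
pooled_d_draws <- function(fit) {
  k <- length(fit$d_names)
  m <- do.call(rbind, lapply(fit$draws, function(x) x[, -ncol(x), drop = FALSE]))
  out <- cbind(0, m)
  colnames(out) <- fit$d_names
  out
}

#' Posterior relative treatment effects
#'
#' Summarizes the derived contrast `d[a] - d[b]` (every posterior draw
#' obeys the consistency identity by construction). On the RR measure
#' the summaries are exponentiated to the relative-risk scale.
#'
#' @param fit an [nma()] result.
#' @param pair optional character vector `c(a, b)`; default summarizes
#'   every treatment against the network reference.
#' @param point `"median"` (default) or `"mean"`.
#' @param level credible level, default 0.95 (central interval from the
#'   empirical posterior quantiles).
#' @return data frame `treatment, comparator, estimate, lower, upper`.
#' @export
relative_effects <- function(fit, pair = NULL,
                             point = c("median", "mean"), level = 0.95) {
  point <- match.arg(point)
  dd <- pooled_d_draws(fit)
  pairs <- if (is.null(pair)) {
    cbind(fit$d_names[-1L], fit$network$reference)
  } else {
    if (!all(pair %in% fit$d_names)) {
      fail("unknown treatment label: %s",
           paste(setdiff(pair, fit$d_names), collapse = ", "))
    }
    matrix(pair, ncol = 2L)
  }
  a <- (1 - level) / 2
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- dd[, pairs[i, 1L]] - dd[, pairs[i, 2L]]
    est <- if (point == "median") stats::median(x) else mean(x)
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE)
    if (fit$network$measure == "rr") {
      est <- exp(est); q <- exp(q)
    }
    data.frame(treatment = pairs[i, 1L], comparator = pairs[i, 2L],
               estimate = est, lower = q[1L], upper = q[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SUCRA treatment ranking
#'
#' Ranks the treatments in every posterior draw (ties share the average
#' rank) and summarizes: the rank-probability matrix `P(treatment has
#' rank r)` and the surface under the cumulative ranking curve,
#' `SUCRA = (T - E[rank]) / (T - 1)`, which equals the mean of the
#' cumulative rank probabilities over ranks `1..T-1`.
#'
#' @param fit an [nma()] result, or a draws matrix (one column per
#'   treatment including the reference, one row per draw) on the model
#'   scale.
#' @param direction `"higher"` when larger effects are better (rank 1 =
#'   largest), `"lower"` otherwise.
#' @return object of class `rank_summary`: `rank_probs` (treatments x
#'   ranks, rows sum to 1), `sucra` (per treatment, in \[0, 1\]),
#'   `mean_rank`, `direction`.
#' @export
sucra <- function(fit, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  dd <- if (inherits(fit, "nma_fit")) pooled_d_draws(fit) else as.matrix(fit)
  k <- ncol(dd)
  if (k < 2L) fail("ranking needs at least 2 treatments")
  sgn <- if (direction == "higher") -1 else 1
  ranks <- t(apply(sgn * dd, 1L, rank, ties.method = "average"))
  mean_rank <- colMeans(ranks)
  # integer rank probabilities; a tied (half-integer) rank splits its
  # mass between the neighbouring integer ranks
  probs <- matrix(0, k, k, dimnames = list(colnames(dd), paste0("rank", 1:k)))
  for (j in seq_len(k)) {
    lo <- floor(ranks[, j]); frac <- ranks[, j] - lo
    tab_lo <- tabulate(lo, nbins = k)
    probs[j, ] <- tab_lo / nrow(ranks)
    tied <- frac > 0
    if (any(tied)) {
      probs[j, ] <- (tabulate(lo[!tied], nbins = k) +
                     0.5 * tabulate(lo[tied], nbins = k) +
                     0.5 * tabulate(lo[tied] + 1L, nbins = k)) / nrow(ranks)
    }
  }
  structure(list(rank_probs = probs,
                 sucra = (k - mean_rank) / (k - 1),
                 mean_rank = mean_rank,
                 direction = direction),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("SUCRA ranking (%s is better):\n", x$direction))
  ord <- order(-x$sucra)
  for (i in ord) {
    cat(sprintf("  %-12s SUCRA %5.1f%%  mean rank %.2f\n",
                names(x$sucra)[i], 100 * x$sucra[i], x$mean_rank[i]))
  }
  invisible(x)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("Bayesian NMA (%s): %d treatments, %d trials; %d chains x %d iterations (+%d burn-in)\n",
              if (x$network$measure == "md") "mean difference" else "relative risk",
              length(x$d_names), length(x$network$trials),
              x$config$n_chains, x$config$n_iter, x$config$n_burnin))
  cat(sprintf("Convergence (PSRF in [%.2f, %.2f]): %s; max PSRF = %.3f\n",
              x$config$psrf_limits[1], x$config$psrf_limits[2],
              if (x$converged) "yes" else "NOT CONVERGED",
              max(x$psrf$psrf, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.nma_fit <- function(object, ...) {
  dd <- pooled_d_draws(object)
  colMeans(dd)[-1L]
}

#' @export
summary.nma_fit <- function(object, ...) {
  eff <- relative_effects(object)
  tau_draws <- unlist(lapply(object$draws, function(m) m[, "tau"]))
  list(effects = eff,
       tau = c(median = stats::median(tau_draws),
               lower = stats::quantile(tau_draws, 0.025, names = FALSE),
               upper = stats::quantile(tau_draws, 0.975, names = FALSE)),
       psrf = object$psrf,
       converged = object$converged)
}

#' Forest-style plot of relative effects against the reference
#'
#' @param x an [nma_fit].
#' @param ... passed to [graphics::plot.default].
#' @export
plot.nma_fit <- function(x, ...) {
  eff <- relative_effects(x)
  k <- nrow(eff)
  null_val <- if (x$network$measure == "rr") 1 else 0
  graphics::plot(eff$estimate, seq_len(k), xlim = range(eff$lower, eff$upper, null_val),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                 xlab = if (x$network$measure == "rr") "Relative risk" else "Mean difference",
                 ylab = "", ...)
  graphics::segments(eff$lower, seq_len(k), eff$upper, seq_len(k))
  graphics::abline(v = null_val, lty = 2)
  graphics::axis(2, at = seq_len(k),
                 labels = paste(eff$treatment, "vs", eff$comparator), las = 1)
  invisible(x)
}
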