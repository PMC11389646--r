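# Independently coded brute-force oracles, kept deliberately naive so
# they share no code path with the implementation they check.

oracle_bands <- function(scores) {
  crit <- 0L; imp <- 0L; unimp <- 0L
  for (s in scores) {
    if (s >= 7) crit <- crit + 1L
    else if (s >= 4) imp <- imp + 1L
    else unimp <- unimp + 1L
  }
  c(crit, imp, unimp)
}

oracle_cv <- function(scores) {
  n <- length(scores)
  m <- sum(scores) / n
  ss <- 0
  for (s in scores) ss <- ss + (s - m)^2
  sqrt(ss / (n - 1)) / m
}

oracle_domain_score <- function(block) {
  # block: appraisers x items
  obtained <- 0
  for (i in seq_len(nrow(block))) {
    for (j in seq_len(ncol(block))) obtained <- obtained + block[i, j]
  }
  n_cells <- nrow(block) * ncol(block)
  100 * (obtained - n_cells * 1) / (n_cells * 7 - n_cells * 1)
}

oracle_tally <- function(records) {
  # nested-loop count of distinct trials per outcome
  outs <- unique(records$outcome_name)
  counts <- integer(length(outs))
  for (k in seq_along(outs)) {
    seen <- character()
    for (i in seq_len(nrow(records))) {
      if (records$outcome_name[i] == outs[k] &&
          !(records$trial_id[i] %in% seen)) {
        seen <- c(seen, records$trial_id[i])
      }
    }
    counts[k] <- length(seen)
  }
  stats::setNames(counts, outs)
}

oracle_psrf <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- sapply(chains, mean)
  w <- mean(sapply(chains, var))
  b <- n * var(means)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# inverse-variance fixed-effect pooled mean difference over two-arm trials
oracle_fixed_effect_md <- function(arms) {
  ids <- unique(arms$trial_id)
  yi <- vi <- numeric(length(ids))
  for (k in seq_along(ids)) {
    tr <- arms[arms$trial_id == ids[k], ]
    tr <- tr[order(tr$treatment), ]
    yi[k] <- tr$mean[2] - tr$mean[1]
    vi[k] <- tr$sd[1]^2 / tr$n[1] + tr$sd[2]^2 / tr$n[2]
  }
  sum(yi / vi) / sum(1 / vi)
}

# expand the bundled per-outcome reporting counts into per-trial records:
# outcome with count k is reported by trials T1..Tk (counts, not identity,
# are what the tally observes)
aecopd_rct_counts_as_records <- function() {
  counts <- aecopd_rct_counts()
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(trial_id = paste0("T", seq_len(counts$report_count[i])),
               outcome_name = counts$outcome_name[i],
               domain = counts$domain[i], stringsAsFactors = FALSE)
  }))
}
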