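# cosel — core outcome selection for clinical trials

`cosel` is an R package for research teams building a **core outcome
set (COS)**: the minimum set of outcomes that all trials of a condition
should measure and report. It implements the quantitative stages of the
selection workflow used in evidence-based outcome selection — the
bundled running example is outcome selection for herbal-injection
trials in acute exacerbation of chronic obstructive pulmonary disease
(AECOPD):

1. **Delphi consensus scoring** (`delphi_round()`): experts rate each
   candidate outcome 1–9 (bands 1–3 unimportant / 4–6 important / 7–9
   critical). Per outcome the package computes band frequencies, the
   agreement coefficients (share of votes in 7–9, and in 4–9), mean, SD
   and coefficient of variation CV = SD/mean, then applies the selection
   rule: flag when selection agreement < 80% *and* CV ≥ 0.3, with an
   evidence-based override set. Panel reliability is summarized by the
   judgement coefficient Ca, the familiarity coefficient Cs, and the
   authority coefficient **Cr = (Ca + Cs)/2** (Cr > 0.7 acceptable).
2. **AGREE II guideline appraisal** (`appraise_document()`): 23 items
   scored 1–7 by multiple appraisers, standardized per domain as
   100·(obtained − min)/(max − min), with two-way ANOVA ICC for rater
   consistency and a configurable A/B/C recommendation grading.
3. **Outcome pooling** (`outcome_pool()`): tally which outcomes each
   randomized trial reports, keep those reported in more than 6% of
   trials, and merge candidates from COS studies, regulatory guidance
   and guidelines with full provenance.
4. **Bayesian network meta-analysis** (`nma()`): arm-based
   random-effects consistency model (normal likelihood for mean
   differences; binomial with log link for relative risks), fitted by an
   adaptive Metropolis-within-Gibbs sampler (default 3 chains × 10,000
   iterations after 1,000 burn-in), with Gelman–Rubin PSRF convergence
   checks (acceptable band 1.00–1.05), posterior relative effects with
   95% credible intervals, **SUCRA** ranking
   ((T − E[rank])/(T − 1)), and a first-order Bucher
   direct-vs-indirect consistency z-test (`bucher_node_split()`).
5. **Synthetic data** (`gen_panel()`, `gen_appraisals()`,
   `gen_extraction()`, `gen_network()`): seeded generators with the
   statistical structure each stage assumes, so the whole pipeline runs
   with no external data.

Results are classed S3 objects with `print()`, `summary()`, `coef()`
and `plot()` methods. CSV/JSON readers and writers for every schema are
included, plus a thin command-line interface at
`system.file("cli", "cosel.R", package = "cosel")`.

## Worked example

```r
library(cosel)

# a 15-expert panel rating four candidate outcomes around latent importances
panel <- gen_panel(
  mu = c("Treatment failure rate" = 8.4, "CAT score" = 6.8,
         "WBCC" = 5.1, "Drug-resistant bacteria" = 4.6),
  sigma = c(0.8, 1.3, 1.9, 2.1), seed = 42)
rd <- delphi_round(panel$ratings, panel$profiles)
rd
#> Delphi consensus round: 15 experts, 4 outcomes
#> Response rate: 100%
#> Authority: Ca = 0.93, Cs = 0.81, Cr = 0.870 (acceptable, Cr > 0.7)
#> Decisions: 3 selected, 0 retained by override, 1 excluded

summary(rd)[, c("outcome_id", "agreement_selection", "cv", "decision")]
#>                outcome_id agreement_selection   cv decision
#> 1  Treatment failure rate              100.00 0.08 selected
#> 2               CAT score               93.33 0.29 selected
#> 3 Drug-resistant bacteria               80.00 0.36 selected
#> 4                    WBCC               73.33 0.40 excluded
```

The treatment-failure outcome draws unanimous selection agreement with a
tightly coordinated panel (CV 0.08); WBCC falls below the 80% agreement
bar with CV ≥ 0.3 and is excluded (no override was supplied).
`Drug-resistant bacteria` sits exactly at 80% agreement — the comparison
is strict, so it is retained. Cr = 0.870 > 0.7 certifies panel
reliability.

```r
# evidence synthesis: herbal injection + conventional care vs conventional care
net <- gen_network(d = c(CI = 0, TanRQ_CI = 8.5), tau = 1,
                   trials_per_comparison = 6, n_per_arm = 80,
                   measure = "md", baseline_mean = 50, arm_sd = 12, seed = 42)
fit <- nma(net, mcmc_config(seed = 42))
fit
#> Bayesian NMA (mean difference): 2 treatments, 6 trials; 3 chains x 10000 iterations (+1000 burn-in)
#> Convergence (PSRF in [1.00, 1.05]): yes; max PSRF = 1.002

relative_effects(fit)
#>   treatment comparator estimate    lower    upper
#> 1  TanRQ_CI         CI  7.07926 5.150733 9.228662

sucra(fit, "higher")
#> SUCRA ranking (higher is better):
#>   TanRQ_CI     SUCRA 100.0%  mean rank 1.00
#>   CI           SUCRA   0.0%  mean rank 2.00
```

The posterior mean difference of 7.1 (95% CrI 5.2 to 9.2) covers the
simulated truth of 8.5 within the between-trial heterogeneity (τ = 1)
and sampling noise of six 80-patient-per-arm trials; the combined
intervention ranks first in every posterior draw, so its SUCRA is 100%.

Bundled example data from a published AECOPD outcome-selection exercise
(`aecopd_consensus_bands()`, `aecopd_agree_items()`,
`aecopd_authority_profiles()`, `aecopd_rct_counts()`) let you run every
stage on real published summaries — see the methods vignette
(`vignettes/outcome-selection-methods.Rmd`).

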