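---
title: "Methods: consensus scoring, guideline appraisal and network meta-analysis in cosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scoring, guideline appraisal and network meta-analysis in cosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosel)
```

`cosel` implements the quantitative stages of a core-outcome-set (COS)
selection workflow of the kind used to choose evaluation outcomes for
clinical trials — the running example throughout the package is outcome
selection for herbal-injection trials in acute exacerbation of chronic
obstructive pulmonary disease (AECOPD). This vignette documents the
models and scoring rules, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generators do and do not
emulate, and the known limitations.

## Delphi consensus scoring

A Delphi round is an experts × outcomes matrix of integer importance
scores on a 1–9 scale, read in three bands: 1–3 unimportant, 4–6
important but not critical, 7–9 important and critical. For each outcome
the package reports:

* **band frequencies** — counts of the panel in each band;
* **agreement coefficients** — the *importance* agreement is the share
  of votes in 7–9; the *selection* agreement is the share in 4–9. By
  construction selection agreement ≥ importance agreement;
* **descriptives** — mean, SD and the coefficient of variation
  CV = SD/mean. CV ≤ 0.3 is the conventional coordination threshold. The
  SD uses the sample denominator (n − 1), the convention in Delphi
  reporting and the default in the common statistical packages; a
  population-denominator option (`sd_denominator = "n"`) is exposed for
  completeness.

**Panel authority.** The judgement coefficient Ca weights each expert's
self-rated impact of four judgement bases (theoretical analysis
0.3/0.2/0.1 for high/medium/low, practical experience 0.5/0.4/0.3,
literature 0.1 at every level, intuition 0.1 at every level) and
averages over the panel; under these weights Ca ∈ [0.6, 1]. The
familiarity coefficient Cs averages a five-level familiarity weighting
(1.0, 0.8, 0.6, 0.4, 0.2), so Cs ∈ [0.2, 1]. The authority coefficient
is Cr = (Ca + Cs)/2, with Cr > 0.7 read as acceptable reliability. The
conventional fixed panel size of 15 in the textbook formulas is
generalized to the actual panel size n.

The bundled example panel (`aecopd_authority_profiles()`) illustrates a
documented inconsistency in its source: the basis-frequency table yields
Ca = 0.913 by direct application of the formula, while the accompanying
text reports 0.92 (and uses 0.92 when forming Cr = 0.875). The package
computes Ca from profiles and leaves reconciliation to the analyst; both
values are preserved in the tests.

**Selection rules.** The default rule flags an outcome when its
*selection* agreement is **strictly below 80%** *and* its CV is **at or
above 0.3**. Flagged outcomes listed in an override set (for example,
outcomes retained on external evidence such as a network meta-analysis
of treatment sensitivity) become `retained_by_override`; other flagged
outcomes are `excluded`; everything else is `selected`. Three design
points deserve note, all config-exposed in `selection_config()`:

* *Polarity.* Descriptions of this rule in the applied literature are
  sometimes garbled ("CV more than 0.3 means selected"); the implemented
  polarity — low agreement *and* high CV flags — is the one that
  reproduces published flag/exclude decisions, and can be inverted via
  `flag_low_agreement_high_cv = FALSE`.
* *Strictness.* The agreement comparison is strict and the CV comparison
  non-strict: an outcome at agreement exactly 80% with CV 0.41 is
  retained. This is the only combination consistent with the bundled
  consensus table, where three such rows are retained.
* *Driver.* Selection agreement (bands 4–9) drives the rule by default;
  `agreement_driver = "importance"` switches to the 7–9 band.

The rule partitions outcomes: every outcome receives exactly one
decision, and re-application is idempotent. Missing ratings are rejected
by default; there is deliberately no silent imputation.

```{r}
st <- delphi_stats_from_bands(aecopd_consensus_bands(), n_experts = 15)
dec <- apply_selection_rules(st, selection_config(override_set = aecopd_overrides()))
attr(dec, "counts")
```

## AGREE II appraisal

The 23 appraisal items (scored 1–7 by each appraiser) partition into six
domains (3, 3, 8, 3, 4, 2 items). The standardized domain score is

> 100 × (obtained − minimum possible) / (maximum possible − minimum possible),

with obtained the total over appraisers and items. Computing from the
raw appraiser × item block and from item means is algebraically
identical; an *aggregated* ingestion mode accepts published item-mean
tables directly (rater ICC is then unavailable and reported as such).
Published item means occasionally dip slightly below the scale minimum
(transcription artifacts); scores down to 0 are tolerated on ingestion.

**Rater consistency** uses the two-way ANOVA ICC. The default is
ICC(2,1) — two-way random effects, absolute agreement, single measures —
with the consistency variant ICC(3,1) selectable; the p-value is the
ANOVA F-test of the subject effect. A constant matrix returns an
explicit `degenerate` status rather than NaN.

**Recommendation grading** is not standardized in the AGREE II manual;
the package default — level A when every domain ≥ 60%, level C when
fewer than 3 domains reach 30%, level B otherwise — was chosen because
it reproduces all nine published grades of the bundled nine-document
appraisal set, and all three thresholds are configurable
(`recommendation_thresholds()`).

Display rounding is half-up to integer percent (this reproduces the
bundled published scores); all internal computation is unrounded, and
`round_half_up()` is applied only at serialization boundaries.

## Outcome pooling across trials

`tally_outcomes()` counts, per outcome, the number of distinct trials
reporting it (set semantics within a trial). `frequency_filter()` keeps
outcomes reported in **strictly more than** a threshold share of trials
— default 6%, the screen used when harvesting candidate outcomes from
large trial pools; strictness is configurable. Name matching is exact
after trimming and case-folding: synonym resolution is a substantive
editorial decision, so only a user-supplied synonym map is applied,
never fuzzy matching. `merge_candidates()` unions candidate sets from
multiple recommendation sources (COS studies, regulatory guidance,
guidelines, trial frequency) and annotates each candidate with its full
provenance; conflicting domain assignments are an error, not a silent
overwrite.

## Bayesian network meta-analysis

The evidence-synthesis stage fits a random-effects consistency model to
an arm-level treatment network.

**Model.** Each trial i has a baseline parameter μ_i (its first arm);
each non-baseline arm has a deviation δ_ik, exchangeable around the
consistency contrast d_{t(ik)} − d_{t(i,base)} with between-trial SD τ.
Continuous arms contribute a normal likelihood for the observed arm mean
(SE = sd/√n), so d is a mean difference; binary arms contribute a
binomial likelihood with log link, so d is a log relative risk, and
proposals implying a risk ≥ 1 are rejected. Multi-arm trials are handled
naturally by the arm-based parameterization (one baseline per trial, one
deviation per extra arm); the correlation bookkeeping of
contrast-based formulations is avoided at the cost of treating the
deviations of a multi-arm trial as conditionally independent given the
basic parameters, a standard simplification at this model scale.
The consistency identity d_AB = d_A − d_B holds in every posterior draw
by construction.

**Priors.** Basic parameters d_k ~ Normal(0, 100²) on the model scale;
τ ~ Uniform(0, U) with U set from the data scale (continuous: 5 × pooled
arm SD; log RR: 2) unless overridden. These are deliberately weak; the
desk-scale networks the package targets carry little information about
τ, and the uniform bound is reported in the configuration echo.

**Sampler.** Adaptive random-walk Metropolis-within-Gibbs: baselines and
deviations update by elementwise Metropolis steps (valid because they
are conditionally independent given the rest), the basic parameters by
exact Gibbs draws from their normal full conditionals, and τ by
Metropolis under its uniform prior. Step sizes adapt toward a 0.44
acceptance rate during burn-in only, so retained draws come from a fixed
kernel. Defaults mirror common practice for this model class: 3 chains,
10,000 iterations each after 1,000 burn-in ("annealing") iterations.
Chain c is seeded `seed + c − 1`, making runs bit-reproducible.

**Convergence** is assessed per parameter with the Gelman–Rubin PSRF
(between/within-chain variance form), with the acceptable band
[1.00, 1.05]. A fit outside the band is returned *flagged*, never
silently accepted; PSRF estimates marginally below 1 are sampling noise
and do not fail the check. A parameter pinned against a boundary (for
example τ under a very tight uniform bound) can legitimately mix slowly;
the flag is honest in that case.

**Summaries.** `relative_effects()` reports posterior medians (or means)
and central 95% credible intervals of any contrast, exponentiated to the
RR scale for binary networks. `sucra()` ranks treatments within each
draw (exact ties share the averaged rank — measure-zero for continuous
draws, relevant for degenerate fixtures) and reports the
rank-probability matrix and SUCRA = (T − E[rank])/(T − 1), with a
per-outcome direction flag (`higher` or `lower` is better). The rank
matrix is doubly stochastic and mean SUCRA is exactly 0.5, both checked
in the test suite.

**Consistency checking** uses a first-order Bucher loop comparison
(`bucher_node_split()`): the direct estimate pools trials containing
both treatments (DerSimonian–Laird random effects via `metafor`); the
indirect estimate chains two legs through a common comparator, excluding
trials that contribute direct evidence so the two are independent;
variances add along the chain and the difference is z-tested. When
several comparators qualify, the one with the most trials on its weaker
leg is used. This is a declared simplification of full node-splitting —
only first-order loops are examined — and is labelled as such in output.
The zero-cell continuity correction (0.5, zero cells only, `metafor`'s
default) applies only to this closed-form path, never to the Bayesian
binomial likelihood, which handles zero-event arms exactly.

## Synthetic-data generators

Every stage has a seeded generator so the full pipeline runs with no
external data:

* `gen_panel()` — ratings as `round(clip(Normal(μ_o, σ_o), 1, 9))`
  around latent per-outcome importances, plus categorical
  judgement-basis/familiarity profiles. Defaults: 15 experts and a
  mostly senior, mostly familiar panel composition (high practical
  experience, low intuition reliance), the typical profile of such
  panels.
* `gen_appraisals()` — item scores
  `round(clip(1 + 6 q_domain + Normal(0, σ), 1, 7))` for 3 appraisers
  around latent domain qualities q ∈ [0, 1].
* `gen_extraction()` — each of (by default) 500 trials reports each
  outcome independently with its own probability, the substrate behind
  reporting-frequency tables from ~500-trial systematic reviews.
* `gen_network()` — trial-level contrasts d + Normal(0, τ), continuous
  arm summaries from simulated raw observations, binary counts from
  log-link risks (clipped at 0.99 with a warning, or rejected, per
  `risk_overflow`).

What these emulate is the *statistical structure* each stage assumes:
independent raters around a latent importance, independent reporting,
exchangeable trial effects. What they deliberately do not emulate:
correlated expert opinion (schools of thought), outcome co-reporting
within trials, rating-scale end effects beyond truncation, systematic
appraiser leniency, or real trial-network geometry and small-study
effects. Passing tests on generated data therefore demonstrate
correctness of the computations and calibration *under the model's own
assumptions*, not robustness to real-data violations of them.

## Numerical choices and problem sizes

* Rounding is half-up (`round_half_up()`), applied only at display and
  serialization; base R's round-half-even would disagree with the
  published two-decimal percentages the package reproduces.
* Validation failures name the offending expert/outcome/cell; errors are
  raised early, before any computation.
* The test suite exercises the sampler at reduced but well-mixing sizes
  chosen as the smallest that make the checks sharp: parameter-recovery
  coverage uses 200 replicates of a 3-treatment, 12-trial network with
  2 chains × 1,200 iterations; the loop-consistency type-I-error check
  uses 400 simulated consistent loops; the inverse-variance agreement
  check uses 3 chains × 3,000 iterations. The full default configuration
  (3 × 10,000) runs in a few seconds on a single core for networks of
  this scale.

## Limitations

* The Delphi stage scores one round; multi-round carry-over of outcomes
  is a pipeline decision left to the analyst.
* The recommendation-grading rule is a reverse-engineered default, not a
  published standard; treat cross-study comparisons of levels with care.
* The Bucher check examines first-order loops only and uses normal
  approximations; it is a screen, not a full inconsistency model. When
  it signals inconsistency the package still reports the consistency
  model, flagged.
* ICC is unavailable when only item means are published (aggregated
  mode); the package reports its absence rather than approximating it.
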