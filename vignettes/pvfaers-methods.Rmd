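---
title: "Disproportionality screening and time-to-onset methods in pvfaers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening and time-to-onset methods in pvfaers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvfaers)
```

## The problem

Spontaneous adverse-event databases such as the FDA Adverse Event
Reporting System (FAERS) collect safety reports without any record of
how many patients took each drug, so incidence cannot be estimated.
Signal detection instead asks a relative question: is event $Y$
reported *disproportionately* often with drug $X$, compared with how
often $Y$ is reported with everything else?  Each (drug, event) pair is
summarized by the 2×2 table

|                | event $Y$ | other events |
|----------------|-----------|--------------|
| drug $X$       | $a$       | $b$          |
| all other drugs| $c$       | $d$          |

with $N = a+b+c+d$ and expected count $E = (a+b)(a+c)/N$ under
independence.  `pvfaers` implements the complete screening pipeline for
FAERS-style quarterly ASCII extracts, validated end-to-end on a seeded
synthetic emulator with known ground truth.

## Ingestion, deduplication, cohort definition

The quarterly extract is seven `$`-delimited tables keyed by
`primaryid` (a report version) and `caseid` (a patient case).  The
reader (`read_faers_quarter()`) enforces the declared header of each
table and quarantines — never silently drops — data lines whose field
count disagrees, recording the line number.  Linking
(`link_faers_tables()`) attaches DRUG/REAC/OUTC/THER/INDI rows to their
DEMO row and normalizes demographics: ages to years and weights to
kilograms via the FAERS unit codes, with values outside plausibility
bounds (age 0–120 years, weight 1–500 kg) or with unrecognized unit
codes set missing.

FAERS distributes successive versions of a case; analyses must count
each case once.  `dedup_faers()` keeps, per `caseid`, the version with
the latest receipt date, breaking ties by the largest `primaryid` under
lexicographic-numeric comparison (longer digit strings are larger, so
"103" beats "15").  This is the convention the FDA documents for
quarterly files; it is deterministic and idempotent.

Exposure is defined by the *primary suspect* (PS) role code: a report
belongs to a drug's cohort when at least one of its drug mentions has
role `PS` and a name that normalizes — case-insensitively, with
punctuation stripped, through an explicit synonym table — to that drug.
No fuzzy matching is attempted: reproducibility is preferred over
recall, and the synonym table is a visible, auditable input.

Events are preferred terms (PTs) in a three-level PT → HLT → SOC
hierarchy.  Real MedDRA is license-restricted, so the package ships a
*mock* vocabulary (40 PTs across four organ classes, including
dehydration, appetite and glycaemic terms) with the same tree
structure; any tab-separated vocabulary with the documented columns can
be substituted.  Analyses restricted to one system organ class keep
reports with at least one in-SOC reaction; term counting can then use
only in-SOC reactions.  A per-term exclusion list supports terms
analyzed only at the HLT level (the mechanism used for ubiquitous
terms, such as an appetite-suppression PT that is also the therapeutic
effect).

## The four statistics and the joint criterion

For each screened term, with all cells from the deduplicated data:

* **ROR** $= ad/bc$, Wald 95% CI on the log scale with
  $SE = \sqrt{1/a + 1/b + 1/c + 1/d}$.
* **PRR** $= [a/(a+b)]\,/\,[c/(c+d)]$, Wald 95% CI with
  $SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$, accompanied by the
  *uncorrected* Pearson $\chi^2 = N(ad-bc)^2 /
  [(a+b)(c+d)(a+c)(b+d)]$.  The uncorrected form is used throughout;
  it reproduces published serious/non-serious contingency statistics
  exactly, which validates the convention.
* **BCPNN information component** $IC = \log_2 \frac{P(X,Y)}{P(X)P(Y)}$
  under the conjugate model of Bate et al. (1998): independent Beta
  posteriors for the joint and marginal reporting probabilities with
  priors $\alpha_1=\beta_1=1$, $\alpha=\beta=2$, $\gamma_{11}=1$ and
  $\gamma$ calibrated so $E(IC)=0$ at independence.  The posterior mean
  and variance of IC are computed *exactly* through digamma/trigamma
  moments of the log-Beta distributions rather than the historical
  log-of-expectation approximation; a Monte-Carlo sampler of the same
  conjugate posteriors verifies them in the test suite.
  `IC025 = E(IC) - 1.96\,\mathrm{sd}(IC)` is a normal approximation of
  the lower credibility bound; because the posterior of IC is mildly
  left-skewed at small $a$, this bound sits slightly above the exact
  2.5th percentile there.  The multiplier is configurable
  (`ic025_multiplier`, default 1.96; some implementations use 2) and is
  recorded in the run metadata.
* **EBGM** from DuMouchel's gamma-Poisson shrinker: $a \sim
  \mathrm{Poisson}(\lambda E)$ with a two-component gamma mixture prior
  on $\lambda$.  The five hyperparameters are fitted by maximizing the
  summed negative-binomial marginal likelihood over all (drug, term)
  cells of the dataset, by bounded quasi-Newton (`L-BFGS-B`) on
  log-transformed parameters from the fixed start
  $(0.2, 0.1, 2, 4, 1/3)$.  The posterior for a cell is a weighted
  two-gamma mixture; $EBGM = 2^{E[\log_2 \lambda]}$ (posterior
  geometric mean, again via digamma moments) and EB05 is the exact 5th
  percentile of the mixture found by bracketed root-finding on its CDF.
  A fit that does not converge is flagged and EBGM refuses to run on
  it.

A term is a **signal** when all four conditions hold simultaneously:
ROR 95% CI lower bound > 1; $\chi^2 \ge 4$ with PRR 95% CI lower
bound > 1; EB05 > 2; IC025 > 0.  This joint criterion is deliberately
conservative: on synthetic nulls its family-wise false-positive count
is essentially zero, while a planted relative risk of 8 with ~60
exposed-case reports is recovered in every seed tested.

### Numerical and design notes

* **Zero cells.** ROR/PRR are reported "not estimable" when any cell is
  zero; the Haldane–Anscombe +0.5 correction is available but off by
  default, to avoid silent bias.  BCPNN and EBGM need no correction —
  their priors regularize zero cells.
* **Minimum count.** Terms with $a < 3$ are not screened by default
  (`min_count`, configurable and recorded in metadata); estimates below
  that are numerically defined but scientifically uninformative.
* **Reference set.** The default background for a (drug, term) table is
  *every* ingested report, not only the organ-class subset
  (`background = "all"`); restricting the reference set to in-SOC
  reports conditions the margins on having an in-SOC event and
  systematically deflates disproportionality.  Both choices are exposed
  and recorded.
* **Expected counts are crude** (unstratified by age/sex/period); no
  stratified variant is provided.
* **Degenerate prior fits.**  On small or under-dispersed cell
  ensembles the gamma-mixture likelihood is maximized on the boundary
  of the parameter space (a component collapsing toward a point mass).
  Hyperparameters are therefore constrained to a wide box
  ($10^{-6}$–$10^6$ after log transform); when the line search stalls
  at the boundary a derivative-free polish on the box-clamped objective
  finishes the fit.  With realistic, heterogeneous ensembles
  (hundreds of cells spanning weak and strong associations) the fit is
  interior.  Fits on fewer than 50 cells warn.
* **Signal monotonicity.** Adding reports to cell $a$ (at fixed
  $b, c, d$ and a fixed prior) never turns a signal off; this is
  enforced as a property test.

### Agreement of the four statistics

In the regime where the drug and the event are each rare and the
signal cell is large, all four statistics estimate the same relative
risk $ad/bc$.  That regime requires *both* small margin shares and a
large $a$: at a database size of a few hundred thousand reports the
two Bayesian statistics still sit a few percent below the ROR because
their priors (the gamma mixture for EBGM, the $\gamma$-weighted
independence point for IC) are not yet overwhelmed, and the expected
count $E$ is inflated by the drug's own excess events.  The package's
test suite verifies the common limit to within 2% on a table with
margins near 0.15% and $a \approx 650$ (total $10^8$ reports — pure
arithmetic, no data are materialized), and separately documents the
residual shrinkage at moderate sizes.

## Severity analysis

A report is **serious** when it carries any of the outcome codes DE,
LT, HO, DS, CA, RI, OT (death, life-threatening, hospitalization,
disability, congenital anomaly, required intervention, other serious);
classification is at the report level via the union of outcome rows.
Per-drug comparisons between serious and non-serious reports use:

* gender: uncorrected Pearson $\chi^2$ when all four expected cell
  counts are ≥ 5, otherwise Fisher's exact test (two-sided, by the
  hypergeometric-sum convention).  The chosen test is recorded per
  comparison.
* age and weight: Mann–Whitney U with the normal approximation —
  tie-corrected variance, no continuity correction — reported with the
  Z statistic.  Two identical samples give Z = 0 exactly.

Descriptive cohort tables report counts and percentages by gender,
weight band (<80, 80–100, >100 kg), age band (<18, 18–44, 45–65, >65
years, with 65 in the 45–65 band), reporter occupation, US/non-US
country, and outcome category, plus medians with IQRs.  Percentages
are computed with `cohort_percent()` — `100·n/total` rounded half-up
to two decimals — using the total report count for demographics and
the outcome-classified total for the serious/non-serious split.
Published cohort tables of this kind sometimes carry an outcome
denominator larger than the report count (outcome *entries* rather
than reports); the helper takes the denominator explicitly so either
convention can be reproduced.

## Time to onset

TTO is the interval in days from the start of therapy with the PS drug
(earliest day-precision start date among that drug's therapy rows) to
the event onset date; 0 means same-day onset.  Records are excluded —
with per-reason counts that must sum back to the cohort — when the
event date is missing or partial (year or year-month only), the start
date is missing or partial, or the event precedes the start (a data
error in spontaneous reports).  Partial dates are excluded rather than
imputed; imputation would manufacture onset intervals from information
that is not there.  There is no censoring model: spontaneous reports
carry no risk set, so only observed onsets are analyzed, mirroring
complete-case practice.

Summaries are medians with IQRs (linear-interpolation quantiles,
`type = 7`: for `{1,2,3,4}` the quartiles are 1.75 and 3.25).  Onset
profiles are characterized by a two-parameter Weibull fit: shape
$\beta$ and scale $\alpha$ (days) by maximum likelihood on
log-parameters, with 95% CIs from the observed-information normal
approximation on the log scale.  Zero-day onsets are shifted to 0.5
day so the density is defined.  A threshold (location) parameter can
be supplied for a three-parameter variant, but the default fixes it at
0: published onset tables report only shape and scale, and the
two-parameter fit is what those numbers parameterize.  Fits require at
least 10 non-identical values.

The shape classifies the hazard: **early failure** when the shape CI
lies entirely below 1 (risk concentrated shortly after exposure
start), **wear-out** entirely above 1, **random** otherwise.  Shape is
dimensionless, so the label does not depend on the time unit.
Between-drug onset distributions are compared with the two-sample
Mann–Whitney test (Bonferroni-adjusted when pairwise); distribution
comparison tests in this setting are rarely named in published work,
so the choice is recorded in the run metadata as an assumption.

## The synthetic FAERS emulator

`faers_scenario()` / `generate_faers()` produce a complete quarter —
all seven tables in the exact ASCII dialect — plus a ground-truth
manifest recording, per case, the drawn drug, PTs, seriousness, true
onset interval, duplicate versions and injected date errors.  The seed
fully determines the output, byte for byte.

The default scenario emulates a GLP-1 receptor-agonist
metabolism-and-nutrition cohort: 61.67% female (4% unknown), age
normal around median 61 (sd 11.1, truncated 18–95, 38% missing),
weight log-normal around median 95 kg (36% sd on the log scale ≈
0.235, 61% missing), 88.4% US reports, 79.3% consumer reporters,
34.07% serious with hospitalization and other-serious dominating the
serious codes, six incretin-mimetic target drugs (25% combined share)
against a 75% non-target background, planted appetite/dehydration
relative risks of 3–6, and early-failure Weibull onset profiles
(shapes 0.4–0.8, scales 20–110 days, with the depot-formulation drug
slowest).  Ten percent of cases are emitted in two report versions;
10% of dated events are corrupted (half placed before the therapy
start, half truncated to year-month); 30% of event dates and 15% of
start dates are missing outright.  These rates are fixed study
conditions, not tuning knobs: large-sample summaries of the default
scenario reproduce the target margins within sampling error, and the
tests assert that.

What the emulator deliberately does **not** model: secular reporting
trends, drug–drug interaction signals, correlated multi-drug exposure
(each case has exactly one PS drug), stratification-relevant
confounding (age/sex do not modify the planted risks), duplicate
reports with *conflicting* payloads, and real MedDRA granularity.
Passing the synthetic-recovery tests therefore demonstrates that the
pipeline's accounting and statistics are correct under a known
generative model — not that any particular real-world signal is true.

## Validation problem sizes

The test suite and acceptance script exercise: 5,000-case quarters
across 20 seeds for planted-signal recovery (relative risk 8, ~60
exposed cases) and null specificity (100 terms at relative risk 1);
10⁵ Monte-Carlo posterior draws per table for the BCPNN oracle and a
4×10⁵-point log-spaced grid for the EBGM integration oracle; 200
replicates of n = 500 Weibull fits at shape 0.46 / scale 35.38 days
for CI coverage, plus n = 2,000 exponential data for the shape-1
boundary; and 1,000-case runs with 10% duplicates for determinism and
deduplication exactness.  These sizes give stable pass/fail behavior
at interactive runtimes.

## Known limitations

* Crude expected counts; no MGPS-style stratification.
* Closed-form BCPNN moments with a normal-approximation IC025; no MCMC
  variant.
* The joint four-method criterion is conservative by construction;
  sensitivity at modest relative risks (≤ 3) and small counts is low,
  which matches its published use as a confirmatory screen.
* Single-axial mock vocabulary; no SMQ support.
* The severity and TTO analyses are univariate; no multivariable
  modeling of seriousness and no onset imputation.
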