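---
title: "Phenotyping physician-documented insomnia from EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping physician-documented insomnia from EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insomniaphen)
```

## The problem

Insomnia diagnoses are rarely billed. A physician will write "patient
reports poor sleep" in a progress note far more often than they will
attach ICD-9 code 780.52 to an encounter, so any cohort defined by codes
alone is both small and biased toward the most severe or most
administratively visible patients. *Physician-documented insomnia* is an
empirical case definition that works with what EMRs actually contain:
a patient is a case when a physician has billed an insomnia code,
prescribed a medication indicated only for insomnia, or documented
sleep difficulty in the narrative record. This package implements a
computable phenotyping algorithm for that definition, plus the full
protocol by which such an algorithm is derived and validated, exercised
end to end on synthetic corpora.

## The scoring model

Seven covariates summarise a patient's record, all of them raw
non-negative counts:

| covariate | meaning |
|---|---|
| `n_sleep_notes` | notes (≥ 500 characters) containing a sleep-disorder expression |
| `n_insomnia_codes` | dated insomnia ICD-9 billing events (307.41, 307.42, 327.00–327.02, 327.09, 780.52) |
| `n_anxdep_codes` | dated anxiety/depression billing events |
| `n_psych_notes` | notes containing a psychiatric-disorder expression |
| `n_insomnia_rx` | prescriptions of insomnia-only medications (zolpidem, eszopiclone, temazepam, zaleplon, flurazepam, estazolam and their brand names) |
| `n_joint_codes` | dated joint-disorder billing events (comorbidity signal) |
| `n_emr_facts` | total data entries on the patient (utilization proxy) |

The published model is a logistic regression on these counts; its nine
constants are carried verbatim by `published_model()`. The operating
threshold, p ≥ 0.828, is the probability cut that achieved 97%
specificity on the original validation sample; ties at the threshold
classify positive (a documented choice — the boundary case is not
specified anywhere, and resolving it toward sensitivity is the
conservative option for a case-finding tool; it is configurable through
the model object).

Why these covariates make sense: sleep-disorder notes are the phenotype's
primary trace (one note takes a patient to p = 0.60, two past the
threshold at 0.94); insomnia codes are specific but sparse (five or more
are needed in a notes-free record); anxiety/depression and joint
disorder are comorbidities enriched among insomniacs (psychiatric
disease and the nocturnal pain of osteoarthritis both disturb sleep);
and the EMR-fact tally absorbs the confounding between utilization and
documentation — sicker patients generate more of everything.

## Extraction rules

Text matching is deliberately primitive: case-insensitive literal
substring search after collapsing whitespace runs, with no stemming and
no negation parsing. The ten sleep-disorder expressions ("poor sleep",
"has trouble sleep", "reduced sleep", "increased sleep", "decreased
sleep", "excessive sleep", "fragmented sleep", "sleeplessness", "sleep
disruption", "sleeps poorly") were curated upstream — by an interactive
expression-discovery process whose output this package consumes as a
fixed list — precisely so that they are non-negated descriptors; a
benign "patient sleeps well" or "denies insomnia" contains the keyword
*sleep* but no expression, and contributes nothing to the covariate.
Fidelity to the published list beats cleverness here: adding a negation
parser would change the covariate definition the coefficients were
estimated for.

Counting conventions, each of which the worked examples force:

* **Notes, not mentions.** The covariate is "# notes indicating a sleep
  disorder": a note containing "poor sleep" three times counts once.
* **Occurrences, not distinct codes.** Code 780.52 billed at three
  encounters counts three — a patient needing "5 or more insomnia
  billing codes" to cross the threshold only makes sense under
  accumulation.
* **The 500-character minimum** note length is stated for cohort
  inclusion; we apply the same single `min_note_chars` knob to
  text-covariate counting. This is conservative (a 200-character note
  full of sleep complaints is ignored) and can be set to 0.
* **EMR facts** = coded events + prescriptions + notes. The original
  tally also drew on labs and visit records that this data model does
  not represent; the formula is a documented convention, and because the
  fact coefficient is tiny (2.3 × 10⁻⁴ per entry) the phenotype
  classification is insensitive to the exact convention at realistic
  record sizes.

The anxiety/depression, joint-disorder and psychiatric vocabularies were
published only in supplementary material; the defaults in
`default_vocabulary()` are placeholder sets assembled from standard
ICD-9 groupings (neurotic/affective disorders 296/300/311,
arthropathies 715/716/719.4) and a small psychiatric descriptor list,
all overridable from a YAML/JSON config. Code-set entries ending in `*`
are explicit prefix wildcards; everything else compares exactly after
trimming.

## Candidate mart and empirical labels

`in_candidate_mart()` reproduces the two-stage cohort funnel: a broad
screen (any insomnia code, any insomnia-only prescription, or any note
merely mentioning "sleep"/"insomnia") intersected with a data-substance
filter (≥ 2 notes of ≥ 500 characters). The mart deliberately admits
clear non-cases — that is its purpose, to define the population the
classifier is applied to. `empirical_case_rules()` is the stricter
any-of-three case definition, usable as an automated reference labeler
for synthetic corpora; it approximates, and must not be confused with,
manual chart review. Age exclusion removes patients younger than 18 at
death or at the study end (default 2010-12-31), retaining a patient who
turns exactly 18 that day.

## The training protocol

`fit_insomnia_model()` implements the adaptive LASSO for logistic
regression:

1. **Pilot:** unpenalized maximum likelihood. Under separation or
   non-convergence the pilot falls back to ridge-stabilized estimates
   (cross-validated `alpha = 0` fit) with a warning; aliased (constant)
   covariates get zero pilots and hence effectively infinite penalty.
2. **Weighted L1:** penalty weights `1/|pilot|^gamma` with γ = 1, the
   literature-standard default; penalty strength chosen by 5-fold
   cross-validated deviance over the `glmnet` path, folds fixed by the
   seed. Counts enter raw and unstandardized — the published
   coefficients act on raw counts, and the adaptive weights absorb the
   scale differences between, say, sleep notes (units) and EMR facts
   (hundreds).
3. Zero-coefficient covariates are dropped; standard errors reported by
   `summary()` come from an unpenalized refit on the selected support
   (the usual post-selection convention — they ignore selection
   uncertainty and are reported as descriptive).

The surrounding protocol mirrors the original study design: a stratified
2:1 train/validation split (stratification is our addition — it
stabilizes specificity targeting in small validation sets; training
share floors, so a 493-patient labeled set splits 328/165);
`select_threshold()` picks the smallest observed-probability cut point
achieving the 97% specificity target on validation negatives (with a
warning and a maximal threshold when fewer than 1/(1 − target)
negatives are available, where the target is unresolvable);
`bootstrap_auroc_ci()` reports percentile 2.5/97.5 bounds over 1,000
patient-resampled replicates (percentile rather than BCa — the interval
type was unstated, and percentile is the simplest defensible choice;
single-class resamples are redrawn); and `overfitting_check()` averages
the held-out AUROC over 100 seeded sub-splits of the training set,
whose closeness to the external validation AUROC is the no-overfitting
evidence. Whether the original 97% was targeted on training or
validation data is unstated; we target it on the designated validation
split.

AUROC is the Mann–Whitney statistic with half credit for ties,
implemented twice (rank form and trapezoidal ROC integration) and
cross-checked to 10⁻¹⁰ in the tests, plus against an independent
reference implementation.

## The synthetic corpus generator

`simulate_corpus()` emulates the *statistical* structure the algorithm
assumes, nothing more: latent Bernoulli status (prevalence 0.46, the
case share of the original 500-patient labeled sample), then
status-conditional Poisson counts per event type. Poisson is the
simplest non-negative count law and makes oracles easy (the planted
mean is testable to √(λ/n)). Default rates encode the phenomenon that
motivates the method — cases average 2.0 sleep-disorder notes but only
0.3 insomnia billing codes, so most synthetic cases are invisible to
codes alone, while controls share a common background of unrelated
notes, codes and prescriptions that feed only the fact tally. Every
planted sleep note embeds exactly one vocabulary expression in
vocabulary-free filler padded past 500 characters, which makes
planted-versus-extracted equality exact rather than approximate;
distractor notes embed benign sleep phrases that must reach the mart
keyword screen and must not reach the covariate. An optional shared
log-normal severity factor can induce positive correlation among a
patient's counts; its calibration is arbitrary (the real joint
distribution is unknowable from published information) and it is off by
default.

What passing tests on this generator do **not** show: robustness to real
clinical prose (abbreviations, templated text, copy-forward), to
expression variants outside the fixed list, or to coding practices that
differ from the Poisson caricature. The generator validates the
machinery, not the clinical performance figures, which are not
reproducible without the original protected data.

`simulate_from_model()` draws feature rows from fixed count laws and
labels from the published model's own probabilities — the
parameter-recovery setting. Its default covariate law is chosen for
identifiability: recurrent events (prescription refills, repeat
comorbidity billing) get multi-year means (4 insomnia prescriptions, 12
joint-disorder codes), and the EMR-fact surplus is overdispersed
negative-binomial (mean 500, size 0.8), giving even the smallest
coefficients several standard errors of information at n = 5,000. Under
a weaker design the adaptive LASSO *correctly* zeroes the joint-code
coefficient — recovery failure there reflects an unidentifiable
experiment, not a broken estimator — so the default law is the one under
which recovery is a property of the method.

## Numerical choices and edge cases

* Probabilities use the overflow-safe logistic
  (`exp(L)/(1+exp(L))` computed as `1/(1+exp(−L))` for L ≥ 0), summation
  in the fixed covariate order for bit-stable linear predictors.
* Threshold candidates are the observed validation probabilities plus a
  point just above their maximum, so "no achievable cut" degrades to
  classify-nobody rather than an arbitrary interior value.
* Problem sizes in the test suite (1,000-patient extraction corpora,
  n = 5,000 recovery, 15–100 permutation refits, a few hundred bootstrap
  replicates) are chosen so the full suite completes in well under a
  minute of CPU per property while keeping every stochastic assertion at
  3 standard errors or better.
* Degenerate inputs fail loudly: single-class labels, sub-10-row fits,
  duplicate patient or note ids, malformed ICD-9 strings, dates before
  birth, and score/label id mismatches are all hard errors naming the
  offender; undefined ratios (PPV with no positives) are `NA`, never 0.

## Known limitations

The expression lists are frozen; the interactive discovery loop that
produced them is out of scope, as are negation parsing, section
segmentation and any general clinical NLP. The supplementary-only
vocabularies are placeholders and should be replaced by site-specific
config before any use on real extracts. The empirical case rules are an
automated approximation of chart review. And the original cohort's
performance figures (AUROC 0.83 combined, PPV 0.81) concern data this
package cannot access; the package reproduces the algorithm and the
protocol, and demonstrates their properties on synthetic data only.
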