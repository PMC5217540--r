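---
title: "Methods: life-course smoking-status classification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life-course smoking-status classification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readsmoke)
```

## The classification model

A patient's coded record is treated as evidence about a latent life-course
smoking trajectory. Every smoking-related code resolves to one of three
base categories — never smoker, ex-smoker, current smoker — via a codelist
registry. Cessation-therapy prescriptions (NRT, varenicline, bupropion)
and cessation administration/advice codes are treated as evidence of
current smoking unless followed by ex-smoker evidence: someone being
treated for cessation is, at that point, a smoker. The hierarchy parent
code carries no category on its own; it is informative only when recorded
with a positive cigarettes-per-day value (then: smoker). A recorded zero
is discarded as uninterpretable, because in practice a zero was entered
both for non-smokers and by habit for smokers, so it identifies neither.

The record is then compressed to six dates — the first and last
informative code date per category — and status at a census date is read
off the rule cascade documented in `?classify_full`. The assumptions worth
stating explicitly:

* **Evidence spans, not point codes.** The interval from first to last
  code of a category is treated as a period during which that designation
  was in play. Overlap of the smoker span with an ex/never span at the
  census yields `RELAPSED_SMOKER`, read as quit attempts with relapse.
* **Smoking leaves a permanent trace.** Once ex/smoker evidence exists on
  or before the census, a never-smoker designation is demoted to
  ex-smoker. This is the temporal-conflict override that distinguishes the
  full algorithm from the no-temporal-checking variant.
* **Post-census information is used, deliberately.** Codes after the
  census distinguish `UNKNOWN_SMOKING_STATUS` (mixed later evidence) from
  `LIKELY_SMOKER` (only smoker-category evidence, reflecting initiation
  years before first recording) and extend spans across the census. The
  classification is therefore retrospective, suited to research
  extracts, not to live clinical decision-making at the census date.

Seven statuses collapse to four for comparisons: relapsed and likely
smokers count as smokers; no-information and unknown count as missing.

### Numerical and ordering choices

* *"Prior to" means on-or-before.* A code recorded on the census day is
  taken to describe status on that day. The predicate is isolated in one
  internal helper (`on_or_before`) so the strict reading is a one-line
  change.
* *Rule order.* Relapse is tested before smoker before ex before never.
  This is the only order consistent with all of the narrated census
  scenarios (overlap → relapsed; smoker-span-only → smoker; contained
  never with history → ex).
* *Nearest-boundary search* (when no span contains the census) uses the
  six first/last dates, not every event: the boundary dates are the
  algorithm's entire state, and the narrated scenarios refer only to
  first/last dates.
* *Tie-breaks.* Equidistant boundaries prefer the one on/before the
  census, then smoker over ex over never — conservative toward smoking,
  consistent with treating therapy evidence as smoking. In daily-resolution
  data exact ties are rare; the test suite checks they occur in under 1%
  of synthetic nearest-code classifications, so the choice cannot move
  agreement statistics materially.
* *Intensity bands.* The printed consumption bands overlap as stated
  ("less than 20 and greater than 0" for medium contains the light range).
  They are resolved as half-open escalating bands — 1–9 light, 10–19
  medium, 20–39 heavy, 40+ very heavy — the ordinary reading of escalating
  categories; when both consumption and time-to-first-cigarette are given,
  the heavier class wins. "Trivial smoker" has no numeric band and is only
  assignable from explicit trivial-smoker codes.
* *Degenerate inputs.* Empty records classify (to `NO_INFORMATION`) rather
  than error; unknown codes are uninformative rather than errors (real
  extracts are mostly non-smoking codes); events dated implausibly are
  retained — no cleaning rules are imposed, and silent dropping would hide
  data faults.

## The codelist

`default_codelist()` ships a synthetic, representative registry mirroring
the structure of the smoking Read-code hierarchy: never-smoked codes, an
annual-review never code, ex-smoker general/intensity/type/admin codes,
current-smoker status and intensity codes, NRT and other therapy codes,
cessation administration/advice codes, and the bare parent code. It is a
stand-in: code strings are illustrative and the large sub-groups (e.g. the
many NRT product codes) are collapsed to a few representative entries.
Every operation takes the registry as an argument, so a production
codelist loaded with `read_codelist()` drops in unchanged. One open point
is the never-smoker annual-review code: it is treated as an ordinary never
code, because the temporal-conflict override already handles the case
where it follows smoking evidence.

## Agreement analysis

`cohen_kappa()` computes unweighted kappa with the large-sample standard
error $se = \sqrt{P_o(1-P_o) / (N(1-P_e)^2)}$ and a normal 95% interval.
Three choices were fixed by verifying them against the packaged published
comparison tables (`reference_tables()`), where all six published
kappas and intervals reproduce to two decimals:

* missing pairs are excluded before kappa (complete-pairs analysis);
* the two-status solution amalgamates ex + never on both axes *after*
  dropping missing;
* discordance denominators are full survey column totals, including
  GP-missing rows.

Two source-level inconsistencies in the published tables are resolved
cell-consistently rather than matched to prose: the nearest-status table's
missing-row total is stored as the value its own column marginals imply
(432, not the printed 423), and each table's disclosure-suppressed
missing/missing cell ("<5") is stored at its marginal-implied value (5)
with a suppression flag. Similarly, two prose percentages disagree with
their own tables at the stated precision (8.6% vs the cell-derived 8.5%;
4.3% vs 4.4%); `discordance_summary()` reports the table-derived values.
An optional output mode (`write_agreement_table(..., suppress_small =
TRUE)`) renders cells under 5 as `"<5"`, mirroring the disclosure control
applied in trusted research environments.

## Prevalence

`annual_prevalence()` classifies everyone aged 16+ at a within-year census
date (July 1 by default — no within-year reference point is prescribed
anywhere, so mid-year is used and configurable) with the full algorithm,
collapses, and reports the smoker share. The denominator is configurable:
patients with a known status (default) or all patients aged 16+, since the
appropriate policy depends on whether missingness is believed informative;
the policy used is recorded in the output.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage — codelist,
timeline, classifiers, agreement, prevalence — can be exercised against a
known truth. Each patient follows a yearly two-state chain: never-smoker
until a Bernoulli(0.45) initiation at a uniform age 14–22, then
smoker/ex-smoker spells with annual quit probability 0.04 and relapse
probability 0.02. GP visits are Poisson (4/year by default) from 1990
(records do not cover early life for older patients); a visit records a
state-consistent code with probability 0.25; recorded smoker events are
therapy/admin codes with probability 0.2, and occasionally the parent code
with a cigarettes-per-day value. Patients aged 16+ in the survey year
(2013) respond with their true state, except ex-smokers claim never with
probability 0.1. The defaults are one-time choices of plausible UK adult
magnitudes (ever-smoking near half, quit rates of a few percent per year,
sporadic recording); they are not calibrated to any dataset. The
observation window closes at the end of the survey year, emulating an
extract taken for a survey-linkage comparison.

Randomness uses one root seed with per-patient sub-streams, so cohorts are
reproducible byte-for-byte and single patients can be regenerated stably.

What the generator does **not** emulate: realistic demographics or
deprivation structure, practice-level clustering or registration windows,
incentive-driven secular trends in recording, smoker under-report at
survey (the hook exists but is fixed at zero), e-cigarette coding, or
miscoding of GP events themselves (recorded codes are always
state-consistent). Consequently, passing recovery tests shows the
*pipeline* is correct — under dense, faithful recording the classifier
recovers truth for ≥99% of patients — not that real GP data are this
clean. In particular the generator's GP/survey agreement is far higher
than in real linked data, where the published two-status kappa for the
full algorithm is 0.64.

## Problem sizes and runtime choices

Test and validation runs use cohorts of 400–3,000 patients (2,000 for the
dense-recording recovery check, with 12 visits/year and recording
probability 1), 3,000–4,000 randomized single-patient scenarios for
oracle-equivalence checks and 10,000 for the totality/monotonicity
properties, and ~300 random grids for the kappa oracle. These sizes give
Monte-Carlo error comfortably below the margins being asserted (e.g.
binomial SE ≈ 0.2% at n = 2,000 against a 1% agreement margin) while
keeping a full suite run to a few minutes on one core.

## Known limitations

* The classification is only as good as the codelist; the shipped one is
  a structural stand-in and production use requires a curated list.
* Long-term NRT users who no longer smoke are classified smokers until an
  ex code appears; this is a deliberate modelling stance, not an oversight.
* No imputation of missing status and no use of registration periods;
  patients with no informative codes are reported missing.
* The kappa interval is the large-sample normal one; no bootstrap or
  weighted variants are provided.
* Same-day contradictory codes are retained and surface only through the
  relapse-overlap rule; day is the temporal resolution throughout.
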