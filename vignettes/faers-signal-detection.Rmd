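---
title: "Disproportionality signal detection for FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect safety reports submitted by patients, clinicians
and manufacturers. They are the main early-warning instrument of
post-marketing pharmacovigilance, and they are messy: the same case
appears in several versions (an initial "I" report plus follow-ups
"F"), drug names are free text, adverse events are coded as MedDRA
Preferred Terms (PTs), dates are frequently missing or truncated to a
month or a year, and there is no denominator of exposed patients.

`faersignal` implements the full analysis chain used to screen such a
database for drug–event associations, with the GLP-1 receptor agonist
(GLP-1RA) class — exenatide, liraglutide, dulaglutide, semaglutide,
tirzepatide — and neuropsychiatric adverse events as the motivating
application: ingestion of the quarterly "$"-delimited files across both
FAERS schema eras, case-version deduplication, dictionary-based
exposure classification with the primary-suspect (PS) filter,
primary-SOC selection and HLT/HLGT-level adverse-event grouping on a
MedDRA-style hierarchy, reporting odds ratio (ROR) disproportionality
with signal criteria and indication stratification, descriptive
tabulation, and time-to-onset (TTO) analysis. Because the real
database is large and MedDRA is licensed, the package also ships a
synthetic report generator with known ground truth; every stage is
tested against that truth.

## The statistic

For a target drug set and an adverse-event PT set, reports are
cross-classified case-level into the 2×2 table

|              | event of interest | any other event |
|--------------|-------------------|-----------------|
| target drug  | a                 | b               |
| comparator   | c                 | d               |

and the reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

A drug–event pair is a *signal* when at least 3 target cases report the
event **and** the CI lower bound strictly exceeds 1. Two conventions
matter and are fixed deliberately:

* **No continuity correction.** A table with a zero cell is reported
  as *not estimable* rather than silently shifted by 0.5; the n ≥ 3
  rule keeps flagged results away from the degenerate region anyway.
* **z = 1.96 is not configurable**, so results stay comparable across
  analyses.

The PT-level scan (`scan_pts()`) reports, for every PT with at least 3
target cases, the CI lower bound ("RORL") and a tier: *strong* when
RORL > 3, *moderate* when 1 < RORL ≤ 3, *none* otherwise — the heatmap
surface. Disproportionality measures reporting imbalance, not risk:
no causal or incidence interpretation is implied, and the scan applies
no multiplicity adjustment (the number of comparisons is reported so
users can post-adjust).

## Comparators and strata

Three comparator constructions are supported: the whole database minus
the target class; non-GLP-1RA antidiabetic classes (DPP-4 inhibitors,
sulfonylureas, metformin, SGLT2 inhibitors, thiazolidinediones,
insulins); and non-GLP-1RA anti-obesity drugs (orlistat, phentermine,
naltrexone-bupropion, phentermine-topiramate). Cases exposed to any
GLP-1RA are always removed from the dictionary-based comparator pools,
and a case falling into both arms is assigned to the target arm only
(the overlap is reported).

Indication strata are assigned from indication PTs by configurable
keyword lists: diabetes when any indication contains "DIABETES",
weight-loss for "OBESITY"/"WEIGHT"/"OVERWEIGHT". A case matching both
belongs to both strata — the cohorts are analyzed separately, not
partitioned.

## Deduplication

Each case keeps its most recent version, selected by a total order:
latest FDA receipt date, then follow-up over initial code, then latest
event date, then largest primaryid. Missing dates sort before any
present date so complete versions are preferred. Because the order is
total, the result does not depend on input row order and the operation
is idempotent; both properties are tested. Deduplication runs on the
pooled set of quarters, so the same caseid recurring across quarterly
files collapses in one pass. Only same-caseid versions are collapsed —
probabilistic cross-case duplicate linkage is out of scope.

## Drug dictionary

Verbatim names are upper-cased, whitespace-collapsed, and stripped of
trailing dose/form tokens ("1 MG", "PEN", "INJECTION", ...). Matching
is by word boundary within the normalized name by default, so
"OZEMPIC 0.5 MG" still matches; "-" counts as a word character so a
combination generic (PHENTERMINE-TOPIRAMATE) is not also hit by its
components. The shipped dictionary covers the five GLP-1RAs with their
brand names plus the comparator classes; it is a reconstruction from
public labeling and is meant to be replaced by users with curated
lists (`load_drug_dictionary()`), which rejects any name mapped to two
classes at load time.

## MedDRA-style hierarchy

MedDRA is licensed and cannot be redistributed. The package defines a
plain TSV format (pt / hlt / hlgt / soc / primary_soc) and ships a
small synthetic hierarchy covering the terms its generator emits. The
cohort-defining PT universe is selected by *primary* SOC ("Psychiatric
disorders", "Nervous system disorders"): MedDRA is multiaxial, and a
PT linked to a target SOC only secondarily is excluded — uniqueness of
the primary link is validated at load. The eight neuropsychiatric
adverse-event groups (headache, migraine, anxiety, depression,
suicide-related, sleep disorders, olfactory nerve abnormalities,
sensory nerve abnormalities) are defined as HLT/HLGT selectors in an
editable config file; the shipped terms are reconstructions, since the
grouping terms are a judgment call that licensed-MedDRA users should
revisit against their own version.

## Time to onset

TTO is the whole-day interval from the earliest fully-dated therapy
start of the suspect drug ("initiation") to the event date. Partial
dates are excluded, never imputed — imputation would fabricate onset
times; likewise excluded are records with a missing date, a start
after the event, or a zero interval, each under an explicit reason so
that every record is accounted for exactly once. When a case reports
several qualifying events, TTO is computed per case × drug with the
earliest qualifying pair. Quartiles use linear interpolation between
order statistics (quantile type 7); conventions differ by up to a day
at quartile boundaries, so the choice is fixed and documented. Default
bins are (0,30], (30,60], (60,90], (90,180], (180,360], >360 days, as
configuration.

## The synthetic generator

`sim_config()` + `simulate_faers()` emit syntactically valid FAERS
quarters — legacy ISR-keyed layout through 2012Q3, primaryid-keyed
afterwards — with ground truth serialized alongside. The generator
emulates:

* a drug mix of roughly 30% GLP-1RA reports split across the five
  agents, comparator antidiabetic and anti-obesity drugs, and a
  non-dictionary background;
* demographics and missingness patterned on the published
  characteristics of GLP-1RA neuropsychiatric reports (63.2% female,
  45.9% missing age, indication mix 54.4% diabetes / 8.5% weight
  loss / 37% missing, 78.6% consumer reporters, 63% missing outcome);
* injected drug–event odds ratios: for comparator cases the event
  probability is $p_0$; for signal-drug cases the odds are multiplied,
  $p_1/(1-p_1) = \mathrm{OR}_{\text{true}} \cdot p_0/(1-p_0)$, so the
  expected table's cross-product ratio equals the injected OR exactly.
  Defaults inject the class-level associations reported for this drug
  class (headache 1.74, migraine 1.28, olfactory 2.44, sensory 1.69)
  plus a semaglutide suicide-related signal of 2.55 confined to the
  weight-loss stratum;
* onset times drawn as round(log-normal), floored at one day, with
  per-drug medians (dulaglutide 7, tirzepatide 13, liraglutide 16,
  semaglutide 27, exenatide 28 days) and dispersion 2.2 on the log
  scale, chosen so the interquartile spread around a median of 16
  spans roughly 3–66 days. The one-day floor matters: without it the
  sub-half-day mass rounds to zero, is excluded by the positivity
  rule, and biases the analyzable median upward by 30–40% at small
  medians. The extreme tail is clamped at 2000 days so calendar dates
  stay sane;
* a 20% duplicate/follow-up rate (superseded initial versions with
  earlier receipt dates), partial-date truncation to 6 or 4 characters,
  and concomitant/secondary-suspect rows that must *not* pass the PS
  filter.

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: name misspellings beyond
dose decoration, co-prescription structure, litigation- or media-driven
reporting waves, true MedDRA term granularity (the synthetic hierarchy
has dozens of PTs, not thousands), and any form of reporting bias.
Recovery on synthetic data validates the machinery, not the
epidemiology.

## Numerical and design choices

* Ages normalize to years by FAERS unit codes (DEC×10, MON÷12,
  WK÷52.1775, DY÷365.25, HR÷8766); a value with a missing unit is
  taken as years, the common FAERS convention.
* Dates of length 8/6/4 digits parse to day/month/year precision;
  anything else — including calendar-invalid strings — is missing.
* Age groups default to <18, [18,65), [65,85], >85 (the boundary ages
  65 and 85 are ambiguous in prose descriptions; the choice is exposed
  as configuration). Report year comes from the receipt date, which is
  always present, rather than the often-missing event date.
* Outcome tabulation keeps the worst outcome per case, ranked
  DE > LT > HO > DS > CA > RI > OT.
* Percentages use the all-cases denominator, with an explicit
  "missing" level, so each dimension sums to the cohort.
* The legacy/current schema break is handled by a declarative registry
  (`faers_schema()`) mapping per-era column names onto one canonical
  set; ISR→primaryid, CASE→caseid, GNDR_COD→sex. Unknown columns pass
  through untouched so future layout additions do not break ingestion.
* Files decode as Latin-1: real FAERS quarters contain non-UTF-8 bytes.

## Problem sizes in the test-suite

The shipped tests exercise: the ROR estimator against an independently
coded oracle on all 20,736 2×2 tables with cells 1..12; CI coverage of
injected odds ratios 1/2/4 over 500 replicate databases of 5,000 cases
(asserted at the nominal-rate band on the pooled replicate checks —
the Wald interval's finite-sample coverage sits within about a point
of 95% per signal); exact duplicate-count recovery at a 20% duplicate
rate; onset-median recovery for planted medians 7/16/28 days at 10,000
cases per drug within 5%; and byte-identical reruns of the full
pipeline. These sizes were chosen to keep each property statistically
decisive at desk scale; all are plain function arguments, so users can
rerun any of them larger.

## Limitations

Disproportionality on spontaneous reports cannot establish causality,
measure incidence, or correct for confounding by indication, and the
whole-database comparator inherits whatever reporting fashions the
database contains. The shipped dictionary and group definitions are
reconstructions; analyses of real FAERS data should substitute curated
name lists and licensed MedDRA exports. Dedup keys strictly on caseid;
true duplicates submitted under different caseids survive.
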