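---
title: "Methods: claims-based AMI phenotyping and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based AMI phenotyping and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amiclaims)
```

## The problem

Administrative healthcare claims are a byproduct of billing, yet they are
one of the few data sources large enough to monitor outcomes such as acute
myocardial infarction (AMI) across tens of millions of people. Using them
requires a *phenotyping algorithm*: a rule that turns diagnosis codes on
claims into a decision about who experienced the outcome. The U.S.
transition from ICD-9-CM to ICD-10-CM on 2015-10-01 broke the continuity of
ICD-9-based AMI algorithms, and this package implements the standard
repair: carry a validated ICD-9-CM definition across the transition via the
CMS General Equivalence Mappings (GEMs), and characterize the population
the combined definition identifies to check that it behaves clinically
sensibly on both sides of the boundary.

The package has four working parts: a claims data model with a flat-file
dialect, the code-list and GEM crosswalk machinery, a cohort engine
applying the epidemiologic inclusion rules, and a characterization layer
producing the descriptive outputs. A calibrated synthetic-claims generator
stands in for the proprietary source database so that every stage runs,
and is testable, from a clean checkout.

## The algorithm

The AMI definition is four wildcard code families, shipped as
`ami_code_list()`:

| Version | Pattern | Meaning |
|---|---|---|
| ICD-9-CM | 410.x0 | AMI, episode of care unspecified |
| ICD-9-CM | 410.x1 | AMI, initial episode of care |
| ICD-10-CM | I21.xx | Acute myocardial infarction |
| ICD-10-CM | I22.x | Subsequent STEMI/NSTEMI |

A lowercase `x` matches exactly one character; a trailing `x` additionally
matches absence, so `I21.xx` covers both 4- and 5-character I21 codes. This
trailing-wildcard rule is deliberate: without it the pattern would fix the
code length and the family would not cover the whole I21 hierarchy. Codes
for subsequent episodes of care (410.x2), old infarction, angina and
chronic ischemic heart disease are excluded by construction — they mark
history or risk, not an acute event. One matching code is sufficient for
identification, irrespective of its position on the claim (principal,
secondary, unspecified) or the healthcare setting; this maximizes
sensitivity at a known cost in specificity, which is the appropriate
trade-off for an algorithm that will later be chart-validated.

`forward_backward()` implements the crosswalk used to derive the ICD-10-CM
side: expand the ICD-9-CM families against the GEM source universe,
translate forward to ICD-10-CM, then translate the result back to ICD-9-CM.
Codes surfacing in the backward pass that were not in the seed
(`newly_discovered`) are candidates for human review, not automatic
inclusions — the default is a single pass because adjudication, not
iteration, resolves them. Multi-pass closure (`iterations > 1`) is
available and is tested against a brute-force reachability oracle; the
iterated sets can only grow. No-map GEM entries contribute nothing to the
sets but are preserved in `flags_per_code` so a reviewer sees them.
Combination-mapping entries are treated as ordinary single-target
contributions, with the flag surfaced: the output of this step is a flat
candidate list for review, so there is nothing to gain by expanding
combination scenarios structurally.

## Cohort rules

`build_cohort()` applies, in order:

* **Era gating.** ICD-9-CM codes count only before 2015-10-01, ICD-10-CM
  codes only from that date; claims violating this are treated as coding
  errors and ignored. All intervals in the package are closed on both ends.
* **Continuous enrollment.** A person enters a year's denominator only if
  their merged enrollment spans cover every day of that calendar year
  (`enrollment_gap_days = 0` by default; a nonzero allowance is available
  for sensitivity analyses). Overlapping or touching spans are merged
  first. For multi-year periods a person qualifies through any one fully
  covered calendar year, and only claims dated inside such a year can
  index — the natural extension of per-year eligibility, flagged here
  because the alternative reading (index anywhere in the period) is also
  defensible.
* **Minimum age.** Age is `year - birth_year`; persons under 1 are excluded
  from numerator and denominator, which is forced by the full-calendar-year
  enrollment requirement in any case.
* **First event.** The chronologically first qualifying claim indexes the
  person; readmissions and subsequent events in the period are ignored
  entirely. Same-day ties prefer the inpatient setting, then principal
  position, then lexicographic code order — the source material is silent
  on ties and this makes output deterministic under record shuffling.
* **Setting scope.** Two cohorts are built: any healthcare setting (all
  nine settings) and inpatient only.

For periods spanning the transition, `version_attribution()` classifies
each cohort member as ICD-9-only, ICD-10-only, or both. "Both" patients are
counted once in cohort sizes, so the counts satisfy
`|C9 ∪ C10| = |C9| + |C10| − |both|`; the suite asserts this identity
against independently built per-version cohorts.

## Characterization

All printed percentages use half-away-from-zero rounding to one decimal
(`pct()`), per-1,000 proportions to two decimals (`per_thousand()`). One
reference cell in the source material (the 65+ share of 120,789/268,424,
printed as 44.9) appears truncated rather than rounded; the package
documents its rounding rule and does not chase that cell.

Windowed queries are closed intervals in days relative to the index date:
conditions use (−1, +1), treatments and procedures (−1, +14). A person
counts at most once per item, and the index claim's own code is *not*
excluded, so additional AMI codes within a day of the first are reported —
in simulated output this makes the index code families rank near the top
of the concurrent tables, more prominently than in real data where the
marginals already include that effect. Ranking is person count descending
with lexicographic tie-break.

Drug classes follow the published top-100 rule: products are ranked by
person count in the treatment window, the top 100 kept, each mapped to its
class, and a person counted once per class. Classes therefore describe the
most common products, not all products in the class. Unmapped products,
codes and conditions fall into an `other` bucket rather than erroring,
because the clinician-assigned category maps are not published in full.

Length of stay links each inpatient-cohort member to the admission
containing (or starting on) the index date, earliest admission first;
members without a linkable admission are excluded and counted. LOS is
`max(1, discharge − admit)` days — the floor matches a reported range
starting at 1 day. Quartiles are median-exclusive (Tukey hinges would be
the alternative; the source does not say which was used). Band proportions
cover 1–5 / 6–10 / 11–14 / >14 days.

The three electrocardiogram CPT codes (93000 tracing with interpretation,
93005 tracing only, 93010 interpretation only) are a configuration
parameter of the any-EKG query (`ekg_codes()`): the source names the
services but not the codes, and these are the standard routine-EKG codes.

Gender–age curves are emitted both over single years of age and over the
six reporting bins, since the published figure's granularity is not stated.
Numerator ages are ages at index; denominator ages are taken at the
period's first year, because an enrolled person without a diagnosis has no
index date to age them by.

## The synthetic generator

`generator_config()` defaults encode the study conditions: 200,000 persons
over 2014–2017, an annual AMI rate of 3.0/1,000 enrollees (inside the
reported 2.83–3.16 range), background demographics from the enrolled
population (48.1% male, 6.7% aged 65+), case demographics from the
reported case mix (61.4% male; age-bin shares 0.2/1.7/5.1/16.2/31.9/44.9%),
an inpatient index share of 63.4%, concurrent-code, drug-product and
procedure marginals matching the reported frequency tables, a 79% any-EKG
probability, and LOS band probabilities 0.699/0.178/0.054/0.069 (the
11–14-day band is the complement of the three published bands). The
both-version probability 0.124 is set so that, with roughly three quarters
of 2015 index dates falling before October, about 9.3% of 2015 cases carry
both code versions.

Choices the source leaves open, fixed once here:

* Ages are drawn per bin and uniformly within bin; 65+ is truncated at 95.
  Case ages are drawn *at the index year* (so the configured case mix is
  exactly the distribution of age at index); background ages at the first
  study year.
* Within-band LOS is uniform on integer days; the >14 band uses a geometric
  tail (success probability 0.12) capped at 384, the published maximum.
  This reproduces banded proportions exactly in expectation without
  inventing an unprinted parametric form for the mean and SD.
* Index dates are uniform within the index year; admissions begin one day
  before the index claim so that a concurrent code one day earlier, when it
  becomes the first qualifying claim, still falls inside the admission.
* Each claim table draws from its own RNG stream split from the master
  seed, so enlarging one table never perturbs another; `generate(c, s)` is
  record-identical across runs.
* About 35% of persons carry background noise claims, including decoy
  cardiac codes (angina, old infarction, chronic ischemia,
  subsequent-episode 410.x2 family) that the algorithm must ignore; ~5% of
  persons have a mid-year enrollment gap (never in a case's index year, so
  simulated cases remain findable and ground-truth sensitivity is exactly 1).

What the generator does **not** emulate: joint distributions (age × drug
class and the like — marginals are independent given case status), claim
adjudication and costs, coding-practice drift, miscoded AMI in non-cases,
or persons entering/leaving enrollment mid-study beyond the single-gap
mechanism. Passing tests therefore demonstrate that the engines implement
the stated rules correctly and recover configured parameters, not that the
algorithm's operating characteristics (PPV, sensitivity) would hold on
real claims — that requires chart validation by design.

## Problem sizes and verification

The test suite runs the full pipeline at n = 200,000 persons (the
full-scale study condition) for parameter-recovery checks, with tolerances
of three binomial standard errors around configured values; oracle
equivalence (brute-force per-person cohort construction, naive window
filters, GEM reachability closure) is checked on bundles of up to a few
hundred persons, where the naive implementations are exact and fast.
Worked-example arithmetic on published cohort counts (annual per-1,000
proportions, the 2015 both-version count by inclusion–exclusion, the
inpatient/male/chest-pain/beta-blocker/EKG shares) is asserted exactly.
`scripts/acceptance.R` re-runs the full-scale end-to-end recovery from a
fresh seed and writes the recovered LOS-band and 65+ shares as JSON.

## Known limitations

* GEM fixtures are synthetic toys (clearly labelled); real GEM releases are
  accepted by `parse_gem()` but not shipped.
* The packaged category maps cover the codes the generator emits plus a
  margin; on other data most items will fall into `other` until a fuller
  map is supplied.
* Incidence rates are out of scope: only the first event per period is
  kept, so prior events cannot be excluded — proportions, not rates, are
  reported.
* No statistical testing is performed anywhere; the outputs are
  descriptive by design.
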