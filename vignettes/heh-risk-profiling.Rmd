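---
title: "Risk profiling of high hyperdiploid ALL from clinical karyotypes"
author: "hehrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk profiling of high hyperdiploid ALL from clinical karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hehrisk)
```

## The problem

High hyperdiploidy (HeH) — the non-random gain of whole chromosomes giving a
modal number of 51–67 — is the most common genetic subtype of B-cell
precursor acute lymphoblastic leukaemia, and although its overall prognosis
is good, its sheer frequency makes it a large contributor to all relapses.
The UKALL-HeH profile splits HeH into a good-risk (GR) and a poor-risk (PR)
group using only the trisomy status of four chromosomes: 5, 17, 18 and 20.
A karyotype is good risk when chromosome 17 and/or 18 is gained and neither
5 nor 20 is gained; every other combination is poor risk. In a large
multi-trial cohort the PR group carried roughly a three-fold hazard of
relapse, event and death, essentially unchanged after adjusting for
end-of-induction minimal residual disease (MRD).

The practical obstacle is that the input is a clinical ISCN karyotype
string, often decades old, with marker chromosomes (`+mar`) of unknown
identity and incomplete (`inc`) descriptions. This package implements the
full path from raw string to risk group, with the uncertainty those
artifacts create handled explicitly, plus a synthetic-cohort simulator and
the survival machinery needed to validate the profile end to end.

## From ISCN string to copy-number profile

`parse_karyotype()` implements a deliberate subset of ISCN: clones split on
`/`, a leading count token (single value or a `51-56` range), a sex token,
and comma-separated abnormality tokens — whole-chromosome gains/losses,
structural rearrangements (`t`, `del`, `der`, `dup`, `i`, `inv`, `add`,
`ins`, `dic`, `r`), `+mar`, `inc`, composite `cp` cell counts and
`idem`/`sl`/`sdl` stemline references. Anything else is preserved as an
unknown token with a warning: on real-world strings the parser must be
total, so only an empty string or an unparseable leading count is a hard
error. FISH/array nomenclature and deep subclone trees are out of scope.

One clone is classified per patient. ISCN lists the stemline first, so
`select_classification_clone()` takes the first clone in document order
whose count range intersects 51–67 (after expanding `idem` clones against
their stemline), falling back to the highest-count clone. Which clone to use
when two unrelated HeH clones coexist is a convention of this package; the
choice is recorded in the reason trail.

`copy_number_profile()` starts from a 46,XX/46,XY baseline (unknown sex
token: XX with a warning), adds named gains and subtracts losses. Structural
tokens change no whole-chromosome count: the profile is defined on whole
trisomies only. Certainty is the load-bearing design choice:

* with no marker, no `inc` and no `?` token, every chromosome is certain;
* otherwise a chromosome is certain **only if a named gain was written for
  it** — a `+17` in the report was seen down the microscope and is always
  trusted, but a marker or an unrecorded abnormality could hide a gain on
  any chromosome that was *not* written as gained.

This is the only reading under which the provisional risk groups are
computable from the karyotype alone, and it makes the uncertainty
enumeration finite: at most the four profile chromosomes matter.

## The decision table and provisional assignment

The 16-entry mapping from (gain5, gain17, gain18, gain20) to GR/PR ships as
versioned JSON (`inst/extdata/rules/ukall_heh_v1.json`), not as code; a
transcription correction or an alternative reading of the rule never
touches the engine, and `classify_karyotype()` accepts any complete table.

`assign_risk()` enumerates every resolution of the uncertain statuses to
gained/not-gained (at most 2^4). If all resolutions agree the case is
definite (D-GR/D-PR). If they disagree it is provisional, named from the
baseline resolution in which every uncertain chromosome is taken as *not*
gained — a karyotype shows what was seen. A consequence worth noting: a
named `+5` makes a case definite poor risk even in a heavily ambiguous
karyotype, because every resolution lands on PR.

Before the table is consulted, two exclusions mimic cohort construction:
t(9;22)(q34;q11) (matched with sub-band tolerance, so `q11.2` matches
`q11`), and a masked near-haploid/low-hypodiploid pattern. The latter is
named but not operationalized in the clinical literature, so the detector
is this package's own: a fully certain profile whose autosome copy numbers
are all even with at least four tetrasomies (threshold configurable) is
treated as a doubled hypodiploid clone. It never fires on uncertain
evidence — exclusion requires positive proof, ambiguity only downgrades
certainty.

## What the simulator emulates — and what it does not

`generate_cohort()` draws latent labels (defaults: GR 0.62, PR 0.22,
non-HeH 0.10, Ph-positive 0.04, masked-doubled 0.02 — a 74:26 GR:PR ratio
among HeH), builds an ISCN string per patient whose 5/17/18/20 pattern is
conditioned on the latent class, and injects ambiguity at configurable
rates (defaults `mar` 0.18, `inc` 0.09, an overall ambiguous fraction near
the 27% seen in registry data). Non-profile gains follow marginal
frequencies typical of HeH (X, 4, 6, 10, 14, 18 common; 21 nearly always,
often twice). Covariate margins follow the published cohort table: 78%
aged 1–9, 91% WCC < 50, 47% female, MRD positivity 30% at 0.01% and 19% at
the HeH-specific 0.03% threshold, independent of risk group by default
(the published association is null, p = 0.85) with a log-odds coupling
knob for sensitivity analyses.

Endpoints are exponential (Weibull shape exposed, default 1) with the
good-risk arm calibrated so its 5-year cumulative risk equals the
configured value (defaults: relapse 6%, event 9%, death 5%) and the
poor-risk hazard multiplied by the configured hazard ratio (defaults 3.52,
2.80, 3.21). Censoring is administrative: uniform entry over 4 years
against a 10-year horizon, so follow-up is uniform on 6–10 years with
median 8. This is the simplest model satisfying proportional hazards
exactly, which gives hazard-ratio recovery tests a well-defined truth.

Deliberate non-realisms: the three endpoints are drawn independently per
patient (no relapse-implies-event coupling); inter-chromosomal gain
correlations beyond marginals are not modelled; there are no competing
risks. Passing tests therefore demonstrate that the machinery recovers the
parameters of a proportional-hazards world, not that real registry data
obey that world.

## Validation layer

Standard survival estimation is delegated to the `survival` package — the
same engine the original analysis used — behind thin, typed wrappers:
Kaplan–Meier with Greenwood variance and log(−log) intervals
(`km_estimate()`, read at t = 5 exactly by `km_at()`), log-rank
(`logrank()`), Cox models with Efron tie handling (`cox_fit()`; Efron
rather than Breslow because registry exports carry heavy year-granularity
ties; switchable), Harrell's concordance (`harrell_c()`) and Schoenfeld
residual checks on identity time transform (`schoenfeld_check()`). The
test suite cross-checks these against independent oracles: a brute-force
Efron partial-likelihood grid maximizer, hand product-limit and
hypergeometric O−E arithmetic, and exhaustive pair counting.

The package's own statistics sit on top: `cochran_q()` (inverse-variance
fixed-effect heterogeneity over subgroup log hazard ratios, cross-checked
against `metafor`), `subgroup_forest()` (per-stratum univariate group
effects over sex, age band, WCC band, NCI risk, MRD band and diagnosis
era, dropping strata without an event in each arm), and
`run_validation()`, which assembles the cohort-table report: categorical
blocks with chi-square tests (Fisher fallback when an expected cell is
below 5), per-endpoint 5-year estimates, unadjusted and MRD-adjusted
hazard ratios, diagnostics, and a definite-vs-provisional comparison.

Choices the published analysis leaves open, fixed here: MRD enters models
as `log10(mrd + 1e-5)`; NCI standard risk is reconstructed as age 1–9 and
WCC < 50×10⁹/L; confidence intervals are Wald (matching the "HR (CI)"
presentation) with the likelihood-ratio p also reported; the 5-year
relapse rate is 1 − KM of relapse-free survival (a cumulative-incidence
estimate would differ in the presence of competing deaths).

## Numerical and degenerate-input behaviour

Copy numbers driven below zero are an error (inconsistent karyotype), as
are empty strings and malformed count tokens; everything else parses with
warnings. A cohort with a single merged risk group produces a report
without hazard ratios plus a warning rather than an error. Cox
non-convergence surfaces as a warning from the underlying engine;
complete separation is flagged. Uncertain profile chromosomes never enter
boolean tests directly — they are only consumed through the enumeration.

## Problem sizes used in the checks

Simulation-based checks run at sizes chosen to put Monte-Carlo error well
inside the assertion bands: hazard-ratio recovery averages 50 replicates of
2500 patients per arm (mean log-HR standard error ≈ 0.01); 5-year KM
calibration uses single arms of 20,000 (±1 percentage point); the
small-sample adult stratum uses 200 replicates of 90 patients, summarized
by the median with CI coverage; type-I calibration of the Schoenfeld and
Cochran's Q tests uses 200 null replicates (binomial ±5-point band around
the nominal 5%). The test suite uses the same designs at reduced replicate
counts with correspondingly widened 4-sigma bands.

## Known limitations

The parser covers the ISCN subset that decides HeH risk, not the full
grammar; constitutional (`c`) and composite (`cp`) karyotypes are
classified with a warning rather than modelled. The masked-hypodiploidy
detector is a heuristic stand-in for expert review. Cohort-level counts
from any specific registry cannot be reproduced from simulation; the
simulator's role is parameter recovery, not demographic fidelity. The
c-index improvement attributable to a larger cohort requires the earlier
comparison cohort and is out of scope.
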