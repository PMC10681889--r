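# hehrisk

Cytogenetic risk profiling of high hyperdiploid acute lymphoblastic
leukaemia (ALL) from raw clinical karyotypes.

High hyperdiploidy (HeH) — non-random gain of whole chromosomes, modal
number 51–67 — is the most common genetic subtype of B-cell precursor ALL.
The UKALL-HeH profile stratifies HeH on the trisomy status of four
chromosomes:

> **good risk (GR):** +17 and/or +18, with neither +5 nor +20
> **poor risk (PR):** every other combination

with PR carrying roughly a three-fold hazard of relapse, event and death
(unadjusted HRs near 3.5 / 2.8 / 3.2), largely unchanged after adjusting
for end-of-induction minimal residual disease (MRD). Real-world karyotypes
carry marker chromosomes (`+mar`) and incomplete descriptions (`inc`) that
leave the four trisomies uncertain; such cases are assigned *provisional*
risk groups (P-GR / P-PR) by enumerating every resolution of the uncertain
statuses against the 16-entry decision table, while unambiguous cases are
*definite* (D-GR / D-PR).

The package is aimed at statisticians and cytogeneticists who need to apply
or stress-test this kind of karyotype-driven stratification: it implements
ISCN parsing with explicit uncertainty semantics, the eligibility and
exclusion rules (modal 51–67; t(9;22)(q34;q11); masked hypodiploidy), the
table-driven risk engine, a synthetic-cohort simulator with proportional-
hazards endpoints, and the survival validation layer (Kaplan–Meier,
log-rank, Cox with Efron ties, Harrell's c, Schoenfeld checks, subgroup
forest with Cochran's Q).

## Worked example

```r
library(hehrisk)

classify_karyotype("57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]/46,XX[8]")
#> <heh_risk_assignment> 57,XX,+X,+4,+6,+10,+14,+17,+18,+21,+21,+mar[12]/46,XX[8]
#>   group: P-GR (merged: GR)
#>   trisomy status: 5=uncertain 17=gained 18=gained 20=uncertain
```

Chromosomes 17 and 18 were written as gained, so they are trusted; the
marker chromosome could hide a +5 or +20, so those are uncertain. The
baseline resolution (uncertain = not gained) is good risk, but a resolution
with +5 would be poor risk, hence *provisional* good risk.

A full synthetic cohort, classified and validated:

```r
cohort   <- generate_cohort(cohort_config(n = 1169, seed = 1))
assigned <- classify_cohort(cohort)
table(assigned$group)
#>     D-GR     D-PR excluded  not_heh     P-GR     P-PR
#>      555      251       76      112      173        2

run_validation(assigned)
#> <heh_validation_report> n analyzed: 981
#>   Relapse: 145 events; 5y GR 94% (92-95) vs PR 76% (70-81); HR 3.64 (2.62-5.04)
#>   Event-free survival: 197 events; 5y GR 90% (88-92) vs PR 73% (67-78); HR 3.24 (2.45-4.29)
#>   Overall survival: 129 events; 5y GR 94% (92-96) vs PR 85% (80-89); HR 3.25 (2.30-4.59)
```

The simulator generated this cohort with GR 5-year risks of 6/9/5 percent
(relapse/event/death) and PR hazard ratios of 3.52/2.80/3.21; the report
recovers those parameters up to sampling noise at n ≈ 1000 (the hazard-ratio
confidence intervals above all cover their generating values), 5-year
estimates are Kaplan–Meier with log(−log) intervals, and the heterogeneity
table (`$forest`) shows no spurious subgroup structure. `run_pipeline()`
wires simulate → classify → validate into one reproducible run with
versioned, seeded artifacts; `inst/scripts/heh.R` exposes the same stages as
shell subcommands.

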