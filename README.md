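# ovatriage

Preoperative triage of women with adnexal (ovarian) masses from
patient-reported symptoms and serum tumor markers.

When an adnexal mass is found — usually on ultrasound in primary care — the
referring physician has to decide whether the woman should go to a
specialized gynecologic-oncology center or can be worked up routinely.
`ovatriage` implements a complete, testable version of the
symptom-plus-marker triage analysis used in cross-sectional diagnostic
studies of this decision: a structured symptom questionnaire is
dichotomized, symptoms are grouped into clusters, a Symptom Index is
scored, CA125 / HE4 / ROMA are classified against menopause-stratified
cutoffs, and the full battery of diagnostic-accuracy statistics is
computed. Because patient-level data from such studies are generally not
deposited, the package ships a seeded synthetic-cohort generator with the
same statistical structure, so every stage of the pipeline can be exercised
and tested end to end.

It is aimed at biostatisticians and clinical epidemiologists who want to
re-analyze, extend, or power similar triage studies, and at methodologists
who need a clean reference implementation of the component statistics.

## The method

**Symptom dichotomization.** Each of 22 symptoms is recorded as presence,
frequency (days/month, in categories `<1, 1–2, 3–6, 7–12, 13–19, >20`) and
onset (months, in categories `<1, 1–2, 3–4, 5–6, 7–9, 10–12, >12`). A
symptom is *positive* iff it occurs on more than 12 days per month **and**
began within the last 12 months, regardless of severity.

**Clusters and the Symptom Index (SI).** Fifteen symptoms eligible for
clustering (excluding those tied to menopause or sexual activity, the very
rare ones, and weight loss) are clustered with Ward's agglomerative method
applied to the binary symptom indicators (symptoms as observations, squared
Euclidean distance, minimum within-cluster variance increase). The canonical
result is six pairs — abdomen, pain, eating, digestion, miscellaneous,
bladder — plus three isolated symptoms. A cluster is positive if *either*
member symptom is positive, and

> SI positive ⇔ cluster abdomen ∨ cluster pain ∨ cluster eating.

**ROMA.** The Risk of Ovarian Malignancy Algorithm combines the markers on
the log scale with menopause-specific coefficients,

    pre:  PI = −12.0 + 2.38·ln(HE4) + 0.0626·ln(CA125)
    post: PI = −8.09 + 1.04·ln(HE4) + 0.732·ln(CA125)

and reports risk as `100·e^PI / (1 + e^PI)` percent. Markers are called
positive above menopause-stratified cutoffs (defaults: CA125 69.8 / 21.7
U/mL, HE4 41.6 / 96.6 pmol/L, ROMA 5.01 / 18.2 % for pre-/post-menopausal
women); Youden-optimal cutoffs can be re-derived from data with
`optimal_cutoff()`.

**Statistics.** Sensitivity/specificity with Wilson 95% intervals, PPV/NPV,
crude odds ratios with Woolf intervals (Haldane–Anscombe corrected at zero
cells), Pearson chi-square or Fisher's exact test chosen by expected cell
counts, ROC AUC by the Mann–Whitney estimator with DeLong variance, and the
paired DeLong test for comparing AUCs on the same subjects.

## Worked example

Odds ratio for the pain cluster from the printed prevalence counts
(33/60 malignant vs 26/116 benign positive):

```r
library(ovatriage)
odds_ratio(c(33, 27, 26, 90))
#> OR 4.23 (2.16 to 8.27)
```

Performance of the Symptom Index from its 2×2 table (47/13/46/70):

```r
performance(c(47, 13, 46, 70))
#> sensitivity  78.3% (66.4 to 86.9)
#> specificity  60.3% (51.2 to 68.8)
#> ppv          50.5% (40.6 to 60.5)
#> npv          84.3% (75.0 to 90.6)
```

A post-menopausal woman with HE4 = 100 pmol/L and CA125 = 50 U/mL:

```r
roma_percent(roma_pi(he4 = 100, ca125 = 50, menopausal = "post"))
#> [1] 39.24508   # 39.2% risk, positive at the 18.2% post-menopausal cutoff
```

The full pipeline on a synthetic cohort (60 malignant / 116 benign / 150
controls, the study's group sizes):

```r
sc <- generate_cohort(default_paper_spec(), seed = 42)
report <- run_triage(sc)
report
#> triage report: 176 tumor records analyzed ( 150 controls excluded )
#>   SI sensitivity 95.0%, specificity 45.7%, PPV 47.5%, NPV 94.6%
#>   referral: 136 refer / 40 routine work-up
```

(The synthetic SI is more sensitive than in real data — the generator's
symptom dependence is weaker than a real cohort's, which inflates any
"at least one symptom" rule; see the methods vignette.) The report contains
every table of the analysis — per-symptom prevalence with pairwise tests,
cluster odds ratios, performance indicators, stage-stratified odds ratios,
and SI-stratified marker AUCs with DeLong comparisons — as plain
data.frames, and `write_triage_report()` writes them as CSV plus a JSON
summary.

A thin command-line front end covering simulate / score / markers / stats /
run lives at `inst/scripts/triage.R`:

```sh
Rscript inst/scripts/triage.R simulate --seed 17 --out cohort.csv
Rscript inst/scripts/triage.R run --in cohort.csv --out report/
```

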