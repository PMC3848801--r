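---
title: "Methods: symptom and tumor-marker triage of ovarian masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom and tumor-marker triage of ovarian masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatriage)
```

## The clinical problem and the analysis pipeline

A woman with an adnexal mass detected on ultrasound faces a referral
decision: specialized gynecologic-oncology center, or routine work-up. The
analysis implemented here evaluates how well patient-reported symptoms and
serum markers separate malignant from benign masses *before* surgery, in a
three-group design (malignant tumors, benign tumors, healthy controls) with
histopathology as the gold standard and borderline epithelial tumors
grouped with the malignant ones.

The pipeline runs in fixed order: dichotomize the symptom questionnaire;
score symptom clusters and the Symptom Index; classify CA125, HE4 and ROMA
against menopause-stratified cutoffs; and assemble the comparison tables.
Controls appear only in the symptom-prevalence table — their symptom burden
is what makes them informative — and are excluded from every accuracy
analysis, which contrasts malignant with benign only.

## Symptom dichotomization

Each of the 22 panel symptoms carries presence, a frequency category
(days/month: `<1, 1-2, 3-6, 7-12, 13-19, >20`), an onset category (months
of the last 12 during which it occurred: `<1, ..., 10-12, >12`) and a
severity score. A symptom is positive iff it is present, its frequency
exceeds 12 days/month (category `13-19` or `>20`), and it began within the
last year (onset not `>12`). Severity is deliberately ignored: the rule
keys on recent-onset, high-frequency symptoms, the pattern most associated
with malignancy. `dichotomize_symptom()` treats a present symptom with
missing categories as a data error rather than silently scoring it
negative.

## Ward clustering and the Symptom Index

Seven symptoms are excluded from clustering (menstrual irregularity,
post-menopausal bleeding, and the two intercourse symptoms depend on
menopausal status or sexual activity; constipation and diarrhea are too
rare; weight-loss frequency cannot be ascertained), leaving 15. The source
analysis states that "sixteen" symptoms entered the model while listing
seven exclusions from 22 and accounting for exactly 15 in its cluster
figure; this package implements 15.

`ward_cluster()` clusters the *symptoms*, not the patients: observations
are the binary indicator columns, the distance is squared Euclidean, and
each merge minimizes Ward's within-cluster variance increase
$\Delta(A,B) = \frac{|A||B|}{|A|+|B|}\lVert\bar x_A-\bar x_B\rVert^2$.
Heights are reported as $2\Delta$, the squared-distance scale on which the
first merge of two singletons equals their squared Euclidean distance (the
same scale as `hclust(d^2, "ward.D")`). Ties are broken toward the lowest
column index, making the dendrogram deterministic; with 15 columns the
direct $O(k^3)$ implementation is instantaneous. The cut defaults to
$k = 9$: six pairs plus three singletons. Whether the original cut was
height- or count-based is not stated; a count-based cut is the only choice
that is deterministic across cohorts.

Scoring, however, never depends on a data-driven dendrogram. The canonical
cluster definitions (abdomen = bloating/increased abdomen size, pain =
pelvic/abdominal pain, eating = unable to eat/full quickly, digestion =
indigestion/nausea-vomiting, miscellaneous = fatigue/breathing, bladder =
urgency/frequency) are frozen constants; a cluster is positive when any
member is ("and/or" semantics), and the Symptom Index is the disjunction of
the abdomen, pain and eating clusters. This keeps the SI deterministic for
any input cohort, and monotone: adding a positive symptom can never switch
the SI from positive to negative.

## Markers, ROMA and cutoffs

ROMA combines the markers on the log scale with menopause-specific
coefficients (pre: $-12.0 + 2.38\ln\mathrm{HE4} + 0.0626\ln\mathrm{CA125}$;
post: $-8.09 + 1.04\ln\mathrm{HE4} + 0.732\ln\mathrm{CA125}$), reported as
$100\,\mathrm{logit}^{-1}(PI)$ percent. The coefficients are exposed as
data (`roma_coefficients()`) because assay platforms differ and refits
exist; the defaults are the widely used published set. ROMA is applied to
all histologies, not only epithelial cancers, matching the referral-triage
framing.

Positivity is *strict* (`value > cutoff`): "elevated" needs a fixed
boundary convention, and strict inequality makes the value-at-cutoff case
deterministic. The default cutoffs (CA125 69.8/21.7 U/mL, HE4 41.6/96.6
pmol/L, ROMA 5.01/18.2% for pre/post) ship as frozen constants — they came
from ROC analysis of the original cohort and cannot be re-derived without
it — while `optimal_cutoff()` provides the data-driven route: it scans the
midpoints between adjacent sorted unique values and maximizes Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$, the conventional criterion when
none is stated, breaking ties toward the larger cutoff (higher
specificity). The scan depends on the data only through ranks, so it is
invariant to monotone transforms. One unit note: the cutoff sentence in the
source reads "U/L" where the assay section says "U/mL"; the package treats
them as the same axis and labels follow the assay section.

## Statistical machinery

* **Proportion intervals**: Wilson score. The source's interval method is
  unstated and several printed intervals are internally inconsistent, so a
  well-behaved default is documented rather than reverse-engineered.
* **Odds ratios**: cross-product with Woolf (log-normal) intervals;
  Haldane–Anscombe 0.5 added to *all* cells when any cell is zero, flagged
  in the result; two zeros in one margin yield `NA`, not a number.
* **Association tests**: Pearson chi-square without continuity correction,
  switching to Fisher's exact (two-sided, point-probability method) when
  any *expected* cell count is below 5 — a concrete reading of "where
  appropriate".
* **AUC**: Mann–Whitney estimator with half credit for ties, variance and
  confidence interval from DeLong placement values (midranks).
* **Paired AUC comparison**: DeLong covariance of placement values. If the
  variance of the difference is zero the statistic is degenerate: identical
  AUCs give $p = 1$, a nonzero but perfectly consistent difference gives
  $p \to 0$; both are flagged.
* Counts feed the estimators as exact integers; nothing is rounded before
  the final display.

Missing markers are missing results, never negatives: records without a
marker stay in symptom tables and are dropped pairwise from that marker's
tables, with per-table denominators reported.

## The synthetic-cohort generator

`default_paper_spec()` encodes the study conditions: group sizes 60/116/150,
stage distribution 32/5/22/1 (I–IV), post-menopausal fractions
0.617/0.422/0.484, and per-symptom, per-group dichotomized prevalences
equal to the printed prevalence table (÷100). Symptoms are drawn from a
latent Gaussian (tetrachoric) model — the simplest generator with
controllable pairwise structure — thresholded at $\Phi^{-1}(1-p)$ so column
means converge to the prevalences exactly; the latent correlation is 0.6
inside each canonical pair and 0.1 elsewhere. Positive draws are realized
as questionnaire answers above the frequency/onset rule; negatives are
absent (60%), present but sub-threshold (30%), or frequent but
long-standing (10%), so the dichotomizer is exercised non-trivially.

CA125 and HE4 are log-normal per group × menopausal stratum with a location
shift for stage II–IV disease. The locations and scales were calibrated
once, by bounded least squares, against the printed positivity rates at the
default cutoffs (CA125 65% malignant / 24% benign; HE4 58% / 15%; with the
stage-I vs II–IV ordering) and the published all-women AUCs (CA125 0.81,
HE4 0.74), with soft anchors keeping benign medians clinically plausible.
ROMA is *always computed from the generated markers* — never simulated
separately — so its algebraic consistency with `roma_pi()` holds by
construction; its emergent positivity and AUC land near, but not exactly
on, the printed values because no joint CA125–HE4 distribution is
published. Ages and BMIs are truncated normals with the reported
means/SDs; they influence nothing downstream (the HE4–age/BMI association
is a documented limitation of the source analysis and is out of scope).

### What the generator does and does not emulate

Parameter recovery holds by construction for marginal prevalences, group
sizes and marker positivity. Two distributional features of the real cohort
are *not* reproduced, and tests on synthetic data must not be read as
validating them:

1. **Global symptom dependence.** With the printed marginals and the
   0.6/0.1 correlation structure, the probability that a malignant case is
   positive on at least one of the six SI symptoms is far higher than the
   real cohort's 78% (it would be 98% under independence). Real symptom
   data are closer to a mixture of broadly symptomatic and broadly
   asymptomatic patients — much stronger global dependence than a
   near-diagonal tetrachoric model can express. Synthetic SI sensitivity
   therefore runs high, and the package treats the printed SI numbers as
   printed-count arithmetic (exact) rather than a generator target.
2. **Prevalence-dominated Ward geometry.** The squared Euclidean distance
   between binary columns is $n(p_j + p_k - 2p_{jk})$, dominated by the
   marginal prevalences. At within-pair correlation 0.6 the joint-positive
   excess is too small for low-prevalence pairs (e.g. bladder) to out-merge
   prevalence-matched unrelated symptoms, so the canonical 9-group cut is
   *not* reliably recovered at 0.6; it is recovered at high within-pair
   correlation (0.9), which is what the recovery property tests use. The
   0.6 default is retained as the stated study condition for everything
   else.

## Problem sizes used in testing

Worked-example arithmetic uses the printed counts directly. Sampling
properties use cohorts at ten times the study's group sizes (600/1160/1500),
where binomial noise on a prevalence is below ~2 percentage points;
prevalence-recovery checks use simultaneous (Bonferroni-adjusted) 99%
binomial intervals across the 64 non-degenerate symptom × group cells, so
the whole panel has 99% joint coverage rather than a ~50% chance of a lone
spurious failure. The Ward-recovery property is measured over 50 seeds; the
DeLong test is cross-checked against a 10⁴-replicate paired bootstrap on a
cohort of 176 tumor records and against an independent implementation
(pROC).

## Known limitations

* The generator's symptom dependence and stage–symptom independence are
  simplifications; SI-stratified marker tables on synthetic data are
  structurally faithful but not numerically matched to the source.
* Printed tables in the source contain small internal inconsistencies
  (drifting denominators from untabulated missing answers, mixed rounding
  conventions, transposed-looking PPV/NPV cells in the cluster performance
  table). Fixtures store printed counts and printed percentages separately;
  computations are definitional, and comparisons against printed values are
  made at printed precision.
* No multivariable or adjusted models, no multiple-testing correction, no
  ultrasound features, and no assay-platform conversion — the source
  analysis reports crude estimates only, and the rest is out of scope.
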