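---
title: "Methods: the aqueous-humor biomarker workflow in aqmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the aqueous-humor biomarker workflow in aqmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqmarker)
```

`aqmarker` implements the statistical spine of an aqueous-humor (AH)
proteomic biomarker study across three diabetic retinopathy stages —
nonproliferative retinopathy (NPDR), proliferative retinopathy (PDR) and
neovascular glaucoma (NVG). This vignette records the models, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open, so that every numerical behavior of the package can be traced
to an explicit choice.

## Study design and the sample-size formula

The validation cohort size follows the classic normal-approximation formula
for a two-group comparison,

$$ n = \frac{(z_\alpha + z_\beta)^2 \cdot 2}{d^2}, $$

with `sample_size()` using the conventional rounded critical values
(z = 1.96 for two-sided α = 0.05, z = 1.28 for 90% power) when they are
supplied explicitly. At the profiling-derived effect size d = 0.759 this
gives 37 patients per group and 73 in total. A 10⁻⁹ rounding guard is applied
before the ceiling so that designs where n is algebraically integral are not
inflated by floating-point slop. The NVG arm of the emulated cohort has nine
patients — the rarity of the condition, not the formula, sets that arm.

## The synthetic cohort generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes, and retains the ground truth so
recovery can be scored. Its defaults are the study conditions; they are set
once and are not tuned to test outcomes.

* **Group sizes** 37/38/9 (NPDR/PDR/NVG) and **ages** from truncated normals
  on [30, 90] years at 66.1 ± 8.3, 54.9 ± 8.9 and 53.3 ± 12.1 — the printed
  validation-cohort characteristics. Male and hypertension prevalences
  (48.6/60.5/55.6% and 56.8/55.3/55.6%) likewise mirror the printed table.
* **Covariates not printed as numbers anywhere** (macular edema, panretinal
  photocoagulation, phakia, cataract-grade distributions) use
  field-realistic defaults: PRP is common after PDR treatment
  (0.15/0.75/0.90), cataract burden is higher in the older NPDR arm
  (grade distribution 0.20/0.40/0.40 vs ≈ 0.4/0.35/0.2 elsewhere). They are
  plumbing for the regression and stratification operations, not estimates
  of the study.
* **Profiling matrices.** Log2 intensity = protein baseline
  (N(20, 1.5²)) + cumulative group effect for true markers + platform
  location shift + platform-scaled Gaussian noise (SD 0.5 by default). The
  LFQ matrix carries four replicate columns per pooled group; TMT carries
  the two replicate channels per group of the labeling scheme and is
  complete. Four LFQ replicates is a deliberate choice: at the |log2FC| ≥ 1
  call rule with effect 1.5 and noise SD 0.5, the normal-approximation
  detection power is 92% at n = 4 versus 89% at n = 3, so the package's
  stated ≥ 90% marker-recovery property is attainable by design.
* **Missingness** is left-censoring-like: detection is Bernoulli with
  logistic probability in log2 abundance, `plogis(intercept + slope · x)`
  (defaults −17 and 1, i.e. ≈ 95% detection at the baseline abundance of 20
  and steeply less below). LFQ only; TMT reporter matrices are complete.
* **MRM peak areas.** Log2 area = transition baseline (N(15, 1.2²)) +
  cumulative group effect + per-sample loading (log-normal; SD 0.5 log2) +
  per-sample, per-protein biological deviation (SD 0.8 log2, shared by a
  protein's transitions and both technical replicates) + replicate noise.
  The replicate-noise SD is derived from the target duplicate CV as
  σ = √log(1 + CV²)/log 2, so the realized technical CV matches `cv_target`
  (default 0.10 — the within-duplicate variance of the real data is not
  published; this is a free parameter, not an estimate). Spike-in peptides
  appear in every sample at a constant level (log2 = 17) plus loading and
  replicate noise, carrying no biological variance — which makes spike-in
  normalization the exact inverse of the loading. Designated "poor" samples
  have a configurable fraction of target transitions forced far below the
  detection threshold, to exercise the 50% sample filter.
* Regeneration under the same seed is bit-identical; group sizes, duplicate
  structure and spike-in presence hold for every seed.

What the generator does **not** emulate: chromatography, retention time,
interference, protein inference, correlated marker panels, and any real
biological covariance between proteins. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the stated
model, not performance on real spectra.

## Transition design

Proteins are digested in silico with trypsin specificity (cleave after K/R,
zero missed cleavages). Cleavage is suppressed when the following residue is
proline — the common trypsin convention; the flag `proline_rule = FALSE`
disables it. Peptides are eligible when 6–30 residues long, free of cysteine
and methionine (to avoid alkylation/oxidation variability), and unique
within the supplied database; uniqueness is deliberately database-relative,
not proteome-wide. A protein must keep at least two eligible peptides to be
retained.

Candidate products are singly charged y and b ions at a 2+ precursor (both
charges configurable). Only products with m/z above the precursor m/z are
eligible — ions below the precursor window are more likely to be
contaminant-derived. Exactly three transitions are kept per peptide. The
published workflow ranked transitions by external spectral-library intensity
evidence, which is not reproducible offline; the package ranks by fragment
index descending (longer fragments carry more sequence evidence) with y
before b at equal index — deterministic and documented. Note the source
protocol's wording is internally inconsistent ("three transitions per
peptide" vs peptides "with more than three transitions"); the package
designs exactly 3 and requires ≥ 3 detected for quantification, with the
`min_transitions` toggle exposed.

Monoisotopic masses use the standard residue table with proton 1.007276 Da
and water 18.010565 Da; `fragment_mz()` and `peptide_mz()` satisfy the b/y
complementarity identity b_k + y_{n−k} = (M+H) + proton, which the suite
checks over random sequences.

## Profiling differential expression

Each platform's matrix is analyzed per protein on the two stage contrasts
(PDR vs NPDR, NVG vs PDR). The fold change is the difference of group means
on the log2 scale. The t test is pooled-variance Student by default — the
platform comparison is equal-n by design; Welch is available via
`var_equal = FALSE`. Call rules are platform-specific: LFQ calls on
|log2FC| ≥ 1 alone (boundary inclusive); TMT requires p < 0.05 **and**
|log2FC| ≥ 0.58, treating the two channels per group as n = 2 replicates.

Missing values occur only on LFQ. When one group is partially missing, the
available values are compared against the mean of the fully observed group
("missing-fallback"). A protein observed in only one group is
"group-specific": it has no finite fold change, so the package caps |log2FC|
at 10 toward the observed group — large enough to always pass the call rule
and keep sorting well defined, while remaining visibly synthetic in output.

The published candidate set ("common 49 proteins") does not spell out its
set algebra; the package interprets it as the **intersection of per-platform
unions over the two contrasts**, exposed via `rule = c("intersection",
"union")`, with deterministic ordering by descending maximum |log2FC|. The
published selection also used a literature review, which is not
implementable; the set-algebra result is the reproducible core.

## Platform integration

`combat_adjust()` is the standard parametric empirical-Bayes location/scale
batch model: per-protein standardization against the covariate-adjusted
grand mean and pooled variance; per-batch location (γ) and scale (δ²)
estimates shrunk under a normal and an inverse-gamma prior respectively,
with moment-matched hyperparameters and the iterative
conditional-expectation scheme run to relative tolerance 10⁻⁶ (cap 500
iterations); then back-transformation. Disease group is supplied as a
protected covariate by default so biological contrast is not absorbed into
the batch term — the source protocol does not state whether it protected
group; protecting it is the safe default. Proteins not observed in every
batch are excluded (`integrate_platforms()` reports the count): the standard
model needs complete rows. Zero-variance proteins are dropped with a
message.

Two numerical notes. First, the returned `batch_model` carries raw and
shrunken γ/δ and the prior hyperparameters for audit. Second, the
adjustment is *approximately* idempotent: shrinkage makes γ\* ≠ γ̂, so one
pass leaves per-protein batch means small but nonzero, and a second pass
moves values by an order of magnitude less than the first rather than by
zero. The suite asserts the second-pass/first-pass movement ratio < 0.05;
exact idempotence is not a property of the empirical-Bayes estimator. The
test suite also cross-checks the whole adjustment against the reference
implementation in the `sva` package to 10⁻⁴.

## The MRM quality-control cascade

The cascade order is fixed: normalize → detect → sample filter → CV filter →
quantify; each stage only removes rows, and rerunning the cascade on its own
output is a no-op.

* **Spike-in normalization.** Per (sample, replicate), the factor is the
  geometric mean of the β-galactosidase spike-in areas divided by the
  cohort-wide median of those geometric means. Geometric (not arithmetic)
  because areas are log-normal and the geometric mean is robust to a single
  hot transition. Within-sample area ratios are untouched.
* **Detection** is strict: area > 10³, assessed on raw pre-normalization
  areas because the threshold is an instrument-scale constant
  (`use_raw = FALSE` switches this). A transition counts as detected in a
  sample only when both technical replicates exceed the threshold — the
  protocol does not say how duplicates enter the rule; requiring both is
  the conservative reading.
* **Sample filter.** Samples with fewer than 50% of target transitions
  detected are excluded; exactly 50% is retained ("fewer than"). Spike-ins
  are excluded from numerator and denominator.
* **CV filter.** Per transition and sample, CV = sd/mean over the two
  replicate areas (n−1 denominator); the transition's summary CV is the
  median over detected samples (the aggregation level is unstated in the
  protocol; the median is robust and the per-sample CVs are retained for
  audit). Transitions with summary CV ≥ 0.20 are removed cohort-wide, as
  are transitions detected in fewer than `min_samples` samples.
* **Quantities.** A peptide is quantified in a sample when ≥ 3 surviving
  transitions are detected there; the quantity is the mean over replicates
  of the summed transition areas — the sum preserves proportionality to
  abundance under the fixed 3-transition design, and the roll-up is not
  defined by the protocol.

## Biomarker statistics

`wilcoxon_rank_sum()` enumerates the exact U distribution for combined
n ≤ 12 without ties (at most C(12,6) = 924 labelings) and otherwise uses the
normal approximation with tie correction and continuity correction. The
exact branch is checked against independent brute-force enumeration and
`stats::wilcox.test`. AUC is computed by the rank-sum identity
AUC = U/(n₁n₂) with ties counted half, auto-oriented to ≥ 0.5 with the flip
recorded. Fold change is the log2 ratio of group arithmetic means of the
normalized quantities.

Multiplicity control is Benjamini–Hochberg via `stats::p.adjust`
(Bonferroni via config) — the adjustment method is unnamed in the source
protocol; BH is the standard for biomarker panels. BH is order-preserving
and never decreases a p-value, but it is **not** idempotent (reapplying it
inflates the plateau), so the suite tests the true properties.

Tiers are strict: candidate requires AUC > 0.7 **and** fold-change direction
concordant with the profiling experiment; strong additionally requires
AUC > 0.9; significance requires adjusted p < 0.05. Peptides absent from the
direction map skip the concordance check and are flagged. ROC is computed at
peptide level; a protein roll-up, where needed, takes the best peptide and
is flagged as such.

## Clinical statistics

The cohort-table tests are chosen to match the published table's printed
values, since the table does not name its tests: Pearson chi-square
*without* continuity correction for frequency comparisons (reproduces
p = 0.584 for hypertension and p = 0.826 for sex) and the Freeman–Halton
exact test — full enumeration of fixed-margin tables, summing the
probabilities of tables no more probable than the observed one — for sparse
tables (reproduces p = 0.395 and 1.0 for the combined-ophthalmic-disease
rows). One printed value is not reproducible: the age profiling-vs-validation
p of 0.700; from the printed summaries the pooled t gives 0.454 and Welch
0.486. `t_from_summary()` reports both variants rather than matching the
printed number. The three-group p-values of the published table are likewise
unverifiable from summaries and are not used as test surfaces.

Odds ratios use ad/bc with the Haldane–Anscombe +0.5 correction when any
cell is zero and a Woolf log-scale 95% interval, reported as log2 for
symmetric plotting. Covariate association is an OLS fit of log2 peptide
quantity on the covariate with group and age as adjustment terms
("normalized" in the protocol's wording is read as adjusted-for), BH across
peptides; collinear designs are flagged and withheld. Stratified re-testing
recomputes Wilcoxon contrasts within strata (age bands, cataract grades)
and reports whether direction and significance persist; strata below
`min_per_arm` per group are marked not evaluable.

## Stage-wise enrichment

`ssgsea_es()` is the integrated-difference single-sample form: genes ranked
by decreasing expression; score = Σ over positions of (weighted hit ECDF −
miss ECDF), hit weights = rank value^α normalized over hits. α = 0.25 by
default (the established single-sample choice; 0 and 1 via config — at α = 0
the score is fully rank-based and invariant under monotone transforms).

Because the stage profiles are single pooled columns without replicates, a
sample-permutation null is impossible; the package uses a
**gene-permutation** null: size-matched random sets (shared across sets of
equal size, 1000 draws per size by default, seeded), NES = ES divided by the
mean |null ES|, empirical significance = fraction of null |NES| at that size
meeting or exceeding the observed |NES|, BH-adjusted across sets within each
stage, gated at FDR < 0.05. The stage statistic is the NES difference,
stage NES minus the cross-stage mean NES, which sums to zero across stages
by construction. The FDR scheme is this package's documented choice; the
source protocol does not describe one for pooled single-sample profiles.

## Problem sizes used by the test suite

The suite's simulation sizes are chosen to give comfortable Monte-Carlo
margins: 10,000 replicates for the power check (binomial SE ≈ 0.3
percentage points at 90%), 1000 null proteins for false-positive-rate
calibration, 1000 planted+null proteins for LFQ recovery, 200 independent
cohort simulations (n = 37/38 per arm) for the MRM fold-change and
tier-sensitivity recovery, 120 proteins × 50 samples per batch for the
batch-adjustment recovery, and 60 planted-signal enrichment simulations at
200 permutations each. All fixtures are generated in code at test time.

## Known limitations

* The generator's independence assumptions (no protein-protein covariance,
  independent covariates) make recovery tests necessary but not sufficient
  evidence for real-data behavior.
* Group-specific proteins carry a synthetic ±10 log2 fold change; any
  downstream consumer ranking by fold change should treat the capped values
  as categorical ("observed in one group only"), not as measurements.
* The transition ranking is a deterministic stand-in for spectral-intensity
  evidence and will not coincide with intensity-optimized transition picks.
* The Freeman–Halton implementation enumerates fixed-margin tables and is
  intended for the sparse, small-count comparisons it serves here; large
  tables should use the chi-square path.
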