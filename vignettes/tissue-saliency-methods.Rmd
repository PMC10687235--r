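---
title: "Opportunistic IHD risk assessment: models, tissue saliency and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic IHD risk assessment: models, tissue saliency and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihdrisk)
```

## The problem

Abdominopelvic CT scans are acquired at enormous volume for reasons
unrelated to the heart, yet the single axial slice at the third lumbar
vertebra (L3) carries body-composition biomarkers — muscle radiodensity,
visceral (VAT) and subcutaneous (SAT) adipose tissue areas — that
correlate with ischemic heart disease (IHD) risk. `ihdrisk` implements
an *opportunistic* risk-assessment pipeline around that observation:
deterministic CT preprocessing, body-composition feature extraction, a
tissue-level interpretability statistic for image-based risk scorers,
EMR (electronic medical record) feature engineering, risk models with
multimodal fusion, and the evaluation statistics needed to compare them
— plus synthetic generators so the whole chain is testable with planted,
recoverable signal and no clinical data.

Training of deep segmentation or imaging networks is out of scope: any
segmenter producing a tissue label mask and any differentiable scorer
exposing a score and a gradient can be plugged in. The package ships a
rule-based attenuation-threshold segmenter and closed-form scorers so
every downstream stage runs end to end.

## Tissue saliency

The core statistic asks: *which tissues drive an image-based risk
score?* Given a scorer with IHD class score $S$, the pixel saliency is
the derivative of the score with respect to each input pixel,

$$w_{ij} = \left.\frac{\partial S}{\partial I}\right|_{I_{ij}},$$

computed by `pixel_saliency()`. Each pixel carries a tissue label
$t \in \{\text{muscle}, \text{VAT}, \text{SAT}, \text{other},
\text{background}\}$. The **observed** tissue saliency is the L1 share
of gradient magnitude falling in class $t$,

$$S^O_t = \frac{\sum_{ij \in t} |w_{ij}|}{\sum_{ij} |w_{ij}|},$$

and the **expected** saliency is the share the class would receive were
saliency uniform — its pixel fraction,

$$S^E_t = \frac{|\{ij : t_{ij} = t\}|}{|\{ij\}|}.$$

Both partitions sum to one. At cohort level, per-image values are
averaged and summarized as the ratio of means $\bar O_t / \bar E_t$: a
ratio above 1 means the scorer concentrates gradient mass on that
tissue beyond its area share. Observed and expected values are compared
per class with two-tailed paired t-tests.

Design choices worth stating explicitly:

* **Signed gradients, magnitudes at aggregation.** The saliency map is
  stored signed; the absolute value enters only the L1 sums.
* **Channel handling.** Scorer inputs replicate one HU grid into three
  channels, so the derivative with respect to the underlying pixel is
  the sum of per-channel gradients; `pixel_saliency()` sums before
  aggregation.
* **Native-grid aggregation.** When the scorer consumes a resized grid,
  gradients are carried back to native pixel coordinates through the
  exact adjoint of the (linear) bilinear resize before aggregation, so
  saliency always aligns with the segmentation mask. Aggregating on the
  resized grid instead would mix neighbouring tissues at the boundary.
* **Ratio of means**, not mean of per-image ratios, is the headline
  statistic (both are reported): per-image ratios are unstable when a
  class occupies few pixels.
* **Body mask wins.** The saliency partition is rebuilt from the
  segmentation plus a body mask (`assign_saliency_classes()`): anything
  inside the body not labeled muscle/VAT/SAT becomes *other tissues*
  (including an extended bone label), and anything outside the body is
  *background*, even if the segmenter claimed otherwise.
* **Zero-saliency images** (a flat scorer) have no defined partition;
  they are excluded from cohort averages and counted, never imputed.

## CT preprocessing conventions

* HU values are clipped to $[-1000, 1000]$ before scoring
  (`clip_hu()`), and window/level normalization uses the inclusive
  linear ramp $v \mapsto \mathrm{clamp}((v - (L - W/2))/W,\, 0,\, 1)$
  with presets soft 400/50, bone 1800/400 and custom 500/50 HU
  (`apply_window()`, `stack_channels()`).
* Resizing uses separable pixel-center bilinear interpolation for
  images and nearest-neighbour for label masks; because the map is
  linear, its transpose is the exact gradient adjoint
  (`resize_grid()`, `resize_adjoint()`).
* The body mask (`extract_body_mask()`) thresholds above air at
  −200 HU, removes bed-like connected components (bounding box touching
  the bottom edge with area below 20 % of the largest component), keeps
  the largest remaining component and fills internal holes. These are
  conventional recipe choices; the threshold and the bed rule are
  arguments.

## Body composition and the reference segmenter

Tissue areas are pixel counts scaled by the pixel area (cm²); the
VAT/SAT ratio is spacing-free; Dice is $2|A\cap B|/(|A|+|B|)$ with the
doubly-empty class defined as 1 (perfect agreement on absence, keeping
per-class sweeps NaN-free). The RMS coefficient of variation for
paired manual/automated measurements uses the duplicate-measurement
convention: per-pair SD $|m-a|/\sqrt2$, CV relative to the pair mean,
RMS across pairs, in percent.

The reference segmenter (`threshold_segmenter()`) applies standard
body-composition attenuation windows — adipose $[-190, -30]$ HU,
muscle $[-29, 150]$ HU — inside the body mask. Adipose components
reaching within 4 mm of the body surface are SAT, the rest VAT; muscle
is restricted to a band within 17 mm of the SAT ring (the abdominal
wall), which in the phantom geometry covers the full muscle layer plus
a small margin. On default phantoms it reaches per-class Dice ≥ 0.90
against ground truth. It is a stand-in for a trained segmentation
network, not a clinical tool.

## Synthetic data: what it emulates, and what it does not

`make_phantom()` renders an L3-like slice as concentric ellipses — SAT
ring at the surface, muscle wall inside it, inner cavity split between
VAT (smooth random blobs occupying a target fraction) and other tissue
— over an air background with an optional ~0 HU scanner-bed strip.
Default HU distributions follow published attenuation conventions
(air −1000, SAT −100 ± 15, VAT −90 ± 15, muscle 45 ± 12, other
30 ± 40 HU); they are configurable because tissue HU distributions are
conventions here, not measured values. The default grid is 256 px at
2 mm spacing (tests use 96 px at 4 mm to keep runtimes low; the
geometry is resolution-independent).

`make_imaging_cohort()` jitters the geometry and muscle HU per patient
and draws binary outcomes from a logistic model on standardized
body-composition features, with the intercept calibrated to a target
prevalence and the latent noise level explicit. `make_emr_cohort()`
generates longitudinal records — encounters, dated vitals and labs with
measurement noise and optional whole-series missingness, diagnosis /
procedure / medication codes whose probabilities track the latent
clinical values, guaranteed pre-scan encounters and post-horizon
follow-up — with outcomes from a planted logistic model; positive
patients receive an IHD diagnosis code inside the horizon so labeling
and inclusion filtering run end to end. Outcome draws use RNG streams
separate from record/geometry noise, so anatomy and outcome
re-randomize independently.

What the phantoms deliberately do **not** model: organ texture, partial
volume effects, contrast phases, scanner physics, 3-D anatomy, or
realistic inter-feature correlation structure in the EMR. Passing tests
therefore demonstrate *correctness of the machinery and recoverability
of planted signal*, not clinical performance.

## EMR feature engineering

All history windows are half-open $(\text{scan} - 365\,\text{d},
\text{scan}]$; outcome windows are $(\text{scan}, \text{scan} +
\lceil 365.25 \cdot h \rfloor\,\text{d}]$ for horizon $h$ years.
Repeated vitals/labs are combined with exponential time weights
$u_i = e^{-\lambda \Delta t_i}$ (default half-life 30 days,
$\lambda = \ln 2 / 30$ per day); the phrase "exponential weighting
inversely proportional to the time difference" admits a second reading,
so the inverse-time form $u_i = 1/(1+\Delta t_i)$ is available behind
`form = "inverse"` rather than hidden. Measurement counts are features
in their own right. Codes roll up by longest-prefix ontology match
(ICD10 blocks, CPT groups, drug → ATC therapeutic subgroup) into
occurrence counts (counts subsume indicators); the Charlson comorbidity
index is computed from an editable ICD-10 prefix mapping shipped as
config. Correlation pruning walks features in column order and drops
any feature correlated above 0.5 (strictly, with a round-off guard)
with an already-kept one — deterministic, and verified by recomputing
the full correlation matrix. Only designated lab covariates are
median-imputed, with medians from the training split; all other missing
values pass through to the gradient-boosted learner, which handles them
natively. Race/ethnicity is not a feature. Demographics contribute age
at scan and a male-sex indicator.

Cohort construction: outcomes are ICD10 I20–I25 strictly after the scan
within the horizon; records with IHD codes at or before the scan are
excluded rather than labeled; inclusion requires age ≥ 18, an encounter
in the pre-scan year, and follow-up reaching the horizon (or an
observed outcome inside it); repeat scans of a patient within 182 days
of an included scan are dropped chronologically. Every removal is
attributed to the first violated rule so the audit conserves counts.
Train/test splits are stratified on the outcome with per-class rounding,
so prevalence matches up to integer rounding.

## Models and evaluation

The bivariate segmentation model and all stacking fusions use ridge
(L2) logistic regression with the penalty chosen by stratified 10-fold
cross-validated AUROC over a grid (ties to the smaller penalty; folds
are capped at the minority-class size with a warning rather than
failing). The clinical model is gradient boosting (xgboost) with
missing-value passthrough and a small cross-validated search grid
(depth 2–3, learning rate 0.05–0.1, up to 400 rounds with early
stopping); stochastic steps take explicit seeds. Published baseline
scores are config-driven Cox-style evaluators
($\text{risk} = 1 - S_0^{\exp(lp - \overline{lp})}$) read from
versioned TSV coefficient tables; each shipped table carries a worked
example that the test suite recomputes. SHAP feature attributions for
the boosted model delegate to the tree-SHAP implementation built into
xgboost, with an additivity spot-check.

Evaluation statistics follow fixed conventions: AUROC via the rank-sum
identity (ties ½); AUCPR as the non-interpolated step-curve area
(average precision), whose constant-score baseline equals prevalence;
95 % confidence intervals by stratified bootstrap (positives and
negatives resampled separately, percentile bounds); AUROC comparisons
by the paired DeLong structural-components test; AUCPR comparisons by
paired stratified bootstrap; operating points at the Youden-maximizing
threshold with ties broken toward the lowest threshold (maximizing
sensitivity at equal J). All tests two-tailed.

## Validation strategy and problem sizes

The test suite validates against independent oracles: brute-force
pair-counting and threshold-enumeration for AUROC/AUCPR/Youden on all
short score vectors; a 10,000-replicate label-preserving permutation
test against the DeLong p-value; closed-form L1 partitions for linear
scorers through the full saliency pipeline; analytic ellipse areas for
expected saliency; and planted-coefficient recovery for the cohort
generators. Bootstrap CI coverage is checked on a binormal design with
known population AUROC (0.80, 125 + 125 per dataset, 200 datasets,
500 resamples). The planted-model recovery runs at 2,000 patients with
complete lab series: with whole-series missingness no learner can reach
the latent-truth oracle, so the recovery comparison is made under
complete observation and missingness is exercised separately. These
sizes were chosen as the smallest at which the sampling noise of each
check is comfortably below its tolerance.

## Known limitations

* The reference segmenter's muscle/other separation leans on the
  phantom's annular geometry; real L3 anatomy (paraspinal muscle
  groups, organs at muscle-like HU) needs a trained segmenter.
* The EMR generator's code assignment is conditionally independent
  given the latent values; real comorbidity co-occurrence is richer,
  so correlation pruning is exercised more gently than it would be on
  real data.
* Baseline score configs ship point coefficients without uncertainty
  and assume the standard covariate set; scores requiring covariates
  outside the feature vector fail loudly rather than silently.
* Tissue saliency quantifies gradient mass, not causal contribution;
  like all gradient attributions it inherits the scorer's local
  linearization.
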