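---
title: "Quantifying multi-rater agreement in longitudinal brain tumor volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-rater agreement in longitudinal brain tumor volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LongiVol)
```

## The problem

Volumetric follow-up of glioblastoma asks whether a tumor compartment is
growing or shrinking between consecutive MR acquisitions. When several
raters — human experts or an automatic segmentation method, treated
identically — segment the same longitudinal series, their absolute volumes
can differ substantially while still telling the same clinical story, or
agree closely on average while contradicting each other on the *direction*
of change at individual transitions. LongiVol implements a descriptive
analysis of exactly that distinction: overlap and volume-scale agreement on
one side, trend (slope-sign) agreement on the other.

The analysis is organised around a seven-point acquisition grid —
preoperative (`PRE`), immediate postoperative (`POST`), and follow-ups at
1, 3, 6, 9 and 12 months (`M1` … `M12`) — with per-patient missingness. A
*transition* is a pair of consecutive *available* acquisitions for one
patient, so a patient scanned at `PRE`, `M1`, `M3` contributes the
transitions `PRE→M1` and `M1→M3`; cohort-wide, transitions equal
acquisitions minus patients. Time enters only through this ordering:
every statistic in the package depends on the sign of the volume change or
on the ratio of endpoint volumes, both of which are invariant to the
(positive) calendar length of a transition, so ordinal time with a unit
denominator is used throughout.

Two compartments carry the analysis by default: contrast-enhancing tumor
(`CET`) and the non-enhancing T2-hyperintense tissue (`NCE_T2`), the merge
of edema and non-enhancing tumor. Necrosis volumes are computed but
excluded from trend statistics by default — the compartment is usually
resected completely and reappears late with small volumes, which makes its
trend signs uninformative.

## From label maps to volumes

Segmentations arrive as 3-D integer label maps (NIfTI) with voxel spacing
in mm: 0 background (healthy-tissue subclasses collapse to 0), 1 necrosis,
2 edema, 3 non-enhancing tumor, 4 enhancing tumor. A compartment volume is
simply the voxel count of its label set times the physical voxel volume,
computed on the native grid of each map. No resampling is performed:
cross-rater overlap only makes sense on co-registered images sharing one
grid, so mismatched shape or spacing is an assertion error, never silently
corrected.

## Overlap and volume-scale agreement

The Dice coefficient $D = 2|A \cap B| / (|A| + |B|)$ compares the voxel
sets of a compartment between two raters. Dice is notoriously unstable for
small structures — a one-voxel shift of a tiny residual enhancement can
halve it — so comparisons are gated: when a rater's compartment volume is
below 90 mm³ the comparison is recorded as excluded rather than computed.
The gate compares physical volume, not voxel count, because cohorts mix
1×1×1 and 1×1×3 mm grids. Whose volume triggers exclusion is genuinely
ambiguous in the underlying definition; the package defaults to the
conservative *either-rater* reading and exposes `rule = "both"` for the
laxer one. Gated-out comparisons are dropped from the group sizes of the
(median, range) summaries, where *range* is the single number max − min.

Volume-scale agreement uses two complementary views: the Pearson
correlation of paired volumes (and of paired volume *differences* over each
rater's own consecutive transitions), with the usual t-transform p-value
reported but never used for gating; and the median relative over- or
underestimation $\mathrm{median}_p\,(V^{num}_p / V^{den}_p)$ per time point,
where patients with a zero denominator are excluded with a reported count.
Correlations are computed both pooled over the analysis compartments and
per compartment, labelled accordingly, since either pooling choice is
defensible.

## Trend disagreement: the core statistic

For each rater, compartment and transition the package records the slope
sign $\mathrm{sign}(V_{t_{i+1}} - V_{t_i})$ and the relative change
$\Delta_{rel} = V_{t_{i+1}} / V_{t_i}$, visualised on the decimal log
scale, where 0 is a stable volume, positive values growth, negative values
shrinkage. A *disagreement* between two raters on a transition is an
opposite strict sign: one rater sees growth, the other shrinkage. Its
magnitude is the absolute difference of the two raters' $\log_{10}
\Delta_{rel}$ values — the vertical gap between the disagreeing points of
the disagreement plot. Summing magnitudes (and counts) over all patients
and transitions for every rater pair yields the disagreement matrix, which
is symmetric with a zero diagonal by construction.

Two boundary policies needed a decision the definition leaves open:

* **Zero slope.** An exactly stable volume disagrees with nothing under the
  default `zeroSignPolicy = "neutral"`, because disagreement is defined
  between the two strict signs. `"strict"` counts 0 against either strict
  sign, for sensitivity analyses.
* **Zero volumes.** $\Delta_{rel}$ is undefined when the earlier volume is
  0, and its log also when the later one is. Postoperative `CET`
  frequently hits exactly 0 in manual segmentations, and dropping those
  transitions would hide real shrink/grow events, so the default
  `zeroVolumePolicy = "epsilon"` floors both endpoint volumes at 1 mm³
  before the ratio and flags the record; `"exclude"` reproduces the
  stricter reading that drops them. Neither is claimed canonical; flagged
  magnitudes are marked in every output.

A useful consequence of working with signs and ratios of consecutive
volumes: a constant multiplicative bias on one rater changes neither the
set of disagreements nor the magnitude of any unflagged disagreement, so a
rater that systematically over-segments by a constant factor is *not*
penalised on trend — only inconsistent deviations are. This is asserted as
a property test. Beyond pairwise counts, the package also counts
consensus-outlier transitions: those where a designated pair of raters
agree with each other while a third disagrees with both.

## The synthetic cohort generator

No clinical volumes ship with the package, so a generator provides cohorts
with the statistical structure the analysis assumes. Its defaults are the
study conditions, chosen once:

* **Schedule.** The preset `schedule = "table1"` reproduces the exact
  presence pattern of the 14-patient reference cohort (64 acquisitions, 50
  transitions; per-time-point group sizes 14, 12, 9, 13, 8, 4, 4).
  `schedule = "random"` keeps `PRE` always present and draws each
  follow-up with that cohort's marginal frequencies (e.g. `POST` with
  probability 12/14).
* **Latent trajectories.** Volumes are positive and follow-up change is
  dominated by multiplicative dynamics, so everything is lognormal: the
  preoperative volume of each base compartment is drawn on the log10-mm³
  scale (means 3.9 / 4.8 / 4.0 / 4.3 and sds 0.4 / 0.35 / 0.4 / 0.4 for
  necrosis, edema, non-enhancing and enhancing tumor — medians of roughly
  8, 63, 10 and 20 cm³, typical of newly diagnosed glioblastoma); surgery
  multiplies by a lognormal residual fraction at `POST` (medians 0.05,
  0.6, 0.5, 0.08 — resection removes most enhancing tumor and necrosis but
  much less of the T2 abnormality); each later transition multiplies by
  $\exp(\mathcal{N}(0, \sigma_g))$ with $\sigma_g$ = 0.25 / 0.2 / 0.25 /
  0.3. The latent grid covers all seven time points (surgery happens
  whether or not `POST` is scanned) and is then subset to the present
  acquisitions.
* **Raters.** A rater observes $V \cdot b \cdot e^{\varepsilon}$,
  $\varepsilon \sim \mathcal{N}(0, \sigma)$, floored to 0 below a
  detection threshold. The presets mirror the reference tendencies:
  `R1` unbiased; `R2` segmenting enhancing tumor more aggressively (CET
  bias 1.4); `B` an automatic method overestimating the T2 components at
  every postoperative time point (bias 1.4), grossly overestimating
  residual enhancement immediately after surgery (CET `POST` bias 6), and
  with no detection floor, while the human presets report 0 below 50 mm³.
  Shared measurement noise is $\sigma = 0.15$ on the natural-log scale.
* Edema and non-enhancing tumor are generated and observed separately;
  `NCE_T2` is their sum, so its additivity holds by construction.

Label-map phantoms are nested spheres (necrosis core, enhancing rim,
non-enhancing band, edema halo) whose shell radii come from the cumulative
requested volumes; a requested 0 gives an empty shell, and achieved volumes
match requests to within the discretized boundary shell. Per-rater
variants scale the radii by $e^{\mathcal{N}(0, j)}$ (kept nested with a
running maximum), making the inter-rater Dice controllable, with zero
jitter giving identical maps.

What the generator deliberately does **not** emulate: spatially correlated
segmentation errors (raters disagree at specific anatomical boundaries,
not isotropically), non-spherical tumor shapes, multifocal disease,
pseudo-progression dynamics, or any MR intensity content. Passing tests
therefore demonstrate correctness of the statistical machinery under a
plausible generative model, not clinical performance of any segmentation
method.

## Numerical choices and degenerate inputs

Everything is deterministic given a seed; identical seed and configuration
give bit-identical cohorts and byte-identical report CSVs. Report tables
round to 6 significant digits only at serialization. A zero preoperative
volume cannot be normalized: the relative-trend series is refused with a
warning and recorded with a reason, never imputed. Empty Dice groups keep
their row with n = 0 and NA summaries; zero variance makes a correlation
undefined and flagged rather than erroring; an empty schedule counts (0, 0).
Grid equality for Dice uses exact shape equality and spacing equality to
1e-8 relative tolerance.

Test and example problem sizes are the package's own choices for fast,
stable checks: property suites run tens of randomized 6³–9³ voxel grids
and 4–14-patient cohorts; bias recovery uses 200 patients (the Monte-Carlo
error of the median ratio at noise 0.1 is about ±0.02, comfortably inside
the ±0.1 assertion); noise-monotonicity aggregates 200 replicate
4-patient cohorts per noise level.

## Limitations

The disagreement count treats every transition equally regardless of its
clinical weight; magnitudes are log-ratio gaps, not effect sizes on any
response-assessment scale. With three raters the matrix is descriptive
only — no significance test between matrices is attempted. The
epsilon-floor magnitude for zero-volume transitions depends on the floor
(1 mm³) and is therefore flagged wherever it is used. Dice requires
co-registered, same-grid label maps; the package will not resample.
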