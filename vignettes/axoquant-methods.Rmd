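---
title: "Methods: quantification models and design choices in axoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification models and design choices in axoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoquant)
```

axoquant implements the quantitative procedures used to study cue-induced
local translation in retinal growth cones and the navigation of retinal
axons: quantitative immunofluorescence (qIF) on growth cones, turning-assay
geometry, DiI optic-tract morphometry, single-arbor branch metrics, and
pulsed-SILAC (pSILAC) nascent-proteome statistics. Every stage is paired
with a synthetic-data generator that produces inputs with known ground
truth, so the package is validated end-to-end by parameter recovery rather
than by fixed reference files.

## Image conventions

All images are numeric matrices in row-major image convention: the row
index is y, the column index is x, the origin is the top-left corner and y
increases downward. Integer pixel indices address pixel centers. ROIs are
simple polygons in the same coordinate frame; a pixel belongs to an ROI
when its center lies inside the polygon. Angles are measured in degrees
from the +x axis with positive rotation toward +y (clockwise on screen
under y-down). Generators and analyses share this frame, so recovery tests
are free of convention mismatches.

## Growth-cone quantitative immunofluorescence

The elementary measurement is the mean pixel intensity per unit area
inside a hand-traced ROI (`roi_mean_intensity()`), from which the mean of
a nearby background ROI is subtracted (`background_subtract()`). Negative
background-subtracted means are retained and flagged rather than clipped:
clipping at zero would bias the downstream ratio distributions upward.

Two polarization statistics quantify asymmetry under a 90-degree cue
gradient:

* **Near:far ratio** (`near_far_ratio()`). The growth cone is bisected by
  a line through the axon shaft; the background-subtracted mean is
  computed separately for the half facing the cue (near) and the opposite
  half (far), and their ratio is reported. The bisection line is placed
  through the ROI pixel centroid along the supplied shaft direction — the
  original measurement draws it by hand; a centroid-anchored line is the
  deterministic, operator-free equivalent. Pixels whose centers fall
  exactly on the line are assigned to the near side (a fixed tie-break).
  A far mean that is non-positive after background subtraction makes the
  ratio undefined; it is flagged, not silently dropped.
* **Center-of-mass shift** (`center_of_mass_shift()`). The fluorescence
  center of mass is the intensity-weighted mean pixel position inside the
  ROI. The morphological reference is the center of mass of the
  brightfield-traced cone; since weighting a near-uniform brightfield by
  intensity is ill-posed, we use the unweighted area centroid of the
  in-ROI pixel set, which reproduces the intended morphology reference
  point with no free parameter. The shift (fluorescence COM minus
  centroid) is projected onto the gradient axis to give a single signed
  statistic, positive toward the cue source.

Both statistics are restricted to the ROI; whether the original COM was
computed over the whole frame is not recoverable from the description, and
the ROI-restricted version is the one whose null is exactly zero. Half
means are plain per-half means (not re-weighted by half area).

### The growth-cone generator

`make_growth_cone_image()` draws an annular fan ("palm") opening along the
shaft axis with half-angle 50 degrees and 3–8 short filopodial spikes, a
shape chosen to match typical growth-cone geometry without modeling fine
morphology. The fluorescence inside the mask is a linear ramp along the
gradient axis plus a uniform background and optional additive Gaussian
noise (a Poisson option was considered and rejected: additive Gaussian is
sufficient for testing asymmetry statistics, which depend only on first
and second moments here). The ramp intercept and slope are solved on the
actual in-mask pixel set so that

* the noiseless near:far ratio equals exactly `1 + gradient_strength`,
* the mean noiseless signal equals `base_signal`, and
* the signal is strictly positive everywhere in the mask.

The third condition bounds the strongest generatable gradient for a given
shape; the annular palm admits `gradient_strength = 1` (ratio 2) with
margin, and steeper requests raise an error instead of silently clipping.
The near side, bisection line and the exact noiseless near/far means and
COM shift are recorded in the ground-truth sidecar, so tests never have to
infer the gradient's orientation.

What the generator does **not** emulate: optical blur, photobleaching,
uneven illumination, and segmentation error (the ROI is exact). Passing
recovery tests therefore demonstrate correctness of the estimators on
their stated model, not robustness to tracing or optics artifacts.

## Turning-assay geometry

`turning_angle()` measures the angle between the initial axon-shaft
direction and the growth-cone displacement vector between 0 and 60 min,
signed positive when the displacement falls in the half-plane containing
the pipette (attraction) and negative otherwise (repulsion). The
displacement vector, not the final neurite-tip tangent, is used — the
description does not distinguish the two; the displacement vector is the
variant that is well defined for arbitrary trajectories, and the tangent
alternative can be obtained by passing the tip tangent as the
"displacement". Zero net displacement is an error ("no net growth"); a
displacement exactly parallel (or anti-parallel) to the shaft has no
defined side and is reported unsigned. Group summaries
(`turning_summary()`) report mean, SEM, n, the empirical cumulative
distribution with plotting positions i/n, and an unpaired two-sample
t-test, pooled by default to match the generic unpaired test, with Welch
as an option.

## Optic-tract morphometry

Ten concentric circles C1–C10 are centered on the optic chiasm (OC) with
C10 passing through the tectal posterior boundary (TPB); circle Ck has
radius `k/10 * |OC-TPB|` ("equally spaced" with C10 at the TPB fixes this
spacing). `circle_widths()` samples each circle at a fixed 0.2-degree step
with nearest-pixel lookup — sub-pixel, deterministic and
resolution-controlled — and reports the tract width at Ck as the arc
length (radius times angular extent) of the maximal contiguous run of
tract-positive samples. Width could also be read as the Euclidean chord;
the arc is the default because it matches a width read along the curved
circle overlay and is stable for oblique crossings, and the chord is
available via `measure = "chord"`. When a circle crosses several disjoint
tract limbs, the largest run is used and a multiplicity warning is
emitted. Pre-turn width is the mean over C2–C4 and post-turn over C5–C8,
both normalized to brain size `|OC-TPB|` (`normalized_widths()`).

The mid-diencephalic turn (MDT) angle (`mdt_angle()`) is reported as the
deviation from a straight continuation, in [0, 180]: the angle between
the OC-to-MDT-vertex vector and the MDT-vertex-to-pioneer-tip vector. A
collinear (unturned) tract scores 0, so a sharper caudal turn yields a
larger angle and the penetrance flag `MDT < 45` captures under-turning;
the interior-angle convention would invert the threshold's meaning. The
tectal projection angle (TPA, `tectal_projection_angle()`) is the angle
between the post-turn tract direction and the most anteriorly projecting
axon, positive when the axon deviates toward the TPB side of the tract
axis and negative toward the tectal anterior boundary (TAB) side; the TAB
landmark is used only to orient the sign when the TPB happens to lie on
the axis. All landmarks are caller-supplied, as in the manual assay; no
landmark detection is attempted. `penetrance()` counts threshold
crossings (MDT below 45 degrees; TPA below the control-group mean, −8.6
degrees in the reference dataset) and compares groups with two-sided
Fisher's exact tests.

### The tract generator

`make_tract_image()` rasterizes a two-segment thickened polyline: a
pre-turn bundle of constant width leaving the OC, a turn of the requested
deviation angle at a vertex placed at 0.45 of the OC–TPB distance (so
circles C1–C4 cross the pre-turn segment and C5–C8 the post-turn
segment), a post-turn bundle continued until it leaves circle C10, and a
thin anterior axon at the requested TPA. Because a straight post-turn
segment crosses the inner circles obliquely, the width read along a
circle near the turn is intrinsically larger than the perpendicular
bundle width — a property of the circle-overlay measure itself, not an
estimator error. The ground truth therefore records, besides the nominal
bundle widths, the exact analytic circle-overlay widths computed on the
continuous geometry (fine angular sampling of the exact point-to-segment
distance, step 0.02 degrees); recovery is tested against those, isolating
rasterization error (about one pixel) from the measure's geometry.

## Arbor metrics

Trees arrive as SWC reconstructions. `assign_branch_orders()` designates
the axon shaft (order 0) as the root-to-terminal path — by default the
longest root-to-leaf path, overridable because the shaft is traced
manually in practice. Branches sprouting from the shaft are primary; a
branch sprouting from an order-k branch is order k+1. At a bifurcation
inside a branch the continuation is the child most collinear with the
incoming direction, mirroring how a tracer follows the "same" neurite
through a fork; the remaining children start daughter branches. Branch
length (`branch_lengths()`) sums segment lengths from the sprout point to
the branch terminal, excluding daughter sub-branches.

The axon complexity index (`aci()`) is adopted as the branch-count-
weighted mean branch order, `ACI = sum_k k * N_k / sum_k N_k` over orders
k >= 1 — consistent with a color-coded order weighting, dimensionless,
equal to 1 for a purely primary arbor and bounded by the maximum order
present. The source figure gives the formula only graphically, so this
definition is also recorded in the pipeline's output metadata rather than
silently assumed. It is undefined (NA, flagged) for an unbranched shaft.
`arbor_group_compare()` compares branch counts by a two-way ANOVA (group
by order, interaction included; single-order data degenerate to the
one-way layout, where F equals the squared pooled t statistic), totals by
unpaired t-tests, and ACI distributions by Fisher's exact test on binned
ACI. How the original analysis binned ACI is not stated; the default bin
edge is the control-group median and it is configurable.

### The arbor generator

`make_arbor()` produces exact requested counts per order with branch
lengths drawn from an exponential distribution of the stated mean (a
standard minimal model for neurite segment lengths). Two construction
rules guarantee that order assignment is recoverable rather than merely
probable: daughters sprout from interior nodes of straight parents at 70
degrees, so the most-collinear continuation rule is unambiguous; and the
shaft length is set after the branch lengths are drawn so the shaft is
always the longest root-to-leaf path. These are generator post-conditions
that make ground truth well defined, not tuning toward any test.

## pSILAC nascent-proteome statistics

The pipeline order is fixed: minimum-ratio-count filter, median
centering, moderated test, Benjamini–Hochberg adjustment, significance
calling (`psilac_pipeline()`).

* **Filtering** keeps proteins quantified from at least 2 peptide ratios
  (`filter_min_ratio_count()`), the threshold used in the reference
  processing.
* **Median centering** subtracts the global median of per-protein mean
  log2 H/M ratios from every replicate value, centering the ratio
  distribution at 0 on the log2 scale so comparable numbers of proteins
  appear up- and downregulated. Centering is idempotent.
* **Moderated one-sample t-test** (`fit_ebayes()`). Each protein's mean
  log2 ratio is tested against zero — a one-sample design, because H and
  M label the two treatments within the same replicate. Per-protein
  variances are shrunk toward a prior: with `n_g` non-missing replicates
  and sample variance `s_g^2`, the posterior variance is
  `s2_tilde = (d0*s0^2 + (n_g-1)*s_g^2) / (d0 + n_g - 1)` and
  `t = mean * sqrt(n_g) / s_tilde` is referred to a t distribution with
  `d0 + n_g - 1` degrees of freedom. The hyperparameters `(d0, s0^2)` are
  estimated by moment matching on the log sample variances using
  digamma/trigamma relations (the Smyth-2004 scheme, including a Newton
  trigamma inverse); this variant is named in the output metadata since
  the reference methods only name the approach generically. Non-positive
  excess variance yields the common-variance limit `d0 = Inf` (normal
  tail); the `d0 = 0` override reproduces the ordinary one-sample t-test
  exactly. Proteins with fewer than 2 non-missing replicates are reported
  untested, since a variance needs at least one degree of freedom. All
  p-values are two-sided, as both directions of regulation are reported.
* **FDR** (`bh_adjust()`): the Benjamini–Hochberg step-up, written out
  explicitly (sort, `p*(m/rank)`, running minimum from the top, cap at 1,
  restore input order) and verified in the tests both against a
  brute-force enumeration and against `stats::p.adjust`.
* **Significance calling** (`call_significant()`): strictly below alpha
  (default 0.10). Whether the reference threshold "p < 0.10" was applied
  to raw or adjusted p-values is ambiguous — the methods describe BH
  correction while the figure legend prints a plain p — so both modes are
  first-class and the command-line interface requires an explicit
  `adjust` choice rather than defaulting silently.

Simplified iBAQ (`ibaq()`) divides the light-channel intensity by the
number of theoretically observable tryptic peptides from an in-silico
digest (cleave C-terminal to K or R, not before P, zero missed
cleavages) with length bounds 7–30 residues — the standard simplified
definition; the bounds are exposed as arguments because the reference
delegates iBAQ to its processing software without stating parameters.
`psilac_qif_correlation()` (Pearson r between pSILAC and qIF fold
changes) and `regulator_overlap()` (shared and pathway-specific fractions
against upstream-regulator target sets, with optional hypergeometric
enrichment) complete the module.

### The pSILAC generator

`make_psilac_table()` draws per-protein variances from a scaled-inverse-
chi-square prior (`d0`, `s0^2`), means from a point mass at zero mixed
with equiprobable-sign effects, and replicate values from normals around
the mean plus a configurable global offset that the centering stage must
remove — exactly the hierarchical model the moderated test assumes, with
defaults (3 replicates, d0 = 4, s0^2 = 0.04, 10% regulated at 1 log2
unit) chosen to mimic a small pSILAC experiment with a few thousand
quantified proteins. It starts at the protein-ratio level: no spectra,
peptide-spectrum matching or isotope envelopes are simulated, so the
tests validate the statistics downstream of quantification, not the
quantification itself.

## Validation scale and numerical choices

The shipped checks use problem sizes chosen to estimate each property
stably while keeping the default test run fast: 500 pure-noise growth
cones for null calibration, a 20-point tract parameter sweep, 20 null
tables of 5,000 proteins for hyperparameter recovery and type-I error,
100 repeats of 1,000 proteins for realized FDR, 1,000 random vectors for
the BH oracle, and every 2x2 table with margins up to 15 for the Fisher
oracle. Degenerate inputs are errors or flags, never silent: empty ROIs,
zero displacement, coincident landmarks, unbranched arbors, all-missing
tables, unobservable iBAQ digests. Stage outputs are written with fixed
significant digits so reruns under the same seed are byte-identical.

## Limitations

The package quantifies; it does not segment, trace, register or search
spectra. ROIs, landmarks and trees are caller-supplied, as in the manual
workflows it mirrors. The synthetic generators cover the statistical
structure each estimator assumes, and parameter-recovery results should
be read as correctness of the estimators under that structure, not as
robustness to the imaging and tracing artifacts of real preparations.
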