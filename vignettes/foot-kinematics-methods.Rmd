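---
title: "Methods: multi-segment foot kinematics and the static-to-dynamic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-segment foot kinematics and the static-to-dynamic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footkin)
```

## The scientific problem

The Root model of clinical foot function assumes that five static foot
"deformities" — rearfoot varus (calcaneus inverted in neutral calcaneal
stance position, NCSP), ankle equinus (static ankle dorsiflexion range
below 10°), limited 1st MPJ dorsiflexion (below 65°), an abnormally
plantarflexed or dorsiflexed first ray, and forefoot varus/valgus — cause
specific kinematic compensations during gait, and that a normal foot
passes through the subtalar-neutral (STN) position in mid-stance.
Testing these claims requires (a) a static clinical assessment, (b)
marker-based multi-segment foot kinematics during walking, and (c) a
statistical battery linking the two. `footkin` implements that entire
chain, together with a synthetic motion-capture generator so every stage
can be verified against known ground truth.

## The measurement model

**Segments and markers.** A six-segment model is used: leg, calcaneus,
midfoot, medial forefoot, lateral forefoot and hallux, each carrying a
rigid cluster of three (leg: four) markers. `foot_model()` fixes a
versioned reference geometry: near-equilateral marker triads roughly
50–65 mm across in the standing pose, in a lab frame with x mediolateral,
y in the direction of progression and z vertical (units mm). The triad
size was chosen at design time so that, with typical optical-capture noise
(0.5 mm per coordinate), the relative orientation of two clusters is
measurable to a few tenths of a degree after filtering; much smaller
triads make the distal joints disproportionately noisy.

**Leg coordinate system.** The leg LCS is anatomical: z joins the
malleolar midpoint to the knee-margin midpoint; the frontal plane is the
least-squares plane through the four anatomical markers constrained to
contain the z direction (a one-parameter problem solved in closed form via
a 2×2 eigendecomposition); y is its anteriorly-oriented normal and x
completes the right-handed frame.

**Calibration defines 0°.** During the standing reference trial every
foot-segment LCS is set parallel to the leg LCS, so all fifteen
inter-segment angles are zero by construction in relaxed standing; gait
angles are therefore automatically zero-referenced to standing posture.

**Tracking.** Per frame, each segment's pose is the least-squares rigid
transform (SVD Procrustes, no scaling) from its standing cluster to the
observed cluster. Frames on which a needed segment has fewer than three
complete markers are excluded and recorded; missing samples are flagged at
the I/O layer and never silently interpolated.

**Angles.** For each of the five joints (rearfoot = calcaneus–leg,
midfoot–calcaneus, medial forefoot–midfoot, lateral forefoot–midfoot,
hallux–medial forefoot) the distal-relative-to-proximal rotation is
expressed in the standing leg LCS basis and decomposed with the Cardan
x–y–z sequence: sagittal (+ dorsiflexion), frontal (+ inversion, so
eversion prints negative, left foot), transverse. Within ±85° of frontal
angle the decomposition inverts composition to better than 1e-9°; gimbal
proximity raises a classed warning and a documented fallback
(transverse = 0), never a silent result.

## Filtering and time normalization

Angle curves are low-pass filtered with a zero-phase (forward–backward)
Butterworth filter. Only the cutoff (6 Hz) is fixed by convention in this
area of gait analysis; the order and phase handling were open choices,
resolved as: order 4 per pass, with the design cutoff pre-warped by
$(\sqrt{2}-1)^{-1/8}$ (≈ 6.70 Hz) so the −3 dB point of the *double* pass
sits exactly at 6 Hz. Each pass is initialized at its first-sample steady
state, making the DC gain exactly 1 in floating point.

Boundary handling is explicit. Synthetic trials contain exactly one gait
cycle, heel strike to heel strike; a gait cycle is periodic by
construction, so the pipeline default wraps the curve around
(`boundary = "periodic"`), which eliminates end transients entirely. For
generic non-cyclic curves the conventional odd-reflection padding is
available (`boundary = "reflect"`).

Curves are resampled to the standard 101-point 0–100 % gait-cycle base by
linear interpolation, and the mean of the (by default eight) walking
trials is taken pointwise. Both the raw-time and normalized views are
kept, and an arbitrary-resolution view is available through
`time_normalize()`; variable extraction changes by less than 0.05° when
the base is refined tenfold.

## Events and dynamic variables

Stance is detected from the vertical ground-reaction force at 1500 Hz:
the longest run above 20 N lasting at least 0.2 s (both config keys;
standard gait-lab practice, the source protocols leave them unstated).
Heel lift is a kinematic event: the first instant after 40 % of stance at
which the sagittal rearfoot velocity goes and stays negative for at least
5 % of stance — the onset of sustained plantarflexion. If the criterion
is never met a configurable fixed fraction of stance (default 65 %) is
used, with a classed warning.

Mid-stance is taken as 15 % of stance (a foot-flat proxy) to heel lift,
and propulsion as heel lift to toe off. These windows are *conventions*:
the clinical literature rarely defines them operationally, so both
endpoints are config keys, and window-dependent results should be read as
convention-dependent. Six scalar variables are extracted from the mean
curves: peak (most negative) rearfoot eversion and peak rearfoot
dorsiflexion during mid-stance, the sagittal rearfoot angle at heel lift,
the mid-stance sagittal range, and the propulsion-phase peak hallux
dorsiflexion and peak rearfoot eversion. Peaks are taken on the
normalized grid augmented with the curve values interpolated at the window
edges — extrema are never located at sub-sample resolution (the 6 Hz
filtered curves are smooth at 100 Hz), but an extremum sitting exactly on
a window boundary is evaluated at the boundary.

## Deformity classification and the STN analysis

`classify_deformities()` applies the Root cut-offs: rearfoot varus iff
NCSP is strictly inverted (> 0°; an exactly vertical calcaneus is not
varus), ankle equinus iff static dorsiflexion < 10°, hallux limitation
iff 1st MPJ dorsiflexion < 65° (values exactly at a threshold classify
normal; all three thresholds are config keys). First-ray and forefoot
categories are clinical judgments recorded as closed ternary
vocabularies and passed through. The deformity count gives one slot to
each of the five assessments (any non-normal forefoot or first-ray
category fills its slot), so counts range 0–5.

The STN analysis compares the frontal rearfoot angle held in
subtalar-neutral standing with the frontal rearfoot gait curve. "Passing
through" neutral means the difference changes sign or touches zero
anywhere in the cycle; whether a finite angular tolerance should count as
"coinciding" is genuinely open, so the touch tolerance is a parameter
(default 1e-9°, i.e. exact). The first crossing is reported and all
crossings are retrievable; feet that never coincide contribute their
minimum difference and closest-approach time. The cohort summary pools
crossing times (passers) with closest-approach times (non-passers),
because the clinical statistic of interest is "passed through *or was
closest*" — and both a full-cycle and a stance-only analysis are
available, since the source protocols use both phrasings.

## The statistical battery

Every sample is gated by a one-sample Kolmogorov–Smirnov test against a
normal with the sample's own mean and SD (the parameter-estimation caveat
of this variant — it is conservative — is recorded in the gate result;
the gate is applied per variable within group, the most conservative
reading, and is configurable). Two-group comparisons use the
pooled-variance t-test or Mann–Whitney; three-group comparisons use
one-way ANOVA with Least Significant Difference post-hoc (pairwise t on
the pooled MSE, uncorrected — that is LSD's definition — and only when
the omnibus is significant) or Kruskal–Wallis with pairwise Mann–Whitney
at the Bonferroni-corrected level α/3. Correlations are Pearson when both
variables pass the gate, Spearman otherwise. All tests are two-sided;
group summaries are means with t-based 95 % CIs; minimum group size for
testing defaults to 5, and any cell below it is reported as an explicit
skip — in a cohort where 97 % of feet are varus, the rearfoot-varus group
comparison is structurally untestable and the report says so.

The grid mirrors the standard design: equinus vs none on three rearfoot
variables; limited vs free hallux on the two propulsion variables;
three-group first-ray and forefoot comparisons; and six static–dynamic
correlations (NCSP ↔ mid-stance eversion; ankle range ↔ mid-stance
dorsiflexion, eversion and sagittal range; 1st MPJ range ↔ propulsion
hallux dorsiflexion and eversion).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is verified.

**Waveforms.** Every joint-plane channel is a sum of at most four
harmonics (built from raised-cosine bumps of power 2 or 4), so curves are
exactly periodic and all window extrema are analytically recoverable by
dense scans of the harmonic form — the oracle used throughout the tests.
The rest shapes emulate the canonical features of multi-segment foot
kinematics: an early-stance rearfoot plantarflexion dip with deep
plantarflexion at toe-off, a mid-stance eversion trough (centred near
48 % of stance) with a narrow re-inversion peak in late propulsion (near
91 % of stance, i.e. ≈ 57 % of the gait cycle), and a hallux dorsiflexion
peak at ≈ 90 % of stance. Three per-participant bump weights are solved
by root-finding so that the realized mid-stance eversion, mid-stance
dorsiflexion and propulsion hallux dorsiflexion equal the drawn targets
*exactly*; heel lift is the rearfoot sagittal maximum in late stance.

**Cohort model.** For each deformity pair a bivariate standard normal
with correlation ρ links a static latent to a dynamic latent. The static
measure is the latent's quantile in a two-component truncated-normal
mixture straddling the clinical threshold, which makes deformity
prevalence exact in distribution and preserves ranks (so ρ = 1 gives
perfect rank correlation and ρ = 0 independence). Mixture components sit
at the reported group means (equinus 4.8° vs 11.9°; varus NCSP 9.2°), and
prevalences default to the symptom-free-cohort values (97 % varus, 87 %
equinus, 9 % hallux limitation, 74/19/7 % first ray, 76/4/20 % forefoot).
The dynamic targets are drawn with between-subject SDs sized from
published cohort confidence intervals (3.3° eversion, 4.0° rearfoot
dorsiflexion, 4.9° hallux dorsiflexion) — variances this large are what
keep most deformity group contrasts statistically unremarkable at
n = 100, as observed in symptom-free cohorts. Deformity classes
additionally shift the targets (`default_group_effects()`). An observed
static–dynamic correlation therefore decomposes into the copula part plus
a point-biserial part from the aligned group effect, and an observed
group contrast into the additive effect plus the class-conditional copula
shift. The default copula values (0.43 rearfoot, 0.08 ankle, 0.27
hallux) and effects (−0.8° equinus dorsiflexion, −5° hallux-limitation
dorsiflexion, ±1–2° first-ray/forefoot eversion shifts) were calibrated
once, by simulating the generator's population, so the *totals* sit near
the reported pattern: |r| ≈ 0.4 / ≈ 0.1 / ≈ 0.4 and contrasts ≈ −1.3° /
−7° for the equinus and hallux cells. In marker mode, targets that no
waveform can realize (a positive mid-stance "eversion peak", a
dorsiflexion peak below the rest curve) are clipped to the realizable
bound and the clipped value becomes the ground truth; the variables-only
mode draws the unclipped linear model. The subtalar-neutral standing
angle is NCSP − RCSP with RCSP ~ N(4.0°, 2.5°); together with the ≈ 4°
re-inversion peak this yields a pass-through fraction of roughly 35–40 %
with crossings/closest approaches in late propulsion, as observed
clinically.

**Noise and inter-trial variability.** Markers receive isotropic
Gaussian noise, default 0.5 mm — typical optical capture noise.
Soft-tissue artifact is deliberately not modelled: the measurement model
treats clusters as rigid, and simulating artifact would test a model the
pipeline does not claim. Trials within a participant differ by a random
amplitude jitter (SD 0.5°) on the three primary bumps, so the eight-trial
mean is meaningfully exercised; the magnitude is a convention (inter-trial
variability is rarely reported) exposed in `cohort_config()`. The
vertical force trace is a smooth double hump (peaks ≈ 1.15 body weight,
mid-stance trough ≈ 0.7), strictly zero outside stance, with optional 2 N
noise inside stance only.

**What passing tests do and do not show.** The generator provides exact
ground truth, rank-preserving prevalence, and realistic noise magnitudes,
so the tests demonstrate correctness of the geometry, signal processing,
event logic and statistics, and calibration of the inference. They do not
demonstrate robustness to soft-tissue artifact, marker occlusion-heavy
real captures, pathological gait, or right feet (the model is left-foot
only, mirroring the single-side convention of the source protocols).

## Numerical choices and degenerate inputs

* Rigid fits require ≥ 3 non-collinear complete points; collinear
  clusters and mismatched labels are classed errors, not NaNs.
* The Cardan gimbal guard is 1e-6 on the middle-angle cosine.
* `solve_bump_weight()` brackets on [0, max(400, 4·|target|)] and fails
  loudly if a target extremum is unreachable.
* Zero-variance samples, n < 5 samples and sub-minimum groups take the
  documented degraded paths (nonparametric branch, flagged skip) with
  classed warnings.
* Filtering needs > 54 samples (6× the filter length) for its padding;
  shorter curves are a signal error rather than a silently transient
  result.

## Problem sizes

The test-suite simulations use the sizes at which the checks are sharp
but quick: 10,000-case sweeps for the rotation and STN oracles, 1,000
noisy clusters for the pose oracle, 1,000 null-cohort replicates
(n = 100) for type-I calibration, 500 replicates for Fisher-z coverage,
and small (n ≤ 6) marker-level cohorts for end-to-end recovery. The
acceptance script additionally processes one full marker-level cohort of
100 participants × 8 trials, the size of a typical clinical study.

## Known limitations

Left foot only; no kinetics, spatiotemporal parameters, or curve-level
statistics (scalar variables only, matching the design it reproduces); no
C3D writing; trials are assumed to span exactly one gait cycle (the
single-force-plate convention); heel-lift detection assumes a
plantarflexion onset exists — flat sagittal profiles fall back to the
fixed fraction with a warning.
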