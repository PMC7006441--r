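---
title: "Methods: gait neuromuscular waveform analysis with gaitSPM"
author: "gaitSPM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait neuromuscular waveform analysis with gaitSPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitSPM)
```

# Scope and data model

gaitSPM analyzes overground-walking recordings of the kind used in
clinical gait neurophysiology: eleven surface-EMG channels (gluteus
maximus and medius, vasti, rectus femoris, hamstrings, triceps surae,
tibialis anterior) sampled at 1,500 Hz together with a heel footswitch,
and four inertial sensors (pelvis, thigh, shank, foot) streaming unit
quaternions at 75 Hz. Every waveform is eventually expressed on a fixed
grid of 101 nodes spanning 0–100% of the gait cycle (heel strike to
heel strike); 101 nodes is the convention of one-dimensional SPM gait
studies and makes node *i* equal *i* percent of the cycle. Per subject,
the mean of 20 included cycles represents each muscle, antagonist pair
and joint.

The central containers are S4 classes with validity checks:
`EmgSession` (channels × samples plus footswitch), `QuaternionStream`,
`BurstTrain` (disjoint half-open activity intervals), `GaitEvents`
(alternating heel strikes and toe-offs), `JointAngleTrack`, and
`SpmResult` (t-curve, smoothness, threshold, clusters). Use the
accessors (`channels()`, `heelStrikes()`, `tCurve()`, `spmClusters()`,
...) rather than slot access.

# EMG processing

Raw EMG is band-pass filtered at 20–500 Hz with a fifth-order
Butterworth filter. The filter is applied forward–backward
(zero-phase), which preserves burst timing at the cost of doubling the
effective order; "fifth order" is the design order per pass. Because
`signal::filtfilt` does not pad, the implementation extends the signal
by odd reflection about its endpoints before filtering so edge
transients decay inside the padding — without this, a 20 Hz high-pass
edge leaves transients of the order of the signal amplitude.

Rectification is the magnitude of the analytic signal (computed by
one-sided spectrum doubling; no installed package provides this
primitive, so it is implemented in-package), and the envelope is that
magnitude smoothed with a zero-phase 6 Hz low-pass Butterworth filter
(order 4 per pass; the smoothing order is a free choice, the cutoff is
not). Tiny negative values left by the smoothing are clipped to zero so
the envelope invariant (non-negativity) holds exactly.

Cycles are delimited by footswitch rising edges. Each cycle is linearly
interpolated onto the 101-node grid. Amplitude normalization divides
all of a subject's cycles for one muscle by a single reference: the
maximum over the included cycles (default), or the median of per-cycle
maxima as a robust alternative. Normalization is per subject, per
muscle, per velocity condition — we read "separately for each group and
velocity" as per-condition rather than pooled across subjects, since
pooling across subjects would let one subject's gain set every
subject's scale. Normalization is idempotent and invariant to channel
gain, which the test suite checks as properties.

## Cycle segmentation conventions

A cycle is the half-open interval `[HS_k, HS_{k+1})`. For time
normalization of kinematic signals sampled at 75 Hz, the closing heel
strike is *included* (`segmentCycles(..., inclusive = TRUE)`) so that
node 100 falls exactly on the next heel strike; with only ~82 samples
per cycle, the half-open convention would skew the normalized time axis
by 1/82 of a cycle and displace steep features (the swing-phase knee
peak) by up to 3°. At 1,500 Hz the distinction is negligible and EMG
uses the half-open convention throughout.

# Co-contraction

For an antagonist pair at node *i*, with `L` the normalized amplitude
of the less active and `H` of the more active muscle,

$$\mathrm{CCI}_i = \frac{L_i}{H_i}\,(L_i + H_i),$$

which ranges from 0 (one muscle silent) to 2 (both at their normalized
maximum). The less active muscle is resolved per node — the formula
indexes by *i* — making the curve symmetric in its arguments. When both
muscles are silent the index is defined as 0, the continuity limit of
`L/H (L+H)` as `L ≤ H → 0`. Seven pairs are predefined: MG–TA, LG–TA,
SOL–TA (ankle) and VL–BF, VM–ST, LG–VL, MG–VM (knee); `cciCurve()`
accepts any pair of normalized curves. CCI is computed per cycle and
then averaged over the included cycles.

The soleus-to-lateral-gastrocnemius slope ratio summarizes load sharing
among plantar flexors in early stance: the least-squares slope of each
muscle's mean envelope over nodes 0 to stance/2, returned as
slope(SOL)/slope(LG). The slope is computed on the mean curve (whether
the original analysis used the mean curve or averaged per-cycle slopes
is not documented; the mean curve is the lower-variance choice and is
what the ratio's published interpretation — a shift of recruitment
from SOL toward LG — requires).

# Burst on/offset detection

Burst detection clusters the per-sample *rectified* signal (not the
6 Hz envelope — the 5 ms minimum-burst rule only makes sense on a
signal that can change in 5 ms; a configuration switch allows envelope
input) into k = 3 amplitude groups. The lowest cluster is inactivity; a
sample is active when it belongs to either upper cluster.

`kmeans1d()` is exact: optimal one-dimensional k-means clusters are
contiguous intervals of the sorted values, so the global optimum is
found by dynamic programming over contiguous partitions
(divide-and-conquer over the monotone optimal split positions,
O(k·n·log n)). This is deterministic, needs no initialization or seed,
and matches a brute-force search over all contiguous 3-partitions on
every small instance — a property the test suite verifies on 200
random instances. A quantile-initialized Lloyd iteration, the textbook
alternative, converges to a suboptimal partition on roughly half of
small random instances, which is why the exact algorithm is used.

Two cleaning rules are applied **in this order**: bursts shorter than
5 ms are discarded, then bursts separated by less than 125 ms are
merged. The order matters: two sub-threshold bursts close together are
removed, not merged. The operation is idempotent. Burst timing per
cycle takes the longest interval overlapping the cycle as the primary
burst; onsets/offsets are expressed in percent of the cycle, and a
burst spanning the heel strike reports its onset in late percent and
offset in early percent, with across-cycle means computed circularly
(period 100). Rectus femoris may carry a second burst; a distinct
interval whose midpoint falls in the stance-to-swing transition window
(default 45–75%) is reported separately.

Burst detection presumes an amplitude distribution that is actually
bimodal (bursts against a quiet baseline). On a burst-free stationary
channel the 3-cluster split labels a large fraction of samples active
in millisecond fragments, and the 125 ms merge rule then fuses them
into near-continuous activity; this is a documented limitation of the
clustering rule, not of the implementation, and the suite pins down
exactly this behavior.

# Kinematics

Sensor-to-segment calibration uses a 10 s neutral standing window: the
reference orientation is the normalized quaternion mean, and motion is
screened by the drift rate between the two window halves (threshold
5°/s) — a per-sample angular-velocity check would reject windows with
ordinary sensor noise (1° orientation noise at 75 Hz is >100°/s sample
to sample), while slow drift is exactly what invalidates a calibration.
All subsequent orientations are expressed relative to the reference.

Euler angles use the intrinsic Z–Y–X sequence with z the mediolateral
axis, so the first rotation is the sagittal-plane angle; the sequence
is the natural one for sagittal gait (the decomposition is exact for
pure z rotations) but is itself a choice the source instrumentation
does not document. A warning is emitted near gimbal lock (|pitch| >
85°). Joint angles are distal minus proximal segment z-angles with
per-joint signs (`jointSignConventions()`) making hip/knee flexion and
ankle dorsi-flexion positive, then low-pass filtered at 10 Hz
(order 4, zero-phase; the order is unstated in the source protocol).
The identification of the flexion–extension plane by a sequence of
standing flexions is replaced by static z-axis alignment; for
sagittal-plane analysis of calibrated streams the two coincide, and
the gap only matters when sensors are mounted obliquely.

Gait events come from the shank z angular velocity: mid-swing is a
prominent positive peak (≥ 50°/s, ≥ 0.5 s apart — tuned for
0.8–1.4 m/s walking), heel strike is the first local minimum after each
peak, and toe-off the deepest local minimum in the window preceding the
peak. A heel strike can therefore only be detected *after* a mid-swing
peak, so the first cycle of a recording is structurally unobservable on
the inertial side; sessions meant to yield 20 analyzed cycles should
record at least 21–22.

Temporal–spatial parameters: mean velocity is total distance over total
time; cycle time mean and CV over heel-strike intervals (sample SD,
n−1, by default; the population estimator is available); stance percent
as (TO − HS)/(HS' − HS)·100 averaged over cycles; ROM per joint as max
minus min of the mean normalized angle cycle.

# Statistical parametric mapping

Group waveforms are compared with a pointwise two-sample pooled-variance
t statistic at each of the 101 nodes. Because adjacent nodes are
strongly correlated, the critical threshold comes from random field
theory: the expected Euler characteristic of a smooth t-field,

$$E[\mathrm{EC}(u)] = P(T_\nu > u) + R\,
\frac{\sqrt{4\ln 2}}{2\pi}\bigl(1 + u^2/\nu\bigr)^{-(\nu-1)/2},$$

with resel count `R = 100 / FWHM`, is set to α/2 per tail (two-tailed
inference on |t|) and solved for `u`. Smoothness (FWHM) is estimated
from the gradient of the normalized residuals, the standard estimator;
on fields generated at FWHM 20 it is unbiased to within a few percent.
As smoothness grows the threshold decreases to the ordinary t quantile,
which the tests check to 1e-3. Nodes with zero pooled variance are
masked (t set to 0) with a warning, so a comparison of identical groups
yields a zero curve and no clusters rather than 0/0.

Supra-threshold clusters of |t| get extent-based p-values through the
Poisson clumping heuristic `p = 1 − exp(−E[m]·P(n ≥ k))` with the
one-dimensional extent survival `P(n ≥ k) = exp(−β k²)` and β matched
to the analytically expected cluster extent. Monte-Carlo calibration at
study scale (n = 13 vs 14, FWHM 20, 1000 null replicates) puts the
family-wise cluster rate at 0.050; the extent survival curve itself
carries a modest approximation error (KS distance ≈ 0.07–0.10 against
10,000 simulated null fields, partly node discreteness), which is the
known accuracy of the extent approximation at moderate thresholds —
cluster p-values should be read with that precision in mind. Exact
interpolated crossings are deliberately not the default; extents are
whole nodes.

Each cluster also reports the mean Cohen's d over its nodes. Scalar
comparisons use the pooled-SD Cohen's d, the equal-variance t-test, the
Wilcoxon rank-sum test (auto-selected when either group fails
Shapiro–Wilk at 0.05), and the continuity-corrected chi-squared test
for 2×2 proportions. A priori power uses the noncentral t with
`ncp = d√(n/2)`: at d = 1.03, α = 0.05, power 0.80 the smallest
per-group n is 13 one-tailed and 16 two-tailed. Both tail modes are
exposed because the published design's n = 13 is the one-tailed
solution while the group tests are two-tailed; the package asserts
neither as the original intent.

Whole-curve RFT-corrected inference is stricter than the scalar design
it accompanies: injecting a d = 1 difference over a 20-node band at
n = 13 vs 14 is detected in roughly half of replicates, not the 0.80 of
the uncorrected one-tailed scalar premise (which the suite reproduces
separately at ~0.82). Scalar power calculations should not be read as
SPM detection rates.

# Synthetic data: what it emulates and what it does not

The generator exists so every stage can be validated against known
ground truth. Its defaults encode the study conditions: 1,500 Hz EMG
and 75 Hz quaternions, cycle time 1.1 s, cycle-time CV 2.6% (patients;
1.7% controls), stance 62.4% (patients; 57.3% controls), 30 m walks,
20 analyzed cycles, and joint ROMs of 35.4/53.7/27.3° (hip/knee/ankle,
controls at preferred velocity) or 29.8/39.3/19.8° (patients).

EMG channels are band-limited Gaussian noise (20–450 Hz, so the
analysis band-pass is near-transparent) amplitude-modulated by the
burst profile — baseline floor, per-burst peak, raised-cosine edge
ramps of 20 ms (step edges would make "onset" ambiguous at the
millisecond scale). The carrier is scaled so the smoothed envelope
equals the profile amplitude (Rayleigh mean correction √(π/2)).
Footswitch rising edges sit exactly on generated heel strikes; cycle
durations are Gaussian with the requested CV (truncated at 0.3× the
mean). Quaternion streams rotate about the mediolateral axis only; the
shank integrates an angular-velocity template with dips at heel strike
(−150°/s) and toe-off (−300°/s, the deepest, at the stance fraction)
and a broader mid-swing peak (+250°/s) whose area cancels the dips so
the integrated segment angle never drifts or wraps. Thigh, pelvis and
foot tracks are built from the shank track plus the joint waveforms, so
the relative rotations reproduce the prescribed hip/knee/ankle curves
exactly while the shank alone carries the events. Between-subject
variation is an additive smooth Gaussian field (FWHM 10% cycle — the
smooth-field regime the RFT inference assumes) scaled by a
between-subject SD; the original study reports no variance components,
so the defaults (0.08 normalized envelope units, 3° for angles, and
Table-level SDs for the temporal scalars) are free parameters chosen to
sit in the range such gait studies report, not estimates of the study.

What the generator does **not** emulate: motor-unit physiology
(interference EMG is not a modulated Gaussian), soft-tissue artifact,
electrode lift or mains interference, out-of-sagittal rotation,
magnetometer drift, or correlated muscle-to-muscle timing jitter.
Passing the round-trip suite therefore shows the pipeline recovers its
own model's parameters at realistic sampling rates and noise levels —
it does not certify accuracy on pathological real-world artifacts.

# Numerical choices and degenerate inputs

* Filters: odd-reflection padding of 12 periods of the lowest band
  edge; padding is capped at the signal length.
* `kmeans1d` requires at least k distinct values; silent channels
  return an empty `BurstTrain` with a warning.
* Cycles without a detected burst contribute missing values and are
  excluded from timing means.
* An all-zero normalization reference (dead channel) is an error, not a
  NaN.
* `rftThreshold` extends its root bracket adaptively; at very low
  degrees of freedom (two subjects per group) with rough residual
  fields the critical threshold legitimately exceeds 50.
* Cluster extent 0 maps to p = 1; p-values are capped into (0, 1].
* Ties in k-means assignment go to the lower cluster deterministically.

# Problem sizes used by the validation suite

Unit and property tests run at the study's native scale where that is
cheap (101 nodes, 13 vs 14 subjects, 20 cycles at 1,500 Hz) and at
reduced replicate counts where a distributional property is being
spot-checked (e.g., 2000–3000 simulated t-fields for threshold and
extent calibration, 1000 for the family-wise error rate); these counts
were chosen so each Monte-Carlo standard error is several times smaller
than the tolerance being asserted.

# Known limitations

* Cluster p-values inherit the extent-approximation error described
  above; permutation SPM is out of scope.
* Burst detection assumes amplitude bimodality (see above).
* The normalization reference uses the subject's included cycles; the
  alternative reading (pooling maxima across subjects within a group)
  is not implemented.
* Which 20 cycles are "included" when more are available is
  unspecified upstream; the pipeline takes the first 20 and warns when
  fewer are available.
* Frontal/transverse kinematics, joint kinetics and stride length are
  out of scope.
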