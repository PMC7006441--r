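# gaitSPM

Gait neuromuscular waveform analysis in R: surface-EMG envelopes,
antagonist co-contraction, k-means burst on/offset detection,
quaternion-based sagittal joint kinematics, temporal–spatial gait
parameters, and group comparison of whole gait-cycle waveforms with
one-dimensional statistical parametric mapping (SPM).

## Who this is for

Movement scientists and clinical gait researchers comparing two groups
of walkers — for example a patient population against controls — when
the outcome is a *waveform* over the gait cycle (an EMG envelope, a
co-contraction curve, a joint angle) rather than a single number. The
package covers the full path from raw signals to corrected group
inference, and ships a ground-truth synthetic-data generator so every
stage can be validated without access to subject data.

## The methods at the core

**EMG conditioning.** Band-pass 20–500 Hz (5th-order Butterworth,
zero-phase), rectification as the analytic-signal magnitude, 6 Hz
zero-phase envelope smoothing, time normalization of each heel-strike
to heel-strike cycle onto a 101-node 0–100% grid, and amplitude
normalization to the maximum (or median of per-cycle maxima) over a
subject's 20 included cycles.

**Co-contraction index.** For an antagonist pair at cycle node *i*,
with *L* the less and *H* the more active normalized amplitude,

```
CCI_i = (L_i / H_i) (L_i + H_i),   0 ≤ CCI_i ≤ 2
```

computed per cycle and averaged; 2 means both muscles at their
normalized maximum. Seven canonical ankle/knee pairs are predefined.

**Burst detection.** Exact one-dimensional k-means (k = 3, dynamic
programming — deterministic and globally optimal) on the rectified
signal; the lowest cluster is inactivity. Bursts shorter than 5 ms are
discarded, then gaps shorter than 125 ms merged. On/offsets are
reported in % cycle with wrap-aware circular averaging.

**Kinematics.** Neutral-stance quaternion calibration, intrinsic Z–Y–X
Euler angles (z = mediolateral, the sagittal angle), joint angles as
distal − proximal with 10 Hz zero-phase smoothing, gait events from the
shank angular velocity (mid-swing peak, heel strike, toe-off), and
velocity / cycle time / cycle-time CV / stance % / ROM.

**1D SPM.** Pointwise two-sample t-curves thresholded by random field
theory: the expected Euler characteristic of a smooth t-field at
smoothness estimated from the normalized residuals sets the
family-wise critical threshold `t*` at α = 0.05 (two-tailed);
supra-threshold clusters get extent-based p-values and mean Cohen's d.
Scalar tests (t / rank-sum / chi-squared with continuity correction),
pooled-SD Cohen's d, and noncentral-t a priori power round out the
statistics.

## Worked example

Simulate one subject's session (11 EMG channels + footswitch at
1,500 Hz, four quaternion streams at 75 Hz, 22 cycles) and analyze it:

```r
library(gaitSPM)

plan    <- gaitPlan(nCycles = 22, cycleTimeMean = 1.1,
                    cycleTimeCv = 2.6, stanceFraction = 62.4)
session <- simulateSession(plan = plan, seed = 42)
bundle  <- runSubject(session)

str(bundle$temporal)
#> List of 5
#>  $ velocity   : num 1.3
#>  $ cycleTime  : num 1.1
#>  $ cycleTimeCv: num 3.17
#>  $ stancePct  : num 62.4
#>  $ rom        : Named num [1:3] 35.4 53.6 27.2
#>   ..- attr(*, "names")= chr [1:3] "hip" "knee" "ankle"

round(bundle$burstTimings$MG$summary, 1)
#>    onsetPct   offsetPct durationPct
#>        16.3        48.5        32.2
```

The recovered stance fraction (62.4%), cycle-time CV, joint ROMs
(generated: 35.4 / 53.7 / 27.3°) and medial-gastrocnemius burst window
(generated: 15–50% cycle, ~1.3% edge bias from the raised-cosine burst
ramps) all match the generator's ground truth.

Compare two groups of per-subject mean cycles — here the second group
has an elevated, earlier lateral-gastrocnemius burst and reduced knee
ROM (39.3° vs 53.7°):

```r
prof  <- defaultMuscleProfiles()
profB <- prof
profB$LG <- muscleProfile("LG", data.frame(onsetPct = 5, offsetPct = 50,
                                           peakAmp = 1), 0.3)
g  <- list(profiles = prof,  waveforms = defaultAngleWaveforms(), plan = plan)
gB <- list(profiles = profB,
           waveforms = defaultAngleWaveforms(c(hip = 29.8, knee = 39.3,
                                               ankle = 19.8)),
           plan = plan)
ds <- simulateGroupDataset(g, gB, nSubjects = c(13, 14), seed = 7)

spmTtest2(ds$A$angles$knee, ds$B$angles$knee)
#> SpmResult: df = 25, FWHM = 9.27 nodes, t* = 3.496 (alpha = 0.05)
#>   cluster 1: 11-19% cycle, p = 0.0004625, mean d = 1.57
#>   cluster 2: 52-92% cycle, p = 2.225e-308, mean d = 3.61
```

The knee difference is localized to early stance and the
stance-to-swing transition where it was injected. Scalar utilities
reproduce standard worked examples, e.g.
`cohensD(35.4, 4.9, 13, 29.8, 5.1, 14)` → 1.12 and
`powerNPerGroup(1.03, 0.05, 0.80, tails = 1)` → 13 subjects per group.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/gaitspm.R simulate --out subj1 --seed 4
Rscript inst/cli/gaitspm.R analyze-subject --emg subj1/emg.csv \
        --quat subj1/quaternions.csv --out out1
Rscript inst/cli/gaitspm.R compare-groups --group-a subj1,subj2 \
        --group-b subj3,subj4 --out report
```

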