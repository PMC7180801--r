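---
title: "Deep-learning-refined upper-limb kinematics from a single depth sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning-refined upper-limb kinematics from a single depth sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(relimb)
```

## The problem

Consumer depth sensors track a human skeleton without markers, which makes
them attractive for upper-limb functional assessment outside the
laboratory. Their joint-center estimates, however, carry large systematic
errors — the depth image is a "2.5D" view, so accuracy is plane-dependent
(worst for axial rotation) and task-dependent (worst when the arm occludes
itself, as when combing hair). Marker-based optical motion capture remains
the clinical gold standard but needs a lab, markers and an operator.

`relimb` implements a hybrid: joint angles are computed from the depth
sensor's skeleton with a conventional segment-frame model, and a recurrent
neural network — trained against concurrently recorded marker-based
kinematics — maps each angle waveform toward its gold-standard counterpart.
The package covers the whole chain: both kinematic models, the signal
alignment between the two systems, the network, leave-one-subject-out
validation, agreement statistics, and a synthetic generator that stands in
for the human recordings.

## Kinematic models

Four angle channels are computed throughout, in fixed order: shoulder
flexion/extension (FE), shoulder adduction/abduction (AA), shoulder
internal/external rotation (IE), and elbow flexion/extension (EFE).

**Skeleton model.** The thorax frame takes its y-axis from SpineMid to
SpineShoulder, its z-axis perpendicular to y and the shoulder line
(ShoulderLeft to ShoulderRight), and x completing the right-handed set.
The upper-arm frame hangs from the elbow: y from elbow to shoulder, z
perpendicular to the arm plane (y and the elbow-to-wrist vector), x
completing. Shoulder angles come from the relative rotation
`R = t(C_thorax) %*% C_upperarm`, decomposed in the z-x-y order

```
R = Rz(FE) Rx(AA) Ry(IE)
FE = atan2(-R[1,2], R[2,2]);  AA = asin(R[3,2]);  IE = atan2(-R[3,1], R[3,3])
```

Within one degree of the gimbal singularity (`|AA| = 90`) the axial
rotation is unobservable; IE is set to 0, FE absorbs the outer rotation and
the frame is flagged. Elbow flexion is the angle between the upper-arm long
axis and the forearm vector; the default convention reports 0 at full
extension (the literal arccosine, 180 at extension, is available as
`convention = "raw-acos"`).

Two numerical choices deserve note. First, when the arm is fully extended
the upper-arm z-axis is undefined (the two defining vectors are collinear);
trajectory processing carries the last valid z forward (or uses the thorax
z before any valid frame exists), flags the frame, and rejects the trial
when more than `max_singular_frac` (default 20%) of frames are singular.
Second, every channel is unwrapped over time by nearest-revolution
continuity, anchored to (-180, 180] at the first frame.

**Marker model.** The gold standard uses the UWA upper-limb marker set:
trunk markers C7, T10, CLAV, STRN; shoulder markers PSH/ASH (ACR optional —
the shoulder center is the centroid of whichever of the three are present,
at least two required); elbow epicondyles EM/EL; styloids RS/US; and
three-marker clusters on the upper arm (PUA) and forearm (DUA). Because the
elbow and wrist markers are removed for dynamic trials, their positions are
reconstructed with the calibrated anatomical systems technique (CAST): a
static trial expresses each landmark in its cluster's technical frame, and
those constant local coordinates re-project the landmark from the cluster's
pose in every dynamic frame. Reconstruction is exact under rigid motion and
degrades linearly with marker noise.

The thorax y-axis runs from the mid T10/STRN point to the mid C7/CLAV
point; z is the normal of the T10-C7-CLAV plane, signed toward the
subject's right (the direction toward the shoulder-marker centroid, or +x
of the lab when no shoulder markers are present); the torso contributes
only its origin. The upper arm mirrors the skeleton construction on the
joint centers S, E, W. The forearm runs y from wrist to elbow center and x
perpendicular to y and the styloid axis, signed anteriorly at the first
frame (positive projection on the thorax x-axis) and by temporal continuity
afterwards — the source conventions are verbal ("pointing laterally",
"anteriorly"), so these sign rules are package conventions, stated here
rather than facts of the original models. Shoulder and elbow rotations both
use the same z-x-y decomposition; elbow varus/valgus and axial rotation are
computed but carried separately from the 4-channel waveform, which keeps
only elbow FE.

## Signal alignment

The two systems record at ~30 Hz (skeleton) and ~100 Hz (markers) with an
unknown start offset. The chain is: cubic-spline resampling of both angle
waveforms onto a common 300 Hz grid; integer-lag synchronization by
cross-correlation of the elbow-FE channel (the largest-amplitude channel in
reaching tasks; configurable); zero-lag fourth-order Butterworth low-pass
filtering at 6 Hz applied identically to both streams; and time
normalization to 101 samples spanning 0-100% of the movement.

Synchronization details matter for reaching movements, whose step-like
waveforms give the plain normalized cross-correlation an almost flat peak:
the correlation of each candidate overlap is therefore centred within that
overlap (a per-lag Pearson correlation), both signals are pre-smoothed with
a 5-sample moving average, and only lags leaving at least the minimum
admissible overlap (default 1 s) compete. Shifted noise-free copies are
still recovered exactly, and 5%-amplitude noise moves the recovered lag by
at most one sample at 300 Hz. A peak correlation below 0.5 raises a
warning; post-shift overlap below the minimum is an error.

The filter is a genuine zero-phase pass: coefficients from
`signal::butter`, odd-reflection padding of 3*(order+1) samples,
steady-state initial conditions, forward and backward application. Its
two-pass magnitude is `1/(1 + (f/fc)^8)`; constants pass through bit-near
exactly and a 20 Hz component is attenuated by more than 99%.

Cubic splines replace the band-limited interpolation used by some motion
labs; at these oversampling factors the difference is orders of magnitude
below sensor noise.

## The refinement network

The corrector is a sequence-to-sequence regressor: three stacked LSTM
layers of 100 units, input and output 4 channels per time step, a
time-distributed linear output head (the minimal choice for a regression
target), mean-squared-error loss, Adam with batch size 20 and learning rate
0.006 for 200 epochs. Before training, inputs and targets are mapped to
[0, 1] by a per-channel min-max scaler fitted on the pooled training
waveforms of both systems, so input and target share one geometry; test
values may leave [0, 1] and are deliberately not clipped, keeping the map
invertible. One model is trained per task (a pooled mode is possible by
passing mixed-task pairs, but per-task is the default behavior of the
cross-validation harness); whole 101-sample trials are the training unit —
no sliding windows, no early stopping, no validation split; incomplete
final batches are kept.

Implementation choices: weights are initialized with the standard uniform
fan-in scheme from the run seed, with the forget-gate bias raised to +1 so
gradients flow through the stack early; gradients are clipped to a global
norm of 1 before the Adam update (at this learning rate the 3-layer LSTM
otherwise diverges occasionally); arithmetic is single precision, the
standard deep-learning choice; all randomness (initialization, batch
shuffling) is drawn in R from the seed, so the C++ trainer is RNG-free and
a seed fully determines the run, bit for bit. Each sequence is prepended
with 10 replicas of its first sample — a warm-up that lets the recurrent
state settle out of its zero initialization before the scored samples; the
corresponding outputs are discarded. Without the warm-up, the first two or
three output samples carry a transient large enough to inflate the refined
range of motion by several degrees.

Leave-one-subject-out cross-validation trains one model per held-out
subject on the remaining subjects' trials; the scaler is fitted inside the
fold, so the held-out subject never touches training in any form (asserted
structurally). Fold f trains with seed `seed + f`.

## Agreement statistics

Waveform similarity uses the coefficient of multiple correlation in its
within-day form,

```
CMC = sqrt(1 - [sum (Y_gt - mean_t)^2 / (G (T-1))] / [sum (Y_gt - mean)^2 / (G T - 1)])
```

computed per trial with G = 2 (one waveform per system), averaged within
subject, then summarized across subjects. Several variants of this
statistic circulate; the within-day form is adopted here as a documented
convention. For very dissimilar waveforms the radicand goes negative; it is
clamped to 0 and flagged, and the identical-constant 0/0 case returns a
flagged NaN. RMSE, range of motion (max minus min of the normalized
waveform) and the angle at the point of target achieved (the final
normalized sample — each task ends with the hand on its target, so the
endpoint is the natural reading) complete the per-trial measures.
Parameter-level agreement uses Bland-Altman limits (mean difference ±
1.96 sample SD) and a Shapiro-Wilk-gated paired test (paired t when the
differences pass normality at 0.05, Wilcoxon signed-rank otherwise; zero
variance is reported as degenerate rather than tested). No
multiple-testing correction is applied. All tests delegate to the standard
R implementations.

## The synthetic generator

No recordings ship with the package, so the generator reproduces the
statistical structure the pipeline assumes, not any individual's data.

**Motion.** Each of the four functional tasks (hand to contralateral
shoulder, hand to mouth, combing hair, hand to back pocket) is a monotone
minimum-jerk trajectory per channel between a start and an end angle,
flanked by stationary holds (1.05 s lead-in, 0.45 s lead-out; the lead-in
also absorbs the random inter-system start offset of up to 1 s). End-angle
means and between-subject SDs follow published gold-standard values for
these tasks; start angles are end minus the signed range of motion. Typical
movement durations of 1.6-2.2 s are the package's choice, as are trial-level
jitters (about 1-1.5 degrees on endpoints, 50 ms on duration).
Thirteen subjects with three trials per task mirror a typical validation
cohort; body segment lengths vary ±5% around anthropometric defaults.

**Forward kinematics.** The thorax sits at the origin; humerus and forearm
frames compose `Rz(FE) Rx(AA) Ry(IE)` and elbow flexion. Markers and
skeleton landmarks are emitted at fixed offsets in their segment frames,
placed so that each model's own frame construction inverts exactly — in
particular the skeleton shoulder-line landmarks are laid along the axis
that makes the skeleton thorax construction recover the generating frame.
The placement is schematic, not anthropometric: the two streams are never
compared positionally, only through their angle waveforms, and exact
invertibility is what makes the generator a usable oracle (on noise-free
data both models recover the generating angles to better than 1e-6 degrees,
so any downstream disagreement is attributable to the injected error).

**Sensor error.** The depth-stream corruption has a deterministic and a
stochastic part. Per channel, a smooth bias — a quadratic polynomial in the
true angle plus one sinusoidal cycle over the movement phase — is applied
by re-posing the skeleton from the biased angles, which emits the error at
the landmark level while keeping each channel's calibration well-posed.
Each landmark is then displaced along the camera depth axis
(elevation-modulated, largest at the wrist), and Gaussian jitter (2 mm) and
occasional occlusion spikes (1% of frames, ~15 mm, smoothed over three
frames to mimic tracker inertia) are added. Zero gain reproduces the input
exactly. Default magnitudes are ordered so axial rotation suffers most,
reflecting the transverse-plane weakness of depth sensing, and are set so
that the combing-hair corpus lands near published uncorrected error levels
(shoulder FE ~42 degrees RMSE, elbow FE ~26 degrees); `calibrate_error_gain`
adjusts per-channel gains to any attainable target, refusing targets below
the stochastic noise floor. Because the systematic part is a smooth function
of the true kinematics shared by all subjects, it is learnable — which is
precisely the property the refinement network exploits, and the limit of
what passing synthetic tests can show: real sensor error also contains
subject- and environment-specific components no simulator guarantees, so
synthetic agreement figures bound the method's behavior under the stated
error structure, not its clinical accuracy.

The sinusoidal bias rides on the movement phase rather than wall-clock
time; a clock-locked bias would tilt the stationary holds and corrupt the
cross-correlation synchronization with an artifact no real sensor shows.

## Problem sizes and runtime

Simulations are sized for a desktop CPU. The test suite trains on corpora
of 6-20 sequences for seconds-scale checks and runs two heavier
cross-validations: the identity-learning check (13 subjects, 3 trials,
zero injected error) at batch size 12 for 500 epochs — identity learning
keeps improving with optimizer steps, and the smaller batch buys more Adam
updates per unit compute than the default schedule — and the
agreement-pattern check on a 7-subject corpus at the default schedule. The
acceptance
script runs the combing-hair corpus at the full 13-subject, 3-trial scale
with the pinned training schedule (200 epochs), and the remaining three
tasks at reduced cohorts (10 subjects for the back-pocket task, whose elbow
endpoints vary most between subjects; 7 for the other two); per-fold
training costs roughly half a minute, so the whole script completes in well
under half an hour. All runs are deterministic given their seeds.

## Known limitations

- The generator's error model is a stand-in: its contract is calibratable
  magnitude and learnability, not fidelity to any particular sensor.
- Only the right arm is modeled; scapula/clavicle kinematics, wrist angles
  and pathological movement patterns are out of scope.
- The gimbal-lock tie-break (IE zeroed within 1 degree of |AA| = 90) is a
  deterministic convention; tasks in this package never approach it.
- The CMC variant and the UWA sign conventions are documented package
  conventions where the source descriptions are verbal.
- Elbow varus/valgus and forearm axial rotation are computed by the marker
  model but excluded from the 4-channel waveform and from evaluation.
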