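---
title: "Analyzing transcription-licensing conflicts on flow-stretched DNA"
author: "kymolyze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing transcription-licensing conflicts on flow-stretched DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymolyze)
```

## The measurement

In single-molecule TIRF experiments on flow-stretched DNA, a 21-kb linear
substrate is tethered to a coverslip and extended by buffer flow so that
genomic position maps onto image position. Fluorescently labeled proteins —
T7 RNA polymerase initiating at a promoter 2.9 kb from the tethered end, and
origin-licensing factors (ORC, the ORC–Cdc6–Cdt1–MCM "OCCM" intermediate,
or loaded MCM2-7 double hexamers) bound around the ARS1 origin at 5.5 kb —
appear as diffraction-limited spots whose position and brightness are
followed over minutes. Reducing each molecule's movie to a kymograph
(position × time intensity matrix) turns the biology into a set of
trajectory-analysis problems:

* How fast does the polymerase transcribe, and how often does it pause?
* What happens when it collides with a protein roadblock — push, bypass,
  pause, stall, or ejection of one of the two molecules?
* Does a displaced licensing factor stay near the terminator, dissociate,
  or slide back?
* How mobile is a sliding MCM double hexamer (diffusion coefficient), and
  how many labeled subunits does a focus contain (photobleaching steps)?

`kymolyze` implements this pipeline — tracking, kinetic change-point
segmentation, transcription and pause statistics, collision-outcome and
terminator-stability classification, diffusion and stoichiometry
estimation — together with a synthetic-data generator whose named condition
presets carry the published kinetic constants, so that every stage can be
validated end to end against known ground truth without the raw videos.

## The synthetic-data generator

`simulateTranscriptionTrace()` draws a per-molecule burst velocity from
$\mathcal{N}(\mu_v, \sigma_v)$ truncated to positive values ($\mu_v = 57.0$,
$\sigma_v = 5.7$ nt/s for the ATP preset; $30.4 \pm 2.8$ nt/s for
ATP$\gamma$S). Velocity variability is modeled *between* molecules, not
within one molecule, matching the Gaussian spread of per-molecule rate
distributions. Pauses are a Poisson process in transcribed distance; each
pause is permanent with probability 0.6 (40% recovery), and a transient
pause lasts

$$ d = 20\,\mathrm{s} + \mathrm{Exp}(126.1\,\mathrm{s}), $$

so that pauses surviving the > 20 s detection rule have mean 146.1 s. Only
the detected mean is published; the offset/excess decomposition is the
generator's model of it. The pause initiation rate is not published either;
the default 0.03 events/kb gives roughly a 40% chance of at least one pause
over a full-length run, consistent with the reported pause behavior. On
terminator-bearing substrates the trace arrests permanently at 13.4 kb with
probability 0.95. Gaussian localization noise (default SD 0.05 kb) is added
per frame at the default 5-s frame interval (0.5 s for the fast
sliding/bleaching modes).

`simulateCollisionEvent()` samples one of six outcomes (push, bypass,
pause, stall, roadblock ejection, pusher ejection) from the preset's
probabilities and realizes it kinematically around the encounter point.
Only some outcome fractions are published per condition (e.g. 21.5% bypass
and ~17% ejection for ORC; 1.4/3.5/13.8% pause/stall/RNAP-ejection for MCM
double hexamers; 6.6/23.2% for OCCM); the remaining probability mass is
allocated to pushing, which dominates every condition. Ejection is realized
as the molecule's intensity falling to background permanently — on real
data photobleaching could mimic this, which the experiment excludes via
long dye lifetimes and which the generator exposes only through the truth
record.

Diffusive traces are 1-D Gaussian random walks with per-step variance
$2 D \Delta t$; with a layout supplied the walk reflects at the DNA ends,
and by default it is unbounded — the sliding analysis extrapolates the MSD
at small lags, which boundary saturation would otherwise bias. Bleaching
traces give each fluorophore an independent geometric lifetime with
per-frame survival $0.5^{1/b}$ ($b$ = 290 frames for LD555, 150 for LD655).
`renderKymograph()` paints trajectories as 1-D Gaussians (integrated area =
intensity) on a constant background with optional Poisson shot noise, using
a default pixel scale of 0.175 kb/px (21 kb across 120 px); the true
calibration is instrument-specific and configurable.

What the generator does *not* emulate: torque and supercoiling, the RNA
product, nucleosome substates, spectral cross-talk, EMCCD gain statistics,
or tracking failures on crowded fields. Passing recovery tests therefore
demonstrates that the analysis is unbiased under the model's assumptions —
piecewise-constant velocities, Gaussian localization noise, ideal outcome
kinematics — not that it is robust to every artifact of real videos.

## Kinetic change-point segmentation

Position-vs-time traces are decomposed into piecewise-linear segments (and
intensity traces into constant steps) by exact penalized least squares:
among all partitions whose segments span at least `minSegment` frames
(default 3), the fit minimizes

$$ \sum_k \mathrm{RSS}_k \;+\; \beta \cdot \#\{\text{segments}\}, \qquad
   \beta = \text{penalty} \times k_p \ln(n) \, \hat\sigma^2, $$

computed by dynamic programming with O(1) per-segment residuals from
prefix sums. This is the Bayesian information criterion under Gaussian
noise: a split is part of the optimum iff it lowers the BIC. The complexity
charge $k_p$ counts the new segment's parameters plus $3/2$ for the
estimated change-point location (the modified-BIC convention for
change-point models), i.e. $k_p = 3.5$ for line segments and $2.5$ for
steps. The noise variance $\hat\sigma^2$ is estimated robustly from the
trace's first differences (MAD × 1.4826, squared, halved), which is
insensitive to the slope itself; a floor of $10^{-12}$ keeps noiseless
traces well-defined. An exhaustive-search variant is used in the test
suite as an independent oracle: on noiseless traces with up to three
change points the dynamic program recovers the exact minimum-RSS
breakpoints, which a greedy binary-splitting search cannot guarantee.

Interior segment boundaries are placed midway between the flanking samples,
so segment durations are unbiased estimates of the underlying dwell times
(assigning boundaries to sample times would shorten every pause by about
one frame). Slopes are reported in nt/s (1 kb = 1000 nt) with their
least-squares standard errors; traces shorter than `2 * minSegment` frames
yield a single-segment table rather than an error.

## Transcription statistics

The analysis rules live in one `analysisConfig()` object:

| rule | default | role |
|---|---|---|
| `sdFilter` | 10 nt/s | drop poorly fitted segments (slope SE above this) |
| `negativeRateFloor` | −10 nt/s | drop backward-sloping artifacts |
| `pauseFold` | 3 | pause = > 3-fold reduced velocity vs non-pause mean |
| `pauseMinDuration` | 20 s | counted pauses must exceed this |
| `pausePositionMax` | 19 kb | pauses past this are end-of-DNA artifacts |
| `approachThreshold` | 0.5 kb | distance defining a collision |
| `exclusionSeparation` | 1 kb | minimum starting separation of a pair |
| `pushThreshold` | 2 kb | roadblock displacement separating push/non-push |
| `bypassTranscriptionMin` | 4 kb | pusher advance past the roadblock for bypass |
| `terminatorRegion` | 12–15 kb | where terminator arrest is scored |
| `stabilityMinTime`, `stabilityWindow` | 120 s, 2 kb | dissociate/remain/slide-back rules |
| `bootstrapCycles` | 10,000 | resamples for SEMs |

Pause classification iterates to a fixed point: starting from no pauses,
the *time-weighted* mean slope of non-pause segments is computed and every
segment at least `pauseFold`-fold slower is marked; the mean is recomputed
until labels stabilize. The pause set can only grow, so at most one
iteration per segment is needed. Whether the reference mean is
time-weighted is not specified in the source analysis; the time-weighted
form matches the burst-rate weighting and is the default, with a flag for
the unweighted mean. The burst rate is the time-weighted average slope of
retained non-pause segments, which makes it invariant under subdividing any
non-pause segment. A pause's position is its segment midpoint (start vs
midpoint is unspecified upstream; the difference is sub-frame). A pause
segment reaching the final frame is permanent even if short, a deliberate
censoring convention.

Two ensemble-level conventions deserve note. First, molecules whose
maximum displacement from the loading site stays under 2 kb never entered
processive transcription — they are stalled complexes that failed to
restart — and contribute no burst rate (`minTranscribedKb` in
`burstRateEnsemble()`); fitting a "rate" to a flat trace would only inject
zeros into the velocity distribution. Second, termination efficiency is
scored among molecules that actually reach the terminator region:
terminated (final permanent arrest inside 12–15 kb) versus escaped
(transcribed past 15 kb). Molecules permanently paused upstream never
probe the terminator and are uninformative about it.

The rate distribution summary is a maximum-likelihood Gaussian fit (sample
mean and ML standard deviation of the raw rates) — bin-free and
deterministic, where histogram curve-fitting would depend on binning.

## Collision outcomes

`detectCollision()` excludes pairs starting closer than 1 kb and sets the
approach time at the first frame with separation below 0.5 kb.
`classifyOutcome()` then applies, in order: roadblock ejection, pusher
ejection (signal loss with roadblock displacement $d < 2$ kb), pause
($d > 2$ kb with a transient pusher pause starting within 2 kb of the
collision site), push ($d > 2$ kb), bypass ($d < 2$ kb, pusher advances
> 4 kb past the collision), stall ($d < 2$ kb with a permanent pusher
pause). Ejection is checked first so that an ejected molecule's residual
drift cannot masquerade as bypass. "Loss of protein signal" is an intensity
run below half the initial level for at least three consecutive frames
persisting to the trace end — the persistence requirement separates
ejection from blinking; the original analysis relied on manual inspection
here. The "> 4 kb transcription" bypass rule is interpreted as advance past
the collision position (not total transcription), with a flag to switch.
Pushed distance is the maximum detected position minus the loading site
(initial position), so a molecule that is pushed and then slides back still
reports its full excursion. Copy numbers are
`round(intensity / unit intensity)` with a floor of one for any detected
focus.

## Diffusion, variance, bootstrap, KDE

The time-averaged MSD uses all sample pairs at each lag; the diffusion
coefficient is half the slope of a least-squares line through the origin
over the first 4 lags, the 1-D relation $\mathrm{MSD}(\tau) = 2 D \tau$.
Four lags keeps the fit in the linear, low-noise regime; a
localization-noise intercept correction exists but is off by default since
the origin-constrained form matches the published $D = \langle x^2 \rangle
/ 2t$ convention. Negative fitted slopes clamp to $D = 0$ with a flag.
Population variance uses the $N$ divisor, $\sigma^2 = \sum (x_i - \mu)^2 /
N$ — the convention printed with the transverse-fluctuation analysis, where
DNA-tethered molecules show ~0.156 px² against ~0.015 px² for surface-stuck
ones. Bootstrap SEMs resample with replacement 10,000 times under a fixed
seed. KDEs of binding positions use a Gaussian kernel with Silverman's
bandwidth by default (the source bandwidth is unpublished) and are
renormalized to integrate to one over the 0–21 kb grid.

## Numerical and validation choices

All randomness flows through per-call seeds on an isolated RNG stream, so
generators are bit-reproducible and never perturb the caller's RNG state.
Linking ties break deterministically by smaller position; segmentation is
deterministic for fixed input. Degenerate inputs (all-excluded segment
tables, zero-variance rate sets, non-bleaching count curves, negative MSD
slopes) return flagged results rather than errors wherever an ensemble
analysis must continue past them.

The validation suite sizes ensembles to desk scale: 200 molecules for the
rate recoveries, 100 walks for diffusion, ensembles accumulated until at
least 300 transient pauses for the pause-duration recovery, 1,000 dyes for
the half-life fit, 2,000 events for the bypass fraction, and 500 molecules
for termination — large enough that two standard errors of the ensemble
mean resolve the published constants, small enough to run in seconds to a
couple of minutes each.

```{r demo}
ens <- simulateTranscriptionEnsemble(kymoPreset("ATP"), n = 40, seed = 1)
bre <- burstRateEnsemble(ens$trajectories)
fitRateDistribution(bre$rates[is.finite(bre$rates)])[c("gaussMean",
                                                       "gaussSd", "n")]
```

## Known limitations

Tracking is 1-D (kymographs), not full 2-D video tracking; channel
registration and DNA-stain overlay are out of scope, and pre-tracked
trajectory tables are accepted instead. The greedy nearest-neighbor linker
is adequate for sparse kymographs but will swap identities when molecules
cross at similar intensities. The collision classifier assumes one leading
roadblock per encounter; trains of roadblocks are handled as ordered
independent events. The exact acceptance statistic of the original
confidence-based change-point method is not reproduced; equivalence is
asserted at the level of recovered kinetics (rates, pause durations,
breakpoint accuracy), not breakpoint-for-breakpoint against that software.
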