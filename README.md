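# kymolyze

Single-molecule kymograph analysis of encounters between transcribing RNA
polymerase and origin-licensing factors (ORC, OCCM, MCM2-7 double hexamers)
on flow-stretched DNA.

In these TIRF experiments a 21-kb DNA is tethered to a coverslip and
stretched by flow, so a labeled protein's genomic position becomes an image
coordinate and each molecule's movie reduces to a kymograph (position ×
time matrix). `kymolyze` turns kymographs — or pre-tracked trajectory
tables — into the quantities that describe transcription–licensing
conflicts:

* **Tracking** — beam-profile flattening, subpixel 1-D Gaussian peak
  localization with annulus background subtraction (inner 2 px, outer
  4 px), greedy nearest-neighbor linking, fiducial-based drift correction,
  and dye-survival fits `y = a·0.5^(x/b)`.
* **Kinetic change-point segmentation** — exact penalized least-squares
  decomposition of position traces into linear segments (velocities in
  nt/s with standard errors) and intensity traces into photobleaching
  steps, via dynamic programming with a modified-BIC complexity penalty.
* **Transcription statistics** — segment quality filters (slope SE
  > 10 nt/s or rate < −10 nt/s excluded), iterative 3-fold pause
  classification, time-weighted burst rates
  `Σ(duration·slope)/Σ(duration)`, pause probability / recovery /
  durations (> 20 s, up to 19 kb), and maximum-likelihood Gaussian rate
  fits.
* **Collision outcomes** — the five-way displacement taxonomy (push
  > 2 kb; bypass < 2 kb with > 4 kb advance; pause; stall; ejection of
  either molecule), pushed distances, copy numbers from intensity, and
  dissociate / remain / slide-back stability calls at the terminator
  (120 s / 2 kb rules in the 12–15 kb region).
* **Statistics** — time-averaged MSD with `D = ⟨x²⟩/2t` from an
  origin-constrained fit, population variance `σ² = Σ(xᵢ−μ)²/N`,
  10,000-cycle bootstrap SEMs, Pearson correlation, and Gaussian-kernel
  densities of binding positions.
* **Synthetic data** — a generator with named condition presets carrying
  the published kinetic constants (`ATP` 57.0 ± 5.7 nt/s, `ATPgS`
  30.4 ± 2.8 nt/s, `MCM_sliding` D = 19.4 kbp²/s, collision presets with
  the published outcome fractions, `terminator` 95% arrest, dye half-lives
  290/150 frames), per-molecule ground truth, and Gaussian-spot kymograph
  rendering, so the whole pipeline is testable end to end.

## Worked example

Simulate an ATP-condition ensemble, run segmentation → filtering → pause
classification → burst rates, and summarize:

```r
library(kymolyze)

ens <- simulateTranscriptionEnsemble(kymoPreset("ATP"), n = 100, seed = 42)
bre <- burstRateEnsemble(ens$trajectories)
rates <- bre$rates[is.finite(bre$rates)]

fit <- fitRateDistribution(rates)
sprintf("Burst rate: %.1f +/- %.1f nt/s (n = %d)",
        fit$gaussMean, fit$gaussSd, fit$n)
#> "Burst rate: 56.3 +/- 5.8 nt/s (n = 97)"

bootstrapSem(rates, seed = 42)$sem
#> 0.60  (nt/s)

ps <- pauseStatistics(bre$tables)
c(ps$pauseProbability, ps$recoveryFraction)
#> 0.40 0.38
```

The Gaussian-fit mean recovers the preset's 57.0 nt/s within sampling
error; three molecules arrested before transcribing 2 kb and contribute no
rate (n = 97). The pause probability (fraction of molecules with a counted
pause > 20 s before 19 kb) and the ~40% recovery fraction reflect the
preset's pause model.

A collision event, simulated and classified:

```r
sim <- simulateCollisionEvent(kymoPreset("MCMDH_collision"), seed = 7)
classifyCollisionEnsemble(list(sim))[, c("outcome", "pushedDistance")]
#>   outcome pushedDistance
#> 1    push       15.5
```

A command-line wrapper is installed at
`system.file("exec", "kymolyze", package = "kymolyze")` with subcommands
`simulate`, `track`, `segment`, `transcription`, and `demo`.

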