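# entrainr

Phase entrainment analysis for finger tapping under amplitude-modulated
background noise.

## The problem

Humans synchronize movement to rhythms they can hear — but do they also
entrain to rhythms they cannot consciously detect? A way to ask this in the
lab is to have people tap at their own pace (or produce single spontaneous
taps) while faint background noise is modulated either periodically at the
tapper's own rate ("near"), periodically at 1.5 times that rate ("far"), or
aperiodically ("baseline"), and then test whether tap times cluster at
particular phases of the modulation. Entrainment in the physicist's sense
predicts phase locking only in the near condition.

`entrainr` provides the full toolchain for this design, with no dependence
on any particular data set:

- **Stimulus synthesis** — signed unit spikes emitted per sample with a
  probability that oscillates between 0.05 and 0.1 (22050 Hz), spectrally
  softened to 1/f^1.5, with the ground-truth instantaneous phase of the
  modulation envelope exposed. Aperiodic baseline envelopes are random
  pulse trains with Poisson(λ = 1) inter-pulse intervals.
- **A generative tapping model** — a phase-correction tapper
  (`t[n+1] = t[n] + μ + ε[n] − (κμ/360)·wrap(φ(t[n]) − ψ)`) with
  controllable coupling strength, plus the realism features of un-paced
  tapping (tempo wander, rate drift, attentional pauses) needed for an
  honest null model. Single-tap trials with optional phase bias are also
  supported.
- **Circular statistics** — Rao's spacing test of uniformity. For sorted
  angles with arc spacings `T_i` (including the wrap-around arc),

      U = 1/2 · Σ |T_i − 360/n|

  in degrees. `U = 0` for perfectly even spacings and `360(n−1)/n` when
  all angles coincide; large U rejects uniformity. U is used as a
  per-block non-uniformity index of tap phases, calibrated by Monte Carlo
  simulation (with a precomputed quantile table as a cross-check).
- **Inference pipeline** — per-block U-values; 2.5 × IQR outlier exclusion
  at block and subject level; block-averaged, rank-transformed U as the
  response of a linear mixed model (condition fixed, subject random,
  likelihood-ratio tested, Satterthwaite F as a secondary readout); paired
  permutation contrasts (5000 label shuffles within subject) between each
  condition and baseline; and a mini-block time-course analysis (10
  contiguous segments of 10% of taps each).
- **Surrogate control** — per block, 1000 surrogate tap sequences drawn
  from a distribution with the block's interval mean and variance, to
  separate genuine phase correction from the phase consistency that mere
  frequency matching produces.

## Worked example

Simulate a 12-subject cohort whose tappers phase-couple only when the
modulation matches their rate (κ = 0.8 in near, 0 elsewhere), then run the
full analysis:

```r
library(entrainr)

cfg <- session_config(n_subjects = 12, blocks_per_condition = 2,
                      kappa = c(near = 0.8), seed = 42)
cohort <- simulate_cohort(cfg)
fit <- entrain_fit(cohort$taps, cohort$envelopes,
                   n_iter = 5000, seed = 42, n_miniblocks = 10)
fit
```

```
Entrainment analysis fit
  12 subjects, 72 blocks (0 excluded), 5277 taps
  baseline  mean U =  129.45 deg (n = 12 subjects)
  far       mean U =  132.15 deg (n = 12 subjects)
  near      mean U =  191.29 deg (n = 12 subjects)
  condition effect (LRT): chisq = 40.53, p = 1.584e-09
  far - baseline: diff = 2.70 deg, permutation p = 0.5925
  near - baseline: diff = 61.84 deg, permutation p = 0.0012
```

The fit reproduces the entrainment signature: tap phases are strongly
non-uniform in the near condition (mean U 191° against a uniform-null
expectation of about 132°), while far and baseline are indistinguishable —
coupling dies when the stimulus frequency is 1.5 times the tapper's own.
`summary(fit)` adds the Satterthwaite F table and the mini-block test
(here `p = 0.54`: entrainment is stationary over the block, as expected
for a time-invariant coupling). `plot(fit)` draws the per-condition
boxplot of subject mean U-values.

The surrogate control distinguishes this from frequency matching:

```r
env <- make_envelope(envelope_spec("sine", frequency = 1/0.694,
                                   duration = 60, sample_rate = 500))
tp  <- tapper(0.694, sigma = 0.07, kappa = 0.8, psi = 45)
blk <- simulate_rhythmic_block(tp, env, 60, seed = 1)
monte_carlo_block_U(blk, env, n_sim = 1000, seed = 2)
```

A phase-corrected block sits above the 95th percentile of its surrogate U
distribution; a metronomically regular but uncoupled tapper does not.

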