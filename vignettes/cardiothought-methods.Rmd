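---
title: "Methods: event-locked cardiac reactivity and thought-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked cardiac reactivity and thought-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Does a covert perturbation of the heartbeat change what people think about,
and does the answer depend on how accurately they perceive their own
heartbeat? `cardiothought` implements the full analysis chain for a paradigm
that probes this question: participants perform a heartbeat counting task
(HCT) that quantifies interoceptive accuracy, then a long vigilance task
during which (a) their pulse is recorded, (b) sub-threshold vibration pulses
are delivered in some trials to nudge heart rate without awareness, and (c)
randomly timed thought probes sample what they were just thinking
(categories 1 task-focused, 2 task-relevant, 3 peripheral stimuli,
4 internal-body states, 5 task-unrelated/self-referential, 6
absent-mindedness, plus contemplation and consistency ratings).

The package covers five analysis stages plus a synthetic-data generator and a
pipeline orchestrator:

1. **Interoception scoring.** HCT error rate
   $\frac{1}{n}\sum_i |a_i - r_i| / a_i \times 100$ over the $n = 6$ counting
   intervals (actual $a_i$, reported $r_i$), analogously for the time
   estimation task (TET), and the HCT-TET Pearson correlation as a check that
   heartbeat counting is not time-based guessing. The divisor is the number
   of intervals actually scored, with a warning when it is not 6, so partial
   sessions degrade loudly rather than silently. Reports above 100% error are
   kept as the formula produces them.
2. **Event-locked cardiac reactivity.** RR intervals (successive pulse-apex
   differences, ms, plausibility-filtered to 250-3000 ms) are windowed from
   5 s before to 10 s after each vibration onset (onsets at 15 s and 30 s of
   a trial, i.e. trial spans 10-25 s and 25-40 s). RR0 is the last interval
   ending at or before the onset — an interval ending exactly at the onset
   counts as RR0, a tie rule fixed for reproducibility — and RR1-RR4 are the
   next four. Change points in mean and variance are detected per window, and
   the *heart-rate change rate* is the percentage of RR1-RR3 slots carrying a
   change point: $\text{hits} / (3 \times 10) \times 100$ per condition
   (vibration trials vs the non-vibration trials immediately preceding them;
   the denominator is fixed at the design's 10 windows even when a window is
   incomplete, which then simply contributes no hits).
3. **Thought-state coding.** Within each 20-trial block: continuations
   (same category on adjacent trials) for categories 1, 2, 4, 5;
   transitions anchored on category 1, grouped (1↔{2,4,5} as a single
   mind-wandering state) and per category; and, among category-5 reports,
   counts of high contemplation (rating 2-3) and high consistency (rating 1).
   Pairs touching category 3 (too rarely reported) or 6 (no verbal content)
   are dropped, and an excluded category never bridges a pair: the sequence
   1, 6, 1 yields no continuation. The pair spanning the between-block break
   is never counted.
4. **Frequency-domain HRV.** Per block, the RR series of the final 3/4 of
   the block (closed on the left) is cubic-spline resampled at 4 Hz,
   detrended with a smoothness-priors (regularized second-difference) trend,
   and Welch-estimated (256-sample Hann segments, 50% overlap). VLF
   (0.003-0.04 Hz), LF (0.04-0.15 Hz), HF (0.15-0.4 Hz) powers are PSD
   integrals; LF/HF is their ratio.
5. **Inference.** Bayesian hierarchical regressions via JAGS: Gaussian
   (identity link) for the change rate and the HRV indices, Poisson (log
   link) for thought counts, always with a participant random intercept.
   Four chains of 2000 iterations (1000 warm-up, thinning 1) give 4000
   retained draws; summaries report the posterior mean, SD, equal-tailed 95%
   interval, split-chain $\hat R$ (converged at $\hat R \le 1.1$), and
   bulk/tail effective sample sizes (bulk on rank-normalized draws, tail as
   the smaller ESS of the 5%/95% tail indicators). A covariate is read as
   supported when its 95% interval excludes 0.

## Participant exclusions

A participant is dropped when any of four rules fires: they noticed the
vibration; they responded correctly on no more than half of the trials
("more than half" is read strictly, so exactly 50% correct is excluded);
they never reported any of categories 1, 2, 4, 5 across the whole task; or
their pulse record is unusable. With the generator's default composition
(9% noticed, 3% low-response, 6% no core categories, 2% bad pulse, allocated
to disjoint participants) a 100-participant cohort retains exactly 80.

## The change-point engine

The change-rate statistic needs a segmentation of ~15-20 RR intervals per
window under a Normal cost with unknown mean **and** variance per segment:
segment cost $m(\log 2\pi + \log\hat\sigma^2 + 1)$, minimum segment length 2
(so each segment's variance is estimable), penalized per change point. The
default penalty is the modified BIC: $(p+1)\log n$ per change point with
$p = 2$, plus $\log m$ per segment. The optimizer is optimal partitioning —
a quadratic dynamic program that returns the exact optimum, verified in the
test suite against brute-force enumeration of every admissible change-point
set on hundreds of random windows. RR values are carried in milliseconds
throughout, but segmentations are invariant to rescaling (the variance terms
shift every candidate equally).

Two properties of this cost are worth knowing. First, a "change point at
RRk" means the first index of a new segment falls at the position labelled
RRk. Second, on pure noise the mean+variance cost with minimum segment
length 2 splits off short low-variance runs fairly often; at window length
15 roughly half of i.i.d. windows contain some change point. That is not a
defect of the optimizer (the brute-force optimum does the same) but a
property of the cost/penalty combination, and it is why the *baseline*
change rate on undisturbed data sits near 10-15% of RR1-3 slots rather than
near zero — consistent with the intercepts this kind of analysis reports.
The vibration effect is therefore always assessed as a contrast against the
matched non-vibration trials, never as an absolute rate.

## The synthetic cohort generator

No raw data from this paradigm is publicly available, so the generator is a
first-class module: it emulates every input of the analysis and plants known
effects so the whole chain is testable end to end.

* **RR process.** Apex times integrate RR(t) = participant mean RR + LF
  sinusoid (0.1 Hz) + HF sinusoid (0.25 Hz) + white noise. Defaults: mean
  850 ms (between-participant SD 60 ms), amplitudes 15 ms each and noise
  8 ms, giving LF and HF band powers near 112 ms² and LF/HF near 1 — within
  normative resting ranges. Amplitudes carry a participant-level lognormal
  spread (log-SD 0.3) and a per-block lognormal jitter (log-SD 0.2): real
  cohorts differ widely in HRV and autonomic tone drifts within a session,
  and without these terms the band-power residuals of the Gaussian HRV
  models would consist almost entirely of periodogram estimation artifacts,
  which is both unrealistic and heavy-tailed. Sinusoids-plus-noise rather
  than a full cardiovascular model keeps every band power known in closed
  form.
* **Vibration effect.** Each onset in a vibration trial triggers, with
  probability `p_vibration_cp` (default 0.6), a mean step of `step_mean_ms`
  (default 80 ms) on the first interval ending after the onset, decaying
  with multipliers 1, 2/3, 1/3, 0 across RR1-RR4 — a transient that has
  settled by RR4, which is what motivates scoring RR1-RR3 only. Spontaneous
  steps of the same shape and random sign occur in any analysis window with
  probability `p_spontaneous_cp` (default 0.1). The step size is about 10%
  of baseline RR and five SDs of the beat noise: large enough that the
  segmentation can resolve it, small enough that detection stays imperfect
  (~50-70% per window), which keeps the vibration/non-vibration contrast at
  a realistic handful of percentage points rather than saturating.
* **HCT/TET.** Six counting intervals (25, 25, 35, 35, 45, 45 s, randomized
  order; 210 s total) with actual counts from the participant's resting RR
  and reported counts `actual × latent_accuracy + noise`, rounded half-up
  (verbal counts are integers) and floored at 0; latent accuracy is a
  moment-matched Beta with cohort mean 0.593 and SD 0.23, so the implied
  error rates match the published cohort mean (~41%, SD ~23). TET intervals
  (23, 23, 49, 49, 56, 56 s) are reported through a multiplicative bias
  drawn independently of latent accuracy, making the HCT-TET correlation
  near zero by construction.
* **Thought reports.** Categories follow a participant-level first-order
  Markov chain started at its stationary distribution. From any non-5 state
  the next category follows base weights (category 3 gets 3% mass,
  mirroring how rarely peripheral-stimulus thoughts are reported); the
  5→5 return probability $q$ is chosen in closed form so that the expected
  number of 5-5 continuations per block equals
  $\exp(b_0 + b_s\,\text{score} + b_v\,\text{vib} +
  b_{sv}\,\text{score}\cdot\text{vib} + u)$ — i.e. the planted coefficients
  live on the log-expected-count scale of the Poisson analysis model, making
  parameter recovery well-posed. With stationary category-5 mass
  $\pi_5(q) = w_5/(1-q+w_5)$ and 19 adjacent pairs per block,
  $q = \mu(1+w_5)/(19 w_5 + \mu)$. Defaults plant intercept $-0.240$, score
  $0.007$, vibration $1.387$, interaction $-0.020$ (so more accurate
  perceivers continue self-referential thought more under vibration), and an
  analogous structure drives the high-contemplation probability of
  category-5 rows. Category-6 rows carry no contemplation/consistency, as
  the follow-up probes are not shown for them. The paradigm's distributional
  details beyond these constraints are free parameters chosen once.
* **Determinism.** Every participant gets a stream seed derived from
  (master seed, index); the same configuration reproduces byte-identical
  cohorts, and each artifact passes the corresponding reader's validation.

What the generator does **not** emulate: realistic pulse-wave morphology
(apex times suffice; a toy raised-cosine waveform exists only to exercise
apex detection), ectopic beats and measurement artifacts beyond the RR
plausibility filter, reaction times, 1/f broadband HRV structure, and any
dependence of thought dynamics on time-on-task. Tests passing on synthetic
cohorts therefore demonstrate that the *pipeline* is correct and that
effects of the planted kind are recoverable — not that the paradigm's
empirical findings generalize.

## Priors, sampler, and two ambiguities

Slope weights have Normal(0, 3) priors; the intercept is Student-t(3, 0,
2.5); random-intercept and residual SDs are half-Student-t(3, 0, 2.5). Two
conventions in the source literature are contradictory and resolved here
explicitly: slopes are sometimes described as "Cauchy" while written as
N(0, 3) — the written Normal form is the default and a Cauchy(0, 3) variant
is switchable (`prior_slopes = "cauchy"`); and "Poisson with a logit link"
is treated as the canonical log link, since a logit link is undefined for an
unbounded count mean. The sampler description "1000 burn-in and 2000
additional samples ... resulting in 1000 posterior samples per chain" is
read as 2000 total iterations per chain with the first 1000 discarded. The
score covariate enters uncentered by default (`center_score` flips this);
the Gaussian change-rate model uses terms vibration + score + sex, the
thought-count models score + vibration + sex + score:vibration, the HRV
models vibration + sex.

## Numerical choices

* Segment variance is floored at $10^{-8}$ so constant segments have finite
  cost; a constant series yields zero change points.
* Welch segments shorten to the series length when a block is short; band
  powers integrate the one-sided PSD bin-wise (`sum * df`), which satisfies
  Parseval within a few percent for in-band signals.
* The smoothness-priors detrend solves a sparse
  $(I + \lambda^2 D_2^\top D_2)$ system ($\lambda = 500$ at 4 Hz), removing
  drift below ~0.03 Hz while leaving LF/HF nearly untouched.
* Apex detection uses local maxima above an adaptive threshold (median +
  half the distance to the 99th percentile) with a 250 ms refractory period.
* Exactly-at-boundary conventions: an RR interval ending at the vibration
  onset is RR0; an apex exactly at the final-3/4 boundary of a block is
  included in the HRV segment.

## Simulation study sizes

The test suite and the acceptance script size their simulation studies as
follows, chosen to make the Monte-Carlo checks stable: oracle equivalence on
500 random windows of length 8-15; the vibration/non-vibration change-rate
contrast on 20 cohorts of 20 participants; parameter recovery of the planted
interaction on 20 replicate cohorts of 80 participants with a reduced
sampler (2 chains × 500 retained draws after 500 warm-up); and the HRV null
calibration on 20 replicate cohorts of 80 participants. The null calibration
disables the event-locked step transients (`p_vibration_cp =
p_spontaneous_cp = 0`, `step_mean_ms = 0`): the planted vibration steps
occur only in the vibration block and are a real — if small — block
difference in spectral power, so "no planted block effect" requires
switching them off; with them on, the Gaussian HRV model correctly flags the
block difference, which is itself a useful positive control.

## Known limitations

* The Poisson models ignore overdispersion; the generator's counts are
  near-Poisson by construction, but real probe counts may not be.
* Continuation across an intervening excluded category (e.g. 1, 3, 1) is
  not counted; the opposite reading is defensible, and the choice matters
  for sequences rich in categories 3/6.
* The correct-response exclusion uses hits only; false alarms are not
  simulated or scored.
* Whether the two analysis windows of a trial should be segmented jointly is
  unknowable from the design; they are disjoint spans and are segmented
  separately.
* Gaussian models on HF power and LF/HF inherit the usual caveat that both
  are skewed; at cohort scale the coefficient posteriors are nevertheless
  well calibrated in the package's own null simulations.
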