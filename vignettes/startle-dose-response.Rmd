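---
title: "Quantifying acoustic startle reflexes and their dose-response thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acoustic startle reflexes and their dose-response thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startler)
```

## The measurement problem

The acoustic startle reflex is a rapid flexor-muscle flinch driven by an
oligo-synaptic brainstem arc. Two stimulus properties govern it: the level by
which the sound exceeds the hearing threshold (sensation level), and the rise
time of its onset. In aquatic animals the flinch can be measured directly with
a suction-cup triaxial accelerometer while calibrated hydrophones record the
received sound field. `startler` implements the full chain from raw
accelerometer and hydrophone records to startle thresholds, rise-time
thresholds and sensation levels, plus a synthetic-data generator that emulates
the whole experiment so that every stage is testable without animal data.

## Startle-magnitude metrics

Within a 1 s analysis window after stimulus onset (the window also used for
pseudorandom no-sound-control segments) two metrics are computed from the
2 Hz high-pass-filtered acceleration record **A**:

* **p-p VeDBA** — the per-axis peak-to-peak span, combined across axes as
  $\sqrt{x^2 + y^2 + z^2}$ (m s⁻²). The per-axis spans are taken
  independently; this is deliberately not $2\max\lVert A\rVert$.
* **maximum norm jerk** — per-axis first differences scaled by the sampling
  rate (m s⁻³), the Euclidean norm at each step, maximised over the window.

Both metrics are non-negative, invariant under axis permutation and sign
flips, and exactly linear in the amplitude of the motion. The high-pass is a
windowed-sinc FIR (Hamming window) whose order is chosen for a transition
band of at most 1 Hz around the 2 Hz cutoff (1057 taps at 320 Hz). It is
applied zero-phase by compensating the group delay, with reflection padding
at the edges, so that flinch latency (detected as the first norm-jerk sample
exceeding `k = 8` times the control-record jerk MAD) is preserved. Whether
the original analysis filtered causally or zero-phase is not knowable from
the filter name alone; both are defensible and the zero-phase variant is the
default because it does not bias latencies.

## Received levels

Sound pressure levels follow the calibration identity
$\mathrm{SPL} = |T_x| - \mathrm{Gain} + 20\log_{10} V$, with $|T_x|$ the
hydrophone voltage sensitivity at the nearest calibration frequency and $V$
the RMS amplitude. For short pulses the default RMS window is the central
90% cumulative-energy window (5%–95%); full-duration RMS is a flag, because
the averaging window of the original measurements is not stated. Levels at
the hydrophone are corrected to the animal's acoustic window assuming
spherical spreading, $+20\log_{10}(d_\mathrm{hyd}/d_\mathrm{ear})$, or by a
fixed per-animal offset. SEL is the discrete time integral of squared
pressure (dB re 1 µPa² s).

Stimuli are synthesized as band-filtered white noise — third-octave bands
around the test frequency, or a broadband pulse with −20 dB edges near 6.8
and 19 kHz — under a raised-cosine rise/plateau/fall envelope ("mild
tapering"; the window shape is a package choice, the stated rise and fall
times are honoured). The three rise-time variants (2/20/100 ms ramps with
136/118/38 ms plateaux) cannot simultaneously share an exact plateau RMS and
an exact SEL: with equal plateau RMS their energy-equivalent durations
(137.5/133/113 ms) spread the SELs by ~0.85 dB. Because the design calls for
both "the same plateau RMS" and "roughly the same SEL", the SEL-normalised
mode splits the difference, scaling each variant by half its measured SEL
mismatch so that both quantities agree within ±0.5 dB across variants.

Echolocation clicks are detected as amplitude peaks with a 2 ms dead time
and attributed to the stationing (focal) animal only if (1) the
projector-side peak exceeds the hoop-side peak by ≥ 30 dB, (2) the hoop
waveform has off-axis character — quantified as a −10 dB duration of at
least 40 µs, since "off-axis character" is qualitative — and (3) the
arrival-time difference matches the hoop/projector geometry within 0.2 ms.

## Dose-response models and thresholds

Startle magnitude is strictly positive and right-skewed, so gamma GLMs are
fitted with log or inverse links (identity added for rise-time data, where
the relationship can be linear); binary video scores use logistic
regression. Candidate models always contain the dose variable; playback
session (factor), a habituation covariate (trial number or its natural log,
never both), and the focal/other-animal echolocation factors are optional,
the latter two only when enough full sessions and focal clicks exist.
Selection is purely by AICc, $AIC + 2k(k+1)/(n-k-1)$, with $k$ counting the
gamma shape parameter; ties within 0.01 go to the smaller model;
non-significant variables are retained. Dispersion is the Pearson estimate.
Wald 95% intervals are $\beta \pm 1.96\,\mathrm{SE}$; p-values are Wald
(matching the interval method; a likelihood-ratio alternative was considered
and left out since the interval convention fixes the reporting scale).

Predictions are evaluated on a 0.1-step grid with other covariates held
fixed — trial at the intermediate value 6.5 when a habituation covariate is
in the model. Intervals are analytic t quantiles on the link scale
(back-transformed), with a seeded Monte-Carlo mode (sampling t deviates,
default 10⁴ draws) that converges to the analytic bounds and exists for
fidelity to interval construction "by sampling". When an inverse-link linear
predictor crosses zero inside the grid the affected grid points are dropped
and flagged rather than propagating a singular mean.

The startle threshold is the first grid RL whose fitted value exceeds the
no-sound-control baseline — pooled across sessions, or per session (and then
averaged) when session is retained. No threshold is reported when the dose
effect has p ≥ 0.05. The video threshold is the 50% point. The rise-time
threshold is the first grid rise time whose fitted value drops below the
baseline; since the crossing usually lies beyond the longest tested rise
time, extrapolation is allowed but flagged, capped at five times the largest
tested value. Sensation levels subtract a hearing threshold interpolated
linearly in log₂ frequency (audiograms are conventionally log-frequency;
linear-in-kHz is a flag). The threshold-versus-frequency trend is a gamma
GLM on frequency with the AICc-preferred of log/inverse links.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions: a gamma/log dose-response with a
9.4% increase per dB anchored at 60 m s⁻² p-p VeDBA at 160 dB re 1 µPa
(12.6%/dB anchored at 2400 m s⁻³ for jerk-calibrated runs, matching the
largest observed jerk), gamma shape 5, three sessions of twelve trials
following the staircase (−6 dB steps to trial 6, +3, then +6 dB steps from a
160 dB start), one no-sound control per session. Flinches are damped 15 Hz
sinusoids (100 ms decay) distributed over the three axes, with latency
200 ms at 130 dB shortening by 2 ms/dB to an 80 ms floor; their amplitude is
calibrated so the clean windowed metric equals the gamma draw. Baseline
records mix 0.05 m s⁻² sensor noise with slow spontaneous movement
(low-passed at 10 Hz, σ = 0.5 m s⁻² per axis) and a gravity offset on one
axis; samples clip at ±58.8 m s⁻² and clipped trials are flagged. The
movement component is what places the no-sound-control baseline at a few
m s⁻² and hence the generator-true threshold inside the tested RL range, as
in a staircase designed to straddle it. Rise-time sessions present the three
rise times in randomised order within a session — a blocked order would
confound rise time with trial number.

Two realities of this generator matter when reading test results. First,
windowed peak metrics are contaminated by the baseline process: near
threshold the flinch and the spontaneous movement are comparable, so
measured dose-response curves are lifted at low RLs and extracted thresholds
sit 1–3 dB below the closed-form crossing of the true curve with the true
baseline (more for jerk, whose baseline-to-flinch ratio is less favourable).
This is a property of the measurement itself, not of the estimator — fits to
the uncontaminated flinch metrics recover the crossing to within 0.1 dB.
Second, the movement noise is spectrally unlike the flinch (its jerk/VeDBA
ratio is about 31 s⁻¹ versus about 55 s⁻¹ for the flinch template), so the
VeDBA-true and jerk-true crossings of a common session differ by several dB;
real spontaneous movements, being muscle transients of the same family as
the flinch, do not show this separation. The generator also makes no attempt
at hydrodynamic realism, tag-attachment geometry, snapping-shrimp noise
spectra, or habituation dynamics beyond the log-trial mean effect, so
passing tests demonstrate correctness of the estimation chain under the
stated statistical structure, not robustness to every field condition.

Small-sample effects worth knowing: logistic slope estimates at n = 36 carry
the usual upward MLE bias (a mean recovered odds multiplier near 1.45 for a
true 1.385) and occasionally separate completely; separated fits are
detected by exploding Wald SEs or boundary fitted probabilities, flagged
non-converged and excluded from recovery summaries. Multiplicative
coefficients are summarised by the exponentiated mean of β (the geometric
mean), the natural average on the link scale. All-subsets AICc retains one
spurious covariate in roughly a fifth of small-sample replicates while
always keeping the true dose term, and log and identity links are close to
indistinguishable from three rise-time levels unless dispersion is very low
— both are properties of the selection criterion at these sample sizes, not
defects.

## Problem sizes

The test suite runs replicate simulations sized to the experiment (36-trial
threshold sessions, 24-trial rise-time sessions): 200 replicates for each
coefficient-recovery check and 50 for end-to-end threshold recovery, with
smaller fixed-seed batches (20–50) for selection-behaviour properties. The
acceptance script reruns the recovery simulations at 200 replicates per
target. Pseudo-R² (Nagelkerke) is computed from model and null deviances —
identical to the likelihood-ratio form for binomial models and well-defined
for gamma likelihoods above one.

## Known limitations

Audiogram interpolation refuses to extrapolate beyond the measured
frequency span. Identity-link gamma fits can fail to find admissible
starting values on pathological data; the fit retries from least-squares
starts and errors if fitted means are non-positive. The baseline-crossing
threshold definition is sensitive to the baseline estimate: five 1 s control
windows give it a standard error of a few tenths of a dB on the RL axis
under the default conditions. WAV I/O supports integer PCM (16/32-bit)
only.
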