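---
title: "Simulating closed-loop vocal and place conditioning in songbirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop vocal and place conditioning in songbirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchloop)
```

## The experiment this package simulates

Adult zebra finches do two things at once in a home cage: they sing, and they
move around. A closed-loop conditioning system can make a brief reinforcer
contingent on either behavior — on the pitch of one targeted harmonic
syllable, or on which of two perches the bird occupies — using one of two
stimuli: a 75 ms band-limited noise burst (1.5–8 kHz, the spectral range of
zebra finch song) or a 75 ms strobe-light flash. The striking empirical
finding such experiments produce is a double dissociation: noise is aversive
to the vocal system (birds shift pitch to escape it) yet *appetitive* to the
navigation system (birds seek the noisy perch), while strobe is aversive to
navigation but leaves song untouched. Each behavior-generating system is
shaped by its own reinforcement signal.

`finchloop` rebuilds that experiment entirely in software: two synthetic
agents (a vocal learner and a navigating place learner) are driven through
the same real-time machinery a hardware rig would use — amplitude-based
syllable segmentation, spectral-feature or inter-onset-interval targeting, a
6 ms FFT pitch measurement, a median-ratchet threshold, and exactly timed
stimulus delivery — and the behavioral read-outs are recovered from the
resulting logs by the same statistics one would apply to real data.

## The vocal agent and its calibration

Rendition pitches are Gaussian: $x_n \sim \mathcal{N}(\mu, \sigma)$ with
$\sigma = 25$ Hz by default, a typical rendition-to-rendition spread for a
harmonic-stack syllable fundamental in the 500–700 Hz range. Escape learning
is a per-hit mean shift: when a rendition falls on the penalized side of the
threshold $T$ (strictly below it, for the "drive pitch up" direction) and
the stimulus is noise, the mean moves away from the penalized region:

$$\mu \leftarrow \mu + s \cdot \mathbf{1}[x_n < T].$$

A strobe hit applies the same rule scaled by the visual coupling, which is 0
by default — that zero *is* the differential-valence wiring under study, and
makes the pitch distribution provably invariant to strobe feedback.

The threshold is initialized to the median pitch of the fifth baseline day
and thereafter ratchets: every 400 renditions (tumbling, non-overlapping
blocks) the block median replaces the threshold if and only if it has moved
in the direction of learning. Ties at the threshold escape.

**Calibrating the per-hit step.** The step $s$ is not a free dial; it is
derived from the daily shift the agent is asked to express. Because the
threshold trails the mean by roughly one day's shift $\Delta$, the hit
probability settles near $\Phi(-\Delta/\sigma) < \tfrac12$, so the naive
choice $s = 2\Delta/N$ undershoots by ~20%. `calibrate_vocal_step()`
instead iterates the deterministic mean-field dynamics of the closed loop —

$$\mu_{n+1} = \mu_n + s\,\Phi\!\left(\frac{T-\mu_n}{\sigma}\right),$$

with $T$ ratcheting to each block's mean-field median — and root-finds the
$s$ for which the expected mean consecutive-day change in daily mean pitch
equals the requested $\Delta$ (8.8 Hz/day for the noise condition). The
mean-field median of a block is taken as the mean of the drifting means,
exact for symmetric rendition noise and a within-day drift much smaller
than $\sigma$.

## The place agent and its calibration

The navigation agent chooses between two test perches by a softmax over
leaky valence accumulators $v_k$ (temperature $\tau$); bout and off-perch
durations are exponential. Each delivered stimulus on perch $k$ updates

$$v_k \leftarrow v_k + \eta\,(\rho - \lambda v_k),$$

where $\rho$ is the stimulus valence — positive for noise, negative for
strobe under the default wiring, both configurable. The fixed point is
$v^\ast = \rho/\lambda$, so the asymptotic probability of choosing the
stimulated perch is $\operatorname{logit}^{-1}(v^\ast/\tau)$. Landings that
deliver no stimulus decay that perch's value by a small extinction factor
(5% per landing by default); without extinction a contingency reversal
would drive both perches to the same fixed point and the preference would
equalize rather than flip.

**Decoupling landing rate from occupancy.** Empirically the two read-outs
differ (e.g. 81.3% of landings but only 73.7% of perch time on the
preferred perch under strobe avoidance). `calibrate_place_agent()` maps a
(landing, occupancy) pair onto the agent exactly: the valence is set from
the landing odds via the softmax fixed point, and the per-perch mean bout
durations are scaled by the ratio of occupancy odds to landing odds,

$$\frac{b_\text{pref}}{b_\text{other}} =
  \frac{p_\text{occ}/(1-p_\text{occ})}{p_\text{land}/(1-p_\text{land})},$$

so both asymptotic observables land on their targets simultaneously.

## The DSP path

*Syllables* are harmonic stacks: equal-amplitude (optionally rolled-off)
harmonics of a rendition-specific fundamental under a trapezoidal envelope,
band-limited below 8 kHz, sampled at 40 kHz. This captures exactly the
feature the pipeline measures — a pitch-bearing harmonic stack — and
nothing else of real song (no frequency modulation, no noise syllables, no
syntax). Passing tests therefore validate the machinery on clean stacks;
they do not certify performance on noisy field recordings.

*Segmentation* rectifies (DC removed), smooths with a 2 ms moving RMS, and
thresholds with hysteresis (offset at 0.8 x the onset threshold); gaps
under 8 ms merge, segments under 15 ms drop. *Feature matching* band-passes
the candidate segment with a zero-phase order-4 Butterworth filter and
tests the in-band power ratio. *IOI matching* is inclusive at its tolerance
boundary. The detection timestamp is the matched segment's offset in
spectral mode and the target's onset in IOI mode; the programmable
10–200 ms trigger delay then places the measurement window.

*Pitch* is measured on a 6 ms window (240 samples, ~167 Hz native
resolution): Hann window, x64 zero-padding, magnitude peak within a
one-harmonic search band, parabolic interpolation over the neighboring
bins, divided by the harmonic number. On clean stacks this is accurate to
well under 1 Hz, comfortably inside the 5 Hz contract; the limiting factor
in the closed loop is the agent's own 25 Hz rendition spread, not the
estimator.

*The noise burst* is synthesized in the frequency domain — in-band DFT bins
of the 75 ms record get unit-variance complex-Gaussian weights, out-of-band
bins are zero — so the burst is exactly band-limited (the >= 99% in-band
power contract holds by construction, where an order-4 IIR filter would
leak several percent across its transition bands). Sound level is digital:
the 88 dB calibration point maps to −20 dBFS RMS, a documented convention
since SPL is not realizable in software.

*Stimulus timing* follows the rig's contract exactly: perch stimuli start
1 ms after the beam-break landing and repeat with each inter-onset interval
drawn as $1/f$, $f \sim \mathcal{U}(1.75, 2.25)$ Hz (the "2 ± 0.25 Hz"
schedule read as deliberate per-interval jitter — the simplest reading; a
fixed 2 Hz with hardware tolerance is the noted alternative), with no onset
after departure. Pitch-triggered stimuli start a uniformly drawn 0–2 ms
after the 6 ms measurement window ends. A stimulus that begins before
departure may extend past it; truncation is deliberately not applied.

## The closed loop and its problem sizes

`run_session()` is event-driven at bout/rendition granularity rather than
streaming audio sample by sample: each rendition's stack is synthesized and
measured through the full DSP path, but silence between renditions is never
materialized. This keeps a 5-bird, 9-day pitch experiment (plus a 5-day
baseline, 400 renditions/day — the default study conditions) under a minute
of CPU, and it is the reason the detector is validated separately, on fully
synthesized song days with ground-truth logs, rather than inside the loop.

Default sizes used throughout the examples and checks: pitch experiments
use 5 birds x 4 contingency days x 400 renditions/day after a 5-day
baseline; perch-noise uses 5 birds x 3 days and perch-strobe 6 birds x 4
days (matching the respective group sizes and per-perch day counts of the
conditions they emulate), each with a 12 h lights-on window; bout structure
defaults to 30 s mean bouts and 30 s mean off-perch intervals, arbitrary
choices in the absence of published bout statistics and irrelevant to the
read-outs beyond giving each day a few hundred landings.

## Metrics and statistics

Landing rate and occupancy are count and time ratios over the two test
perches with lights-off clipped from every denominator; empty denominators
propagate as missing values, never zeros. The singing state runs from 1 s
of silence before a song onset to 1 s of silence after an offset, tiling
the lights-on day; perch bouts are apportioned to states by interval
intersection. Daily pitch change is the mean day-to-day difference of daily
mean pitch (differences across excluded days — those with fewer than 20
renditions — are divided by the day gap). The t tests delegate to
`stats::t.test` (constant input handled explicitly beforehand); the
two-way ANOVA fits `occupancy ~ condition * singing_state` with Type II
sums of squares, which tolerates the unbalanced bird-day tables these
experiments produce and reduces to the classical decomposition on balanced
ones.

## Seeding and reproducibility

Every generator is a pure function of (config, seed). One master seed per
session; per-bird, per-day and per-stream child seeds derive from it by a
portable 32-bit multiply-add hash (`derive_seed()`), so any single day can
be regenerated independently and a rerun of the same config reproduces all
logs bit for bit. All seeded code runs under `withr::with_seed`, leaving
the caller's RNG state untouched.

## Known limitations

- Song realism stops at harmonic stacks; detector performance on real,
  noisy recordings is out of scope.
- The learning rules are phenomenological. They reproduce the direction,
  magnitude and reversibility of the conditioned effects they are
  calibrated to, but make no claim about mechanism or about generalizing
  beyond the calibrated regime.
- The ANOVA's experimental unit is the bird-day, chosen to mirror the
  degrees of freedom such analyses report; bird-level aggregation is the
  conservative alternative.
- The 400-rendition threshold window is read as tumbling (non-overlapping);
  a sliding window is the plausible alternative reading and would update
  more often.
- Causality is simulated on recorded buffers; there are no real-time
  latency guarantees.
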