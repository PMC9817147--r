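---
title: "Measuring binaural hearing: stimuli, staircases, lateralization metrics, and normative deviation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring binaural hearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`binlat` implements the measurement and analysis machinery of a binaural
psychoacoustic test battery as used in clinical single-case research: two
headphone experiments (binaural tone-in-noise detection and lateralization
of interaural differences), the metric battery that quantifies a
lateralization session, and a normative framework that flags individual
listeners against a control group. Because clinical raw data are not part
of the package, a parametric virtual-listener module generates complete
simulated sessions with the same statistical structure, which makes every
analysis stage testable end-to-end.

This vignette explains the models and the choices behind them. It states
no empirical result that the package's test suite and
`scripts/acceptance.R` do not themselves compute.

## Stimuli

All stimuli are built at a 48-kHz sample rate from one-octave-wide
Gaussian noise with *arithmetic* centre frequency 500 Hz: the band runs
from 2/3 to 4/3 of the centre, i.e. 333.3–666.7 Hz (333 Hz bandwidth).
The arithmetic-centre convention (rather than the geometric 353.6–707.1 Hz
octave) is forced by the printed band edges of the protocol this package
implements. The noise is synthesised in the frequency domain: white
Gaussian noise is filtered with a brick-wall mask whose spectral edges are
raised-cosine flanks of 5 Hz width, a choice that keeps the band edges
sharp (out-of-band power is more than 40 dB down, which the test suite
verifies by direct spectral integration) without the ringing of an ideal
rectangle. Every generator is a pure function of its parameters and a
seed.

Calibration uses a fixed digital reference: a full-scale sine corresponds
to 100 dB SPL, stored per buffer as `level_ref` (dB SPL per unit RMS). For
a stereo buffer the level is defined on the mean of the per-channel
mean-square amplitudes, so a diotic signal measures the level of either
channel and an energy-preserving interaural level difference (ILD) leaves
the measured level unchanged.

Interaural cues follow one sign convention throughout: **positive favours
the right ear**, so the 9-key response scale (1 = left ear, 5 = centre,
9 = right ear) increases with the cue value. An ILD is imposed with the
constant-power gain split

$$g_L = \sqrt{\frac{2}{1 + 10^{ILD/10}}}, \qquad g_R = g_L\,10^{ILD/20},$$

which guarantees $g_L^2 + g_R^2 = 2$: the two-channel energy equals the
diotic presentation exactly (asserted to $10^{-12}$). An interaural time
difference (ITD) is realised as a whole-waveform fractional delay — a
frequency-domain phase ramp with zero-padding as an edge guard — applied
symmetrically (±ITD/2 per channel) to the *already gated* signal, so both
the envelope and the fine structure carry the ITD. Applying the delay
after gating matters for the ±1500-µs stimuli, whose perception rests
partly on envelope cues; whether one gates before or after the delay is
not dictated by the protocol, so the alternative order is available via
`gate_after_itd`. The symmetric split makes the channel-swap mirror
identity exact: swapping the channels of the +x stimulus reproduces the −x
stimulus sample for sample.

Tone-in-noise trials consist of three 500-ms noise bursts (20-ms
raised-cosine ramps, 60 dB SPL, fresh noise per interval) separated by
300-ms gaps; one interval adds a 420-ms, 500-Hz tone, ramped identically,
whose onset is 40 ms after the noise onset. In the N$_0$S$_0$ condition
the tone is interaurally in phase; in N$_0$S$_\pi$ the left-channel tone
is sign-inverted. Lateralization stimuli are 1-s tokens with 10-ms cosine
ramps at 70 dB SPL; the cue grid is ITD ∈ ±{200, 400, 600} µs plus the
supra-physiological ±1500 µs, ILD ∈ ±{4, 8, 12} dB, the diotic stimulus,
and monaural left/right presentation.

## Adaptive staircases

Two transformed up-down procedures are implemented. Audiometry uses
one-up one-down (50% convergence): steps of 20 dB, 10 dB after the second
reversal, 5 dB after the fourth; eight reversals, threshold = mean of the
last four. Tone-in-noise detection uses one-up three-down, which converges
to the level where $p^3 = 0.5$, i.e. $p = 0.5^{1/3} = 79.4\%$ correct:
steps of 4 dB until the second reversal then 2 dB, ten reversals,
threshold = mean of the last eight, tone level capped at 80 dB SPL.

Three semantics had to be fixed where a human protocol does not translate
directly into code:

* *Step schedule keying.* "After the second reversal" is read as: the new
  step size applies to movements following the completion of that
  reversal, including the movement away from the reversal point itself.
* *Reversals* are recorded at the extremal level where the movement
  direction changes.
* *Cap behaviour and invalidation.* A would-be increase beyond the cap
  clamps to the cap and counts one cap hit. The human protocol
  (re-instruct, then abandon) cannot be simulated; instead a track is
  invalid once the cap has been hit on 6 trials, or after 200 trials
  without completing its reversals. Both constants are configurable in
  `staircase_config()`.

The binaural masking level difference (BMLD) is the N$_0$S$_0$ threshold
minus the better (lower) of the two N$_0$S$_\pi$ thresholds. When the
N$_0$S$_0$ track is invalid the BMLD is missing with reason
`no_convergence_all`; when only both N$_0$S$_\pi$ tracks fail the reason
is `no_convergence_dichotic`. PTA3 (pure-tone average over 500, 1000,
3000 Hz) is computed per ear; a listener is excluded when either ear's
PTA3 is strictly above 40 dB HL (one source text states "40 dB HL or
more", another "more than 40 dB HL"; the strict reading is implemented).

## The lateralization battery

The trial log keeps one row per presentation. The first trial of every
stimulus is discarded before analysis (a stimulus left with a single trial
is dropped with a warning), leaving 5 trials per stimulus and 7 diotic
trials in the full 104-trial protocol. The battery then comprises 31
variables; positions are in response keys (one key = 1/8 of the interaural
distance), ratios are natural logarithms:

* **Slopes and fits** (`itd_l_slope`, …, `ild_r_fit`): trial-level
  ordinary least squares of key on cue value in protocol steps (200 µs or
  4 dB per step) over the three stimuli of one side; `fit` is the mean of
  the fitted values at the three positions. Trial-level rather than
  per-stimulus-mean fitting is used because it is identical for equal
  trial counts but degrades gracefully when trials are missing.
* **Side bias** (`itd_mean`, `ild_mean`, `diotic_percept`, centres): means
  over the physiological grid including the diotic stimulus and excluding
  monaural and ±1500-µs trials, which have dedicated variables. The
  centres are the mean cue value over trials answered with key 5,
  reported in native units (a step-normalised variant is also emitted);
  they are missing for listeners who never report a centred percept.
* **Variability** (`diotic_std`, per-stimulus and per-side standard
  deviations, their log ratios).
* **Ranges** (`itd_range`, `ild_range`, `range_ratio`): max − min of the
  *per-stimulus mean* responses over the physiological grid — stimulus
  means rather than single-trial extremes, so that one aberrant key press
  cannot set the range.
* **Monaural and supra-physiological percepts** (`mon_left`, `mon_right`,
  `neg_1500`, `pos_1500`): plain mean responses.

Whether the ITD/ILD means should include the ±1500-µs trials is genuinely
ambiguous; the package default excludes them (switchable with
`include_extreme_in_mean`), because those stimuli carry their own
variables and cluster. Diotic trials contribute to both the ITD and the
ILD aggregates (`diotic_in_both`), since the diotic stimulus belongs to
both interleaved stimulus sets.

Mirroring a trial log (`mirror_table()`) maps keys to 10 − key, negates
cue values and swaps the monaural sides; it is an involution. Its
algebraic image on the battery (`mirror_metrics()`) reflects position
variables about key 5, swaps side-specific variables, and negates centres
and side-asymmetry log ratios. One subtlety: `range_ratio` compares *cue
types* (ILD vs ITD), not sides, so it is mirror-*invariant* — its
augmented mean is not forced to zero, unlike the side-asymmetry ratios.
The identity `compute_metrics(mirror_table(t)) ==
mirror_metrics(compute_metrics(t))` is asserted for every battery field on
randomised tables, and the whole battery is cross-checked against an
independent brute-force recomputation to $10^{-12}$.

## Normative bands and deviation flags

Per variable, the normal range is the control mean ± 1.5 SD, read as a
closed interval (a value exactly on the boundary is normal). To avoid
biasing the group mean by individual left-right asymmetries, each
control's metrics are pooled with the metrics of their mirrored session
before the mean and SD are computed. Two consequences of this
augmentation are handled explicitly:

* The mirrored rows are not independent observations, so the SD divisor
  stays at $2(n-1)$ rather than $2n-1$. This makes augmentation exactly
  neutral for a perfectly symmetric cohort, and gives the closed form
  $\mathrm{var}_{aug} = s^2 + \frac{n}{n-1}(\bar x - c)^2$ for a
  self-mirroring variable with symmetry point $c$ (key 5 for positions, 0
  for centres and side-asymmetry ratios). The often-heard claim that
  mirror augmentation "leaves the SD unaffected" is thus only exact for
  a symmetric cohort; the offset term quantifies the difference.
* Missingness propagates: an invalid tone-in-noise task marks all
  detection variables (cluster A) missing.

Flags are aggregated in two ways. The cluster-by-lesion-group divergence
matrix reports, per (group, cluster) cell, the percentage of deviant
(participant, variable) pairs among the non-missing pairs; missing cells
are excluded from the denominator because the corresponding display
convention marks them separately rather than counting them as deviant.
The condensed group summaries pool left- and right-sided groups and
report (1) the share of patients whose BMLD is flagged low *or* who could
not complete the detection task — here non-convergence does count, as the
inability itself is the clinically meaningful event — and (2) the
per-patient percentage of non-missing cluster B–G variables flagged
low/high, averaged within the group with its across-patient SD. The
default cluster assignment (A thresholds, B side bias, C variability,
D slopes, E ranges, F monaural, G ±1500 µs; B–G hold 31 variables) is a
documented default and fully overridable.

## The virtual listeners

No listener model is part of the measurement protocol; this module is
openly a stand-in whose obligation is to reproduce the statistical
structure the analysis assumes, so that every stage can be tested.

*Detection* listeners follow a three-alternative forced-choice
psychometric function
$P(\text{correct}) = \tfrac13 + (1 - \tfrac13 - \lambda)\,
\Phi\!\big((L - \mu_c)/\sigma\big)$, with the N$_0$S$_\pi$ midpoint lower
than the N$_0$S$_0$ midpoint by the configured binaural advantage.
Defaults: $\mu_{N_0S_0} = 64$ dB SPL (just above the 60-dB-SPL masker),
advantage 13 dB with a 3.5-dB between-subject SD — chosen so the simulated
control BMLD distribution spans roughly the 7.5–20 dB normal range
reported for healthy listeners of this task — $\sigma = 3$ dB, lapse 0.02.

*Lateralization* listeners map a cue to an internal position
$x = b + g_{side}\, s(\text{cue}) + \varepsilon$ on $[-1, 1]$, with
$s(\text{ITD}) = \text{ITD}/600\,\mu s$, $s(\text{ILD}) = \text{ILD}/12$ dB
(clipped), side-specific gains, i.i.d. Gaussian noise, and
$x = b \pm$ `mon_extent` for monaural stimuli. The position maps to keys
via $\text{round}(5 + 4x)$, snapped to the listener's allowed key set
(ties to the lower key); with probability `confusion_prob` the mirrored
key is reported. A ±1500-µs ITD is ambiguous for a 500-Hz carrier whose
period is 2000 µs: a 1500-µs lead is also a 500-µs lag. With probability
`ambiguity_weight` (default 0.5) the listener hears the alias side;
either way the extent is that of a 500-µs ITD.

Control defaults (`gain_itd` 0.7, `gain_ild` 0.45, `noise_sd` 0.25,
`mon_extent` 0.9) were set from the qualitative structure of control data
for this protocol — ITD-based lateralization more extensive than
ILD-based, ±12 dB not strongly lateralized, trial-to-trial SD about one
key, monaural stimuli heard near the ears — and the cohort generator adds
between-subject jitter (e.g. bias SD 0.05, gain SDs 0.05–0.06, log-normal
noise spread) so that controls differ realistically and mirror
augmentation has real asymmetries to absorb. Archetypes reproduce
patient patterns by overriding one defining parameter after jitter:
`shifted` (bias ≥ 0.25, one key rightward), `high_variability` (doubled
noise), `flattened_itd` (ITD gains ≈ 0.05 with ILD preserved),
`categorical`/`side_oriented` (restricted key sets), `lr_confusion`,
`no_binaural_benefit`, and `task_failure` (detection midpoint far above
the level cap, so tracks never converge).

What the generator does **not** emulate: attention drift and sequential
dependence (responses are i.i.d. given the listener), learning across
runs, asymmetric hearing loss interacting with lateralization, and any
physiological mechanism (no equalization-cancellation or
cross-correlation modelling). Passing tests therefore show that the
*analysis machinery* is correct and calibrated under the stated
statistical assumptions — not that those assumptions hold for real
patients.

## Numerical choices and degenerate inputs

* Log ratios are natural logs; they are missing when a constituent slope
  is ≤ 0 or an SD or range is 0, rather than ±∞.
* Centres are missing when key 5 was never pressed for that cue type;
  ranges need at least two per-stimulus means.
* Key snapping resolves ties toward the lower key (a fixed, documented
  tie-break; with response noise it has no systematic effect beyond
  single-key granularity).
* Fractional delays pad by the delay plus 64 samples before the FFT phase
  ramp, so circular wrap-around never touches signal content.
* Per-participant seeds are derived from the master seed by one draw of
  `sample.int(.Machine$integer.max - 1)`, keeping every derived seed a
  valid 32-bit integer.

## Problem sizes

The shipped test suite and acceptance script run everything at sizes
chosen to make Monte-Carlo tolerances meaningful on a single CPU in a few
minutes: 60 long staircases (60 reversals) for the convergence asymptote,
200 protocol tracks for threshold recovery, 100 sessions for BMLD
recovery, control cohorts of 100–300 for normative bands, 1000
independent controls for the flag-rate calibration (the per-variable
deviant rate of approximately normal variables should approach
$2\Phi(-1.5) = 13.4\%$), and 100 seeds per archetype for detection rates.
The example analysis under `analysis/` simulates a 62-participant cohort
(12 controls, 50 patients across lesion groups).

## Known limitations

* The deviation framework is descriptive: no single-case inferential
  statistics (e.g. Crawford–Howell t) and no multiple-testing correction
  across the 34 variables — by design, matching the descriptive use of
  such batteries.
* Band estimates from 12 controls are noisy; the 1.5-SD rule inherits
  that noise (the flag-rate calibration in the tests uses larger control
  cohorts precisely to separate rule calibration from small-sample
  variability).
* Discrete 9-key responses make several battery variables mildly
  non-normal; the 13.4% calibration holds for trial-averaged variables
  but not for clipped ones (monaural percepts near the scale ends), which
  is why those are excluded from the calibration set.
* Stimulus synthesis is tested acoustically (spectra, lags, phases,
  energies), but the virtual listeners respond to cue *parameters*, not
  to the waveforms; linking the two would require an auditory-periphery
  model, which is out of scope.
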