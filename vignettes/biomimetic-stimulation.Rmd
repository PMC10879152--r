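---
title: "Designing and evaluating biomimetic tactile neurostimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating biomimetic tactile neurostimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactstim)
```

## The problem

Conventional sensory neuroprostheses encode touch with tonic (constant
frequency, typically 50 Hz) electrical pulse trains on a peripheral nerve.
Tonic stimulation synchronizes large afferent populations in a way natural
touch never does, and the evoked sensations are reported as artificial.
*Biomimetic* neurostimulation instead modulates the pulse frequency so that
the train mimics the aggregate firing of the natural afferent population
responding to the same mechanical stimulus.

`tactstim` implements the full computational chain needed to design such
patterns and to test — on ground-truthed synthetic electrophysiology —
whether biomimetic stimulation evokes neural activity that is more similar
to natural touch than tonic stimulation is.  The chain has four stages:

1. **Afferent simulation** (`buildPopulation`, `makeRampAndHold`,
   `simulateResponses`): parametric rate models of the four cutaneous
   mechanoreceptor classes of the foot sole.
2. **Stimulation encoding** (`populationPsth`, `smoothProfile`,
   `profileToFrequency`, `frequencyToPulseTimes`, plus the comparison
   encoders `makeTonic`, `makePoisson`, `makeLinear`, `makeDiscrete`,
   `makeSinusoidalPw`, and `validateCharge`).
3. **Synthetic electrophysiology** (`synthesizeRecording`,
   `makeTouchDrive`): 32-channel extracellular recordings with complete
   ground truth.
4. **Analysis pipeline** (`robustSigma`, `combNotch`, `butterHighpass`,
   `blankArtifacts`, `bandExtract`, `detectSpikes`, `buildPsth`,
   `triggerAverageLfp`, `klLfpAmplitudes`, `computeCsd`,
   `channelwiseCorr`, `alongProbeCorr`) and nonparametric study statistics
   (`compareGroups`, `summarizeRatings`, `normalityScreen`,
   `learningEffect`).

## Afferent rate models

The full biophysical skin-mechanics-to-firing models fitted on human
microneurography are out of scope here; `tactstim` replaces them with
transparent parametric rate models that reproduce the class-typical
dynamics.  With $s(t)$ the applied pressure (used directly as the skin
stress — the mechanical deformation sub-model is deliberately omitted, a
documented limitation):

* **SA1** (slowly adapting I): $r = g_s\,s(t)\,A(t) + g_d\,[\dot s]_+$,
  where the adaptation state $A(t)$ relaxes from 1 towards a floor of 0.2
  with time constant $\tau$ while the skin is indented and recovers with
  time constant $4\tau$ otherwise.  This produces sustained but adapting
  responses, including the progressive decline over repeated indentation
  cycles.
* **SA2**: the sustained term only, with a lower gain and slower $\tau$.
* **FA1** (fast adapting I): $g_d\,|\dot s|$ smoothed over 20 ms — purely
  transient, firing at the ramps.
* **FA2**: $g_a\,|\ddot s|$ smoothed over 5 ms — responding to
  acceleration transients.

All rates add the unit's spontaneous rate and are clipped to
$[0, r_\mathrm{sat}]$.  Unit parameters are drawn log-normally (CV 0.25)
around class means chosen so that a unit-amplitude ramp-and-hold evokes
SA hold rates of tens of spikes/s and FA transient rates of hundreds of
spikes/s.  The default FULL composition (15% SA1, 15% SA2, 60% FA1, 10%
FA2) follows microneurographic surveys of the human foot sole, which is
FA1-dominated.  Spikes are drawn by thinning an inhomogeneous Poisson
process with an absolute refractory period of 1 ms; tests verify the
expected spike count against direct numerical integration of the clipped
rate (with the standard dead-time correction $r/(1+r\tau_r)$).

The standard stimulus is 2 s of repeated ramp-and-hold cycles (0.15 s on,
0.3 s off) with additive uniform environmental noise bounded by 0.5% of
the peak amplitude.  The on/off values describe one duty cycle which is
tiled across the 2 s stimulus; ramp rise and fall each take 20% of the on
phase (configurable — the source material gives no value).

## From population activity to pulse trains

```{r design}
design <- designBiomimeticTrain("FULL", nUnits = 160, seed = 1)
design$train
validateCharge(design$train)
```

The population PSTH (10 ms bins) is smoothed with a 30 ms gaussian and
mapped affinely onto a stimulation frequency range, by default
$[0, 100]$ Hz: zero rate maps to $f_\min$ and the profile maximum to
$f_\max$ (the clinically used range is not documented; both bounds are
arguments).  Pulses are then placed by time rescaling: a pulse is emitted
whenever $\int_0^t f(\tau)\,d\tau$ crosses the next whole number.  This
rule is deterministic, emits exactly $\lceil \int f \rceil$ pulses, and
collapses to the regular tonic train for a constant profile, which is the
property the tests pin down.  Amplitude and pulse width stay constant
(60 uA, 0.5 ms — the values used during nerve stimulation, giving 30 nC
per pulse, far below the 120 nC electrode safety limit enforced by
`validateCharge`).

The comparison encoders mirror the clinically tested strategies: TONIC
(50 Hz), POISSON (exponential intervals at 50 Hz mean, with a refractory
floor protecting the biphasic pulse shape; the exponential rate is
compensated so the mean stays exact), LIN (charge follows the normalized
pressure between a perceptual-threshold and a maximal comfortable charge,
at fixed 50 Hz), DISC (0.5 s bursts at contact and release, overlapping
bursts merged) and SINUS_PW (sinusoidal pulse-width modulation, default
1 Hz across the full width range; the cited source gives no parameters).

## The synthetic animal experiment

`synthesizeRecording` emulates the recordings used to compare stimulation
with natural touch: a 32-channel linear probe in the spinal cord sampled
at 25 kHz (the DRG preset uses 30 kHz).  Each trial is driven either

* **electrically** (a `StimTrain`): every pulse recruits each channel's
  multi-unit activity with probability 0.9 at 1.5 ms mean latency and
  0.5 ms jitter.  Each channel sees a small compound volley — by default
  three fibre groups at conduction delays 2.5 ms apart — so electrical
  drives synchronize channels strongly; or
* **naturally** (a `RateProfile` from `makeTouchDrive`): channels spike as
  independent inhomogeneous Poisson processes scaled by per-channel gains.
  The default natural drive is the expected aggregate response of a mixed
  afferent population to repeated light contacts (rubbing), i.e. the same
  ramp-and-hold duty cycle compressed to the 0.8 s span of the touch
  response.  This is deliberate: the biomimetic pattern *encodes* that
  population response, and the analysis bins (100 ms for the 2 s
  electrical conditions, 40 ms for the 0.8 s natural condition) place both
  on the same 20-bin grid.

The voltage model sums: spike templates (biphasic, ~1.2 ms, 6 robust SDs
at the negative peak); low-amplitude multi-unit *hash* (150 events/s at
0.4 SD) — distant units that inflate the robust noise estimate exactly as
in real recordings and are not part of the ground truth; an LFP component;
50 Hz line noise with harmonics; slow sinusoidal drift; steep-red Gaussian
background noise (two cascaded one-pole sections, corner 300 Hz —
extracellular noise is strongly low-frequency-weighted, which is what
makes a 3-sigma spike threshold usable in practice); and rare large
common-mode artifacts.

The LFP forward model uses two temporal components — a fast envelope of
the drive intensity and a slower copy delayed by 120 ms — riding on
trial-locked oscillatory carriers (85 and 45 Hz), weighted along the probe
by two gaussian source profiles.  A fixed laminar fine structure
(alternating sink/source bands with a 600 um period) multiplies both
profiles; it represents the anatomy of the dorsal horn and is therefore
identical across drive types, which is what gives the CSD its spatial
structure at the 100 um probe pitch and lets matched channels correspond
across conditions.  Electrical drives are strong (60 uV) and dominated by
the fast component; natural drives are weaker (25 uV) with a stronger
slow component.  This reproduces the along-probe similarity pattern of the
recordings: electrically evoked activity is highly correlated along the
whole probe, naturally evoked activity decorrelates with depth.

What the generator does *not* emulate: biophysical volume conduction,
spike-sorting realism (multi-unit threshold crossing is all the pipeline
needs), electrode drift over sessions, or behaving-animal movement
artifacts.  Passing tests therefore show that the analysis chain measures
what it claims on data with known ground truth — not that real tissue
behaves like the forward model.

## Analysis pipeline and numerical choices

The preprocessing follows the animal-data analysis exactly: robust noise
SD $\sigma = \mathrm{median}(|x|)/0.6745$ per channel; artifacts blanked
where $|x| > 15\sigma$ with 10 ms padding; drift removed with a zero-phase
3rd-order 30 Hz Butterworth high-pass; powerline removed with a comb of
2nd-order band-stops at 50 Hz and harmonics (width $f_0/Q$, $Q = 35$;
no quality factor is documented); LFP band 30–300 Hz; spike band
800–5000 Hz with threshold $-3\sigma$ (spinal convention; DRG uses
$4\sigma$) and 1 ms dead time.  Zero-phase (forward–backward) filtering
avoids latency distortion in trigger averages.  For speed the end-to-end
wrapper runs the LFP path on a decimated (~1.25 kHz) copy — the band of
interest ends at 300 Hz — and omits the comb on the spike path, where the
configured harmonics carry no power.

PSTH bins are 10 ms for transmission analysis and 50 ms for condition
comparison; `fdBinWidth` implements the Freedman–Diaconis alternative
($2\,\mathrm{IQR}\,N^{-1/3}$, with an explicit error on degenerate IQR so
callers can fall back to fixed widths).

Three comparison statistics mirror the headline figures:

* **KL divergence of LFP amplitudes** (`klLfpAmplitudes`): shared 50-bin
  histograms over the pooled range, $\epsilon = 10^{-10}$ regularization,
  direction KL(condition ‖ natural) since natural touch is the expected
  distribution.  Channels enter via the 12 most active (largest
  trigger-averaged peak-to-peak; the selection rule is exposed as a
  parameter since only the count is documented).
* **CSD** (`computeCsd`): negative three-point second spatial difference
  with duplicated edges, time-binned by averaging, per-condition
  normalization to max $|v| = 1$.  The condition maps are computed on the
  *rectified* trigger-averaged LFP: a strictly band-passed signal has
  near-zero mean over bins much longer than the filter time constants, so
  signed bin averages of the raw band signal would track oscillation phase
  rather than response magnitude; the envelope is what the coarse 100/40 ms
  bins can meaningfully compare.  The `computeCsd` contract itself
  (linear profile → zero interior CSD; delta source → $(-1, 2, -1)$) is
  unchanged and tested directly.
* **Channel-wise correlation with shuffled-channel null**
  (`channelwiseCorr`): per-channel Pearson r across time bins, pooled r
  over all channel-bin pairs with a Fisher-z 95% CI, and a seeded null
  that permutes the channel order 100 times.  Genuine spatial
  correspondence vanishes under permutation, so the shuffled correlations
  centre on zero.

## The end-to-end experiment

`runSyntheticExperiment` runs the whole chain at the study scale: 90
biomimetic-FULL trials, 90 tonic trials, 15 natural trials on the spinal
preset (about 9 minutes and 5 GB on one CPU; the trial counts are the
study's, the trial lengths are 2 s electrical / 0.8 s natural).  The
acceptance tests assert the direction of every headline comparison:
KL(biomimetic ‖ natural) < KL(tonic ‖ natural); summed normalized PSTH
activity maximal for tonic; median channel-wise CSD correlation with
natural touch higher for biomimetic than for tonic; shuffled-control
median correlation within 0.05 of zero; and a transmission
cross-correlation peak of at least 0.8 between the stimulation frequency
profile and the evoked PSTH (the evoked 10 ms PSTH is smoothed with the
same 30 ms gaussian used in the design chain before correlating, so both
sides live on the same time scale).

## Study statistics

`compareGroups` performs the tie-corrected Kruskal–Wallis test (via
`stats::kruskal.test`; an exhaustively enumerated rank oracle checks the
H statistic in the tests) with Dunn-style pairwise z-tests and Bonferroni
correction — the post-hoc procedure is not documented, so Dunn/Bonferroni
is the package default.  The reported effect size f is likewise not
defined in the source material; it is computed as Cohen's f from the rank
epsilon-squared, $\epsilon^2 = (H - k + 1)/(N - k)$, and both choices are
arguments.  `normalityScreen` applies the one-sample Kolmogorov–Smirnov
test against N(0, 1) to z-scored data by default (raw-scale data cannot
plausibly match a standard normal; a raw mode exists), plus QQ points and
a histogram summary.  `learningEffect` is Spearman's rank correlation of
a metric against session index.

Rating and task tables are plain CSV with documented schemas
(`readRatingsTable`, `readTaskTable`); a YAML column mapping adapts
foreign headers, and `depositedBenchmarks` recomputes the published
human-study summaries (pooled naturalness medians per encoding family,
stairs-task speed) from such tables when they are available locally.

## Known limitations

* The afferent models are phenomenological; absolute rates are not fitted
  to microneurography, so only relative/structural claims are tested.
* Pressure is used directly as skin stress; no spatial mechanics.
* The LFP forward model is a two-source abstraction, not volume
  conduction; CSD comparisons are restricted to the linear probe.
* Serialization is CSV/JSON; recordings are regenerated from seeds rather
  than stored.
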