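---
title: "Methods: MEA network activity, viability and puncta quantification under oxygen and temperature stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA network activity, viability and puncta quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaoxia)
```

## The assay and its outcome measures

The package analyses multiwell micro-electrode array (MEA) recordings of
cultured human iPSC-derived neuronal networks: 24 wells, 12 electrodes per
well, voltages sampled at 10 kHz. A session consists of a 10-minute
baseline recording, 10-minute recordings every 2 h during a 48-h exposure
(e.g. hypoxia at 2% O2 combined with a temperature regimen of 34, 37 or
39 °C), and a final recording 6 h after physiological conditions are
restored.

Three network-level outcome measures summarise each recording:

* **MFR** — mean firing rate: spikes/s per electrode, averaged over
  *active* electrodes (≥ 0.1 spikes/s).
* **NBR** — network burst rate: synchronous network-wide events per
  minute.
* **NBD** — network burst duration: mean duration (ms) of those events;
  undefined when none occur.

Each well's metrics are expressed as a percentage of that same well's
baseline; wells whose baseline fails the inclusion criterion (MFR > 0.1
spikes/s **and** NBR > 1/min, both strict) are excluded from analysis.

## Detection chain

**Filtering.** Traces are band-limited with a 2nd-order Butterworth
high-pass at 100 Hz and a 4th-order Butterworth low-pass at 3.5 kHz.
Both are applied zero-phase (forward–backward) so spike latencies are not
shifted between channels — this matters because network-burst detection
downstream depends on cross-channel timing. Coefficients come from the
standard bilinear-transform design and were verified against an
independent reference implementation.

**Spike detection.** The noise level of a filtered trace is estimated as
`median(|x|)/0.6745` (MAD about zero). A robust estimator is essential
here: the spikes themselves would inflate a plain SD and raise their own
threshold. Spikes are threshold crossings of |x| beyond 5 × noise SD
(bipolar; the acquisition system's polarity convention is unreported, so
the permissive reading is used), timed at the extremum of each crossing,
with a 2 ms dead time. The activity criterion "minimum of 0.1 spikes per
second" is read as inclusive (≥).

**Burst detection.** A burst is a maximal run of ≥ 4 spikes with
inter-spike intervals ≤ 50 ms (inclusive boundary). Candidate bursts on
one electrode closer than 100 ms are *merged* into one event — whether
the original analysis merges or discards such runs is unreported; merging
is chosen because the 100 ms rule is phrased as differentiating
consecutive bursts. A channel is a *bursting channel* at ≥ 0.4
bursts/min.

**Network burst detection.** All bursts of a well are chained by temporal
overlap (closed intervals: touching endpoints overlap — the permissive
reading of "temporally overlapping", fixed and documented). A chain is a
network burst when (a) it contains bursts from ≥ 6 distinct channels and
(b) at some instant ≥ 4 distinct channels are bursting simultaneously
(sweep-line maximum). "Six distinct bursting channels" is interpreted as
six channels contributing bursts *to the chain*, not six channels passing
the 0.4/min classification (which is reported separately); the scoping of
the defining sentence supports this reading. Both thresholds are
parameters of `network_burst_params()`.

## The synthetic-data generator as a stated world

No raw recordings from the original experiments are public, so the
package carries a generator whose *ground truth encodes the reported
group-level trajectories*. Each oxygen × temperature condition is a
**condition profile**: piecewise-linear multipliers of baseline MFR, NBR
and NBD versus hours of treatment, with knots taken from the reported
anchor values (e.g. normothermia + hypoxia: linear decline of activity to
zero at 42 h; recovery at 54% MFR, 29% NBR, 63% NBD; hypothermia +
hypoxia: NBR at 50% from 2 h to 34 h, zero at 48 h, 1.7-fold NBR at
recovery; hyperthermia + hypoxia: 1.5-fold NBR until 24 h, zero by 42 h).
Linear interpolation between anchors is the minimal assumption; knots
live in a versioned JSON file (`inst/extdata/condition_profiles.json`),
not in code. Shapes the source quantifies only qualitatively (the
normoxia arms' declines, hypothermia's MFR/NBD recovery) are package
choices, flagged in the JSON descriptions.

Baseline activity defaults (`baseline_params()`): tonic 1 spike/s per
electrode, 2 network bursts/min of 500 ms involving 10 of 12 electrodes —
values that comfortably pass the inclusion criteria and resemble
published hiPSC MEA activity at seven weeks in vitro.

Mechanically, a recording is a homogeneous Poisson process of
network-burst events (rate = baseline NBR × profile multiplier; events
closer than 200 ms are thinned so distinct events stay distinct to the
detector — realised events are the recorded truth). Each event recruits
10 electrodes with ± 10 ms per-channel jitter (the synchrony
microstructure is unreported; jitter is a parameter) and lays spikes at
40 ms spacing across the event duration. Two deliberate deviations from
a naive reading of the design:

* **Spikes per burst follow duration.** A fixed count per burst cannot
  satisfy the 50 ms intra-burst ISI rule across the duration range the
  profiles span (8 spikes over 500 ms gives 71 ms ISIs — invisible to
  the detector). The count is `ceil(duration / 40 ms) + 1`, floored at 4.
* **The MFR multiplier targets the observable.** The profile's MFR
  multiplier scales the *total* per-electrode rate; the tonic Poisson
  component is back-solved by subtracting the burst contribution (floored
  at zero). Without this, normalised MFR would track a mixture of the MFR
  and NBR multipliers and the profile could not be recovered from the
  pipeline — the calibration property the generator exists to provide.

Recovery-phase multipliers get per-well lognormal variability (CV 0.2,
mean 1) to give realistic across-well dispersion; the source reports
group means without per-well spread, so this CV is a stand-in, and green
calibration tests establish recovery of *means*, not of dispersion.

`render_traces()` turns spike trains into 10 kHz voltage traces (biphasic
template, trough-normalised, in Gaussian noise) so the detection chain
can be scored end to end against known spike times. What the generator
does **not** emulate: electrode-to-electrode gain differences, LFP-band
structure, artifacts, bursts with internal rate modulation, and any
biophysics — a green detection test establishes correctness of the
implemented rules, not robustness to real-world recording pathologies.

## Imaging arm

**Viability.** Synthetic fields carry ~100 nuclei as Gaussian blobs
(DAPI), with apoptotic cells additionally marked in the CellEvent channel
and dead cells in CellEvent + PI; packaged class compositions per
condition and timepoint are the reported percentages
(`inst/extdata/viability_compositions.json`). The classifier segments
nuclei on DAPI (Otsu threshold, 8-connected components, size filter) and
scores marker positivity by mean in-mask intensity against an adaptive
threshold (0.3 × the strongest nucleus's background-subtracted mean),
with a channel-level contrast guard so a signal-free channel yields
all-negative. Classification is therefore invariant to global intensity
scaling. The rubric is: live = DAPI only; apoptotic = DAPI + CellEvent;
dead = all three. The DAPI + PI-only pattern has no class in the original
rubric and is reported separately as *unclassified* rather than silently
folded in; the generator seeds 1% of such cells. The original count was
manual and blind; this module automates it, and its accuracy (≥ 95%
per-cell on synthetic mixtures) is established only on synthetic fields.
The nucleus minimum separation (16 px at σ = 3.5 px) is chosen so
adjacent blobs' tails cannot sum above a global threshold and merge —
real micrographs with touching nuclei would need a splitting step this
package does not implement.

**Synaptic puncta.** Neurites are random-walk curves of known arc length
in the MAP2 channel; synapsin puncta are a linear Poisson process along
the curve at the packaged density (per 10 µm), plus off-neurite
distractors ≥ 3 µm away. The quantifier thresholds MAP2 (adaptive,
scale-invariant, with the same contrast guard), thins the mask by
Guo–Hall thinning, and measures neurite length as the
diagonal-corrected skeleton path length (0.980/orthogonal, 1.406/diagonal
step; diagonal adjacencies that merely shortcut a corner pixel are
skipped). Guo–Hall is used instead of the more common Zhang–Suen because
the latter leaves two-pixel staircases on oblique curves that inflate
path length by up to ~30% at 30°; with the corrected estimator the
length bias is within ±6% at any orientation and ~0 on the packaged
fields. Puncta are local maxima of a difference-of-Gaussians filtered
synapsin channel above 6 robust SDs, counted when within 1 µm of the
skeleton, and reported per 10 µm of neurite. The estimator carries a
small negative bias (~5–10%) from unresolvable puncta pairs at higher
densities; this is inherent to maxima-based counting at diffraction-like
spot sizes and stays well inside the ±15% acceptance band. Pixel size
defaults: 0.32 µm (40×, viability) and 0.16 µm (60×, puncta).

## Statistical protocol

* **Normality**: one-sample KS statistic against a normal with estimated
  mean/SD. Estimated parameters invalidate the classical KS null
  (Lilliefors' situation), so the p-value comes from a parametric
  bootstrap (default 1999 replicates) — exact up to Monte-Carlo error
  rather than relying on approximation formulas.
* **Outliers**: ROUT-style flagging reduced to the one-sample location
  case (the source applies it to grouped summary values, not regression
  curves): median centre, robust SD from the 68.27th percentile of
  absolute residuals (with a small-sample df correction), per-point
  t statistics, Benjamini–Hochberg selection at Q = 1%. Points are
  flagged, never silently dropped. Applied per timepoint.
* **ANOVA**: two-way (condition × timepoint) with Type-III sums of
  squares via sum-to-zero contrasts and reduced-model comparisons —
  appropriate for the unbalanced well counts of multi-arm MEA
  experiments, and matching the behaviour of the commercial software the
  protocol mirrors. Verified against an independent Type-III oracle.
* **Post-hoc families**: Tukey (all condition pairs within a timepoint,
  studentized range), Sidak (two-group contrast per timepoint, family =
  timepoints), Dunnett (each timepoint vs the baseline reference). The
  two-sided Dunnett adjusted p is computed by direct numerical
  integration of the equicorrelated (ρ = 1/2) multivariate-t orthant
  probability; for unbalanced cells this equicorrelation is an
  approximation. Significance stars use the 0.05/0.005/0.0005/0.0001
  cutpoints and p < 0.0001 is reported as "<0.0001".

## Numerical choices and degenerate inputs

* Times are seconds in doubles; all windows half-open `[t0, t1)`;
  sample indices 0-based in time (`t = (i-1)/fs`).
* ISI ≤ 50 ms and rate thresholds at 0.1 spikes/s and 0.4 bursts/min are
  inclusive; the network inclusion criteria (MFR > 0.1, NBR > 1/min) are
  strict, following the wording of each rule.
* NBD at a timepoint with no network bursts is *missing*, not zero
  (zero would bias NBD means downward); normalised series with a zero or
  undefined baseline are missing; a well is dropped only for a failed
  *baseline*, never for later activity loss — loss of activity is the
  phenomenon under study, and lost wells score 0% rather than leaving
  the average.
* Empty traces error in the noise estimator; empty spike trains,
  burstless recordings, blank images and zero-nucleus fields all return
  well-defined empty/flagged results.
* The spike-table format stores times at 1 µs resolution; write→read→
  write is byte-stable.

## Known limitations

* Profiles interpolate a handful of reported anchor values; the true
  trajectories between anchors are unknown.
* The well-to-well CV (0.2) and every composition marked "inferred" in
  the packaged JSON are stand-ins, not reported data.
* The imaging classifiers are validated on synthetic fields only; no
  claim is made about performance on real micrographs.
* Dunnett's adjustment assumes equicorrelation (exact for balanced
  designs only); ROUT here is the location-model reduction, not the full
  robust-regression procedure.
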