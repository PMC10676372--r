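---
title: "Laminar analysis of spreading depolarizations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of spreading depolarizations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdlamina)
```

## The scientific problem

A spreading depolarization (SD) is a slowly propagating wave of near-complete
neuronal and glial depolarization. On a DC-coupled electrode it appears as a
large negative shift of the slow extracellular potential; classically it is
assumed to be accompanied by *spreading depression* — suppression of
spontaneous cortical activity. On laminar (depth) recordings, however, SD
waves frequently stop partway down the cortical column. `sdlamina`
implements the analysis chain needed to study what such *partial* SDs do to
cortical activity at every depth:

1. **SD detection and vertical stop depth.** Per channel, the SD onset is
   the peak of the negative first derivative (SD$'$) of the low-passed slow
   potential (1 Hz lowpass for laminar DC recordings; a 0.001–45 Hz band for
   200 Hz clinical DC-ECoG). Channels whose SD$'$ peak does not exceed
   1 mV/s are not counted as invaded, and the *stop depth* is the depth of
   the deepest invaded electrode.
2. **Depression / no change / boom classification.** Band power is computed
   in 5 s windows sliding in 1 s steps over a pre-SD epoch and an SD epoch
   ([-120,-90] s and [10,40] s around the onset for ECoG; [-40,-10] s and
   [10,40] s for laminar recordings, the latter with Slepian multitaper
   estimators: 0.5 Hz half-bandwidth, 3 tapers). The SD/pre ratio of mean
   window powers and a two-sided Wilcoxon rank-sum test give the label:
   `no_change` if p > 0.05, otherwise `depression` or `boom` by the sign of
   the ratio against 1.
3. **Generators of the laminar field potential.** The recording
   $u_m(t) = \sum_n V_{mn}\, s_n(t)$ is decomposed into spatial profiles
   ($V_{mn}$) and time courses ($s_n$) by PCA reduction to 5–6 components
   followed by FastICA; components carrying less than 1% of the variance are
   discarded. Current source density is the second spatial difference of the
   potential along the probe, depth-smoothed with a (1,2,1)/4 kernel.
4. **Multi-unit activity and the three laminar zones.** Spikes are negative
   events below 4 standard deviations of the quietest 100 s control fragment
   of the 250–4000 Hz trace, with an SD-adaptive threshold (below). Pooling
   per-channel delta-power, gamma-power and MUA-rate changes across SDs,
   aligned on depth relative to the stop depth, yields three zones:
   a depressed zone above the stop, a ~300 µm *sub-SD excitation* band just
   below it (gamma-organized firing increase with delta suppression), and an
   unchanged deep zone.
5. **Intracellular metrics.** The membrane potential is corrected by
   subtracting the field potential of the nearest probe channel; action
   potentials are events above 5 mV in the 50 Hz-highpassed trace; the
   depolarization-block threshold is the slow (<0.2 Hz, 5 s sliding-median)
   potential at the last spike before a rising silence of at least 5 s.

## The synthetic cortical column

Because the underlying animal and clinical recordings are not public, the
package ships a forward model (`simulate_laminar_session()`,
`simulate_human_ecog()`, `simulate_intracellular()`) whose defaults define
the study conditions for every validation:

* **Geometry.** 16 channels at 100–1600 µm below the pia, 100 µm spacing,
  LFP at 1 kHz, wideband at 10 kHz (a desk-scale stand-in for acquisition
  rates of tens of kHz; configurable).
* **Delta generators.** Four named generators: `Main` (polarity reversal at
  ~300 µm, broad maximum over layers 4–5, gain 0.025 mV), `L3` (supragranular,
  0.0125 mV), `L56` (deep, 0.0575 mV) and a flat `Remote` source
  (0.00625 mV). Sources are UP/DOWN event trains — 150–400 ms smoothed
  (50 ms Gaussian) rectangular depolarizations with inter-onset intervals of
  0.35–1.1 s, placing the dominant rhythm in the 0.5–4 Hz band; the remote
  source is delta-filtered heavy-tailed noise, reflecting an extracortical
  origin with a much shorter correlation time. Per-channel *local* delta
  sources (narrow profiles, 0.00875 mV) and localized gamma sources tied to
  each cortical generator complete the mixture. Amplitudes are a few hundred
  µV of delta on a −20 mV DC shift, matching the amplitude hierarchy of real
  DC recordings — this is what keeps background activity below the 1 mV/s
  SD$'$ threshold.
* **Volume conduction.** The deep generator's profile has a far-field limb
  reaching the surface (with a polarity transition near 1200 µm), so that
  during a partial SD the top channel retains most of its delta power from
  the spared deep source while invaded mid-depth channels, whose delta is
  locally generated, lose theirs. The profile shapes are declarations of the
  statistical structure the analysis assumes, not biophysical claims.
* **The SD wave.** A piecewise DC waveform per invaded channel: sigmoidal
  fall whose time constant sets the SD$'$ peak (default 4 mV/s at −20 mV),
  60 s plateau, exponential recovery (τ = 15 s); top-down propagation at
  100 µm/s. Generators are silenced (smooth 0/1 mask) from the moment the
  front reaches their core depth whenever the stop depth reaches it;
  the spared deep source gains ×√2 in amplitude during surface-partial SDs,
  fading linearly to no gain at 1.4 mm penetration. Local sources above the
  stop depth and within the 300 µm sub-SD band are silenced; deeper ones are
  untouched.
* **Spiking.** Inhomogeneous Poisson (1 ms Bernoulli thinning), baseline
  5 Hz UP-locked; invaded channels emit a brief gamma-locked burst at SD
  arrival and then fall to 2% of baseline; the sub-SD band fires at 3× the
  baseline mean with 40 Hz gamma modulation; deeper channels are unchanged.
  Wideband traces add a biphasic 1 ms template at 8× noise RMS; the SD-related
  noise increase is modelled as *high-frequency-weighted* (twice-differentiated
  white) noise, reflecting the impedance origin of that noise — this is what
  an adaptive threshold keyed to a >4 kHz reference band exploits.
* **Intracellular trajectories.** Rest −65 mV with 8 mV UP depolarizations
  driven by the deep generator's envelope (the same one dominating the L6
  LFP, so LFP-detected UP states align with the cell). Invaded cells ramp to
  −26 mV and stop firing at the planted −36 mV block threshold; cells within
  300 µm below the stop plateau at −47 mV and fire throughout; deeper cells
  shift by under 3 mV. The recorded trace is the true potential plus the
  local field potential, so the correction step is testable.

### What the simulations do and do not show

The generator demonstrates that the implemented detectors and statistics
recover planted parameters under the statistical structure the analysis
assumes (volume-conducted mixtures, propagating DC shifts, rate-modulated
point processes). It does not emulate electrode drift, movement artifacts,
non-Gaussian sensor noise, biophysical SD mechanisms, or the horizontal
propagation of the wave; passing these checks therefore validates the
*analysis*, not any claim about biology beyond the model's bookkeeping.

## Numerical and design choices

* **Filters.** The source papers in this area name band edges, never filter
  families; all bands here are 4th-order Butterworth responses applied
  forward-backward (zero phase), with bandpasses realized as a
  highpass–lowpass cascade for numerical stability at very low normalized
  corners. A highpass corner with fewer than ~3 cycles in the record (the
  0.001 Hz clinical corner on a 540 s fragment) degenerates numerically and
  is realized as a linear detrend — its limit behaviour at record scale.
* **Window stepping.** "5 s windows, 1 s overlap" is implemented as a 1 s
  *step* (26 full windows per 30 s epoch), the reading consistent with
  "thirty 5 s fragments" per epoch. Note a statistical consequence: with
  heavily overlapping windows the per-window powers are strongly dependent,
  and the rank-sum test between epochs becomes anti-conservative (simulated
  null "no change" rates near 63% rather than 95%). The classifier itself is
  exactly calibrated on independent windows, which is how its type-I
  behaviour is validated; labels on overlapped windows should be read as a
  descriptive, deliberately sensitive rule — as published — rather than a
  calibrated test.
* **Rank-sum p-values** are exact for two untied samples of ≤ 25, and use
  the normal approximation with continuity/tie correction otherwise.
* **Multitaper estimation** computes Slepian tapers from the classical
  symmetric tridiagonal eigenproblem (cached per window length); laminar
  traces are decimated to 200 Hz first since all analysis bands lie below
  45 Hz.
* **ICA.** FastICA with symmetric orthogonalization and the logcosh
  contrast (tolerance 1e-5, up to 400 iterations, retries with perturbed
  seeds; if every retry stalls in a near-converged oscillation the best
  iterate is used with a warning, the standard practice). The DC replica
  subtracted before ICA is a 0.6 s moving average — the "0.6 × sampling
  rate" window read as 0.6 s of samples. Profiles are unit-norm with the
  largest-magnitude weight positive; sources carry the scale. Because the
  residual of the SD front after DC removal is ~50× larger than the
  generator signals, the unmixing should be *fitted* on samples away from
  the fronts (`exclude_s`) and then applied to the whole epoch; the
  measurement epochs for generator power remain the two 40 s windows before
  and during the SD, skipping ±5 s around every channel onset.
* **Adaptive spike threshold.** One threshold per SD window:
  4 × STD of the >4 kHz reference band over that window × the control-period
  ratio between the 250–4000 Hz and >4 kHz STDs. At sampling rates of
  8 kHz or less the reference band falls back to the top octave below
  Nyquist. The quietest 100 s control fragment is found with a sliding
  minimum-RMS window (10 s hop).
* **Zone mapping** bins channels by depth relative to the stop depth in
  100 µm bins (the electrode spacing) and requires at least 6 pooled SDs per
  bin — the smallest sample whose signed-rank test can reach p ≤ 0.05;
  sparser bins are dropped rather than mislabelled.
* **Block detection.** The qualifying silence is ≥ 5 s and must begin while
  the slow potential is still rising (> 0.5 mV over the next second) with
  the cell already ≥ 5 mV above rest — guards against resting-state gaps.
* **Vertical speed.** The default SD propagation speed is 100 µm/s so that
  the fixed [10,40] s SD power window falls after full vertical invasion for
  full SDs, preserving the published window semantics; 50 µm/s remains a
  per-plan parameter.
* **Deep-generator gain.** The default ×√2 amplitude gain of the spared deep
  source during surface-partial SDs reproduces the ≈2× deep-generator power
  enhancement reported for surface-partial SDs while the graded fade-out
  keeps deeper partial SDs neutral; an explicit gain of 2 (power ×4) is
  available for sensitivity analyses. Whether that enhancement is a true
  rate increase or an unmasking artifact is unresolved in the literature;
  the simulator treats it as a source gain because only its signal-level
  consequence matters here.
* **Fig-style depolarization relation.** The cell-to-stop distance stored in
  `cell_sd_metrics` is `cell depth − stop depth`; the depolarization
  relation is reported against *penetration* (`stop − cell`), so deeper SD
  penetration relative to the cell gives a positive correlation with
  depolarization.

## Problem sizes used in validation

The validation drivers (`validate_*`, also run by
`scripts/acceptance.R`) use: 50 single-SD sessions for onset/stop recovery;
1000 null draws and 2 × 100 scaled plants for classifier calibration; 60
sessions with 1000 permutations for the depth–ratio relation; a 600 s
four-generator benchmark at power-SNR 10 for the decomposition; one 240 s
wideband session for spike detection; 30 partial-SD sessions for the
three-zone map; 1000 uniform-phase runs for the Rayleigh calibration; and a
4 × 3 grid of stop depths × cell depths for the intracellular relation.
These sizes keep every check within a few minutes on one CPU while leaving
the statistical margins comfortable.

## Known limitations

* The forward model is phenomenological: silencing masks and gain ramps are
  config declarations, and no conductance-based or ion-diffusion SD model is
  included (out of scope by design).
* ICA separability of weak, nearly-Gaussian sources (the flat remote source
  against a weak supragranular generator) is fundamentally limited by the
  number of *effective* samples — UP/DOWN trains carry roughly one
  independent event per 0.7 s, so short epochs leave a few percent of
  profile cross-talk regardless of sample rate.
* The stop depth is quantized to the electrode spacing; recovery beyond
  ±100 µm is not possible from the probe geometry alone.
* Clinical headline statistics (phenotype fractions, population correlation
  magnitudes) are properties of non-shared patient and animal data; the
  package validates sign- and parameter-recovery claims on synthetic ground
  truth instead.
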