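---
title: "Multi-band sensor-level MEG connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-band sensor-level MEG connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`megnet` analyses resting-state magnetoencephalography (MEG) at the
sensor level. Each recording — a channels × samples block in
femtotesla — is decomposed into seven frequency bands covering
0.1–250 Hz (slow wave 0.1–1, delta 1–4, theta 4–8, alpha 8–12, beta
12–30, gamma 30–80, ripple 80–250 Hz). In every band, a signed
functional-connectivity weight is estimated for each of the
$n(n-1)/2$ sensor pairs:

* the **magnitude** is $\sqrt{\overline{C^2_{xy}(f)}}$, the square
  root of the Welch magnitude-squared coherence averaged over all
  frequency bins inside the band, which puts the weight on a
  correlation-like $[0,1]$ scale;
* the **sign** is the sign of the zero-lag Pearson correlation of the
  two band-filtered signals, so positively co-fluctuating pairs
  ("excitatory" connections, drawn red on contour maps) get positive
  weights and anti-correlated pairs ("inhibitory", drawn blue) get
  negative ones.

Coherence by itself cannot distinguish positive from negative
coupling; combining a coherence magnitude with a correlation sign is
the smallest estimator that supports both the signed topographic
patterns and the magnitude-based graph analysis.

From each subject–band matrix the package derives

1. **topographic patterns**: after applying one fixed threshold
   $\tau$ to $|w_{ij}|$ (the same $\tau$ for every subject, so
   patterns are comparable), boolean presence of excitatory and
   inhibitory connections within the frontal, left/right temporal and
   left/right occipital sensor groups, and across the two bilateral
   pairs;
2. **graph metrics**: average connection strength
   $\overline{|w_{ij}|}$ over all pairs of the full weighted matrix;
   characteristic path length on the thresholded graph with edge
   length $1/|w_{ij}|$ (mean shortest path over reachable pairs;
   unreachable pairs are excluded and flagged rather than imputed, so
   the statistic stays on its natural scale); and the Onnela weighted
   clustering coefficient (weights normalised by the network maximum,
   nodes of degree < 2 contribute 0), which reduces to the classic
   unweighted clustering coefficient for binary weights;
3. **group statistics**: Fisher's exact test (probability-ordering
   two-sided rule, conditional odds ratio) on each pattern boolean for
   migraineurs vs controls and for migraine-with-aura (MwA) vs
   without (MwoA); two-tailed pooled-variance Student t-tests on the
   three network parameters with Bonferroni correction 0.05/3 ≈ 0.016;
   one-way ANOVA on band power (channel-mean mean-squared amplitude,
   fT²); and Spearman correlations (mid-ranks; exact permutation p for
   n ≤ 9, t approximation otherwise) of the clinical covariates
   against metrics and pattern presences within the migraine group.
   Pattern tests are reported at the uncorrected 0.05 level.

## The synthetic cohort generator

Recordings of the study this design mirrors are not publicly
deposited, so the package ships a generator that produces cohorts
with known ground truth; it is first-class, tested code and the input
to every simulation experiment.

* **Background**: each channel is independent Gaussian noise with a
  $1/f^{\gamma}$ power spectrum ($\gamma$ configurable, default 1.0 —
  a reasonable qualitative match to resting MEG spectra), synthesised
  in the frequency domain (independent complex-Gaussian coefficients
  with amplitude $f^{-\gamma/2}$, one inverse FFT) and scaled to an
  exact per-channel RMS (default 100 fT, a plausible order of
  magnitude for axial gradiometer background; no amplitude figures
  are published for the reference recordings, so this is a free
  parameter, not a calibrated one).
* **Couplings**: a coupling specification names a band, one region or
  a region pair, a sign, a strength (shared-source RMS as a multiple
  of the background RMS), a prevalence, and a target group. For each
  subject of that group, expression is a Bernoulli draw at the
  prevalence; an expressed coupling adds one band-limited Gaussian
  source to all channels of the region(s), negated on the second
  region when the sign is −1 — which directly realises anti-correlated
  band amplitudes. A within-region inhibitory coupling splits the
  region's channels into two sign groups.
* **Cohort structure**: defaults are 23 migraineurs (first 10 MwA)
  and 23 controls. Clinical covariates are drawn independently and
  uniformly within the demographic ranges of the reference cohort
  (age 20–40 y, history 2–30 y, 1–4 attacks/month, attack duration
  1–72 h, pain intensity 3–8, onset-to-scan 3–20 days); no dependence
  structure between covariates is modelled, and none is claimed for
  the real cohort. Controls carry `NA` for migraine-specific fields.
* **Reproducibility**: every subject draws from an RNG stream derived
  from `(seed, subject index)`, so enlarging the cohort never
  perturbs earlier subjects, and identical configurations give
  bit-identical cohorts.
* **Scales**: the package's desk scale is 64 channels, 1200 Hz, 60 s;
  the full 275-channel, 6000 Hz, 120 s geometry is available by
  configuration. Sensor layouts are golden-angle spirals on the upper
  hemisphere with angular region labelling (anterior → frontal,
  lateral → temporal, posterior → occipital split by hemisphere,
  vertex → central, upper posterior → parietal); a fix-up step
  guarantees that the five pattern regions are always populated, down
  to the 8-channel minimum.

What the generator does **not** emulate: volume conduction / field
spread (each sensor sees only its own noise plus planted sources), a
realistic head geometry or leadfields, heteroscedastic sensor noise,
artifacts, or any attack/aura dynamics. Passing simulation tests
therefore demonstrates that the pipeline recovers what it is designed
to recover under its own generative assumptions — not that those
assumptions capture real migraine MEG.

## Numerical choices

* **Filters.** Band-passing uses a true Butterworth band-pass:
  the analog order-4 low-pass prototype is mapped through
  $s \to (s^2+\omega_0^2)/(Bs)$ and discretised biquad by biquad with
  the bilinear transform, then applied forward and backward
  (zero-phase) with odd-reflection padding (about $1/f_{lo}$ seconds)
  and steady-state initial conditions. Second-order sections are
  essential: the direct-form coefficients of the 0.1 Hz edge at kHz
  sampling rates are numerically unusable. Gain is exactly 1 at the
  geometric band centre; one octave outside either edge the
  attenuation exceeds 40 dB (the acceptance requirement is 20 dB).
  The first and last 2 s of each filtered recording are discarded
  before connectivity (when the recording is at least 20 s) to drop
  residual edge transients.
* **Welch estimator.** 4 s Hann-tapered segments with 50 % overlap by
  default. Because a band-filtered signal carries no information
  above its upper edge, it is decimated to at least 4× that edge
  before the spectral stage; the frequency resolution (1/segment
  length) and the number of segments $K$ — hence the estimator's
  statistical properties, including the $1/K$ coherence bias floor —
  are unchanged, while the cost of the low bands collapses.
* **Graph metrics.** Shortest paths use a vectorised Floyd–Warshall
  relaxation; tests cross-check it against an independent scalar
  implementation and against `igraph::distances`. Clustering uses the
  matrix form of the Onnela coefficient. The same $\tau$ (default
  0.5) serves metrics and maps; $\tau \to 0$ recovers fully weighted
  path/clustering behaviour, and the choice is recorded in the
  pipeline log.
* **Degenerate inputs.** Zero-variance channels get zero
  rows/columns with a warning; disconnected graphs report
  `connected = FALSE`; a graph with no suprathreshold edge has
  infinite path length and zero clustering; constant samples give
  t = 0, p = 1 (equal means) or |t| = ∞, p = 0 (distinct means);
  tied ranks fall back from the exact to the t-approximate Spearman
  p-value.

## Design choices that were genuinely open

* The reference analysis names "coherence" but also signed
  connections; the magnitude/sign split above was chosen over
  alternatives (imaginary coherence, amplitude-envelope correlation)
  because it stays closest to both statements with the least
  machinery. No volume-conduction-robust variant is offered, matching
  the scope of the original analysis.
* The fixed display/analysis threshold value is not published; 0.5
  was fixed once as the package default and is configurable. Pattern
  presence requires at least `min_edges` (default 1) suprathreshold
  edges, making the otherwise visual judgement explicit.
* Sensor-to-region membership is a property of the layout file, not
  of the algorithms; the generator's angular convention is one
  reasonable choice and any layout with the seven region labels can
  be supplied instead.
* Head-position QC (the 5 mm rule) is exposed as a pure function on
  fiducial coordinates; synthetic cohorts default to zero movement.
* The artifact rule (>6 pT) flags recordings rather than silently
  deleting them; exclusion is a pipeline switch, keeping QC auditable.

## Problem sizes used by the shipped experiments

The simulation experiments are sized to run comfortably on a single
CPU; all sizes below are the package's own choices and are encoded in
the defaults of `null_calibration()` and
`planted_effect_experiment()`.

* **Type-I calibration**: null cohorts of 12 + 12 subjects, 16
  channels, 1200 Hz, 30 s, slow band, 150 replicates in the test
  suite (100 in the acceptance script). The slow band is used because
  it carries the primary group contrast; its 4 in-band bins also give
  the threshold-crossing statistics enough variance to be observable
  at all.
* **Planted-effect recovery**: 100 cohorts of 23 + 23 subjects (10
  MwA) at 16 channels, 600 Hz, 20 s, with the frontal slow-wave
  excitatory coupling at prevalence 0.75 (migraineurs) vs 0.05
  (controls) and the bilateral-occipital theta inhibitory coupling at
  prevalence 0.9 (MwoA and controls) vs 0.05 (MwA), strength 2.
* **Determinism**: the end-to-end pipeline is rerun twice on a
  12-subject, 16-channel, 20 s, seven-band configuration and must be
  byte-identical.

## Known limitations

* With the default $\tau = 0.5$ and tens of seconds of data, the
  in-band averaging concentrates null coherence near $\sqrt{1/K}$
  (≈ 0.3), so null networks are very sparse. Two consequences are
  worth knowing. First, the discrete statistics are conservative
  under the null: the Fisher pattern test and the clustering t-test
  reject far below the nominal 5 % (pattern prevalences are nearly
  all-false, clustering piles up at zero), while the continuous
  strength and path-length t-tests calibrate correctly. Second, this
  very sparsity is what makes planted couplings (coherence ≈ 0.9)
  detectable with essentially no false positives.
* Graph metrics are computed on $|w|$; sign enters only the pattern
  analysis.
* Sensor-level only: no source reconstruction, no leadfield, no
  correction for field spread — a real-data analogue of the
  excitatory/inhibitory sign would partly reflect sensor geometry.
* The generator's amplitude scale and coupling strengths are not
  calibrated to any real recording, because no such calibration data
  are published; only relative/contrast conclusions should be drawn
  from simulations.

## File formats

Layouts are JSON (channel ids, 3D positions, region labels);
recordings are tab-separated channel × sample matrices with a JSON
sidecar (sampling rate, channel ids, unit, QC flags, band);
connectivity matrices and all result tables are TSV; every pipeline
run writes a parameter log and an MD5 manifest of its outputs.
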