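# megnet — multi-band sensor-level MEG connectivity networks

`megnet` is an R package for analysing resting-state
magnetoencephalography (MEG) functional connectivity across the full
0.1–250 Hz range, and for simulating synthetic MEG cohorts with known
ground truth to validate that analysis. It is aimed at researchers who
study frequency-specific network alterations in clinical populations
(the package's running example is episodic migraine, with and without
aura) and who need a fully reproducible, testable sensor-level
pipeline.

## The method

Each recording (channels × samples, fT) is decomposed into seven
bands — slow wave (0.1–1 Hz), delta (1–4), theta (4–8), alpha (8–12),
beta (12–30), gamma (30–80) and ripple (80–250 Hz) — with zero-phase
Butterworth band-passes. Per band, every sensor pair *(i, j)* gets a
signed weight

&nbsp;&nbsp;&nbsp;&nbsp;*w*<sub>ij</sub> = sign(corr(x<sub>i</sub>, x<sub>j</sub>)) · √( mean<sub>f∈band</sub> C²<sub>ij</sub>(f) )

where C²<sub>ij</sub> is the Welch magnitude-squared coherence and the
sign comes from the zero-lag correlation of the band-filtered signals:
positive weights are "excitatory" (amplitudes co-fluctuate, drawn red
on contour maps), negative ones "inhibitory" (anti-correlated, drawn
blue). From the thresholded network (one fixed τ for all subjects) the
package derives regional excitatory/inhibitory presence patterns
(frontal, bilateral temporal, bilateral occipital sensor groups) and
three weighted graph metrics: average connection strength
mean|w<sub>ij</sub>|, characteristic path length (edge length
1/|w<sub>ij</sub>|), and the Onnela weighted clustering coefficient.
Group inference uses Fisher's exact tests on pattern prevalence,
pooled-variance t-tests on the three metrics with Bonferroni
correction (0.05/3 ≈ 0.016), one-way ANOVA on band power, and Spearman
clinical correlations.

Because the motivating study's recordings are not deposited, the
package includes a synthetic cohort generator (1/f background noise
plus band-limited shared sources planted in named sensor regions, with
controllable sign, strength and group prevalence) so every stage is
testable end to end. See the methods vignette
(`vignettes/megnet-methods.Rmd`) for the model, defaults and
limitations.

## Worked example

Simulate a cohort in which 75 % of migraineurs but only 5 % of
controls express a frontal slow-wave excitatory coupling, then run the
full pipeline:

```r
library(megnet)

cfg <- pipeline_config(
  cohort = cohort_config(
    n_migraine = 23, n_mwa = 10, n_control = 23,
    n_channels = 32, sampling_rate = 600, duration_s = 30,
    coupling_specs = list(
      coupling_spec("slow", "frontal", sign = +1, strength = 2,
                    prevalence = 0.75, group = "migraine"),
      coupling_spec("slow", "frontal", sign = +1, strength = 2,
                    prevalence = 0.05, group = "control")),
    seed = 2026),
  bands = default_bands()[1:3, ],     # slow, delta, theta
  tau = 0.5)

res <- run_pipeline(cfg, out_dir = "demo_run")

subset(res$results$pattern_tests,
       band == "slow" & roi == "frontal" &
       connection_type == "excitatory" &
       comparison == "migraine_vs_control")
#>   band     roi connection_type          comparison n1 n2 present1 present2
#> 1 slow frontal      excitatory migraine_vs_control 23 23       17        5
#>   odds_ratio      p_value significant
#> 1   9.581466 0.0009406056        TRUE

subset(res$results$metric_tests, band == "slow" & metric == "strength")
#>   band   metric mean_migraine mean_control statistic      p_value significant
#> 1 slow strength     0.3211324    0.2992569  5.867941 5.274398e-07        TRUE
```

17 of 23 simulated migraineurs show frontal excitatory connections
against 5 of 23 controls (Fisher p ≈ 9.4 × 10⁻⁴, odds ratio ≈ 9.6),
and mean slow-band connection strength is elevated in the planted
group (0.321 vs 0.299, Bonferroni-significant). The run directory
contains the layout, cohort table, one connectivity matrix per
subject and band, the metrics/patterns/power tables, all statistical
result tables, a parameter log and an MD5 manifest; rerunning the
same configuration reproduces every file byte for byte.

A thin command-line wrapper is installed at
`inst/scripts/megnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/megnet.R", package="megnet"))')" \
    --config config.yaml --seed 1 --out out_dir
```

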