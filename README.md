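# microstates

Resting-state EEG microstate analysis in R: segmentation of multichannel
EEG into the four canonical quasi-stable scalp topographies (classes
A–D) and group-level statistics on their temporal dynamics.

EEG microstates are brief periods (tens of milliseconds) during which the
scalp potential topography stays fixed while its strength varies and its
polarity may invert. Their temporal parameters — mean duration,
occurrence rate, coverage and transition structure — are studied as
candidate electrophysiological biomarkers, for example in prodromal
neurodegeneration (REM sleep behavior disorder, Parkinson's disease,
Lewy body dementia). This package provides the complete analysis chain
for such studies, plus a synthetic-EEG generator with known ground truth
so every stage can be validated.

## What it implements

- **Preprocessing**: polyphase resampling, zero-phase FIR band-pass
  (1–40 Hz) and 50 Hz notch, automated bad-channel detection (flatline /
  noise / spatial-correlation criteria) with spherical-spline
  interpolation, average referencing, 0.5-s / 20-SD artifact-window
  rejection, 2-s epoching. BrainVision (`.vhdr/.vmrk/.eeg`) and EDF
  readers are included.
- **Topographic clustering**: GFP-peak extraction and polarity-invariant
  Atomize-and-Agglomerate Hierarchical Clustering (AAHC), with
  GFP²-weighted global explained variance (GEV):
  `GEV = Σₜ (GFPₜ · corr(vₜ, T₍label₎))² / Σₜ GFPₜ²`.
- **Group templates**: permutation/sign alignment of subject maps,
  group-mean templates, canonical A–D labelling against built-in
  archetype fields.
- **Backfitting**: per-sample labelling by maximal |spatial correlation|,
  mean duration / occurrence / coverage / GEV per class, observed
  transition percentages and the segment-count independence null
  `E(i→j) = 100 · qᵢqⱼ / Σ_{a≠b} q_a q_b`.
- **Group statistics**: Shapiro–Wilk-gated t / Mann–Whitney comparisons,
  Pearson correlations and OLS regressions against a severity score,
  ANCOVA group×score interaction, Cohen's d, Holm/Bonferroni/BH
  adjustment, and observed-vs-expected transition tests (unpaired
  reporting convention; calibrated paired variant behind a flag).
- **Synthetic EEG**: Markov chains over smooth random topographies with
  geometric segment durations, amplitude envelope, polarity inversions,
  sensor noise and injectable artifacts; two-group demo cohorts with
  plantable, severity-scaled effects.

## Worked example

```r
library(microstates)

cfg <- generatorConfig(nChannels = 32, nStates = 4, samplingRate = 250,
                       duration = 60, meanSegmentMs = 80,
                       noiseSigma = 0.1, seed = 42)
sim <- simulateRecording(cfg)
pp  <- preprocessRecording(sim$recording, targetRate = 250)
str(pp$log)
#> List of 4
#>  $ nBadChannels    : int 4
#>  $ propBadChannels : num 12.5
#>  $ nRejectedWindows: int 0
#>  $ nEpochs         : int 30

ts   <- subjectTemplates(pp$epochs, source = "demo")
arch <- canonicalArchetypes(channelPositions(sim$recording))
lab  <- labelCanonical(ts, arch)
lab$templates
#> TemplateSet 'demo': 4 templates on 32 channels
#>   labels: A B C D
#>   GEV: 0.869

seg <- backfit(pp$epochs, lab$templates)
computeParameters(seg)
#> MicrostateParameters:
#>                   A      B      C      D
#> duration_ms  18.404 17.116 18.183 17.771
#> occurrence_s 13.367 13.183 15.117 14.600
#> coverage_pct 24.493 22.480 27.213 25.813
#> gev           0.201  0.187  0.208  0.208
#>   total GEV: 0.805
```

Reading the output: 4 of 32 channels were flagged (12.5%) and rebuilt by
spherical-spline interpolation; no 0.5-s window exceeded the 20-SD
amplitude criterion; the four AAHC templates explain 86.9% of the
GFP²-weighted topographic variance at the clustered GFP peaks and 80.5%
over all samples after backfitting. Unsmoothed backfitting of noisy data
yields short durations (~18 ms here against an embedded 80 ms segment
mean) because noise flips the per-sample assignment — the expected
behavior of unsmoothed pipelines; the embedded class structure is still
recovered (the templates correlate > 0.99 with the generating maps).

For a full two-group study, `runPipeline()` simulates (or ingests via a
manifest) a cohort, derives per-group templates, backfits every subject
and emits tidy parameter/transition CSVs plus the complete statistics
report; see also the thin CLI at `inst/scripts/microstates`
(`simulate` and `run` subcommands) and the methods vignette
(`vignettes/microstate-analysis.Rmd`).

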