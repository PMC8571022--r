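---
title: "EEG microstate analysis: models, parameters and design choices"
author: "microstates package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstates)
```

## The model

Resting-state EEG spends most of its time in one of a few quasi-stable
scalp topographies ("microstates", conventionally four classes A--D) that
last tens of milliseconds each; within a state the spatial pattern is
fixed while its strength waxes and wanes and its polarity may invert. The
package implements the standard analysis of this model:

1. **GFP.** The global field power
   $\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_c (v_c(t)-\bar v(t))^2}$
   is the spatial SD of the instantaneous map; its peaks are the moments
   of highest topographic signal-to-noise and supply the maps that are
   clustered.
2. **AAHC.** Atomize-and-agglomerate hierarchical clustering starts from
   every GFP-peak map as a singleton cluster and repeatedly dissolves the
   cluster contributing least global explained variance, reassigning each
   orphaned map to the surviving template it correlates best with
   (absolute spatial correlation -- polarity is ignored throughout), until
   K = 4 clusters remain. A cluster's template is the first principal
   direction of its member maps: unlike the plain mean it cannot cancel
   under polarity inversions, and the cluster's GEV contribution is then
   exactly its scatter matrix's leading eigenvalue (divided by the
   constant $C\sum_t \mathrm{GFP}^2$), which is what the implementation
   tracks incrementally. A naive reference implementation, recomputing
   everything from the definitions, is kept in the test suite and must
   produce identical partitions.
3. **Group templates.** Subject template sets are aligned by the
   permutation (exhaustive over 4! = 24) and per-map signs maximizing the
   summed squared spatial correlation with the running group mean,
   iterating alignment and averaging to a fixed point; the aligned maps
   are averaged per class and renormalised. A second-level clustering of
   pooled subject maps is a known alternative; the permutation alignment
   was chosen because it is deterministic and exhaustively testable.
4. **Labelling.** Group templates are assigned to the canonical classes by
   the one-to-one matching that maximizes total |spatial correlation|
   against four built-in idealized archetype fields (A and B the two
   mirrored diagonal gradients, C an anterior--posterior gradient, D a
   fronto-central focal map), synthesized on the montage in use.
5. **Backfitting and parameters.** Every preprocessed sample is labelled
   with the template of maximal |spatial correlation| (ties to the lowest
   class index; samples of near-zero GFP inherit the previous label so
   envelope zeros cannot create spurious segments). From the label runs
   the package extracts the mean duration (ms; interior runs only --
   boundary-truncated runs would bias durations down, but they do count
   as genuine visits for the occurrence rate), occurrence (onsets/s),
   coverage (% of samples), GEV
   $\left(\sum_t (\mathrm{GFP}_t\, r_t)^2 / \sum_t \mathrm{GFP}_t^2\right)$,
   and observed transition percentages over ordered class pairs, never
   counted across epoch boundaries.
6. **Transition null.** Expected transition percentages under
   independence of consecutive segment labels are
   $100\, q_i q_j / \sum_{a\neq b} q_a q_b$ with $q_k$ the segment-count
   fraction of class $k$ (a coverage-weighted variant is available).
7. **Group statistics.** Parameter cells are compared between groups by a
   Shapiro--Wilk-gated procedure (pooled-variance t when both samples
   pass at $\alpha = 0.05$, Mann--Whitney U otherwise; Welch behind a
   flag), related to symptom severity by Pearson correlation and OLS
   regression, with an ANCOVA interaction test (y ~ group * x) for cells
   whose pooled correlation is significant, and Holm adjustment (default;
   Bonferroni and BH selectable) across the 12 transition cells.

No temporal smoothing is applied by default. Unsmoothed backfitting of
noisy data produces short mean durations (tens of ms) because noise can
flip the per-sample argmax; this matches the magnitudes typically
reported by unsmoothed pipelines. `smoothLabels()` implements optional
absorption of segments below a minimum duration for users who want it.

## Preprocessing

The fixed stage order is resample (polyphase, Kaiser-windowed sinc),
band-pass 1--40 Hz plus 50 Hz notch (zero-phase FIR; the band-pass is a
difference of two unity-DC-gain lowpass kernels so DC is removed
exactly), bad-channel detection and spherical-spline interpolation
(stiffness m = 4, Legendre expansion to order 50, regularisation 1e-5),
average reference, amplitude-based window rejection (0.5-s windows, 20
robust SDs against statistics calibrated on the cleanest quartile of
windows), and 2-s epoching that never crosses a rejection cut. Filter
edge transients are confined to roughly one transition-width-determined
kernel length (about 1.7 s at a 1 Hz transition band) at each end of the
recording; attenuation figures quoted for the filters hold at the
multi-minute recording lengths the analysis is meant for.

Bad channels are flagged by three criteria. Flatline: any constant run of
5 s or more. Noise: robust z-score (> 4) across channels of the scaled
MAD of the channel's *second difference* -- the quasi-stable signal is
piecewise smooth, so its second difference is sparse and the MAD sees
essentially sensor noise; the cross-channel scale is floored at 5% of the
median level so that near-identical channels cannot manufacture
outliers. Correlation: the channel's Pearson correlation with its
leave-one-out spherical-spline prediction from the remaining channels
falls below 0.8 in the majority of 1-s windows; a second pass drops
first-pass bad channels from the predictor set so one bad channel cannot
drag its neighbours under the criterion. The spline prediction was chosen
over a distance-weighted neighbour average after the latter proved to
have a curvature bias that pushes clean channels below the 0.8 criterion
even on noise-free smooth fields.

## The synthetic-EEG generator

`generatorConfig()` / `simulateRecording()` produce multichannel
recordings with known ground truth: a Markov chain over K = 4 smooth
topographies (random combinations of low-degree solid harmonics on the
montage -- real scalp fields are spatially smooth, and spatially white
maps would make any neighbour-based channel diagnostic meaningless), with
geometric segment lengths (memoryless, matching the backfitting
assumptions; default mean 80 ms, the middle of the canonical range),
per-segment polarity inversions (p = 0.5), a rectified 10 Hz sinusoid
amplitude envelope scaled to mean 1 (so GFP waxes and wanes at alpha-band
rate and GFP peaks exist), and spatially white Gaussian sensor noise
(default SD 0.1 of the unit map norm). The default montage is a
deterministic quasi-uniform spherical cap (a stated approximation of an
extended 10/20 layout; any digitised montage can be passed in).
`makeDemoCohort()` assembles a two-group study of the reference shape (22
patients vs 46 controls, severity scores >= 17 in the patient group) with
plantable per-class duration effects that scale with the drawn severity
score; its generating maps are perturbed canonical archetypes
(`archetypeTemplateMaps()`), so a planted class-D effect surfaces under
letter D after canonical labelling.

What the generator does **not** emulate: full-rank background brain
activity, spatially correlated noise (a config hook is reserved), 1/f
spectra, and realistic ocular/cardiac artifact morphology (artifacts are
injected as flat spans, independent-noise channels and high-amplitude
bursts). Two consequences matter for interpreting green tests. First,
channels lying near the nodal lines of all four maps carry almost no
signal, so at the default noise level they are genuinely unpredictable
from the montage and may legitimately be flagged and interpolated
(typical flagged proportions at default noise mirror the double-digit
percentages reported for automated cleaning of real data); the
zero-false-positive property of the detector is therefore verified in a
low-noise, constant-envelope regime (64 channels, noise 0.005, no
envelope) where every channel's signal dominates its noise, which is the
regime the criterion's premise describes. Second, per-sample spatial
correlations after the full chain are capped by in-band noise (about
0.94 at noise 0.1 on 32 channels), while the *templates* recovered by
clustering remain essentially exact (> 0.999); tests assert the former
at 0.9 and the latter at 0.95.

## Statistics: calibration notes

Each subject's observed and expected transition percentages are computed
from the same segment counts, so they co-fluctuate. An unpaired t-test of
observed vs expected (the common reporting convention, and the default
here) ignores that positive correlation and is markedly conservative
under the independence null (empirical size about 0.01 at nominal 0.05).
The paired variant (`paired = TRUE`) uses the within-subject differences
and is correctly calibrated (empirical size about 0.05); the acceptance
suite asserts the paired test's size inside [0.03, 0.07] and that the
unpaired default never becomes anticonservative. The normality-gated
group comparison requires *both* samples to pass Shapiro--Wilk; constant
samples (Shapiro--Wilk undefined) fall through to Mann--Whitney and are
flagged.

## Numerical choices and degenerate inputs

Polarity-invariant correlations are Pearson across channels with the
absolute value taken; zero-variance maps are an error. AAHC tie-breaks:
equal GEV contributions atomize the lowest cluster index first; equal
assignment correlations go to the lowest cluster index; GFP-peak ties
within the minimum distance keep the earlier sample. Per-map rescaling of
the input legitimately changes AAHC results (contributions are
GFP-weighted); sign flips and common scaling do not. Templates and
archetype matching are exhaustive over the 24 permutations, so labelling
is deterministic. Classes absent from a segmentation report NA duration
(not zero), zero occurrence and zero coverage. Recordings failing basic
sanity (under 4 usable channels; over half of all windows rejected) abort
rather than produce silently degraded output.

## Problem sizes used by the tests and the acceptance script

The validation suite runs synthetic studies at desk scale, chosen as the
smallest sizes at which the checked properties are stable: template
recovery on 4 subjects x 120 s at 32 channels; parameter recovery on one
noise-free 120-s subject; AAHC oracle equivalence on 50 instances of up
to 40 maps on 8 channels; the transition-null size on 200 cohorts of 20
subjects; planted-effect recovery on 20 cohorts of 22 + 46 subjects
(label-sequence level); detector false positives on 100 seeded 64-channel
minutes; and the acceptance script's full end-to-end study on 68 subjects
x 60 s at 19 channels and 250 Hz (recordings are synthesized at the
analysis rate; the resampler is exercised separately). Statistical
engines are cross-validated against an independent implementation
(scipy/numpy) on 50 seeded datasets.

## Known limitations

Modified k-means and other clustering families are out of scope (AAHC
only). Artifact windows are rejected, not reconstructed; an external
cleaner (e.g. an ICA-based one) can be plugged in between rejection and
epoching via the `cleaner` hook. The canonical archetypes are idealized
fields, not normative empirical maps; labelling of real data should be
reviewed. Headline numbers from any specific clinical study depend on
its raw recordings and cannot be reproduced from synthetic data; the
package's claims are therefore property-based (recovery of known ground
truth, calibration of tests, oracle equivalence).
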