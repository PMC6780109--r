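---
title: "Peak quality classification and picker optimisation in peakforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak quality classification and picker optimisation in peakforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated peak picking is the weakest link in large-scale GC-MS
metabolomics. Different algorithms (and the same algorithm under different
parameters) report substantially different peak sets, and the raw count of
detected peaks is a poor quality metric because it rewards parameter
settings that also flood the result with noise. peakforge addresses this by
treating *peak quality* as a first-class, machine-learned quantity:

1. Candidate peaks are harvested from pooled/QC samples with several
   pickers over wide parameter ranges.
2. A human (or, for simulated projects, a rule-based auto-labeller) assigns
   each apex-centred peak window one of **seven quality classes**:
   A (apex shifted left), B (centred apex), C (apex shifted right),
   D (noise), E (peak much narrower than its window), F (peak truncated by
   the window border), G (merged/shoulder doublet). A, B and C are *high
   quality*; D is noise; E, F, G are intermediate-quality true peaks that
   deserve manual review rather than silent quantification.
3. A support vector machine per picker learns the classes from the labelled
   windows.
4. Each picker's parameters are optimised by exhaustive grid search against
   a class-weighted score, computed on optimisation samples disjoint from
   the training samples.
5. The optimised pickers run on the full dataset; their classified peak
   sets are filtered, deduplicated, merged across algorithms, and split
   into high-quality / review / noise partitions. Only the high partition
   feeds the feature table, annotation and statistics; nothing is deleted.

## Peak windows and preprocessing

A window is the intensity matrix of the peak's m/z channels (default
`n_mz = 10`, ranked by apex height, zero-padded when the compound has fewer
fragments) over `n_t = 41` time points spanning `window_s = 8` s centred on
the apex. Eight seconds is twice the typical 4 s full base width of a
capillary-GC peak, which leaves room for the E and F geometries to be
expressible; none of the window dimensions is critical as long as training
and classification use the same ones (they are recorded inside the trained
classifier and reused automatically).

Preprocessing is deliberately transparent: per channel, a linear baseline
through the means of the first and last 10 % of columns is subtracted and
negative values are clipped; the window is then scaled by its global
maximum and flattened row-major. The resulting vector is invariant to
per-channel additive offsets and to global rescaling, so the classifier
sees shape, not abundance.

## The classifier

A multi-class (one-vs-one) RBF-kernel SVM is trained per picker algorithm,
with `(C, gamma)` chosen over a log grid (`C` in 0.1-100, `gamma` in
1e-4-1) by 5-fold stratified cross-validation under a fixed seed. The
recommended training-set size is at least 700 labelled windows with at
least 7 in the smallest class; smaller sets train with a warning. The
chosen pair, per-fold accuracies and preprocessing parameters are stored in
the returned object, so classification is reproducible from the object
alone.

## Scoring and grid search

Counting the peaks per predicted class in an optimisation sample gives
counts `n_A ... n_G`, scored linearly:

    S = sum over classes of w_c * n_c,

with defaults `w_A = w_B = w_C = +1`, `w_D = -1`, `w_E = w_F = w_G = -0.5`.
The weights are user-definable (subject to a positive high-quality weight
and a non-positive noise weight) to favour discovery versus precision. The
parameter optimum is the exhaustive-grid argmax of `S` with deterministic
tie-breaks (fewest class-D peaks, then lexicographic parameter order).
Plain grid search is used on purpose: the score landscape is shallow and
broad, so descent or annealing buys nothing and can stall in local optima.
A useful diagnostic of the whole approach, reproduced in the test suite,
is that the grid point with the *most* peaks is not the optimum - its
extra peaks are predominantly class D.

## Built-in pickers

Both pickers operate per EIC (bin width = the `step` parameter for the
matched filter, 1 Th for the CWT picker) and estimate noise as 1.4826 x MAD
of the filter response, which is robust and parameter-free.

* **matched_filter** convolves each EIC with a Gaussian second-derivative
  kernel of the configured FWHM; apexes are response local maxima above
  `snthresh` times the noise scale, and boundaries sit at the response
  zero-crossings. Convolution pads by edge replication: zero padding would
  fabricate a response step wherever a run ends on an elevated baseline
  (column bleed), which previously produced a spurious late-RT
  pseudospectrum.
* **cwt** computes a Mexican-hat wavelet transform over scales spanning
  `[peakwidth_min, peakwidth_max]`, skips EICs failing the intensity
  prefilter (`prefilter_k` consecutive points above `prefilter_i`), and
  reports best-scale response maxima. Scale mismatch is rejected through a
  measured-width gate - the detected FWHM must fall inside
  `[0.5 * peakwidth_min, 2 * peakwidth_max]` - because on clean signals the
  MAD noise estimate collapses towards zero and a response threshold alone
  cannot veto a 2 s peak found by a 20-40 s search. Boundaries are apex
  +/- 1.5 x the matched half-width.

Single-m/z hits are grouped into compound-level pseudospectra by
single-linkage clustering of apexes within `rt_tol` (default 1 s); the
grouped peak takes the union of channels, the height-weighted mean apex and
the envelope bounds. Grouping precedes classification because the
classifier consumes full compound spectra. The 1 s default is a
configuration choice, not a value inherited from any reference data.

## Integration

Duplicates are defined by *both* an apex-RT tolerance (2 s defaults) and a
binned spectral cosine (>= 0.8): RT alone would collapse co-eluting but
spectrally distinct compounds. Within a duplicate group exactly one peak
survives, chosen by class priority `B > A = C > G > E > F > D` (centred
apexes quantify most reliably), then larger summed apex intensity, then
earlier RT. The same criterion merges peak sets across algorithms, with
provenance recording every contributing algorithm. Every input peak is
accounted for: high + review + noise + dropped-by-min-m/z +
collapsed-as-duplicate always equals the input count, and the identity is
asserted in the tests. The minimum fragment filter defaults to 3 m/z.

Cross-sample alignment is greedy: clusters are seeded from the most
intense unassigned feature and absorb at most one feature per sample within
the RT/similarity gates. Cells hold summed apex heights (areas alongside);
missing values are zeros with an explicit mask. Group statistics use
Welch's t-test on `log2(x + 1)` with the fold-change sign convention that
negative values denote a decrease (`-1/r` for ratios below 1); raw
p-values by default, Benjamini-Hochberg behind a flag. Features with an
all-zero group are flagged, not tested.

## Annotation

Retention indices come from linear interpolation between n-alkane anchors
(the appropriate form for temperature-programmed GC; the logarithmic
isothermal form is available via `method = "kovats"`), with flagged linear
extrapolation outside the ladder. Library matching is *reverse* weighted
cosine - computed over the library spectrum's m/z positions only, weights
`mz^2 * sqrt(intensity)` on both sides - which ignores contaminating query
ions from co-elution. A hit is high-confidence only if it lies within the
1.5-RI-unit window *and* scores above 0.9; candidates inside the window
with lower similarity are reported as low-confidence, and candidates
outside the window are never reported.

## The simulator: what it emulates, and what it does not

The synthetic-data module exists so the entire workflow is testable
without instrument data. It emulates: Gaussian and exponentially modified
Gaussian elution with ~4 s full base widths at a 5 Hz scan rate,
multi-fragment EI spectra (4-8 fragments, base peak abundance 1),
baseline with slow linear drift, end-of-run column bleed as a monotone
ramp after its onset, zero-truncated Gaussian shot noise, sporadic
one-scan spikes, and a configurable per-sample RT offset. Ground truth
records every injected fragment and the *observable* apex (the profile
mode, which differs from the Gaussian centre for skewed peaks).

The class-window generator produces all seven classes from parametric
templates (shifts of 25-35 % of the window for A/C versus <= 5 % for B; a
<30 %-width peak for E; border truncation for F; a doublet with
valley-to-apex ratio in 0.55-0.90 solved numerically for G; active-channel
counts varied as real compound windows vary). A rule-based checker
re-derives the injected label from window geometry alone and agrees with
the generator >= 99 % of the time at SNR >= 50; it doubles as the
auto-labeller for fully synthetic projects.

Not emulated: isotope patterns, mass accuracy drift, detector saturation,
retention-time warping beyond a constant offset, and real co-elution
statistics. Passing tests on this generator therefore demonstrate the
correctness and internal consistency of the workflow - recovery of known
apexes, exactness of the filters and scores, gate enforcement - not
instrument-grade performance on biological matrices, which still requires
manually labelled training data as in any real deployment.

## Numerical choices and degenerate inputs

* Seeds: a single project seed is fanned out per step (and per window /
  per run) through a deterministic integer derivation; all seeds stay
  below 2^31.
* All-zero windows preprocess to all-zero vectors; flat EICs yield no
  peaks; empty peak lists flow through every stage unchanged.
* Peaks detected at the very first/last scan get half-scan-width bounds so
  apex < end always holds.
* MSP intensities are written on the NIST 0-999 integer scale and
  max-normalised to 1.0 on read; any positive input scale is accepted.
* CSV outputs round RTs to 3 decimals (1000x finer than the scan grid) and
  are byte-stable under re-runs with the same seed.

## Problem sizes used by the tests

The packaged tests and the acceptance script run, by choice, at desk
scale: a 700-window corpus (100 per class, SNR 50) with a stratified
70/30 split; two 12-compound optimisation runs against 27-point grids per
picker; one 30-compound study run for end-to-end recovery; 10-compound
noiseless runs for annotation. These sizes keep the full suite reproducible
on a laptop while exercising every stage at the study's stated operating
point (>= 700 training peaks, >= 2 optimisation samples, 4 s peaks).

## Known limitations

* Exactly seven classes are hard-coded; changing the taxonomy requires
  code changes by design.
* One label per window - genuinely ambiguous peaks (wide *and* skewed)
  must be labelled consistently by convention.
* The auto-labeller is only as good as the template geometry; real
  projects should label windows manually from the exported sheets.
* No multiple-testing correction by default; enable `p_adjust = "BH"` when
  testing many features.
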