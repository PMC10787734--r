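---
title: "Proteomic fingerprinting for metazoan species identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic fingerprinting for metazoan species identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`massprint` implements a complete MALDI-TOF proteome-fingerprinting
workflow for identifying metazoan specimens: deterministic spectrum
conditioning, peak detection and cross-spectrum binning, quality
screening, random-forest identification with an empirical post-hoc
acceptance test, higher-taxon fallback models, and the surrounding
machinery for tuning the data-processing parameters and sizing a
reference library. This vignette explains the models and procedures, the
parameters that matter, and the design decisions taken where more than
one defensible choice existed.

## The measurement and its conditioning

A linear-mode MALDI-TOF acquisition of crude tissue extract yields a
"fingerprint": intensities of (mostly singly charged) peptide and
small-protein ions against mass, here restricted to 2-20 kDa. Raw
spectra from different spots and days differ in absolute ion yield,
baseline shape and noise, so every spectrum passes a fixed conditioning
chain before any comparison:

1. **Trim** to a common closed interval (default 2000-20000 Da), so all
   spectra cover the same axis.
2. **Square-root transform** of intensities. Detector counts behave
   shot-like (variance roughly proportional to intensity); the square
   root renders the noise level approximately uniform along the axis,
   which the later global noise estimate relies on.
3. **Savitzky-Golay smoothing**: each point is replaced by the centre
   value of a degree-`sg_polyorder` polynomial least-squares fit over
   `2*sg_half_window + 1` points (defaults 3 and 10). Smoothing operates
   on the sample index; near the edges the polynomial is fitted on the
   truncated window. The defaults are ordinary choices for this
   instrument class; the acquisition itself fixes no value.
4. **SNIP baseline removal**: the iterative clipping recursion
   `y_i <- min(y_i, (y_{i-k} + y_{i+k})/2)` with the window half-width
   `k` running 1..m (optionally m..1; implementations differ, so the
   schedule is a flag). The default m = 22 is the value at which the
   grid search described below bottoms out; note that an optimum of this
   kind is specific to the implementation it was measured under.
   Clipping is applied after the global square-root transform; no
   additional transform is applied inside the baseline estimator.
   Negative residuals after subtraction are clamped to zero.
5. **TIC normalisation**: division by the summed intensity, making every
   spectrum a discrete distribution over the mass axis.

The chain is deterministic and its stages are exposed individually, so
each contract (closed trim interval, polynomial reproduction of the
smoother, pointwise dominance of the baseline, unit total) is testable
in isolation.

## Peaks, binning, and the feature matrix

**Noise** is estimated globally as `1.4826 * MAD` of the conditioned
intensities — robust to the peaks themselves sitting in the tail. A
degenerate zero MAD falls back to a machine-epsilon scale with a
warning.

**Peak detection** keeps point *i* iff its intensity exceeds
`snr * noise` and is the maximum of the window `[i-hws, i+hws]`; exact
ties keep the leftmost point, which makes detection deterministic and
order-independent. Raising either `snr` or `hws` can only remove peaks,
a monotonicity the tests assert. Defaults `snr = 3`, `hws = 7` are the
grid-search optimum.

**Binning** makes peaks comparable across spectra. All peaks are pooled
and sorted; a candidate group becomes one feature iff (a) every member
is within `tolerance * mean` of the group's mean mass (default relative
tolerance 0.002) and (b) no spectrum contributes two peaks. A violating
group is split at its largest internal mass gap (leftmost on ties) and
re-examined. Because re-labelling peaks with bin means can enable
further merges, the pass is **repeated until the feature count is
unchanged between rounds**; the count is non-increasing and bounded by
one, so convergence is guaranteed.

The **feature matrix** holds one row per specimen (technical replicates
averaged per feature by default — the replicate-aggregation rule is not
fixed by the acquisition, so a `separate` policy is provided for
sensitivity analysis) and one column per converged bin, zero where a
peak is absent. Rows are then **Hellinger-transformed**
(`sqrt(x / rowsum)`), the standard variance stabilisation for
composition-like data; each row becomes a unit vector of square-rooted
proportions.

## Quality screening

Spectra are screened with an **arc-length atypicality score**
`A = sum |I_{i+1} - I_i| / max(I)` on the TIC scale: clean
peak-on-baseline traces travel little relative to their tallest peak,
noisy or distorted ones travel far. Scores above the Tukey fence
`Q3 + 1.5 IQR` are flagged for review, above `Q3 + 3 IQR` for discard;
if discards leave a species with a single specimen, that specimen is
discarded too, since a one-specimen class cannot be trained on. The
score is a deliberate, explicit re-specification of the screening
statistic in common MALDI QC tooling — the intent (flag atypical
spectra for a human eye) is preserved, bit-level parity is not claimed.

## Random-forest identification and the post-hoc test

A random forest (default `ntree = 2000`, `mtry = 35`, clamped to
`floor(sqrt(p))` when the matrix is narrower) is trained on the
Hellinger intensities at a chosen taxonomic level. Out-of-bag (OOB)
error is the model's quality measure throughout. Beyond the forest, the
model stores, per class, the **empirical distribution of OOB assignment
probabilities** of that class's own training rows — the fraction of OOB
trees voting the true class.

A query is assigned its majority-vote class (ties broken towards the
lexicographically first label, for determinism) with vote fraction
`prob`. The **post-hoc test** computes the left-tail proportion of the
predicted class's stored distribution at `prob`; the identification is
*accepted* iff that proportion exceeds `alpha` (default 0.05). A query
whose assignment probability sits below everything the model ever
produced for genuine members of that class is thus flagged as a likely
false positive — the guard for querying a library with a species it
does not contain.

Two practical notes on this empirical test. First, external queries are
aligned to the model's feature masses by re-binning their *peaks*
(nearest feature within the binning tolerance); the intensity of
unmatched query peaks stays in the Hellinger denominator so query rows
are normalised exactly like training rows were. Second, the test's
granularity is `1/n` for `n` stored values per class: with few
specimens per species the test can only distinguish "below the observed
minimum" from "inside the distribution", which caps the acceptance rate
of genuine members near `n/(n+1)`. Well-sampled reference libraries
(15-20 specimens per species) are therefore needed before the nominal
`alpha` is meaningful — the same reason permutation tests need at least
`1/alpha - 1` replicates.

**Evaluation protocols.** Leave-one-out identification removes one
specimen (all its replicates), retrains, and identifies it; summaries
report fraction correct and fraction correct-and-accepted, overall and
per class/phylum. The higher-taxon fallback removes *all* spectra of a
species, trains at class or phylum level, and classifies the removed
specimens — the realistic situation of querying a library that lacks
the species. Congeneric affinity asks how often a removed species is
assigned to a congener. Gini importance ranks the discriminating
features; bootstrap clustering (resampling features with replacement)
scores the stability of hierarchical groupings, with newick export.

## Tuning and library sizing

`grid_search` evaluates the full Cartesian product of baseline
iterations, `hws` and `snr` by running the entire chain per grid point
and recording the species-level OOB error; each point uses a seed
derived from the master seed and its coordinates, so rows are
individually reproducible and evaluation order is irrelevant. The
canonical ranges (baseline and HWS 5-30, SNR 3-20) expand to 12,168
combinations. Ties on OOB error are broken towards fewer features, then
lower `snr`, `hws`, baseline iterations — preferring the most
parsimonious, least aggressive settings.

`fit_gam` then asks which parameter drives classification success: a
binomial GAM (logit link) of the OOB error on penalized smooth terms of
the three parameters, with the number of specimens as the binomial
denominator (the weighting is a modelling choice and is exposed as an
argument). Basis dimensions are capped at 5 — the responses of interest
are near-linear — and shrunk further for predictors with few unique
values; constant predictors are dropped with a warning.

`specimen_saturation` answers "how many specimens per species does the
library need": for each n in a range (default 2-11) it repeatedly
(default 100, seeded per cell) samples n specimens per eligible species
(those with at least 11), retrains, and records the OOB error,
summarised as mean/SD/min/max per n. OOB error falls and stabilises as
n grows; the package's simulated libraries reproduce that saturation
shape.

## The synthetic fingerprint generator

All of the above is validated against a generator that emulates the
structure of a real multi-phylum reference library without shipping
data. Its model:

- **Hierarchical peak inheritance**: each species' peak set is the
  union of peaks shared by its phylum, class and genus plus
  species-specific peaks, drawn uniformly over the mass window with a
  minimum separation (resolution proxy, default 60 Da). Shared peaks
  keep their mass *and* base intensity across all descendants, so
  congeners look more alike than members of different genera, and so on
  upward — the property the higher-taxon fallback exploits.
- **Biological variability**: per specimen, lognormal intensity
  multipliers (CV default 0.35) and Bernoulli peak dropout (default
  0.05) — the two simplest mechanisms that produce both
  presence/absence differences and intensity-pattern differences.
  Specimen-level draws (multipliers, dropout, mass jitter of 200 ppm)
  are shared by that specimen's technical replicates; replicates add
  only a small lognormal wobble (CV 0.1) and fresh detector noise.
- **Measurement**: Gaussian peaks (sigma 12 Da) on a decaying
  exponential baseline `a*exp(-b*m)`, sampled on a uniform 4 Da grid
  (4500 points over 2-20 kDa — desk-scale runtimes), intensities
  clipped at zero.
- **Noise**: shot-like scaling (SD proportional to the square root of
  the local intensity) with two components — white point noise and a
  *bounded* smooth background texture (uniform marginal, correlated
  over ~10 grid points). The bounded texture reflects how summed-shot
  spectra ride on chemical-background ripple rather than on heavy-tailed
  point noise; with a purely Gaussian background, maxima in the 3-4
  sigma tail would masquerade as peaks at any noise amplitude, which is
  not how good-quality acquisitions behave and would make an SNR-3
  threshold unusable on any data.

The default library is 20 species (2 phyla x 2 classes x 5 genera),
8 specimens per species, 2 replicates. Scenario helpers construct
cryptic species pairs (identical masses, intensity ratios >= 2x on part
of the peak set) and sex dimorphism (sex-exclusive peaks plus
intensity-shifted shared peaks).

What the generator does *not* model: isotope envelopes, detector
saturation, mass-dependent resolution, warping/miscalibration beyond
linear ppm jitter, matrix clusters, or correlated dropout. Passing
tests on simulated libraries therefore demonstrate the internal
consistency and statistical behaviour of the workflow, not its accuracy
on any particular instrument's output.

## Validation scenarios and problem sizes

The test suite exercises the workflow end-to-end at sizes chosen to
keep a full run in minutes:

- *Recovery and identification*: the default 320-spectrum library;
  detection must recover >= 90% of simulated peaks with <= 10% spurious
  detections, and leave-one-out identification must exceed 95% correct.
- *Saturation*: a deliberately confusable library (3 genera x 2
  congeneric species sharing 10 genus-level peaks, 12 specimens each,
  raised variability) with 25 resamples per library size; the mean OOB
  error at n = 2 must exceed that at n = 10 across master seeds.
- *Optimisation*: congeneric pairs separable only through
  species-specific peaks whose intensity is scaled to sit between the
  low and high SNR thresholds (scale 0.3, giving detected SNR mostly
  3-12). The grid's argmin must select the low SNR, and the GAM must
  flag SNR (p < 0.01) while leaving HWS — irrelevant here because peaks
  are >= 150 Da apart — non-significant. Baseline iterations are held
  fixed in this scenario because stripping low-intensity peaks is
  precisely what they do; they are not a null parameter when the signal
  is in weak peaks.
- *Post-hoc calibration*: a 20-species library at 18 specimens per
  species (a well-sampled library: past the saturation knee, and deep
  enough that the empirical test's 1/n granularity sits below alpha =
  0.05); fresh in-library specimens must be accepted at >= 90% while
  specimens of four novel species are accepted at least three times
  less often.
- *Fallback*: the default library's class-shared peaks; leave-species-
  out class assignment must reach 80%.

`scripts/acceptance.R` re-runs these computations from scratch at a
given seed and writes the resulting rates and errors as JSON.

## Numerical choices and degenerate inputs

- Duplicate masses on reading are merged by summing intensities (the
  conservative choice for counts); rows are sorted, so readers are
  permutation-invariant.
- Length-1 spectra are legal containers; operations that need more
  points (noise, smoothing) say so.
- The smoother may undershoot below zero next to sharp peaks; the
  subsequent baseline subtraction clamps at zero.
- `savitzky_golay` with `sg_half_window = 0` and
  `baseline_iterations = 0` skip their stages, which keeps the pipeline
  composable for diagnostics.
- Grid points at which the workflow degenerates (no features, a
  specimen with no peaks) are recorded with OOB error 1 and a flag
  rather than aborting the whole search.
- Feature columns are named by bin mass at 4 decimals; name collisions
  after rounding are suffixed and warned about, and the CSV round trip
  is lossless to 12 significant digits.
- All stochastic steps (forest training, grid points, saturation cells,
  simulated specimens) use seeds derived deterministically from a
  master seed and the cell's coordinates, so any single cell can be
  reproduced in isolation.

## Known limitations

- The screening score and the post-hoc test are explicit contracts of
  this package; they are not bit-compatible with the external tools
  that inspired the workflow, and the grid-search optimum (22/7/3)
  should be re-derived on one's own data rather than assumed.
- The empirical post-hoc test is conservative for thinly sampled
  classes (see above); report acceptance rates together with per-class
  reference depths.
- Binning is strict single-linkage-style splitting on the pooled peak
  set; heavily overlapping peak clouds from badly calibrated
  instruments would need warping/recalibration, which is out of scope.
- mzML is read-only; vendor raw folders are not parsed.
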