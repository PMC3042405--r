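---
title: "Label-free MS1 peptide profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free MS1 peptide profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peparray)
```

This vignette is the package's own account of the science behind each
stage: what is modeled, which knobs matter, what the synthetic data does
and does not emulate, and where the design was genuinely open.

## From scans to ions

An LC-MS1 run is an ordered series of full scans; each scan is a pair of
m/z and intensity arrays. The pipeline's first two stages reduce a scan to
charge-deconvoluted mono-isotopic ions.

**Noise and centroiding.** The scan noise level is the median of the
nonzero intensities times a factor (default 1). The median is used because
in a complex MS1 scan the large majority of data points are electronic or
chemical noise, so the median is insensitive to the peptide peaks riding
on top. Profile spectra are centroided at local maxima at least `min_snr`
(default 3) times the noise level; the centroid m/z is the
intensity-weighted mean over the apex ± 2 profile points (narrow, because
high-resolution peaks span few points and a wider window pulls in
neighboring isotopes at charge 3, which are only ~0.33 Da away), and the
reported intensity is the apex value. Centroided input passes through with
only the signal-to-noise filter.

**Isotopic clusters and charge.** Peptide isotope peaks are spaced by the
neutron-equivalent mass difference Δ = 1.0033548 Da divided by the charge.
Cluster search is greedy and intensity-descending: the most intense
unassigned peak seeds a candidate; for each candidate charge (default
{2, 3, 4, 5} — singly charged ions are dominated by matrix and solvent
species in nano-ESI and are excluded by default, re-enabled by passing
`charges = 1:5`) the ladder is walked down to the mono-isotope and up over
at most 6 members within 10 ppm. Observed member intensities are scored
against the expected envelope by normalized dot product and the best
charge is kept if the score reaches `min_score` (default 0.7) and at least
two members exist. Accepted members are consumed, which makes the
procedure deterministic and prevents double counting; ties between seeds
break toward lower m/z, ties between charges toward the lower charge.

The expected envelope comes from the averagine model: the neutral mass is
converted to an average elemental composition (C 4.9384, H 7.7583,
N 1.3577, O 1.4773, S 0.0417 per 111.1254 Da, counts rounded) and the
isotope distribution is obtained by exact convolution of the per-element
isotope distributions. This is the standard choice when the sequence is
unknown; its main limitation is sulfur-rich or heavily modified peptides,
whose true envelopes deviate from the average composition.

Deconvolution itself is exact arithmetic: MH+ = z·(m/z) − (z−1)·proton
with proton = 1.0072765 Da. Theoretical peptide masses
(`peptide_mh()`) are sums of monoisotopic residue masses derived from
atomic masses (H 1.00782503207, C 12, N 14.0030740048, O 15.9949146196,
S 31.972071 Da) plus water and a proton; methionine oxidation adds
15.9994 Da per site.

## From ions to features

Ions of equal charge whose MH+ agrees within 10 ppm in *consecutive* MS1
scans are chained. A chain qualifies as a feature when its gap-free streak
reaches `min_scans = 4` consecutive scans — a deliberate filter against
spikes — and is quantified at the apex of the mono-isotope elution
profile, with the feature MH+ as the intensity-weighted mean over the
trace. Two decisions here were open:

* **Gaps.** The qualifying streak must be gap-free, but a chain that has
  already qualified may bridge single-scan gaps. Rationale: the qualifying
  rule is a noise filter and should stay strict, while a long tailing peak
  that flickers around the detection threshold should remain one feature
  rather than fragmenting into several matrix rows.
* **Charge combination.** Apex intensities of different charge states of
  one peptide (equal MH+ within 10 ppm, apexes within 60 s) are *summed*;
  `combine = "max"` is available. Summing treats the charge states as
  split observations of the same eluting amount. The 60 s window is
  deliberately tighter than the 5-minute matrix window to avoid chimeric
  merges.

Chains shorter than 4 scans are not discarded: they form the run's *noise
list*, used later for rescue.

## Retention-time alignment

Between consecutive runs on the same column, the retention-time difference
of a peptide is largest right after the dead time and decays with
retention time. This is modeled as

dt(tR) = A · exp(−c · (tR − tm)),

where A (seconds) is the drift at the dead time tm and c (1/s) a decay
rate. The physical derivation writes the exponent as a product of a
dimensionless factor and the gradient slope, but those constituents never
appear separately in any computation, so the package fits a single
composite rate — two separate parameters would be unidentifiable from
anchor pairs. tm defaults to 120 s and is fixed rather than fitted (it is
weakly identified and nearly collinear with A); it can be overridden.

Anchors are unique mutual nearest-mass matches between two feature lists
(10 ppm; anything with several within-tolerance candidates is dropped as
ambiguous; |dt| is capped at 300 s). The fit is two-stage: pairs are
binned by retention time (20 bins), the median dt per bin suppresses the
mismatched-pair outliers that survive the mutual-match rule, and the
exponential is least-squares fitted to the bin medians (log-linear start
when all medians share a sign, Levenberg–Marquardt refinement). If every
bin median is zero the degenerate A = 0, c = 0 model is returned, which
makes alignment a no-op — so aligning an already-aligned pair is
idempotent up to the noise floor. A cubic-polynomial fallback
(`form = "poly3"`) is provided for columns whose drift does not follow
the exponential law; the exponential remains the default because it
extrapolates sanely beyond the anchor range, which a cubic does not.

The first run in a study is the reference; all others align to it. This is
arbitrary but deterministic.

## The profile matrix

Features from all runs are aggregated within a 10 ppm mass window and a
conservative 5-minute (300 s) time window. Three rules shape the result:

* **Greedy matching.** Rows are seeded from the union of per-run features
  in descending intensity; matched features are consumed. Ties break
  toward the smaller mass difference. Every feature therefore contributes
  to exactly one row.
* **Rolling redundancy collapse.** Detections of one mass are grouped by a
  rolling rule: a re-detection within the time window of the group's
  *last* member joins the group and becomes the new reference point. A
  high-abundance peptide that tails for an hour — far longer than the
  window itself — is still recorded as a single row. The row's reference
  time is the retention time of its most intense member, since the apex is
  the quantity of record. Merged rows keep each sample's apex intensity.
* **Noise rescue.** After collapse, each remaining empty cell is searched
  for in that run's noise list within the same windows; a short trace that
  just missed the 4-scan rule fills the cell with its apex intensity. Each
  noise ion is used at most once. Rescue runs after collapse (not before)
  so that it fills cells of final rows rather than creating rows of its
  own — noise-list entries alone should never seed a matrix row.

Presence flags are derived as intensity > 0 and the row total is their
sum, so the flags can never disagree with the intensities. Missing cells
are written as 0, not blank.

## The comparison grid

To compare mass lists from different tools without trusting any tool's
retention times, masses are projected onto a fixed multiplicative grid:
first mass 1600 Da, each successive mass ×(1 + 20e-6), ending at the
first mass ≥ 2400 Da, *which is included*. This endpoint convention gives
⌊ln(1.5)/ln(1.00002)⌋ + 2 = 20,275 grid masses. Each input mass goes to
its single nearest grid point — guaranteed within the ±10 ppm matching
window because the grid spacing is twice the tolerance — and collisions
sum. Retention time is deliberately ignored here; the
`split_multiplicity_report()` diagnostics quantify the price: inputs near
a window edge that could bin either way, and grid points absorbing
several distinct masses.

## Group statistics

Replicate CVs use the sample standard deviation (n−1); relative intensity
is log10 of the row mean over the largest row mean, so the most intense
peptide sits at 0. The two-group test is the two-sided
Wilcoxon–Mann–Whitney: exact enumeration of the rank-sum statistic (with
midranks for ties) for m + n ≤ 12, otherwise the normal approximation
with tie and continuity corrections. Zero cells (absent peptides) enter
as intensity 0 by default — absence itself is evidence of differential
presence; `drop_zeros = TRUE` restricts to detected values. No
multiple-testing correction is applied by default; the significance
reference is instead a label-randomization baseline: the per-bin average
p-value histogram over (default) 10 distinct random reassignments of the
sample labels, seeded for reproducibility.

One calibration subtlety: the rank-sum statistic is discrete, so even
under a perfect null the p-value histogram is *not* exactly 5% per 0.05
bin — some bins systematically hold more support points of the discrete
null law than others, at any group size. The calibration test therefore
compares observed bin counts against the exact null mass of each bin,
obtained from the enumerated null distribution of the U statistic
(`stats::dwilcox`) pushed through the same p-value computation, at a
3-standard-deviation tolerance. That is the correct reference
distribution for the reported p-value; a flat-5% reference would fail for
every faithful implementation of the test.

## The synthetic-data generator

`simulate_run()` emulates the features of Orbitrap-like MS1 data that the
pipeline's assumptions touch, with these fixed study conditions as
defaults: a 2-hour gradient at 1 scan/s; acquisition window 400–1600 m/z;
isotope envelopes at charges 2 and 3 with averagine abundances and Δ/z
spacing; Gaussian elution (σ 8–15 s) with optional exponential tailing;
2 ppm mass jitter; 10% multiplicative replicate intensity noise
(lognormal with matched CV); 25 noise peaks per scan, uniform in m/z and
exponential in intensity (mean 50) — simple, but sufficient to exercise
the signal-to-noise thresholds; and inter-run drift following the
exponential law with A = 60 s, c = 5e-4 1/s, tm = 120 s, applied
cumulatively over consecutive replicates.

It does **not** emulate: profile-mode peak shapes (scans are generated
centroided; the centroider is tested on synthetic Gaussian profiles
separately), resolution-dependent peak widths, detector saturation,
co-eluting chimeric clusters beyond what random mass placement produces,
or electrospray ionization suppression. Passing tests on synthetic data
therefore demonstrate the pipeline's correctness under its own model
assumptions — linkage, alignment, collapse, rescue, statistics — not
robustness to every artifact of real instrument data.

Tests and the acceptance suite run the generator at desk scale — a 1500 s
gradient at 2 s scan intervals with 200 peptides and 3 replicates for the
end-to-end recovery property — which keeps the full suite under a minute
of simulation while leaving every per-scan density (peptides eluting per
scan, noise peaks per scan) at the default conditions.

## Numerical choices and degenerate inputs

* Masses are compared in ppm of the observed mass throughout; windows are
  one-sided ±tolerance.
* The grid is built by cumulative products so the neighbor ratio is
  constant to floating precision.
* `estimate_noise()` of an all-zero spectrum is 0; an empty scan yields no
  clusters; an empty feature list is an error for matrix building
  (`build_matrix()` needs at least one feature) but not for linking.
* Exact WMW enumeration caps at m + n = 12 (924 assignments), a size
  where enumeration is instant; beyond it the corrected normal
  approximation differs from the exact value by well under 0.01 for
  tie-free data at m = n = 6, which the tests assert.
* mzML/mzXML parsing is delegated to mzR; because that backend silently
  accepts files truncated before their closing tags, `read_run()` first
  verifies XML well-formedness and raises a parse error naming the last
  declared scan instead of returning a truncated run.
* Retention times are exposed in seconds everywhere, converting on read
  where needed; files use UTF-8, '.' decimals, no thousands separators.

## Known limitations

* Quantification is apex-based; area-under-curve integration is out of
  scope by design, so saturated or asymmetric peaks are represented by
  their apex only.
* The deisotoper assigns each peak to at most one cluster; genuinely
  chimeric peaks (two peptides sharing an m/z within tolerance) go to the
  more intense envelope.
* The alignment model is global in retention time; local warps (pressure
  fluctuations mid-run) are not modeled — the polynomial fallback can
  absorb some of this at the cost of extrapolation safety.
* MGF input is used for precursor lists only; fragment spectra are never
  interpreted.
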