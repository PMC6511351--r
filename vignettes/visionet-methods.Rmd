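---
title: "Methods: vision-related network connectivity and morphometry"
author: "visionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vision-related network connectivity and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visionet)
```

## Scientific setting

Cirrhosis affects the brain well before overt hepatic encephalopathy is
diagnosed, and several lines of evidence point at vision-related cortex —
lingual and fusiform gyri, calcarine cortex, and the visuospatial
attention system — as an early site of both structural and functional
change. Two complementary measurements address this:

* **Voxel-based morphometry (VBM)**: voxel-wise comparison of modulated
  gray-matter density maps between a patient and a control group, with
  inference that respects the massive multiplicity of voxels.
* **Resting-state network functional connectivity (FC)**: correlation
  structure of spontaneous BOLD fluctuations among regions of interest
  (ROIs) grouped into the primary visual network (PVN, 2 ROIs), the
  higher visual network (HVN, 4 ROIs), and the visuospatial network
  (VSN, 13 ROIs), summarized per subject as a 3×3 matrix of
  intra-network (diagonal) and inter-network (off-diagonal) coupling.

`visionet` implements both analysis chains, plus the preprocessing they
require and a synthetic-cohort generator with known ground truth, so that
every stage is testable end-to-end without access to patient data.

## The synthetic cohort generator

The generator emulates the data structure of a two-group resting-state
study: 20 subjects per group, 240 BOLD volumes at TR = 2 s (the first 4
discarded during preprocessing), a 19-ROI atlas split 2/4/13 into
PVN/HVN/VSN, and a clinical table whose variables are drawn from the
published cohort moments (e.g. venous blood ammonia 51.60 ± 33.34 µmol/L,
patients only).

**Grid.** The default grid is 24×24×24 voxels at 4 mm isotropic —
desk-scale, while leaving room for smoothing and cluster-level inference.
ROIs are 3×3×3-voxel blocks on an interior lattice, none touching the
boundary. The 27-voxel ROI size is chosen so that averaging voxel noise
(SD 0.5 by default) within an ROI leaves the ROI-mean noise small enough
(SD 0.5/√27 ≈ 0.10) that correlation attenuation by measurement noise
stays well below the recovery tolerances used in validation.

**BOLD model.** Connectivity targets are specified on the Fisher z scale
as a symmetric 3×3 matrix per group and expanded to an ROI×ROI
correlation matrix by `tanh`: every within-network pair shares the
network's intra value, every cross-network pair the corresponding inter
value — the simplest structure consistent with network-level averaging.
The default targets are the published group-mean matrices of the
reference cohorts, in which patients show reduced HVN–PVN and HVN–VSN
coupling. If a user-supplied target implies a non-positive-semi-definite
matrix it is repaired by eigenvalue clipping at zero and renormalization
to unit diagonal, with a warning. ROI signals are unit-variance Gaussian
draws with exactly this population correlation; each ROI voxel adds white
noise (`noise_sd`) and a slow drift; background voxels are pure noise.

**Drift.** The drift is a sum of two sinusoids with periods 128 s and
200 s — both below the 0.01 Hz pass-band edge — with ROI-specific random
phases. Phases vary across ROIs deliberately: a brain-wide drift with a
single phase would act as a shared signal, and the portion any
finite-window filter leaves behind would inflate every pairwise
correlation; with independent phases the residual behaves as additional
uncorrelated noise. Note that 1/128 Hz lies about one DFT bin below the
0.01 Hz edge at 472 s of data, so roughly 2–3% of that component's
variance survives *any* linear filter with a decent pass band. At the
default amplitude (1, in signal-SD units) this residual measurably
attenuates the largest intra-network entry (z ≈ 0.96 is pulled down by up
to ~0.1); the recovery benchmarks below therefore characterize
estimation accuracy at the nominal noise level with the drift generator
off, and the filter's drift suppression is validated separately by its
amplitude contract.

**Motion and clinical tables.** Motion traces are small-step random walks
(clamped within ±1.5) in 3 translations (mm) and 3 rotations (degrees);
with probability `motion_spike_prob` a single spike in (2.2, 3) units is
injected and the ground-truth exclusion label recorded. Clinical
laboratory values are drawn from zero-truncated normals whose location is
calibrated so the post-truncation mean equals the published mean
(truncation would otherwise inflate ammonia by about 4 µmol/L); the
mean ± SD presentation of the source table motivates the normality
assumption, which the table itself cannot confirm. Controls carry `NA`
for patient-only laboratory indices, matching the source table.

**Seeds.** All generators are pure functions of (configuration, seed).
Per-subject seeds derive from the master seed by a counter-based scheme
(patient *i* uses counter 2*i*, control *i* counter 2*i*+1, with separate
streams for BOLD, gray matter, motion and clinical draws), so enlarging a
cohort never reshuffles existing subjects.

**What the generator does not emulate.** No anatomy, no hemodynamic
response function, no spatial noise correlation, no scanner artifacts
beyond drift + white noise, and no registration errors (all images are
generated in a common grid, so spatial normalization is out of scope).
Passing tests on these cohorts validate the statistical machinery, not
robustness to the full complexity of real MRI data.

## Preprocessing

The pipeline applies, in order: volume discarding (default 4), motion
QC, temporal band-pass filtering, spatial smoothing. Re-running with a
fixed configuration is idempotent.

**Motion exclusion** follows the conventional 2 mm / 2° rule. "Over" is
read as strictly greater, so a value of exactly 2 passes; columns are
compared in their native units (rotations in degrees, not converted to
arc displacement). Only exclusion is implemented — the source protocol
describes no motion regression.

**Band-pass (0.01–0.08 Hz).** The default realization is zero-phase and
exactly linear, in two steps: (1) projection out of a discrete cosine
(DCT-II) subspace of all components below the low edge — the DCT's
half-bin frequency resolution suppresses slow drift that does not align
with a DFT bin; (2) an ideal FFT-domain filter that zeroes every
frequency bin outside the band. A hard FFT cut alone fails its stop-band
requirement on finite windows: a 0.005 Hz probe (one octave below the
band) can retain up to ~29% of its amplitude through spectral leakage,
versus ≤ 10% after the DCT step. Measured on 236 points at TR 2 s, the
combined filter retains ≥ 99.7% at 0.04 Hz, ≤ 9.6% at 0.005 Hz, ≤ 5.2%
at 0.2 Hz, and removes DC exactly. A zero-phase 4th-order Butterworth
(forward–backward) is available as `method = "butterworth"` for smoother
roll-off.

**Smoothing.** Isotropic Gaussian convolution parameterized by FWHM
(σ = FWHM/2.3548; the functional default is 6 mm FWHM, the gray-matter
default σ = 3 mm), implemented as separable 1D convolutions with
nearest-edge replication and a unit-sum kernel truncated at 4σ, so
interior point sources conserve total intensity; conservation and
translation-commutation hold exactly only away from the boundary.

## Voxel-based morphometry

Per voxel, a pooled-variance two-sample t statistic (zero-variance voxels
are set to t = 0 rather than NaN — synthetic backgrounds make these
common). The statistic map is enhanced by **threshold-free cluster
enhancement**:

$$\mathrm{TFCE}(p) = \sum_{h = dh,\,2dh,\,\dots}^{t_p} e(h, p)^{E}\, h^{H}\, dh$$

with `e(h,p)` the size of the connected component containing `p` at
threshold `h`. Defaults are the method's canonical `E = 0.5`, `H = 2`,
`dh` = map maximum/100, 26-connectivity (6 available); the source
protocol names the method but no parameters, so these remain
configuration, not claims. Positive and negative contrasts are enhanced
separately on t and −t; the pipeline's default contrast is control >
patient (gray-matter *reduction* in patients). The C++ implementation
processes thresholds in descending order with an offset-carrying
union-find, and is verified exactly against a brute-force flood-fill
oracle on small integer maps.

**Inference** is by max-statistic permutation: group labels are permuted
`n_perm` times (default 5000 for analyses; tests and the examples here
use 300–500), the null distribution is the maximum TFCE over voxels and
both signs, and each voxel's family-wise-error-corrected p is
`(1 + #{perm max ≥ observed})/(1 + n_perm)`, never below
`1/(n_perm + 1)`. An exact mode enumerates all label assignments for
small cohorts and is used to validate the Monte-Carlo path. Clusters are
connected components of `{p < α}` (reporting default α = 0.0002,
following the reference analysis; read as voxel-level corrected-p
thresholding followed by clustering), sorted by size then peak p, with
peaks in world coordinates and an optional ROI-based label lookup.

## Network functional connectivity

Per subject: mean time series per ROI (unweighted voxel average) →
pairwise Pearson correlations → Fisher z = atanh(r) → 3×3 network matrix
by averaging z over within-network pairs (diagonal; undefined for a
single-ROI network and reported `NA`) and cross-network pairs
(off-diagonal). Averaging happens on the z scale *before* any
within-subject or across-subject mean — the variance-stabilized scale is
the defensible one for averaging correlations — with an r-scale option
(`scale = "r"`) exposed for sensitivity checks. Degenerate r = ±1 values
(possible in noise-free synthetic data) are clamped to ±(1 − 10⁻⁷) with
a warning before atanh.

**Group comparison.** Each of the six network pairs (3 intra + 3 inter)
is tested with a pooled-variance two-sample t test (Welch available);
Benjamini–Hochberg FDR at 0.05 is applied separately within the intra
family and within the inter family, mirroring how the reference analysis
controls "within each subsystem" and stars only inter rows. Group-mean
and difference (patients − controls) matrices are reported alongside.
Recomputing the reference Table's inter-FC p-values from its printed
means and SDs does not reproduce them under either pooled or Welch
flavors (both give smaller p; the intra-VSN row does reproduce); the
implementation reports both raw and adjusted p rather than guessing the
source's exact procedure.

**Clinical correlation.** For each significant pair, Pearson correlation
and simple least-squares regression of the patient-group connectivity
values against laboratory covariates (default ammonia and bilirubin),
significant at p < 0.05.

## Numerical choices and degenerate inputs

* Correlation requires ≥ 3 paired points and nonconstant series; constant
  input is an explicit error, as is an atlas ROI with zero voxels.
* Zero pooled variance: t = 0/p = 1 when means agree, an error otherwise.
* The chi-square test is Pearson's without continuity correction (1 df).
* The BH step-up is delegated to `stats::p.adjust` and validated against
  an exhaustive evaluation of the definition on short lists.
* Band edges must satisfy 0 ≤ low < high < Nyquist; runs must have ≥ 16
  time points after discarding.
* TFCE thresholds use a tolerance of 10⁻¹² when comparing voxel values
  against threshold multiples, so integer-valued maps with `dh = 1`
  reproduce hand computations exactly.

## Validation summary and problem sizes

The test suite validates each stage against independent oracles: sampling
oracles for the generator (noise-free runs of 10⁴ volumes recover target
correlations within 0.03), FFT amplitude oracles for the filter,
flood-fill TFCE and literal BH step-up oracles, `stats::t.test` /
exhaustive label enumeration for the group statistics, and two published
summary statistics recomputable from printed moments (the age comparison,
p = 0.85, and the VSN intra-FC comparison, p = 0.5326).

Simulation studies run at reduced, stated sizes chosen to keep the suite
fast while leaving Monte-Carlo error well inside the tested margins: FC
operating characteristics over 100 cohorts of 20 + 20 subjects (236
retained volumes, voxel noise SD 0.5, drift off — see the drift note
above), where both reduced inter pairs are flagged in ≥ 80% of cohorts,
intra false positives stay near 5%, and the Monte-Carlo mean of group
means recovers every target entry within 0.05; and permutation-FWE
calibration over 200 null cohorts (12³ grid, 10 + 10 subjects, 500
permutations), where the family-wise rejection rate is 0.05 ± 0.03.
`scripts/acceptance.R` re-runs scaled versions of the same computations
from scratch.

## Known limitations

* No spatial normalization, skull stripping, slice-timing correction,
  nuisance regression, or template construction: inputs are assumed
  co-registered, which the generator guarantees and real data would not.
* The generator's noise is white in space and time; permutation FWE
  calibration on spatially correlated real noise is expected to hold by
  exchangeability but is not demonstrated here.
* Network matrices assume the fixed three-network taxonomy; other
  parcellations pass through `network_matrix` but `compare_groups`
  expects exactly three networks.
* Single-ROI networks have no intra-network connectivity; entries are
  `NA` and excluded from testing rather than imputed.
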