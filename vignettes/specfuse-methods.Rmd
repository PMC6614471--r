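---
title: "Merging infrared and elemental tissue images: models, parameters and design choices"
author: "specfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging infrared and elemental tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfuse)
```

# The problem

An FTIR microscope and an LA-ICP-MS instrument observe the same tissue
section through different physics. The infrared image is a cube: at every
6.25 µm pixel, an absorbance spectrum over 4000–700 cm⁻¹ at 4 cm⁻¹ spacing
reports the organic composition. The elemental image is a stack of nine
per-isotope intensity maps at roughly 50 µm resolution. Before the two can
be analyzed as one block of data, each modality needs its own corrections,
the grids must be brought into register, and the unrelated units must be
normalized away. `specfuse` implements that chain and the downstream
chemometrics, together with a synthetic paired-scene generator that makes
every stage testable against known ground truth.

# The FTIR correction chain

Processing runs per pixel spectrum in a fixed order — water vapor, CO₂,
scaling, baseline, SNR — and `preprocessFtir()` hard-codes that order
because the steps do not commute: scaling uses the raw amide area, and the
baseline deliberately changes that area afterwards (the suite verifies the
amide area equals its target *immediately after* the scaling step, not at
the end of the chain).

**Water vapor.** Rotational-vibrational vapor lines contaminate the
spectrum wherever the purge is imperfect. The subtraction coefficient for a
spectrum $s$ is

$$k = \frac{A(s;\,1878\text{–}1860)}{A(\mathrm{ref};\,1878\text{–}1860)},$$

where $A$ is the trapezoidal band area taken *after removing the straight
line joining the band's two endpoint absorbances*. The local two-point line
is a design choice: the band area alone would absorb any broad sample
baseline into $k$; with the local correction, $k$ responds only to the
narrow vapor line in the window, and the construction makes the output's
corrected band area exactly zero. Because the whole operation is linear, a
spectrum built as clean + k·ref is recovered to machine precision, which is
the package's strongest recovery test.

**CO₂.** The 2450–2250 cm⁻¹ interval carries no biological absorption;
values strictly inside it are replaced by the straight line between the
grid points nearest the interval ends. The operation is idempotent.

**Scaling.** Microtome sections vary in thickness by up to tens of percent;
absorbance scales with path length. Each spectrum is multiplied by
`targetArea` / its own 1730–1490 cm⁻¹ area. The target (default 100
absorbance·cm⁻¹) is arbitrary — any positive constant cancels in the later
z-scoring — and configurable. Pixels whose amide area is not positive (bare
substrate) cannot be scaled; they are flagged unusable rather than scaled
by a near-infinite factor. This flag matters downstream: see
*Registration* below.

**Baseline.** A piecewise-linear baseline through the spectrum's own values
at fourteen anchor wavenumbers (3900, 3800, 3666, 3116, 3000, 2700, 1800,
1490, 1422, 1358, 1138, 1114, 980, 900 cm⁻¹) is subtracted between the
outermost anchors. Anchors snap to the nearest grid point; no sub-grid
interpolation is attempted, matching the "spectral points" character of the
anchor list. The anchor set contains the pair 1138/1114; interpolation
knots must be monotonic, so the list is stored sorted descending while
preserving the set. After this correction the spectrum is exactly zero at
every anchor point — which is why, after fusion, those feature columns have
zero variance and are flagged rather than standardized (the
`zeroVariance = "keep"` mode of `standardizeFused()`; correlation maps show
them as no-data lines instead of NaN).

**SNR.** Noise is the plain sample SD of the 2000–1900 cm⁻¹ window — no
detrending, taking the definition at its word; a linear-detrended variant
was considered and rejected as an unstated embellishment. Signal is the
maximum over 1730–1490 cm⁻¹ above the chord joining the window's endpoint
values. Pixels with SNR below 150 are excluded from analyses; the
double-clustering display uses the stricter 500. Noiseless synthetic pixels
get an `Inf` sentinel rather than NaN.

# Elemental processing

Background rectangles drawn in no-tissue areas give a mean background
vector that is subtracted from every pixel; per-element z-scoring then puts
the wildly different count scales of the nine isotopes on a common footing.
On typical sections (tissue under half the frame) the no-tissue areas end
up negative and tissue positive, so the default tissue rule — keep pixels
with ¹³C > 0 *and* ⁶⁴Zn > 0 — follows directly from the standardization
geometry. The complementary readings of that rule are genuinely ambiguous
(a display caption reads as the complement of an OR), so "or" and
"13C"-only rules are selectable; AND-retention is the default.

Sections of different sizes are compared by zero-padding each onto a
180 × 180 frame. Padding is centered with the odd remainder going to the
bottom/right; a section larger than the frame is center-cropped with the
extra row/column removed from the bottom/right (the same convention in both
directions). Six study-sized sections stitch to exactly 194,400 spectra,
and the stitched matrix is renormalized by the per-element SD pooled over
all sections — over all pixels by default; a tissue-only pooling flag
exists because the choice is not dictated by anything stronger than
convention.

# Registration

The FTIR cube is brought onto the elemental grid in three linear stages:

1. **Rotation** about the image center by a user-supplied angle (the worked
   examples use 2°), inverse-mapping output coordinates through the
   rotation matrix and interpolating bilinearly. Pixels mapping outside the
   field become no-data. Automated angle estimation is out of scope; the
   angle is an input.
2. **Binning** by the largest integer factor that keeps both dimensions at
   or above the target ("slightly above" the elemental image), averaging
   non-overlapping blocks. For i.i.d. noise this divides the noise SD by
   the factor — the reason the registered spectra are so clean.
3. **Fourier crop** per wavenumber plane: shift the 2D DFT so the
   zero-frequency bin is centered, keep the centered block of the target
   size (for even targets the extra Nyquist line comes from the
   negative-frequency side), inverse-transform, force real, and rescale by
   the pixel-count ratio so the image mean is conserved. A pure harmonic
   inside the kept band is reproduced exactly; on smooth scenes the result
   correlates > 0.99 with brute-force block averaging.

No-data pixels are filled with the plane mean before the DFT — hard zeros
would ring — and re-flagged afterwards by nearest-pixel mapping of the
validity mask. `registerCube()` also accepts a validity `mask` from the
preprocessing (usable & SNR-passing). This matters numerically: the scaling
step multiplies bare-substrate spectra whose amide area is a small positive
noise value by enormous factors, and without masking, that amplified noise
leaks through the averaging into the low-resolution grid and degrades the
registered SNR by an order of magnitude. With the mask, registered tissue
spectra reach several times the raw per-pixel SNR, as the binning argument
predicts.

Known limitation: the Fourier crop assumes periodic content; sharp
non-periodic edges produce Gibbs ringing at the percent level. The oracle
comparisons therefore use band-limited (integer-cycle) test planes, and
real-data users should expect mild ringing at tissue borders.

# Fusion and normalization

Only 1800–900 cm⁻¹ carries the fingerprint information used downstream;
spectra are linearly interpolated onto the fixed descending grid 1800,
1796, …, 900 cm⁻¹ — endpoints included, hence (1800−900)/4 + 1 = 226
features. Each element channel is replicated five times and appended after
the 900 cm⁻¹ end, giving 271 features. Replication is a weighting device,
not physics: it makes the 9 element channels legible next to 226
wavenumbers in correlation displays and gives them meaningful weight in
PCA; the factor is configurable. A section-specific background (mean
feature vector over a no-tissue region) is subtracted, then each feature is
z-scored over the retained pixels. The SNR gate is applied after background
subtraction and before standardization — the order is not dictated
externally, and this choice keeps the background estimate independent of
the quality gate. Replicated element columns remain exactly identical
through every affine step, and feature provenance (wavenumber or
isotope + replicate index) travels with the matrix so any downstream map
can be re-labeled.

# Chemometrics

*Correlation mapping* is the plain Pearson matrix over feature pairs, with
zero-variance features flagged. *PCA* is computed from the singular value
decomposition, optionally without centering: uncentered, the first
component aligns with the mean feature vector (cosine > 0.99 in the
acceptance checks), reproducing the convention in which the first component
of fused data "is the mean". Variance fractions are squared singular values
over their total, and each component's sign is fixed so its
largest-magnitude loading is positive. *Hierarchical ordering* of pixels
uses Euclidean distances with Ward linkage (ward.D2) by default — the
linkage is not specified beyond "shortest distance" agglomeration, Ward is
the standard choice in FTIR histopathology, and single/complete/average are
selectable precisely because this is a documented deviation risk.
*Feature K-means* clusters the columns on their pixel profiles, best of 10
seeded restarts (centers drawn from distinct feature profiles) by lowest
within-cluster sum of squares, ties to the lowest restart index, labels
canonicalized by first occurrence so identical (replicated) columns always
share a label and a fixed seed reproduces the assignment bit for bit.
*Double clustering* combines both: pixels passing the SNR ≥ 500 gate are
re-standardized, ordered by the dendrogram leaf order, features split into
K = 4 clusters, and the heatmap view is exported together with the
cluster-ordered mean feature vector computed *prior* to standardization
(the "sorted spectrum" convention for display).

`crossBlockSummary()` condenses the correlation map into the quantity the
fusion exists to interrogate: the maximum and mean |r| between the FTIR and
element blocks, next to the within-block summaries, with replicated columns
collapsed. `correlationNullBound()` supplies the Fisher-z
Bonferroni-corrected null bound for a given sample size and pair count.

# The synthetic generator

`makeScene()` emulates what the pipeline must cope with, not the full
physics. The scene is an elliptical stroma blob (tissue fraction ≈ 0.59 of
the frame) containing epithelium-ringed duct lumina, observed at 128 × 128
FTIR pixels and 41 × 41 elemental pixels over the same field by default —
sizes chosen to keep a full pipeline run at desk scale while preserving
the ~3× resolution ratio of the instruments. Endmember spectra are sums of
Gaussian bands (widths 15–40 cm⁻¹: amide I/II, CH stretch, phosphate,
sugars, glycosylation), sufficient for a pipeline whose operators are
linear; Mie scattering, transflection standing waves and ablation-plume
washout are deliberately not modeled, so passing tests demonstrate correct
data handling, not instrument realism. Corruptions mirror the corrections:
a multiplicative thickness field in [0.8, 1.2], a smooth additive baseline
drift (amplitude 0.02), a per-pixel water-vapor coefficient in [0, 0.3], a
CO₂ bump, and i.i.d. Gaussian noise (absorbance SD 0.002 — placing tissue
pixels comfortably above the 150 SNR gate and duct lumina near it; element
SD 0.2 against tissue abundances of 1–5). Elemental noise is Gaussian
rather than Poisson since the pipeline standardizes channels anyway. The
elemental frame is rotated 2° from the FTIR frame, the value used in the
worked examples.

By default the element abundances are *identical across tissue classes*,
with within-tissue heterogeneity supplied by smooth per-element fields
drawn independently of the class map: the modalities are orthogonal by
construction, matching the study condition the method was built to
demonstrate. Cross-modal or within-FTIR correlations are planted
explicitly: rows of `crossCorr`/`ftirCorr` mix a latent pixel field into
both sides as $\rho L + \sqrt{1-\rho^2}\,W$, optionally sharing one latent
across several rows (the construction behind a joint "all elements + one
band" cluster). Every corrupting field is stored in the scene, rendering
is a pure function of the scene, and each preprocessing operation has a
recovery test against the stored truth.

Two subtleties the tests respect rather than hide. First, the positivity
tissue mask truncates the lower tail of any element whose tissue mean is
within ~2 SD of zero, which attenuates a planted correlation measured on
masked pixels; planted-correlation scenes therefore put the neutral
element level at 4 noise-SD, the regime real tissue contrast occupies.
Second, partial-volume pixels at the tissue boundary scale both modalities
with the covered fraction, a genuine (and realistic) source of cross-modal
correlation; the orthogonality checks use spatially flat element fields
(i.i.d. noise) so that the Bonferroni bound — an i.i.d. null — is the
correct reference.

# Numerical conventions and degenerate inputs

Band and anchor lookups snap to the nearest grid point. Trapezoidal areas
are oriented positively regardless of axis direction (axes are stored as
acquired, typically descending). Zero noise yields an `Inf` SNR sentinel;
zero denominators in ratio images and masked pixels yield `NA`. Zero-SD
features abort standardization with the offending descriptor named, except
in the pipeline's `keep` mode where baseline-anchored features are expected
to be flat. Isotope channels are re-sorted into the canonical panel order
at every read. On-disk coordinates (region JSON, pad offsets) are 0-based
(row, col) with row 0 at top; in-memory R indexing is 1-based, converted at
the I/O boundary. The internal lossless container uses R serialization;
ENVI (BSQ/BIL/BIP, float32/float64, either byte order, axis from the
header's wavelength field) and headerless per-isotope CSV grids cover
interchange with other software.

# Problem sizes in the checks

The test suite and acceptance script run scenes between 32² and 128² FTIR
pixels (8²–41² elemental) with the full 826-point axis where the complete
correction chain is exercised, and the 226-point fusion axis where only
registration/fusion behavior is at stake; planted-correlation checks use
120 × 120 / 40 × 40 scenes (≈ 950 tissue pixels). These sizes were chosen
so the whole suite completes in about a minute while leaving every
statistical check comfortably powered; all thresholds above are stated at
those sizes.
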