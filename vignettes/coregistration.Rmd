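---
title: "Co-registering Visium and MSI data: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-registering Visium and MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msialign)
```

`msialign` aligns spatially resolved transcriptomics (10x Visium) with mass
spectrometry imaging (MSI) from the same or consecutive tissue sections.
This vignette documents the underlying models, the tunable parameters and
their defaults, the synthetic data the package tests itself on, and the
design decisions taken where more than one reasonable choice existed.

## The registration model

Both modalities are reduced to 2-D point sets: Visium spot centres live in
the full-resolution H&E pixel frame (the frame of
`tissue_positions.csv`, related to the hires/lowres images by the
scale factors), and MSI pixels live in the instrument's native raster
coordinates. Registration estimates a map from the MSI frame into the
Visium full-resolution frame from user-supplied landmark pairs
$(s_i, t_i)$, $i = 1 \ldots n$ — corresponding locations identified on the
MSI data-generated image and the Visium H&E image.

**Affine** (`estimate_transform(kind = "affine")`): the six-parameter map
$f(s) = As + b$ fitted by least squares over all pairs. It needs $\ge 3$
non-collinear pairs, preserves lines and parallelism, and is the
recommended choice when landmarks are sparse or uncertain, because it
cannot produce exaggerated local distortions.

**Thin-plate spline** (`kind = "tps"`): the interpolating warp

$$f(s) = c + Bs + \sum_{i=1}^{n} w_i \, U(\lVert s - s_i \rVert),
\qquad U(r) = r^2 \log r^2,$$

subject to the standard orthogonality constraints on $w$. With the default
zero bending regularisation the spline passes through every landmark
exactly; the `regularization` parameter trades that exactness for
smoothness when landmarks are noisy. Affine maps lie in the null space of
the bending penalty, so a TPS fitted to affine-consistent landmarks
reproduces that affine everywhere — a property the test suite asserts to
$10^{-6}$ on held-out grids. TPS needs $\ge 4$ pairs and is preferable for
consecutive sections with genuine non-rigid deformation.

Two numerical details matter in practice:

* **Coordinate normalisation.** The bordered TPS system is built on
  centred, RMS-scaled source coordinates. Full-resolution pixel
  coordinates are in the thousands, and $r^2 \log r^2$ on that scale makes
  the raw system computationally singular for unremarkable landmark
  configurations; normalising restores conditioning without changing the
  fitted map.
* **Inverse TPS.** Backward image warping needs the inverse map, which a
  TPS does not have in closed form. `invert_transform()` fits a fresh TPS
  on the swapped pairs — an approximation that is accurate for the mild
  warps seen between consecutive sections, and exact for affines.

**Two-stage registration.** When an intermediate microscopy image of the
MSI section exists (e.g. post-acquisition H&E), registration proceeds in
two legs — data image → microscopy image, microscopy image → Visium — and
`compose_transforms()` chains them. Affine∘affine collapses to a single
matrix; any chain containing a TPS is kept as a sequential applicator
rather than resampled into a single spline, so composition introduces no
additional approximation.

## The data-generated image and tissue labels

MSI has no photograph of its own section, so an image is synthesised from
the intensities: each pixel coloured by its first 1–3 principal components
(RGB), or by one informative peak. Choices made here:

* PCA **centres but does not scale** peaks by default (`scale. = FALSE`):
  high-intensity structural peaks then dominate PC1, which is what makes
  tissue boundaries visible. Unit-variance scaling is available as a flag.
* PCA signs are fixed by forcing each component's largest-magnitude
  loading positive, making images reproducible across runs and platforms.
* Components are clipped at the 1st/99th percentiles before rescaling to
  [0, 255], so single hot pixels do not compress the dynamic range. A
  single-peak image caps at the 99th percentile for the same reason.
* The PNG is written with a JSON sidecar holding the raster frame
  (offsets and steps), so landmark pixel coordinates picked on the image
  convert back to MSI native coordinates exactly.

Tissue/background labels for the MSI modality come from thresholding PC1
(`tissue_labels_from_pc1()`). PC1 is oriented so the side with the higher
total ion intensity is "tissue"; the threshold is either user-supplied or
chosen by Otsu's criterion on a 256-bin quantisation of the scores
(exhaustive search maximising between-class variance). If the histogram is
degenerate and all pixels land on one side, the function warns and returns
a single label rather than failing.

## Pixel-to-spot aggregation

Visium spots and MSI pixels differ in size and spacing, so a 1:1 matching
requires a radius convention (`compute_spot_radius()`):

| mode | radius | when to use |
|---|---|---|
| `expanded` (default) | half the minimum inter-spot centre distance | comparable resolutions; discs tile the array without overlap |
| `visium` | `spot_diameter_fullres / 2` (the 55 µm spot) | MSI much finer than Visium |
| `msi` | `(pixel_pitch / 55) × spot_diameter_fullres / 2` | MSI coarser than Visium; one pixel may serve several spots |

In `expanded`/`visium` modes each pixel is assigned to the nearest spot
centre within the radius (k-d tree search; exact distance ties broken by
the lexicographically smallest barcode, a rule that exists only to make
runs deterministic). Because the expanded radius is half the minimum
centre distance, no pixel can be within radius of two spots — the code
still asserts this on every run. The expanded radius is **global** (one
value for the whole array) rather than per-spot: per-spot maximal
non-intersecting radii are underdetermined at array edges. Circles at
half the centre distance necessarily leave small interstitial gaps; pixels
falling there are reported in `unassigned` rather than silently dropped or
reassigned, so the user can see how much signal the radius choice leaves
on the table.

Reduction per spot and peak is `sum`, `mean`, or `weighted_average` with
$w_i = 1/(d_i + \varepsilon)$ and $\varepsilon = 10^{-6} \times$ radius.
The inverse-distance form is a choice (nothing in the aggregation contract
forces it); $\varepsilon$ exists only to bound the weight of a pixel
sitting exactly on a spot centre and is recorded in the run manifest.
Spots with no assigned pixels are kept as zero rows with an `empty_spots`
flag, so the output matrix stays 1:1 with the Visium barcodes.

With `fn = "sum"` in expanded mode the grand total of the output matrix
equals the summed intensity of all assigned pixels exactly — a
conservation identity the acceptance tests verify against a brute-force
all-pairs assignment.

## Alignment accuracy

Co-registration quality is scored as the fraction of spots whose
tissue/background label agrees between modalities:
$(\mathrm{tt} + \mathrm{bb}) / n$. MSI pixel labels are reduced to spot
labels by majority vote over each spot's assigned pixels; vote ties go to
"tissue", and spots with no pixels are "background". All barcodes in the
Visium object enter the denominator — including spots outside the MSI
capture area — which makes the score conservative when the two capture
areas differ; that choice is deliberate and documented rather than
configurable, so scores are comparable across runs.

The landmark benchmark (`landmark_benchmark()`) refits the registration
for every combination of landmark count k, repeat, transform kind, and
stage, drawing k pairs without replacement from the pool. Each cell's
random draw is seeded by a hash of (seed, k, repeat), so any single cell
can be reproduced in isolation and the full table is bit-identical across
runs. Cells below a transform's minimum pair count are recorded as failed
rather than aborting the sweep. `autoplot()` shows mean accuracy ± s.e.
against k.

## What the synthetic generator emulates — and what it does not

The generator (`synthetic_truth()`, `simulate_visium()`, `simulate_msi()`,
`simulate_landmarks()`, `simulate_scenario()`) provides paired fixtures
with known geometry. Its defaults are fixed study conditions, not tuning
knobs:

* **Visium**: a 14×14 hexagonal lattice with 100 px centre spacing (odd
  rows offset by half a spacing, row pitch $100\sqrt{3}/2$), so the
  minimum centre distance equals the spacing; `spot_diameter_fullres`
  = 55 px, mirroring the 55 µm spot at ~1 µm/px. A 30-gene panel is drawn
  from a negative binomial with dispersion 0.5 — the over-dispersion
  regime typical of spot-level counts — with mean 20 inside the tissue
  mask and 2 outside for the first third of genes; the panel includes
  ribosomal/mitochondrial-style names (`Rpl3`, `mt-Co1`, …) so gene
  pattern filters are exercisable.
* **Tissue mask**: an ellipse (semi-axes 500 × 380 px) with two interior
  holes. The holes are not decoration: distinctive boundary features are
  what makes landmark placement well-posed, in simulation as on real
  sections.
* **MSI**: a rectilinear raster covering the inverse-warped Visium extent
  at a configurable resolution (default 3 pixels per spot spacing,
  mimicking a 65 µm raster against a 100 µm array; the conservation tests
  use 7, ~11 000 pixels). Peak intensities are
  `baseline + effect × mask + N(0, sd)` truncated at zero, with a
  structural peak (m/z 89.02, effect 160 vs noise 8) tracking the mask and
  a compound peak (m/z 550.16) nonzero only inside two deposition discs
  covering ~2.5% of pixels — large enough that a 99th-percentile display
  cap retains them, the regime in which single-peak images are useful.
* **Warp**: an 8° rotation plus a (350, 260) px translation, displacing
  spots by ~4.5 spacings on average. That magnitude is chosen so an
  unregistered overlay is unambiguously wrong (identity-mapping accuracy
  ~0.60 on the default scenario) while registration from exact landmarks
  reaches ~0.99.
* **Landmarks**: sampled in a band around the mask boundary (where a human
  would pick them), with targets `warp(source)` plus optional Gaussian
  jitter; jitter 0 gives pools that recover the generating affine to
  $10^{-8}$.

What the generator does **not** emulate: non-rigid section-to-section
deformation (the truth warp is affine), tears and folds, MSI signal
diffusion, mass accuracy artefacts, chemical noise structure between
peaks, or realistic spectra (five peaks stand in for hundreds). Passing
tests therefore demonstrate the correctness of the geometry, aggregation
and scoring machinery — not that any particular real tissue pair can be
registered well, which remains dominated by section quality and landmark
placement.

## Degenerate inputs and tie rules

* Collinear landmark sources, or fewer than 3 (affine) / 4 (TPS) pairs,
  are fatal with the condition named; inside the benchmark the cell is
  marked failed instead.
* Duplicate landmark source points and duplicate MSI pixel coordinates
  are fatal (the latter would silently overwrite raster cells).
* Peak deduplication groups by m/z rounded to 2 decimals, keeps the peak
  with the highest total intensity across all supplied samples, and breaks
  ties toward the lower exact mass; it is idempotent.
* Pixel quality filters are strictly greater-than (a pixel with exactly
  300 detected peaks fails a ">300" threshold); spot count filters
  likewise, while fraction filters (e.g. mitochondrial content) remove at
  the threshold. Filter thresholds for MSI intensities are deliberately
  user parameters with neutral defaults: published cutoffs apply to
  vendor-normalised scales that do not transfer between instruments.
* TIC normalisation rescales pixels to the **median pre-normalisation
  total** by default rather than to 1, so downstream intensity thresholds
  keep raw-like units; `scale = "unit"` gives plain relative intensities.

## Output format choices

Aligned MSI data is written as a Space Ranger-style bundle: a 10x-schema
HDF5 feature-barcode matrix (peaks as features of type `"Peak"`, named by
their m/z strings exactly as they appeared in the input header), a
`spatial/` folder with the headered positions table, scale factors JSON
and hires/lowres images. Intensities are stored as floating point — never
rounded to integers — because TIC-normalised values are continuous and
rounding would break the conservation identity. The bundle reuses the
Visium sample's scale factors and full-resolution frame, so both bundles
overlay without further transformation, and sets `spot_diameter_fullres`
to the aggregation diameter actually used. JSON written by the package
carries 17 significant digits so write→read round trips are bit-exact.
Both tissue-positions dialects are read (Space Ranger v1 headerless
`tissue_positions_list.csv` and v2 headered `tissue_positions.csv`); the
writer emits v2.

## Problem sizes and runtime

The shipped tests run the full pipeline on the 196-spot / ~2 100-pixel
scenario (seconds), the conservation and brute-force assignment checks on
~11 000 pixels, and the benchmark sweep at 4–20 landmarks × 5 repeats ×
{affine, TPS}. These sizes were chosen to exercise every code path at
interactive speed; the algorithms are k-d-tree and closed-form linear
algebra throughout, and scale to full-size acquisitions (10⁵–10⁶ pixels)
without structural change.

## Known limitations

* The TPS inverse is approximate (swapped-pair refit); for strong warps
  the warped image and the transformed coordinates can disagree by more
  than interpolation error. Coordinates always use the forward map and
  are unaffected.
* `msi`-mode aggregation models each pixel as a disc touching spot
  centres, not as an area-overlap weighting; partial-overlap geometry is
  out of scope.
* imzML ingestion is not included; the package consumes the tabular
  exports of vendor tools, which is where peak picking and TIC
  normalisation are assumed to have happened.
* Automatic landmark detection and any intensity-based (mutual
  information) registration are out of scope by design — landmarks are
  the interface.
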