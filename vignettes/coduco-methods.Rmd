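---
title: "Methods: dual-color in situ decoding, simulation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-color in situ decoding, simulation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, parameter choices and numerical
decisions behind the package — the things a maintainer would want to know
before changing a default.

## The encoding model

Each marker is assigned an unordered pair of signal channels (a
*dual-color code*). With six signal channels and two-color codes there are
$\binom{6}{2} = 15$ possible codes. One channel pair is special: Cy5
emission leaks into the TexasRed detection band, so any code containing
TexasRed other than {TexasRed, Cy3} risks decoding a bright Cy5 spot as a
TexasRed coincidence. The default panel therefore restricts TexasRed to
Cy3 (the hematopoietic pool), leaving 11 codes. Codes are stored as sorted
2-tuples, making order-insensitivity structural rather than conventional.

A transcript is decoded when one spot in each of its code's two channels
colocalizes within `coloc_radius` (default 2.5 px — half the upper end of
the 3–5 px shrunk-spot diameter range; spots are represented as peak
points, so the radius plays the role that object overlap plays for
area-based spots).

## Decoding semantics

Spots are grouped by single-linkage chaining at the colocalization radius.
The statuses partition all candidates:

* groups spanning **more than 4 channels** are unspecific (a literal
  reading of "detectable in > 4 channels": spans of 5 or 6);
* groups spanning 2–4 channels that contain **no code as a subset** are
  off-code rejections (one record per group);
* spots in no pair are single-channel rejections;
* everything else decodes per constituent code. A 3-channel group such as
  {Atto488, Cy3, Cy5} is *not* rejected: VIM, AR-FL and PSMA are each
  decoded and the masking hierarchy arbitrates. This choice follows the
  stated motivation for masking — dense regions cause spurious
  multi-decoding, and high-expression transcripts are the prior for which
  call is real.

Matching within a code is greedy one-to-one by ascending distance with
(y, x) tie-breaks. On small random instances this agrees with an
exhaustive minimum-distance matching in ≥ 99% of cases (tested); the
greedy form is deterministic and O(n log n).

**Masking hierarchy.** Level 1: accepted AR-FL within the radius of an
accepted VIM or KRT is masked. Level 2: accepted EPCAM, PSMA, AR-V7, NE,
SLFN11 or DLL3 within the radius of a VIM, KRT, AR-FL or PSA source is
masked. The source set for level 2 includes AR-FL calls that were
themselves masked at level 1: masking is bookkeeping about which *call*
to report, but the underlying spots are physically real high-expression
transcripts and still contaminate their neighborhood. This was a genuinely
open point; the alternative (post-mask sources only) would let one VIM
call switch off an entire chain of maskings.

## Thresholding

`li_threshold()` implements minimum cross-entropy thresholding by
exhaustive search: every candidate threshold is scored by
$-\left[\sum_{bg} g \log \mu_{bg} + \sum_{fg} g \log \mu_{fg}\right]$ and
the minimizer returned. For images with ≤ 256 distinct values the search
runs on the exact value histogram, so the result is bit-identical to a
brute-force per-pixel oracle (this is asserted in the tests); continuous
images use a 256-bin histogram. Values are shifted by $1 - \min$ when the
minimum is ≤ 0, since class means enter logarithmically. A constant image
returns the constant (empty foreground) rather than erroring — the
adaptive wrapper relies on this.

`adaptive_mask()` computes tile-wise Li thresholds, interpolates them
bilinearly to a per-pixel threshold surface, multiplies by a correction
factor, and floors the surface at a lower bound. Correction factor and
lower bound are exposed per channel because that is how the original
workflow was operated (manual per-sample tuning); the pipeline defaults
(`lower_bound = 150` for spots) sit above both the noise floor and the
bleed-through ghost amplitude of the simulated world (0.15 × 600 = 90)
while staying far below the spot amplitude (600).

## Registration

`estimate_rigid()` does a coarse-to-fine search: FFT cross-correlation
over a rotation grid for an integer-translation seed, then Nelder-Mead on
the mean squared difference over the overlap, with bilinear resampling.
Accuracy on synthetic pairs is well inside 0.5 px / 0.2° for true
transforms within ±15 px and ±3° (property-tested over 20 seeded trials).
Decisions worth recording:

* "multiplying the transform matrix by the bin factor" is interpreted as
  scaling the **translation only** — literally scaling a rigid matrix
  destroys rigidity, and rotation angle is scale-invariant;
* rotation is about the image center (unstated in the original; standard
  for rigid stack registration);
* background subtraction clamps at zero, because images are unsigned;
* the full-resolution background is warped once globally, and each ROI
  then refines the small residual (±5 px, ±1°) on its own DAPI crop.

Pixels whose source sample falls outside the scan are flagged invalid and
decoded signals landing there are masked (`masked_border`).

## Segmentation

ROIs come from the binned DAPI image; each ROI keeps its own upscaled
nucleus mask so neighbouring nuclei inside overlapping boxes are excluded.
ROI thresholding takes a correction factor and floor too: a global Li
threshold on a field dominated by bright nuclei sits above the dim-nucleus
intensity, so the pipeline default is `0.25 × Li`, floored at 200 counts.

Nucleus detection runs twice: the first pass has a high threshold floor
(bright nuclei), the second runs on the remaining area (dim nuclei).
Pass-2 objects overlapping pass-1 objects are dropped, as is everything
outside the configured equivalent-diameter range. Two details matter:

* a `halo_margin` (8 px) around pass-1 nuclei is excluded from pass 2 —
  otherwise the soft intensity skirt of a bright nucleus re-detects as a
  ring at the lower pass-2 threshold;
* declumping of touching nuclei is an intensity-seeded watershed: peaks of
  the smoothed DAPI (minimum separation `declump_min_distance`) seed a
  priority-queue flood over the binary mask.

Cells are nuclei expanded by 12 px (area < 2800 px²) or 32 px (≥ 2800 px²)
via an exact Euclidean distance transform with nearest-label tracking;
contested pixels go to the nearest nucleus, so cells are disjoint by
construction. Area exactly 2800 px² takes the 32 px budget ("below or
above" leaves the tie open; larger nuclei have larger cytoplasm).

## The synthetic world

The generator states one fixed world rather than a dial to turn:

* **Scale**: 1 px = 1/6.2 µm, the scale at which the published 2800 px²
  area cutoff equals 73.6 µm² and 12 px ≈ 2 µm. Tumor-line nuclei are
  drawn with radii 34–48 px (so their areas straddle the 2800 px² budget
  cutoff), blood-cell nuclei 20–28 px.
* **Optics**: spots are isotropic Gaussians, σ = 1.2 px (FWHM ≈ 3 px, the
  lower end of the published 3–5 px shrunk diameter), amplitude 600 over a
  background of 100 with Gaussian read noise σ = 8 per scan; 16-bit
  unsigned semantics.
* **Counts**: per-class, per-marker counts follow hurdle negative
  binomials `Bernoulli(positivity) × (1 + NB(µ, size))` fitted by grid
  search so the mixture quantiles match the published positivity, median
  and IQR of the PBMC and VCaP cohorts (e.g. PBMC hem: 86% positive,
  median 3, IQR 1–5; VCaP AR-FL: 99%, median 34, IQR 25–43). The hurdle
  makes positivity exact by construction; the NB captures the
  overdispersion the published IQRs imply (Poisson spread is too narrow).
* **Artifacts**: artefacts are multi-channel autofluorescent blobs without
  nuclei; in situ false-positive cells are nuclei overlapped by such a
  blob; both render identically in the original and background scans, so
  subtraction and the dual-channel artifact mask both get exercised.
  Free-floating debris is Poisson-distributed over the field.
* **Bleed-through**: TexasRed receives 0.15 × the Cy5 content of the same
  scan. The original work gives no coefficient; 0.15 is large enough that
  an unrestricted codebook would mis-decode (the regression property the
  channel restriction exists for) and small enough to sit below the spot
  threshold at default amplitudes.
* **Misalignment**: the background scan is rigidly transformed by
  (dx = 3.5 px, dy = −2.5 px, θ = 0.4°) before noise — sub-cell, like a
  restained and remounted slide.
* **RCP exclusion**: signal centers within a cell keep a minimum
  separation of 4 px (~0.65 µm). RCPs are micron-scale amplified DNA
  balls and cannot physically overlap; without this the uniform-placement
  model stacks transcripts at separations below the optical merge
  distance, which is overlap stress, not realism. Decoding of genuinely
  overlapping signals is exercised separately by constructed fixtures in
  the unit tests.

What the simulator does **not** emulate: FFPE tissue texture, z-stack
optics (the source data are extended-focus projections), intensity
variation between RCPs of one transcript species, cell debris touching
cells, or segmentation-quality annotation noise. A green end-to-end test
therefore establishes that the pipeline recovers a clean but complete
stated world (registration + subtraction + two-tier nuclei + artifacts +
bleed-through), not that it matches wet-lab performance on patient
material.

## Classifier

The random forest is implemented in-package (bagged CART, Gini impurity,
`mtry = floor(sqrt(p))`, 100 trees, unlimited depth, majority vote with
deterministic tie-breaks) because no forest library is available in the
target environment; hyperparameters follow common defaults since the
original delegates them to CellProfiler Analyst without reporting them.
Features are the 11 marker counts plus `total` (whether `total` was a
feature originally is unstated; it is included by default and
toggleable via the `features` argument). The training split draws
200/500/100/100/100 cells per class among cells with clean quality flags;
flagged cells stay in the test set. Evaluation reports one-vs-rest
precision, recall, specificity and F1 per class, and the generalized
(Gorodkin) multiclass Matthews correlation — on two classes it reduces to
the familiar binary MCC (tested against the closed form).

Synthetic annotation rules mirror the class glosses: CTC-like cells carry
epithelial/prostate-marker counts, PBMC-like cells hematopoietic counts,
negative cells none; artefact and false-positive classes get dedicated
low-count models (multi-marker Poisson λ = 0.8 and sparse Poisson
λ = 0.35). Artefact vs false-positive is barely separable from counts
alone — as in the source data, where the distinction is morphological —
so per-class confusion between those two is expected and tolerated; the
acceptance bar is CTC recall and specificity.

## Spatial module

`points_to_regions()` follows the bin–smooth–cluster recipe: accepted
signals are binned onto a `pixel_size` grid (default 20 px), each marker
layer is Gaussian-smoothed with σ = smoothing/pixel_size grid units
(default smoothing 20), and k-means (seeded, 10 restarts) clusters the
per-cell composition vectors. k is user-set; the source shows five
region labels for its tissue but does not state k as a parameter.
`cluster_cells()` subsamples at most 10,000 profiles and uses average
linkage on Euclidean distances of raw counts (metric/linkage unstated in
the source; average/Euclidean is the common default for count heatmaps).

## Numerical and I/O choices

* TIFF I/O is a minimal in-package codec (uncompressed, little-endian,
  grayscale 8/16-bit, single strip) because no TIFF package is available
  in the target environment; it round-trips bit-exactly and reads both
  byte orders. Compressed or RGB TIFFs are rejected loudly.
* Configs, codebooks, transforms and forests serialize as JSON
  (jsonlite); no YAML parser is available.
* Coordinates are 0-based (row, col) = (y, x) everywhere; bounding boxes
  are half-open.
* The colocalization neighbor search buckets spots on a radius-sized grid,
  keeping decoding near-linear in spot count.
* All stochastic entry points (`simulate_*`, `split_training`, `rf_train`,
  `points_to_regions`, `cluster_cells`) take explicit seeds; the pipeline
  itself is deterministic.

## Known limitations

* The tissue mode reuses the cell-mode code path under different
  parameters (2×2 binning, no subtraction, Atto425/Atto488 artifact
  scans); the two-step large-tile/small-tile registration of whole-slide
  mosaics is represented by the global + per-ROI refinement pair, not by
  an explicit 26,040 px tiling.
* Spot splitting resolves same-channel peaks separated by more than the
  maximum spot diameter; transcripts closer than ~3 px in a shared channel
  merge, as they would after object shrinking in the original workflow.
* The optional cytoplasm-propagation segmentation step of the original is
  out of scope; the expansion rule is always used.
* The forest offers no class-probability calibration, only votes.
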