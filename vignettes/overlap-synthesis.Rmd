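---
title: "Synthesizing overlapping-nucleus images by optical-density compositing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing overlapping-nucleus images by optical-density compositing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OverlapSynth)
```

## The problem

Automated DNA ploidy analysis classifies microscope images of
Feulgen-stained nuclei into classes such as "single typical epithelial
cell", "two epithelial cells", "three epithelial cells", and so on.
Overlapping-nuclei classes are clinically the most interesting — malignant
cells cluster — and also the rarest in collected data, so classifiers
trained on the raw class distribution neglect exactly those classes.
`OverlapSynth` attacks the imbalance at the image level: it *manufactures*
overlapping-nucleus images from abundant single-nucleus images, rather than
resampling or reweighting feature vectors.

The physics makes this defensible.  The Feulgen stain is DNA-stoichiometric:
the local optical density $A = \lg(I_0/I)$ of a pixel (transmitted
intensity $I$ against blank background $I_0$) is proportional to the amount
of stained DNA in the light path.  When two nuclei physically overlap, their
absorbing material stacks, so optical densities — not gray values — add:

$$A = A_1 + A_2 = \lg\frac{I_0}{I_1} + \lg\frac{I_0}{I_2}
    = \lg\frac{I_0}{I_1 I_2 / I_0},
\qquad I_s = \frac{I_1 I_2}{I_0}.$$

A synthesized overlap region built with $I_s$ is therefore darker than
either source but *not* as dark as a naive gray-value sum, and the
integrated optical density (IOD) of the composite — the DNA-content proxy —
equals the sum of the sources' IODs exactly (before integer rounding of the
output grays; the test suite checks the identity to $10^{-12}$ per pixel).

## The synthesis chain

`synthesizeOverlap()` composes an $i$-cell and a $j$-cell image into an
$(i{+}j)$-cell image in six steps, each exported on its own:

1. **Segmentation** (`valleyThreshold`, `segmentImage`, `extractRegion`).
   The 256-bin gray histogram is smoothed with a width-5 moving average
   (raw histograms of small images are too jagged for a stable valley) and
   thresholded at the deepest local minimum strictly between the two
   highest modes; pixels with $f(x,y) \ge T$ are background.  If no
   interior valley exists the Otsu threshold is used and flagged in the
   result.  The largest 4-connected nucleus component is kept, interior
   holes are filled (nuclei are solid), and background pixels in the
   extracted patch are set to the white sentinel 255, so "non-white"
   traversal during overlap search is well defined.
2. **Rotation** (`rotateRegion`).  Each region is rotated by an angle drawn
   uniformly on $[0, 360)$ degrees, with bilinear interpolation on an
   expanded canvas; the mask is re-binarized at 0.5 and the region geometry
   recomputed.  Rotation about the patch center plus recomputation of the
   centroid is the same as rotation about the centroid up to a translation,
   which the placement step absorbs.
3. **Overlap length** (`sampleOverlapLength`).  The degree of overlap $d$
   between the two bounding rectangles is drawn uniformly on
   $[0, R_{\min}/2]$, where $R_{\min}$ is the smallest bounding-box side
   (width or height) over the two regions — "width" is not otherwise
   pinned down, and the smallest side is the conservative reading that
   keeps $d$ admissible for any relative orientation.  $d = 0$ is
   tangency.
4. **Placement** (`placeRegions`).  Region 2 slides along the horizontal
   axis through region 1's centroid until the bounding rectangles overlap
   by exactly $d$ (rounded to the pixel grid), vertically centered on that
   axis.  Relative orientation randomness comes entirely from the two
   rotation angles, so the angle and the length stay the only two random
   inputs of the geometry.
5. **Overlap localisation** (`findOverlapPixels`).  The bounding rectangles
   are intersected; the search rectangle is that intersection widened by
   two pixels along its width; every non-white pixel inside it that lies in
   *both* masks (mask membership operationalizes "within both contours")
   joins the reconstruction set.  Since mask overlap is a subset of
   bounding-box overlap the two-pixel padding is conservative.
6. **Compositing** (`compositeRegions`, `reconstructPixel`).  The canvas is
   filled with $I_0$; non-overlap nucleus pixels are copied unchanged;
   every reconstruction-set pixel becomes
   $I_s = \mathrm{round}(I_1 I_2 / I_0)$, clipped to $[0, 255]$.

```{r, eval = FALSE}
gen <- LCG(seed = 42)
a <- generateNucleus(nucleusSpec(c(16, 12), orientation = 20), gen)$image
b <- generateNucleus(nucleusSpec(c(14, 14), centerGray = 100), gen)$image
syn <- synthesizeOverlap(a, b, gen)
syn$meta   # angles, d, Rmin, I0, overlap pixel count, thresholds
```

### Numerical conventions

* **$I_0$.**  The background mean and the segmentation threshold are
  treated as the same quantity; the default takes $I_0$ to be the valley
  threshold of the *first* source image (always available, and consistent
  with segmenting the composite afterwards).  It is overridable through
  `synthesisConfig(I0 = ...)`.
* **Zeros.**  Gray 0 has infinite optical density; values are clamped to 1
  before OD conversion.
* **Rounding.**  Reconstruction rounds half-up, once, at composite time;
  `roundGray = FALSE` exposes the real-valued composite on which OD
  additivity is exact.
* **Boundary case.**  $f = T$ is background, so a uniform image at the
  threshold segments to all-background.
* **Ties and degenerate inputs.**  A constant image has no contrast and is
  rejected; a valley tie takes the first (darkest) minimum; adjacent or
  missing modes fall back to Otsu with a flag.

## Randomness: one generator for everything

All stochastic choices — rotation angles, overlap lengths, fixture noise,
source-pair sampling — draw from a single linear congruential generator
$x_n = (\alpha x_{n-1} + c) \bmod M$, $\lambda_n = x_n/M$, exposed as the
`LCG` class.  The method's description pins the recurrence but not the
constants, so exact replication of any particular historical draw sequence
is impossible; the package defaults to the full-period Numerical Recipes
constants $\alpha = 1664525$, $c = 1013904223$, $M = 2^{32}$ (Hull–Dobell
satisfied; the test suite verifies the full period on a small modulus).
All parameters and the seed are overridable; derived streams
(`lcgSpawn`) keep test fixtures independent of training fixtures.
Pseudo-Gaussian fixture noise is built from sums of 12 uniforms so even the
noise stays on this generator, and a whole pipeline run is bit-reproducible
from one seed.

## Source selection

To stop near-duplicate source images from being synthesized repeatedly,
`selectRepresentative()` keeps a subset of the candidate pool in which all
pairwise Euclidean feature distances strictly exceed $T$, the mean pairwise
distance of the *initial* pool.  The concrete rule — a greedy first-kept-wins
scan in manifest order, $T$ recomputed from the initial pool — is the
simplest procedure consistent with the stated goal; the original loop is
only paraphrased in prose, so ordered-vs-unordered pairs and greedy-vs-global
selection are genuinely open, and this reading is the package's choice.
Strict inequality guarantees exact duplicates always collapse.
`selectImages()` z-scores the 28-feature vectors first, since Euclidean
distance across mixed-unit features is otherwise dominated by the
large-scale ones (area, diameter).

## Features

`extractFeatures()` produces the selected 28-dimensional vector (20
morphologic + 8 texture), with a 30-name extended set adding integrated
optical density and the horizontal run-length pair.  Conventions worth
noting:

* `distance` is the mean *absolute* deviation of gray from the region mean
  and `sigma` the standard deviation of those absolute deviations, so
  `roundness = 1 - sigma/distance` stays bounded; a constant region is
  assigned roundness 1 (0/0 convention).
* `M11`, `M20`, `M02` are normalized central moments of the mask coordinate
  distribution ($\mu_{pq}/area^2$, about $1/4\pi$ for a disk), and
  `Ia`/`Ib` are the eigenvalues of that moment matrix, so `Ia >= Ib` and
  `Ia*Ib = M20*M02 - M11^2` identically.
* `mean` and `deviation` are computed on gray normalized by 255.
* GLCM texture uses 32 gray levels, distance 1, the four directions
  0/45/90/135 degrees averaged, symmetric counts, and only pixel pairs that
  both lie inside the mask.  These parameters are package choices (the
  method description names the statistics but no parameters).
* `anisotropy` (morphologic) is the moment-ellipse anisometry $R_a/R_b$;
  `anisotropy_tex` is the histogram-entropy anisotropy (fraction of the
  gray-histogram entropy contributed by levels up to the median), a signed
  quantity near $-0.5$ for symmetric histograms.  The name appears in both
  the morphologic and the texture lists of the source taxonomy; keeping
  both, under distinct names, preserves the 28-name count.
* `sides` inverts the regular-polygon isoperimetric identity
  $P^2/A = 4 n \tan(\pi/n)$ for a continuous side count; `bulkiness`
  ($\pi R_a R_b / A$) and `structurefactor` (anisometry·bulkiness − 1)
  follow the standard region-feature definitions.
* Contour perimeter uses corner-corrected chain-code weights
  (0.948/1.340), which keeps the circularity of a digitized disk within a
  few percent of 1.

No attempt is made to reproduce any published per-class feature magnitudes:
several of the printed reference values are internally inconsistent (the
second-moment scale does not match the inertia scale under the stated
formulas), so the package fixes a single self-consistent convention and
freezes the column order instead.

## Evaluation

`confusionMatrix`, `cmAccuracy`, `cmRecall`, `gMean` and `imbalanceRatio`
implement the standard multiclass bookkeeping.  The G-mean is the geometric
mean of per-class recalls; a class that is present in the test set but never
predicted correctly drives it to 0, while a class with *no* test samples is
an error (undefined recall), deliberately distinct.  Table-style ratio
output rounds half-up to one decimal, which is how 20000/16000 prints as
1.3.

## The fixture generator and what passing tests mean

The hospital image collections this method targets are not publicly
deposited, so the package ships a generator of Feulgen-like fixtures that
every stage consumes.  `generateNucleus()` renders a dark ellipse on a
bright background: intensity climbs linearly with the normalized elliptical
radius from `centerGray` at the centroid to 60% of the way toward the
background at the rim (`rimFraction = 0.6`).  The partial ramp is
deliberate: it makes optical density positive and radially decreasing
inside the nucleus, as Beer–Lambert compositing expects, while keeping a
sharp rim so the histogram retains a valley and noise-free masks are
recovered exactly.  Additive pseudo-Gaussian noise (default sd 6 gray
units) models sensor noise.  Default per-class parameter ranges follow the
8-class ploidy taxonomy: mid-size epithelial nuclei (typical brighter,
atypical larger and darker), small dark lymphocytes, small pale centrioles;
composite classes (3, 4, 5, 8) are built by the synthesis chain itself —
two epithelial singles, 2-cell + single, 3-cell + single, two centrioles.

What the fixtures do *not* emulate: cytoplasm, debris, staining artifacts,
chromatin texture, optics blur, or the intensity distribution of any real
scanner.  Passing tests therefore demonstrate that the algorithms meet
their stated contracts (geometry, conservation laws, metric arithmetic,
monotone response to rebalancing) — not that any particular accuracy level
transfers to hospital data.  Note also that in fixture land the "real"
overlap images of the test set are produced by the same synthesis chain as
the augmentation images; with real data the test set would be genuinely
independent, and the published headline accuracies (which required some
300 patients' images) are out of reach by construction.

## The imbalance sweep

`runExperiment()` reproduces the experimental design at 1/100 scale by
default: majority classes hold 200 training images while the minority
classes {3, 4, 5, 8} grow through 2, 5, 10, 20, 40, 60, 80, 100, 120, 140,
160, 180, 200 — imbalance ratios 100 down to 1 over 13 conditions.  The
source taxonomy is ambiguous about which classes are minority (one passage
says {4, 5, 7, 8}, the count table implies {3, 4, 5, 8}); the set is
therefore a plan parameter defaulting to the table's reading.  Training
sets are nested (synthesized images are appended gradually), the feature
table is extracted once, and a held-out test set of 25 images per class is
generated from a spawned, disjoint seed stream.  Source pairs for synthesis
are drawn uniformly with replacement from the representative subsets of the
donor classes, and every synthesized image's provenance (sources' class,
angles, $d$, $R_{\min}$, $I_0$, overlap pixel count) is logged.

At these problem sizes the full MLP sweep takes a few minutes on one core;
the expected outcome, checked by the acceptance suite, is a positive
Spearman correlation between balance level and G-mean — the scaled
qualitative analogue of the published monotone trend, not a reproduction of
its absolute values.  Classifier adapters delegate to standard libraries
(`nnet`, `e1071`, `mclust`, `xgboost`, `randomForest`): the contribution
under test is the synthesis method, and the learners are interchangeable
consumers.  An optional principal-component reduction (the "number of
transformation characteristics" in the reference settings) is available per
adapter and off by default.

## Known limitations

* Composites inherit $I_0$ (the first source's threshold) as their
  background gray, which is darker than the sources' native background;
  downstream consumers that mix composites and originals should segment
  each image independently, as `featureTable()` does.
* A drawn $d$ near 0 can produce tangent or barely-separated masks; if the
  composite then segments into two components, region extraction keeps the
  larger one.  For composite-of-composite builds this occasionally yields
  an image with fewer visible nuclei than its label claims — label noise
  that real datasets share, but worth knowing.
* Placement is along the horizontal centroid axis only; arbitrary approach
  directions are representable because both regions are randomly rotated
  first, but the bounding-rectangle overlap measure is axis-aligned by
  construction.
* The LCG is adequate for reproducible simulation, not for statistics-grade
  Monte Carlo; that is all the pipeline asks of it.
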