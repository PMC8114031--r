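---
title: "Methods: spatial segmentation and differential statistics for MALDI imaging of printed membrane microarrays"
author: "spotMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial segmentation and differential statistics for MALDI imaging of printed membrane microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotMSI)
```

## The measurement this package models

Membrane homogenates of extracellular-vesicle (EV) preparations are printed
as a microarray on a glass slide (4 nL per spot, 3-5 replicate spots per
sample) and imaged by MALDI mass spectrometry in negative-ion mode over an
m/z window of 550-2000. The instrument rasters the slide on a regular grid
of coordinates 150 um apart; with a printed spot diameter of 450 um, nine
raster pixels fall inside each spot. Each pixel yields one mass spectrum
dominated by membrane lipids (sphingomyelin, SM, and glycerophospholipids
such as phosphatidylcholine, PC, observed as negative ions).

The analysis has four stages, each a module of this package:

1. **Synthetic data** (`make_layout()`, `generate_dataset()`): array
   geometry and spectra with known ground truth, so every downstream stage
   is testable without instrument data.
2. **Preprocessing** (`preprocess_dataset()`): total-ion-current (TIC)
   normalization, peak picking, the 0.5%-of-base-peak filter, cross-pixel
   alignment, and assembly of the pixel x m/z-bin matrix.
3. **Segmentation** (`diana_rankcompete()`): divisive hierarchical
   clustering of pixels with a competing-random-walker split function,
   correlation-based segment colouring, and PCA.
4. **Differential statistics** (`aggregate_spot_intensities()`,
   `test_lipid_differences()`, `dual_replicate_filter()`,
   `classify_fold_change()`): spot-level aggregation, the dual-replicate
   Student-t rule for lipid forms, and the fold-change/significance filter
   for protein quantitation tables.

## Array geometry

Spots are placed on a regular grid, one sample per row, with a
centre-to-centre pitch that is a multiple of the raster spacing. The raster
is axis-aligned and phase-aligned to the spot centres (a raster node falls
on every centre); a raster node belongs to a spot when its Euclidean
distance to the centre is at most the spot radius, boundary included. This
convention reproduces the nine-pixels-per-spot geometry for 450 um spots on
a 150 um raster (`pixels_per_spot(450, 150)` is 9: the centre node, four at
150 um, and four diagonal nodes at 212 um, all within the 225 um radius).
The default pitch (600 um for default geometry) is the smallest
raster-multiple that leaves a gap between spots; pitch and raster margin
are configurable.

## The generative model of a pixel spectrum

For pixel $i$ with condition $c$ and species $s$ of a panel, the apex
intensity is

$$ y_{is} = b_s \, f_{sc} \, \lambda_i + \varepsilon_{is}, $$

where $b_s$ is the species' base intensity, $f_{sc}$ a condition-specific
fold change, $\lambda_i$ a per-pixel log-normal TIC scale factor with mean
1 and coefficient of variation `tic_scale_cv`, and $\varepsilon_{is}$
Gaussian additive noise. Peak positions are jittered with Gaussian sd
`mz_jitter_sd`. Each peak is emitted as a narrow Gaussian profile (apex
plus two shoulder points per side, width 0.005 Da, emulating the ~60,000
resolving power of an Orbitrap at these masses), and a flat chemical
baseline of level `baseline_level` is sampled every 5 Da across the whole
window so that local-maximum peak detection and MAD noise estimation see a
realistic floor. Off-spot (background) pixels emit matrix-cluster peaks
only, giving the segmenter a spatially structured background class, as a
sublimated MALDI matrix does. Intensities are clamped at zero.

Randomness is driven by one master seed through an independent child
stream per pixel, so per-pixel reproducibility does not depend on
iteration order, and serialized datasets are byte-identical across runs
with the same seed.

### Default noise parameters and why

| parameter | default | rationale |
|---|---|---|
| `tic_scale_cv` | 0.15 | typical pixel-to-pixel total-signal variability of dry-matrix MALDI spots; removed by TIC normalization |
| `mz_jitter_sd` | 0.0035 Da | a quarter of the 20-ppm alignment tolerance at m/z 700, so alignment is exercised but species stay resolvable |
| `additive_noise_sd` | 5 | signal-to-noise of 8-20 for the panel's species (base intensities 40-100), a realistic Orbitrap floor |
| `baseline_level` | 0.5 | small flat chemical background, ~0.5% of the strongest species |
| `dropout_prob` | 0 | species dropout is available but not part of the default conditions |

### The default differential panel

`default_species_panel()` has 12 negative-ion lipid forms: three SM forms
up-regulated 1.5-fold and three PC forms down-regulated to 0.7-fold in the
`cd9ko` condition, and six unchanged membrane lipids (PE, PI, PS, PG,
sulfatide). Base intensities are chosen so the panel is **TIC-balanced**:
the summed intensity gained by SM up-regulation (3 x 60 x 0.5) equals that
lost by PC down-regulation (3 x 100 x 0.3). TIC normalization closes the
composition (intensities are divided by their sum), so an unbalanced panel
would shift *every* species between conditions and make nominally
unchanged species truly differential; balancing keeps the configured fold
changes identifiable after normalization. Real lipidomes are not exactly
balanced — this is a property of the benchmark, not of biology — and the
consequence is discussed under "What passing tests do and do not show".

## Preprocessing

The order of operations is fixed for determinism: per pixel, (1) TIC
normalization to a common target (default 100), (2) peak picking, (3) the
0.5% base-peak filter; then, across pixels, (4) alignment and (5) matrix
assembly.

* **TIC normalization** divides by the spectrum sum; an all-zero spectrum
  is a degenerate-input error (the pipeline driver downgrades it to a
  warning and an all-zero matrix row, since off-tissue pixels can be
  legitimately empty).
* **Peak picking** takes local maxima after optional moving-average
  smoothing (`window`, default 1 = none, since the generator's profiles
  are narrow); the noise floor is the median absolute deviation of the
  whole spectrum and peaks must exceed `min_snr` (default 3) times it.
  Boundary points are padded with themselves so flat regions produce no
  edge apexes; plateau interiors are never apexes.
* **The 0.5% filter** removes peaks with intensity strictly below
  `fraction` (default 0.005) of the spectrum's strongest peak. Equality
  survives: the rule filters what is *below* the threshold. The base-peak
  intensity is recorded before filtering, which makes the operation
  idempotent.
* **Alignment** pools all peaks, sorts by m/z, and starts a new consensus
  bin whenever the gap to the previous peak exceeds the tolerance (default
  20 ppm, evaluated at the local m/z); the consensus m/z is the
  intensity-weighted mean. Greedy gap-based agglomeration is
  order-independent (it depends only on the sorted pooled list) and is
  exact when clusters are separated by more than the tolerance, which the
  generator's jitter (tolerance/4) guarantees with large margin.
* **Matrix assembly** sums each pixel's peaks per bin; pixels are ordered
  row-major by grid index; all-zero columns are dropped with a warning,
  all-zero rows kept and flagged; duplicate pixels are an error.

No mass recalibration, baseline subtraction beyond the noise floor, or
isotope handling is attempted.

## Segmentation: competing random walkers inside a divisive hierarchy

### The similarity graph

Pixels are compared by correlation distance $d = 1 - r$ between their
feature vectors — scale-free, so residual per-pixel intensity differences
do not dominate. A k-nearest-neighbour graph (default $k = 8$, one less
than a spot's pixel count) is symmetrized by union; edge weights are the
Gaussian kernel $w = \exp(-d^2 / 2\sigma^2)$ with $\sigma$ the median
neighbour distance. Zero-variance pixels (e.g. empty background rows at
zero noise) are at distance 0 from identical rows and 1 from everything
else. Edges whose weight underflows to zero are dropped; in practice this
disconnects spectrally unrelated classes, which is exactly the behaviour
the divisive driver expects.

### The split function

Two walkers compete to bisect a (connected) graph. Walker $k$ is
personalized on seed pixel $s_k$ and ranks every node by the stationary
distribution of a restart random walk,

$$ r_k = (1 - \alpha) P^\top r_k + \alpha e_{s_k}, $$

with $P$ the row-normalized weight matrix and restart probability
$\alpha = 0.15$. The fixed point is computed by power iteration to an L1
residual below $10^{-10}$ (ranks stay non-negative and sum to one at every
iteration); on graphs of up to 8 nodes the result matches a dense linear
solve of $(I - (1-\alpha)P^\top) r = \alpha e_{s}$ to $10^{-8}$, a
property the test suite checks on randomized graphs. Each pixel joins the
walker with the larger rank; ties go to the first walker, and each seed
always belongs to its own walker, so both segments are non-empty. Seeds
are the two pixels at maximal correlation distance within the segment
(ties broken by lowest index) — a deterministic analogue of divisive
analysis' "most disparate" object. Whether the original implementation's
walkers interacted during iteration or were compared post hoc is not
documented anywhere we could find; the independent-ranking reading is
implemented because it is fully specified, deterministic and
oracle-checkable.

### The divisive driver

Connected components of the full graph are forced top-level segments
(walkers cannot compete across components). Then, repeatedly, the segment
with the largest diameter — the maximum over its pixels of the average
dissimilarity to the rest of the segment — is bisected, until one of three
stopping rules fires: `max_segments` (default 8) reached;
no split leaves both children with `min_segment_size` pixels (default 9,
one spot); or the relative reduction in total within-segment dissimilarity
falls below `min_split_gain` (default 1%). A segment of identical pixels
(diameter 0) is never split. If a segment's subgraph is disconnected, the
first component is split off without running walkers. With
`max_segments = 2` on a connected graph the result reduces to a single
walker split. The segmentation runs on the peak-picked pixel matrix, not
on profile spectra: the matrix is what the preprocessing contract
produces, and correlation distances on it are well defined.

### Segment colouring

Segments are coloured on a $[0, 1]$ scale from the pairwise correlations
$r$ of their mean spectra: the pair with the lowest correlation occupies
the two extremes (the lower-indexed segment at 0), and the remaining
segments are ordered along a path between those extremes, choosing — by
exhaustive search over orderings, feasible up to 9 segments; beyond that a
distance-sort fallback is used — the ordering minimizing the squared
stress between colour distances and the $1 - r$ distances. Colour values
are cumulative path distances rescaled to $[0, 1]$, so segments with more
similar average spectra receive closer colours. A single segment gets 0.5
with a warning.

PCA (`pca_embed()`) is plain mean-centred `prcomp()`, exposed with scores,
loadings and explained-variance ratios.

## Differential statistics

The printed spot replicate — the mean of its (normally nine) pixels per
m/z bin — is the statistical unit. Within one experiment the two
conditions are compared per species with a two-sided Student t-test
(pooled variance by default, Welch by option; both implemented in closed
form so that the degenerate zero-variance cases have defined semantics:
equal means give $t = 0, p = 1$, unequal means are flagged). With the
default design (4 spots per condition) each test has 6 degrees of freedom.
No multiple-testing correction is applied, mirroring the original
reporting; what controls false positives instead is the **dual-replicate
rule**: a lipid form is reported only if $p < 0.05$ in *both* independent
replicate experiments with concordant direction. Under the null this
composite has a pass probability of roughly $\alpha^2/2 \approx 0.00125$
per species, so single false positives over a few hundred null trials are
within expectation; direction concordance is required because a doubly
significant but discordant species would be contradictory to report.

Protein quantitation tables (gene, accession, significance on the
$-10\log_{10} p$ scale, one ratio column per contrast, optional peptide
counts) are classified per contrast: `excluded` when the significance
score is below 20 (i.e. $p > 0.01$) or the peptide rules fail (at least 2
distinct and 1 unique peptide, applied only when the table carries count
columns — published tables often already applied them upstream);
otherwise `up` when the ratio is at least 1.5, `down` when at most 0.66,
else `unchanged`. Thresholds are **inclusive** so that "more than
1.5-fold" table colour coding and the textbook example of a 1.49 ratio
falling just short are honoured simultaneously; both bounds are
configurable. Plot coordinates are $\log_2$ ratios with guide lines at
$\pm\log_2 1.5 = \pm 0.58$.

## Numerical choices, tie-breaks and degenerate inputs

* Correlation with zero-variance vectors: distance 0 if the vectors are
  identical, else 1 (deterministic, no NaN propagation).
* kNN ties and seed ties: broken by lowest pixel index.
* Rank ties in walker assignment: first walker.
* Segment ids: ordered by each segment's lowest pixel index.
* The 0.5% filter and the spot-assignment radius are both inclusive (≥ /
  ≤).
* Power-iteration tolerance $10^{-10}$ (L1), oracle agreement $10^{-8}$;
  TIC conservation asserted at $10^{-9}$ relative.
* All randomness in the package flows from explicit integer seeds; the
  segmentation and preprocessing path is fully deterministic.

## What the generator emulates, and what passing tests do not show

The generator reproduces the array geometry, the negative-ion window, a
condition-dependent multiplicative signal structure, TIC-scale
variability, m/z jitter, additive noise and a structured background. It
does **not** model isotope envelopes, ion suppression, peak-shape
asymmetry, mass-calibration drift, spot-printing gradients ("doughnut"
morphology), or compositional imbalance between conditions. Consequently,
passing the planted-partition and parameter-recovery benchmarks shows the
algorithms are correct and well calibrated under the stated conditions; it
does not show that real EV arrays are this easy. In particular, on real
data TIC normalization of a lipidome whose total signal differs between
conditions redistributes intensity across all species (compositional
closure), and fold-change estimates are then relative, not absolute — the
dual-replicate rule mitigates but does not remove this.

## Problem sizes used by the shipped benchmarks

The differential benchmark uses two experiments of 2 samples x 4 spots
(72 on-spot pixels each, ~209 raster pixels) over 20 seeds; the
segmentation benchmark uses 3 regions x 3 spots (225 pixels) with
`max_segments = 4`, 20 seeds at default noise plus one zero-noise run; the
walker-vs-linear-solve check uses 100 random graphs of at most 8 nodes.
These sizes were chosen so the full suite exercises every code path on
hundreds of spectra while remaining quick to run on a laptop.

## Known limitations

* imzML input is not supported; the package reads its own documented
  tabular dialect (`pixel_x, pixel_y, mz, intensity` plus a JSON
  manifest). An adapter would slot in at `read_dataset()`.
* Greedy gap-based alignment can chain peaks in the pathological case of a
  dense m/z ladder with gaps all just under the tolerance; the generator
  never produces this, but real data with near-isobaric species might.
* The divisive driver recomputes a kNN subgraph per split; the
  implementation is dense ($O(n^2)$ distances) and intended for
  array-sized experiments (hundreds to a few thousand pixels), not
  whole-tissue imaging.
* The exhaustive colour-ordering search is limited to 9 segments; beyond
  that the fallback ordering is heuristic.
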