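---
title: "Methods: unspliced-RNA cellbin segmentation and radial gradient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unspliced-RNA cellbin segmentation and radial gradient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`cellbins` processes micrometre-resolution sequencing-based spatial
transcriptomics, where each 250 nm × 250 nm pixel bin accumulates
deduplicated molecule counts, into per-cell expression profiles and a
radial gene-expression gradient analysis. The pipeline has five stages:
read demultiplexing, tissue masking, cell segmentation, quality control,
and boundary-distance correlation. A seeded synthetic-scene generator
provides ground truth for every stage.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical conventions, and the design decisions taken
where the procedure was genuinely under-determined.

## Coordinate and unit conventions

All structures live on a `grid_spec`: 0-based integer bin indices, origin
top-left, `x` rightward, `y` downward. Distances are reported in bin
units; `bins_to_um2()` converts areas using the grid pitch (default
250 nm, so 16 bins = 1 µm²). Mixing pixel and physical units is a classic
source of silent drift, so one canonical unit is used everywhere and
conversion happens only at the reporting boundary. Mitochondrial genes are
recognized by the case-insensitive id prefix `mt-` (mouse nomenclature:
*mt-Nd4*, *mt-Cytb*, ...).

## Demultiplexing

Read 1 carries the 30-nt spatial barcode at positions 1–30 and the 10-nt
UMI at positions 88–97 (1-based); the intervening bases are fixed
chemistry. Reads shorter than 97 nt cannot carry a complete UMI and are
discarded with reason `"short"`.

Barcode correction allows one substitution against the chip whitelist: an
exact hit always wins; otherwise the 90 single-base variants of the query
are looked up and a hit is accepted only if it is unique. Ambiguous
1-mismatch hits are **dropped**, not assigned randomly — the conservative
convention of standard demultiplexers; with realistic whitelists
(10³–10⁶ barcodes in a 4³⁰ space) ambiguity is rare, so the cost is
negligible while mis-assignment would corrupt coordinates. Correction is
sequence-only; base qualities are not consulted.

UMIs are compared by exact string identity: reads sharing (corrected
barcode, gene, splice class, UMI) collapse to one molecule, and
`umi_count` is the number of distinct UMIs per (barcode, gene, splice
class). No UMI error correction (e.g. directional networks) is applied.
Sequencing saturation is defined as `1 − unique_UMIs / assigned_reads`,
the conventional definition; this is an assumption, as depth metrics vary
between platforms.

## Tissue masking

The manual-contour path rasterizes the closed polygon, bridges small
annotation gaps by a 5 × 5 morphological closing of the contour raster,
flood fills from an interior seed with 8-neighbourhood connectivity, and
closes the filled mask with the same 5 × 5 square element. One deliberate
deviation: polygon edges are drawn with a **supercover (4-connected)**
digital line rather than a thin 8-connected Bresenham line. A thin
8-connected curve does not block the diagonal moves of an 8-connected
flood fill — the fill leaks through diagonal pixel pairs — whereas a
4-connected curve does; the two rasterizations agree on axis-aligned
fixtures. The fill errors out if it reaches the grid border, which catches
both unclosed contours and seeds placed outside.

Otsu thresholding uses 256 equal-width bins over the value range and
exact per-bin value sums (not bin centres) for the class means, returning
the internal bin edge that maximizes between-class variance; pixels
strictly above the threshold are foreground. Constant input is rejected
as a degenerate histogram. Ties on the variance curve (plateaus between
well-separated modes) resolve to the lowest candidate threshold.

## Cellbin segmentation

The segmentation rests on one biological assumption: unspliced transcripts
are nuclear, so smoothed unspliced-RNA density peaks at nuclei.

1. **Density building.** Per-bin sums of `umi_count` for the unspliced and
   total channels; totals are conserved exactly.
2. **Smoothing.** Separable Gaussian convolution, reflecting boundaries,
   kernel truncated at 4σ and normalized — constants are preserved,
   non-negativity maintained.
3. **Core detection.** Foreground = smoothed unspliced density above its
   Otsu threshold; markers = regional maxima of the foreground thinned to
   a minimum mutual separation of 2σ (greedy by descending value, ties by
   (y, x)); marker-seeded watershed floods the foreground in order of
   decreasing intensity. Cores with raw unspliced UMI below
   `min_core_umi` are discarded; survivors are renumbered by descending
   core UMI, ties by topmost-then-leftmost pixel.
4. **Expansion.** The same watershed, seeded with the cores, runs on the
   smoothed total-RNA landscape to absorb the scattered cytoplasmic and
   pericellular signal, clipped to (a) a chamfer geodesic distance
   `expansion_max_dist_bins` from the core and (b) a growth substrate.
   The substrate is the **Otsu foreground of the smoothed total map**,
   not merely "any positive signal": with any nonzero extracellular
   background, smoothing makes every pixel positive and an unthresholded
   expansion degenerates into geodesic disks several times larger than
   the cells. Using the same foreground rule as core detection also gives
   the natural limit case — a core with no surrounding signal expands to
   exactly itself. Cellbins exceeding `max_area_bins` are trimmed by
   removing their geodesically farthest pixels (ties broken toward larger
   y, then x); cellbins under `min_total_umi` total UMI are dropped.
5. **Assignment.** Each record maps to the label at its bin; label 0 is
   "unassigned" and is preserved as a spot table, so assigned +
   unassigned UMI equals the input exactly. Centroids are unweighted
   means of label pixels (matching the cross-sectional-area framing, and
   robust to a single high-count bin); `n_genes` counts genes with at
   least one UMI; `mito_fraction` = mitochondrial UMI / total UMI.

Determinism is engineered, not incidental: watershed flooding breaks
intensity ties by (y, x) pixel order and then push order, label numbering
and trimming have fixed tie-breaks, and the optional marker jitter
(`rng_seed`) is off by default. Identical inputs and parameters give
bit-identical label maps.

### Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `sigma_bins` | 8 | bins (2 µm) | nucleus-scale smoothing: large enough to pool ~1 µm-spaced captures into one nuclear mode, small enough to keep 10 µm-spaced nuclei separate |
| `min_core_umi` | 50 | UMIs | drops noise clusters; a real nucleus at ~0.4 unspliced UMI/bin over a 5 µm-diameter footprint carries ≳100 |
| `max_area_bins` | 40 000 | bins (2 500 µm²) | hard sanity cap ~8× the reported median cell area; binds only on pathological merges |
| `min_total_umi` | 100 | UMIs | minimum evidence for a usable expression profile |
| `expansion_max_dist_bins` | 60 | bins (15 µm) | allows a full cell radius of growth beyond the nucleus without letting a core annex a neighbourhood |
| `rng_seed` | 1 | — | only consumed by optional marker jitter (off) |

None of these values are dictated by the chemistry; they are declared,
CLI-overridable defaults tuned to sample characteristics (cell size,
capture depth), and the scale-equivariance property (doubling all counts
and both UMI thresholds leaves boundaries unchanged) documents how they
interact with depth.

## Quality control

`summarize_cellbins()` reports cellbin count, medians of area, UMI count,
detected genes and mitochondrial fraction, and the UMI recall rate
(assigned / total). Medians use the **lower-median** convention for even
n — reported per-cellbin medians are integers, and the lower median is an
actual data value.

The per-gene recall classification asks, for each gene, whether its
in-cellbin fraction departs from the global recall rate: an exact
two-sided binomial test of `umi_in ~ Binomial(umi_total, global_rate)`
(two-sided by pmf summation, the `binom.test` convention), followed by
Benjamini–Hochberg adjustment across genes. A gene is *recalled* when
significantly above the rate, *unrecalled* when significantly below
(extracellular-leaning — e.g. secreted matrix transcripts), *neither*
otherwise; zero-total genes are *neither* with `p_adj = 1`. The choice of
test is an assumption — the classification concept is standard but no
canonical test exists — which is why the package treats the
recalled/unrecalled counts as descriptive output, not as a calibrated
detector.

## Radial gradient analysis

Tubule boundaries are closed polygons in bin coordinates, rasterized to
boundary pixel sets. Cellbins are selected when their centroid lies inside
a tubule polygon by the even-odd rule, and each is assigned to the single
containing tubule; overlapping polygons are rejected rather than
arbitrated. Distances are the minimum Euclidean distance from the centroid
to the pixels of **its own tubule's** boundary — not the global minimum
over all tubules, which would let a cell near a tubule wall be measured
against a neighbouring tubule.

For each gene expressed in at least `min_cells` selected cellbins
(default 10, mirroring the low-abundance filter used for trajectory
analyses), the Pearson product-moment correlation between expression and
distance is computed, with the two-sided p-value from
t = r·√((n−2)/(1−r²)) on n−2 degrees of freedom. Expression defaults to
library-size-normalized counts (counts × 10⁴ / total UMI per cellbin), so
a cell-size or depth gradient along the radius is not mistaken for a
per-gene gradient; raw-count mode is available
(`normalize = FALSE`) since the choice is not canonical. Zero-variance
vectors yield an undefined result that ranking excludes. Ranking sorts by
r (descending for the positive list, ascending for the negative), ties
broken lexicographically by gene id.

## The synthetic world

`generate_scene()` states a world rather than tuning one:

* five circular tubules (radius 110 bins ≈ 27.5 µm) on a lattice, each
  with a 30-bin lumen and ten cells — 50 cells total on a 768 × 768 grid;
* cells are 20-bin-radius disks with 10-bin nuclei (10 µm and 5 µm
  diameters), packed without overlap at stratified angles and alternating
  inner/outer radial depths (sequential rejection sampling alone wedges
  the last cell of a tubule in some layouts; the stratified restart stays
  within the same 10⁴-attempt budget);
* nuclei emit unspliced RNA at 0.4 molecules/bin (with spliced at the
  80:20 complement), cytoplasm spliced at 0.3/bin (95:5), background
  0.02/bin everywhere outside cells — roughly 25–30% of molecules
  extracellular, the same order as real recall losses;
* 40 pool genes of equal weight plus three mitochondrial genes at 1.5%
  combined weight (~1% mito fraction); two extracellular-only genes take
  10% of the background;
* four gradient genes whose whole-cell Poisson rate follows
  max(0, baseline + β·d) in the cell's membrane distance d:
  β = ±0.010 ("strong") and ±0.006, baselines chosen so rates stay
  positive across the d ∈ [22, 60]-bin band the geometry produces.

What a green test does establish: the segmentation recovers compact,
non-overlapping cells from nuclear unspliced signal under Poisson noise
and diffuse background, conserves UMIs, and the radial analysis recovers
planted linear gradients with correct signs and ranks. What it does not:
real tissue has irregular cell shapes and sizes, touching and overlapping
cells, cell-type expression structure, segmentation-dependent recall
biases and spatial artifacts (section folds, capture gradients) — none of
which the generator emulates. Scene scale (50 cells vs tens of
thousands) keeps the suite inside its time budget; the algorithms are
resolution- and extent-agnostic.

`evaluate_segmentation()` matches predicted to true cells greedily by
descending IoU (one-to-one, ties by true then predicted id) and reports
the matched fraction at a threshold (default 0.5) plus the relative count
error.

## Degenerate inputs and numerical conventions

* Empty spot tables error in `segment_cellbins`; empty foreground in core
  detection yields zero cores, which is a valid result.
* Otsu on constant data errors (`degenerate histogram`); expansion falls
  back to the any-signal substrate if the total map cannot be
  thresholded.
* Correlations need n ≥ 3 and nonzero variance; |r| is clamped to 1
  before the t-transform and p = 0 at |r| = 1 exactly.
* Kernel truncation at 4σ bounds the smoothing error at ~6 × 10⁻⁵ of the
  mass; the impulse-normalization test asserts 10⁻⁶, linearity 10⁻⁹.
* File formats are plain text end to end: TSV spot tables, MatrixMarket
  count matrices, P2 PGM label maps (16-bit), GeoJSON/CSV tubules — every
  reader/writer pair round-trips losslessly. The run configuration is
  JSON (schema in `run_config()`), written back beside the outputs with a
  provenance record.

## Known limitations

* The watershed variant (marker rule, foreground rule, expansion stop) is
  a declared reconstruction; the original method's exact choices are not
  public, so parameter values should be re-tuned per sample.
* One section, 2-D only; no multi-section registration or 3-D merging.
* Barcode correction ignores base qualities; UMI collapse ignores
  sequencing errors in the UMI itself (both understate duplication
  slightly).
* The gene-recall test treats molecules as independent Bernoulli trials;
  spatial autocorrelation within cells makes the effective n smaller, so
  its p-values are anti-conservative for strongly clustered genes.
* Tubule boundaries are taken as given (manual outlines); no automatic
  tubule detection is attempted.
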