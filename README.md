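# cellbins

Cell segmentation and radial gradient analysis for micrometre-resolution
spatial transcriptomics, built around dense tissue such as mouse testis
sections.

## The problem

Sequencing-based spatial transcriptomics at ~1 µm spot pitch resolves
molecules well below the size of a single cell (10–20 µm), but without
staining there is no direct image of cell boundaries. In tissue this
dense, naive binning mixes transcripts from neighbouring cells. The key
biological observation this package operationalizes: **unspliced
(intron-containing) transcripts are retained in the nucleus**, so the
spatial density of unspliced RNA is a marker-free proxy for nucleus
positions. Segmenting cells from that signal turns a molecule table into
per-cell expression profiles ("cellbins"), which in turn enables spatially
resolved analyses such as the basement-membrane-to-lumen expression
gradient inside seminiferous tubules.

## What the package does

* **Demultiplexing** (`demux_reads`): extract the 30-nt spatial barcode
  (read-1 positions 1–30) and 10-nt UMI (positions 88–97), correct
  barcodes against the chip whitelist allowing one mismatch (ambiguous
  hits dropped), deduplicate UMIs per (barcode, gene, splice class), and
  report sequencing saturation `1 − unique/assigned`.
* **Tissue masking** (`mask_from_contour`, `mask_from_threshold`,
  `barcodes_in_mask`): flood fill of a manually outlined contour with
  8-neighbourhood connectivity and 5×5 morphological closing, or Otsu
  threshold binarization of a density map.
* **Cellbin segmentation** (`segment_cellbins`): Gaussian-smooth the
  unspliced density (σ = 8 bins by default), detect cell cores by
  marker-based watershed above the Otsu foreground, expand the cores over
  the smoothed total-RNA landscape under a geodesic distance cap, a
  maximum-area cap and a minimum total-UMI filter, then aggregate spots
  into a sparse cellbin × gene matrix with per-cellbin QC fields.
  Fully deterministic: label order, watershed flooding and all
  tie-breaks are fixed.
* **QC** (`summarize_cellbins`, `gene_recall_table`): per-cellbin medians
  (area, UMI, genes, mitochondrial fraction), UMI recall rate
  (assigned/total), and a per-gene recall classification — exact
  two-sided binomial test of each gene's in-cellbin fraction against the
  global rate with Benjamini–Hochberg correction.
* **Radial gradient** (`radial_gradient`, `rank_gradient_genes`): assign
  cellbins to manually outlined tubules (even-odd rule), compute each
  centroid's minimum Euclidean distance to its tubule's rasterized
  boundary, and for every gene the Pearson correlation *r* between
  (library-size-normalized) expression and distance with the two-sided
  *p*-value from *t* = *r*·√((n−2)/(1−r²)).
* **Synthetic scenes** (`generate_scene`, `evaluate_segmentation`):
  seeded ground-truth generator — ring-shaped tubules, non-overlapping
  cells with nuclear unspliced / cytoplasmic spliced Poisson emission,
  extracellular background, planted gradient genes with linear
  distance–rate laws — plus IoU-based segmentation scoring.

Coordinates are 0-based integer pixel-bin indices (default pitch 250 nm,
so 16 bins = 1 µm²); distances are in bin units unless converted with
`bins_to_um2`.

## Worked example

```r
library(cellbins)

scene <- generate_scene(scene_spec(seed = 1L))   # 50 cells, 5 tubules
seg   <- segment_cellbins(scene$spots, verbose = TRUE)
#> cores: 50; cellbins: 50; UMI recall: 0.911

summarize_cellbins(seg$cellbins, unassigned_umi = sum(seg$unassigned$umi_count))
#> <qc_summary> 50 cellbins
#>   median area       : 1612 bins
#>   median UMI        : 2086
#>   median genes      : 47
#>   median mito frac  : 0.0033
#>   UMI recall rate   : 0.9110

evaluate_segmentation(seg$labels, scene$truth$labels)$matched_fraction
#> [1] 1     # 100% of true cells matched at IoU >= 0.5

grad <- radial_gradient(seg$matrix, scene$truth$tubules)
rank_gradient_genes(grad$results, 3)$positive
#>     gene_id pearson_r  p_two_sided
#> 1: gradpos1 0.9919979 8.361103e-45
#> 2: gradpos2 0.9873727 4.513305e-40
#> 3:   gene14 0.2932933 3.872057e-02
```

The planted gradient genes (`gradpos*` emitted with rates increasing
toward the lumen, `gradneg*` decreasing) head the two ranked lists with
the correct signs; the residual genes' correlations hover near zero. The
median cellbin here covers 1,612 bins ≈ 101 µm² — smaller than a real
testicular cell because the simulated cells are 10 µm disks.

A command-line front end mirrors the API (`inst/exec/cellbins`):

```sh
cellbins simulate --out sim --seed 1
cellbins segment  --spots sim/spots.tsv --out seg
cellbins qc       --cellbins seg --out qc.tsv
cellbins gradient --cellbins seg --tubules sim/tubules.geojson --out grad
cellbins run      --config cfg.json --seed 1 --out outdir
```

## Documentation

`vignettes/cellbins-methods.Rmd` describes the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, and the numerical conventions
(tie-breaks, medians, histogram thresholding).
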