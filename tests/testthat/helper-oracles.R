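# Independent brute-force oracles used across the suite. These stay free of
# the package's own code paths: plain loops and base R only.

# exhaustive Hamming-distance barcode scan
oracle_hamming_match <- function(query, wl_barcodes) {
  qs <- strsplit(query, "")[[1]]
  d <- vapply(strsplit(wl_barcodes, ""), function(w) sum(w != qs), integer(1))
  if (any(d == 0L)) return(which(d == 0L)[1])
  ones <- which(d == 1L)
  if (length(ones) == 1L) ones else NA_integer_
}

# exhaustive Otsu: try every histogram cut, compute between-class variance
# directly from the partitioned raw values
oracle_otsu <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  best <- -Inf; best_thr <- NA_real_
  n <- length(v)
  for (t in edges[2:n_bins]) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    sb <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_thr <- t }
  }
  best_thr
}

# direct product-moment formula + t-test
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

# O(n) scan for minimum point-to-pixel distance
oracle_min_dist <- function(cx, cy, pixels) {
  best <- Inf
  for (i in seq_len(nrow(pixels)))
    best <- min(best, sqrt((pixels[i, 1] - cx)^2 + (pixels[i, 2] - cy)^2))
  best
}

# even-odd rule by explicit ray casting, one point at a time
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# random 30-mers
random_barcodes <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
}

# small randomized spot table on a given grid
random_spot_table <- function(n, grid, n_genes = 6) {
  spot_table(
    barcode_id = sprintf("b%03d", seq_len(n)),
    x_bin = sample.int(grid$width_bins, n, replace = TRUE) - 1L,
    y_bin = sample.int(grid$height_bins, n, replace = TRUE) - 1L,
    gene_id = sample(c(sprintf("g%d", seq_len(n_genes - 1)), "mt-Nd4"),
                     n, replace = TRUE),
    splice_class = sample(c("spliced", "unspliced"), n, replace = TRUE),
    umi_count = sample(1:5, n, replace = TRUE),
    grid = grid
  )
}

# a small, fast synthetic scene for tests that do not need the default one
small_scene_spec <- function(seed = 1L) {
  scene_spec(grid = grid_spec(236L, 236L), n_tubules = 1L,
             cells_per_tubule = 6L, seed = seed)
}

# cache the default scene + segmentation once per test run (used by several
# files; generation is seeded so this is pure)
default_scene_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- generate_scene(scene_spec(seed = 1L))
      seg <- segment_cellbins(scene$spots)
      cache <<- list(scene = scene, seg = seg)
    }
    cache
  }
})
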