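#' Tubule boundary
#'
#' A manually outlined seminiferous-tubule boundary: a closed polyline of
#' vertices in bin coordinates plus its rasterized boundary pixel set
#' (0-based (x, y) pairs), the set distances are measured against.
#'
#' @param id tubule identifier.
#' @param vertices two-column (x_bin, y_bin) matrix, >= 3 vertices, closed
#'   implicitly.
#' @param grid a [grid_spec()].
#' @return Object of class `tubule_boundary`.
#' @export
tubule_boundary <- function(id, vertices, grid) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("tubule boundary needs >= 3 vertices")
  raster <- rasterize_contour(vertices, grid)
  idx <- which(raster)
  h <- nrow(raster)
  pixels <- cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
  structure(list(id = id, vertices = vertices, pixels = pixels, grid = grid),
            class = "tubule_boundary")
}

#' Read tubule boundaries from CSV vertex lists or GeoJSON
#'
#' CSV: columns `tubule_id,x_bin,y_bin` (one closed polygon per id).
#' GeoJSON: a FeatureCollection of Polygons (outer ring used; an `id`
#' property, else features numbered in order).
#'
#' @param path input file (.csv/.tsv or .json/.geojson).
#' @param grid a [grid_spec()].
#' @return list of [tubule_boundary()] objects.
#' @export
read_tubules <- function(path, grid) {
  if (!file.exists(path)) stop("tubule file not found: ", path)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    feats <- gj$features
    lapply(seq_along(feats), function(i) {
      f <- feats[[i]]
      ring <- f$geometry$coordinates[[1]]
      v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      # GeoJSON rings repeat the first vertex; drop the duplicate
      if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
      id <- if (!is.null(f$properties$id)) f$properties$id else i
      tubule_boundary(id, v, grid)
    })
  } else {
    dt <- fread(path)
    stopifnot(all(c("tubule_id", "x_bin", "y_bin") %in% names(dt)))
    lapply(split(dt, by = "tubule_id", sorted = TRUE), function(d)
      tubule_boundary(d$tubule_id[1], cbind(d$x_bin, d$y_bin), grid))
  }
}

#' Write tubule boundaries as GeoJSON
#'
#' @param tubules list of [tubule_boundary()].
#' @param path output file.
#' @export
write_tubules <- function(tubules, path) {
  feats <- lapply(tubules, function(tb) {
    ring <- rbind(tb$vertices, tb$vertices[1, ])
    list(type = "Feature",
         properties = list(id = tb$id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# even-odd (ray casting) point-in-polygon; boundary behaviour follows the
# half-open edge rule, "strictly inside" for generic interior points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Select cellbins inside tubules
#'
#' Keeps cellbins whose centroid lies inside a tubule polygon (even-odd
#' rule) and tags each with its containing tubule. Overlapping tubule
#' polygons are rejected because the assignment would be ambiguous.
#'
#' @param cellbins per-cellbin data.table (needs `cellbin_id`,
#'   `centroid_x`, `centroid_y`).
#' @param tubules list of [tubule_boundary()].
#' @return The subset with an added `tubule_id` column.
#' @export
select_cellbins_in_tubules <- function(cellbins, tubules) {
  cb <- as.data.table(cellbins)
  hit <- matrix(FALSE, nrow(cb), length(tubules))
  for (j in seq_along(tubules)) {
    v <- tubules[[j]]$vertices
    hit[, j] <- point_in_polygon(cb$centroid_x, cb$centroid_y, v[, 1], v[, 2])
  }
  multi <- which(rowSums(hit) > 1L)
  if (length(multi)) {
    pair <- which(hit[multi[1], ])
    stop(sprintf("tubules %s and %s overlap (cellbin %s inside both)",
                 tubules[[pair[1]]]$id, tubules[[pair[2]]]$id,
                 cb$cellbin_id[multi[1]]))
  }
  sel <- rowSums(hit) == 1L
  out <- cb[sel]
  out[, tubule_id := vapply(which(sel), function(i)
    as.character(tubules[[which(hit[i, ])]]$id), character(1))]
  out[]
}

#' Minimum Euclidean distance from a point to a boundary pixel set
#'
#' @param cx,cy centroid coordinates (bin units, may be fractional).
#' @param pixels two-column (x, y) boundary pixel matrix.
#' @return Minimum distance in bins.
#' @export
min_distance_to_boundary <- function(cx, cy, pixels) {
  if (!nrow(pixels)) stop("empty boundary pixel set")
  sqrt(min((pixels[, 1] - cx)^2 + (pixels[, 2] - cy)^2))
}

#' Distance of every selected cellbin to its tubule membrane
#'
#' For each cellbin (already assigned to a tubule by
#' [select_cellbins_in_tubules()]) the minimum Euclidean distance from its
#' centroid to the pixels of its own tubule's rasterized boundary.
#'
#' @param selected output of [select_cellbins_in_tubules()].
#' @param tubules list of [tubule_boundary()].
#' @return data.table `cellbin_id`, `tubule_id`, `distance_bins`.
#' @export
distance_table <- function(selected, tubules) {
  ids <- vapply(tubules, function(tb) as.character(tb$id), character(1))
  d <- vapply(seq_len(nrow(selected)), function(i) {
    tb <- tubules[[match(selected$tubule_id[i], ids)]]
    min_distance_to_boundary(selected$centroid_x[i], selected$centroid_y[i],
                             tb$pixels)
  }, numeric(1))
  data.table(cellbin_id = selected$cellbin_id,
             tubule_id = selected$tubule_id, distance_bins = d)
}

# Pearson r with the two-sided t-test p-value, computed from the
# product-moment formula (kept free of cor.test so tests can use the
# latter as an independent oracle).
pearson_cor <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sum((x - mx) * (y - my)) / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df = n - 2), n = n)
}

#' Correlate one gene's expression with radial distance
#'
#' Pearson product-moment correlation between per-cellbin expression and
#' the cellbin-to-membrane distance; two-sided p-value from the
#' t-distribution with n - 2 df. Zero variance in either vector yields an
#' undefined result (NA r/p) that downstream ranking excludes.
#'
#' @param expr per-cellbin expression values for one gene.
#' @param dist matching distances (bins).
#' @return list `r`, `p`, `n`, `direction` ("positive"/"negative"/NA).
#' @export
gene_distance_correlation <- function(expr, dist) {
  stopifnot(length(expr) == length(dist))
  res <- pearson_cor(expr, dist)
  res$direction <- if (is.na(res$r)) NA_character_ else
    if (res$r >= 0) "positive" else "negative"
  res
}

#' Correlate two genes' expression
#'
#' @param expr_a,expr_b per-cellbin expression of the two genes.
#' @return list `r`, `p`, `n`.
#' @export
gene_gene_correlation <- function(expr_a, expr_b) {
  stopifnot(length(expr_a) == length(expr_b))
  pearson_cor(expr_a, expr_b)
}

#' Radial gradient analysis over all genes
#'
#' Runs the full membrane-to-lumen analysis: select cellbins inside the
#' tubules, compute their boundary distances, optionally library-size
#' normalize expression (counts x 10^4 / total UMI, the default), drop
#' genes expressed in fewer than `min_cells` selected cellbins, and
#' correlate every remaining gene with distance.
#'
#' @param matrix a [cellbin_matrix()].
#' @param tubules list of [tubule_boundary()].
#' @param normalize library-size normalize before correlating (default
#'   TRUE).
#' @param min_cells minimum number of selected cellbins expressing a gene
#'   (default 10).
#' @return list with `results` (data.table: gene_id, n, pearson_r,
#'   p_two_sided, direction), `distances` (the [distance_table()]),
#'   `selected` cellbins.
#' @export
radial_gradient <- function(matrix, tubules, normalize = TRUE,
                            min_cells = 10L) {
  sel <- select_cellbins_in_tubules(matrix$cellbins, tubules)
  if (!nrow(sel)) stop("no cellbin centroid falls inside any tubule")
  dists <- distance_table(sel, tubules)
  rows <- match(sel$cellbin_id, matrix$cellbins$cellbin_id)
  counts <- matrix$counts[rows, , drop = FALSE]
  expr <- if (normalize) {
    tot <- pmax(1, Matrix::rowSums(counts))
    counts * (1e4 / tot)
  } else counts
  n_expressing <- Matrix::colSums(counts > 0)
  genes <- colnames(counts)[n_expressing >= min_cells]
  res <- rbindlist(lapply(genes, function(g) {
    r <- gene_distance_correlation(as.numeric(expr[, g]), dists$distance_bins)
    data.table(gene_id = g, n = r$n, pearson_r = r$r,
               p_two_sided = r$p, direction = r$direction)
  }))
  if (!nrow(res))
    res <- data.table(gene_id = character(), n = integer(),
                      pearson_r = numeric(), p_two_sided = numeric(),
                      direction = character())
  list(results = res[], distances = dists, selected = sel)
}

#' Rank gradient genes
#'
#' Top-k positively and negatively distance-correlated genes; undefined
#' correlations are excluded, ties broken lexicographically by gene id.
#'
#' @param results the `results` table from [radial_gradient()].
#' @param k list length (default 20; warns and returns all if fewer
#'   available).
#' @return list `positive`, `negative` (data.tables sorted by r).
#' @export
rank_gradient_genes <- function(results, k = 20L) {
  res <- as.data.table(results)[!is.na(pearson_r)]
  if (!nrow(res)) stop("no defined correlation results to rank")
  if (k > nrow(res)) {
    warning(sprintf("k = %d exceeds %d available genes; returning all",
                    k, nrow(res)))
    k <- nrow(res)
  }
  pos <- res[order(-pearson_r, gene_id)][seq_len(k)]
  neg <- res[order(pearson_r, gene_id)][seq_len(k)]
  list(positive = pos, negative = neg)
}
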