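#' Segmentation parameters
#'
#' Tunables of the cellbin segmentation. None of these are dictated by the
#' chemistry; they are adjusted to sample characteristics (cell size,
#' capture depth) and every one is overridable from the CLI.
#'
#' @param sigma_bins Gaussian smoothing scale in bins (default 8, ~2 um at
#'   250 nm pitch).
#' @param min_core_umi minimum unspliced UMI inside a detected core for the
#'   core to be kept (default 50).
#' @param max_area_bins hard cap on cellbin area in bins (default 40000,
#'   i.e. 2500 um^2 at 250 nm pitch).
#' @param min_total_umi minimum total UMI for a retained cellbin
#'   (default 100).
#' @param expansion_max_dist_bins geodesic growth limit from the core, in
#'   bins (default 60).
#' @param rng_seed integer; only consumed by optional marker jitter, which
#'   is off by default, so segmentation is deterministic.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_bins = 8, min_core_umi = 50L,
                                max_area_bins = 40000L, min_total_umi = 100L,
                                expansion_max_dist_bins = 60L,
                                rng_seed = 1L) {
  stopifnot(sigma_bins > 0, min_core_umi > 0, max_area_bins > 0,
            min_total_umi > 0, expansion_max_dist_bins >= 0)
  structure(list(sigma_bins = as.numeric(sigma_bins),
                 min_core_umi = as.integer(min_core_umi),
                 max_area_bins = as.integer(max_area_bins),
                 min_total_umi = as.integer(min_total_umi),
                 expansion_max_dist_bins = as.integer(expansion_max_dist_bins),
                 rng_seed = as.integer(rng_seed)),
            class = "segmentation_params")
}

# Regional maxima of a smoothed map above `floor`, thinned so that kept
# maxima are pairwise at least `min_sep` apart (greedy by descending value,
# ties by (y, x)). Plateau pixels collapse onto the first pixel in (y, x)
# order within min_sep.
find_markers <- function(map, floor_value, min_sep) {
  h <- nrow(map); w <- ncol(map)
  is_max <- map > floor_value
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (map >= shift_mat_num(map, dy, dx, fill = -Inf))
  }
  idx <- which(is_max)
  if (!length(idx)) return(matrix(integer(), 0, 2))
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  ord <- order(-map[idx], r, c)
  r <- r[ord]; c <- c[ord]
  keep_r <- integer(0); keep_c <- integer(0)
  for (i in seq_along(r)) {
    if (!length(keep_r) ||
        min((keep_r - r[i])^2 + (keep_c - c[i])^2) >= min_sep^2) {
      keep_r <- c(keep_r, r[i]); keep_c <- c(keep_c, c[i])
    }
  }
  cbind(row = keep_r, col = keep_c)
}

shift_mat_num <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Detect cell cores from smoothed unspliced-RNA density
#'
#' Cores are the nuclear footprints used to seed cell segmentation:
#' (i) foreground = pixels above the Otsu threshold of the smoothed map;
#' (ii) markers = regional maxima of the foreground at minimum mutual
#' separation `2 * sigma_bins`; (iii) marker-seeded watershed on the
#' (negated) smoothed map restricted to the foreground; (iv) cores whose
#' raw unspliced UMI falls below `min_core_umi` are discarded. Labels are
#' renumbered 1..K by descending core UMI, ties by the core's topmost then
#' leftmost pixel.
#'
#' @param smoothed smoothed unspliced density (see [smooth_density()]).
#' @param raw_unspliced raw (unsmoothed) unspliced density, used for the
#'   per-core UMI filter.
#' @param params a [segmentation_params()].
#' @return Integer core label matrix (0 = background). Zero cores is a
#'   valid outcome, not an error.
#' @export
detect_cores <- function(smoothed, raw_unspliced, params = segmentation_params()) {
  if (any(smoothed < 0)) stop("smoothed map must be non-negative")
  thr <- tryCatch(otsu_threshold(smoothed), error = function(e) NA_real_)
  if (is.na(thr)) return(matrix(0L, nrow(smoothed), ncol(smoothed)))
  fg <- smoothed > thr
  if (!any(fg)) return(matrix(0L, nrow(smoothed), ncol(smoothed)))
  mk <- find_markers(smoothed, thr, 2 * params$sigma_bins)
  markers <- matrix(0L, nrow(smoothed), ncol(smoothed))
  if (nrow(mk)) markers[mk] <- seq_len(nrow(mk))
  ws <- cpp_watershed(smoothed, markers, fg, Inf)
  labels <- ws$labels
  relabel_cores(labels, raw_unspliced, params$min_core_umi)
}

# drop labels below the UMI floor, renumber by descending UMI then (min_y,
# min_x) of the label's pixels
relabel_cores <- function(labels, raw_density, min_umi) {
  k <- max(labels)
  if (k == 0L) return(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  umi <- vapply(split(raw_density[idx], lab), sum, numeric(1))
  h <- nrow(labels)
  rr <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  min_y <- vapply(split(rr, lab), min, numeric(1))
  min_x <- vapply(split(cc, lab), min, numeric(1))
  ids <- as.integer(names(umi))
  keep <- umi >= min_umi
  ids <- ids[keep]
  if (!length(ids)) return(matrix(0L, nrow(labels), ncol(labels)))
  ord <- order(-umi[keep], min_y[keep], min_x[keep])
  remap <- integer(k)
  remap[ids[ord]] <- seq_along(ids)
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[idx] <- remap[lab]
  out
}

#' Expand cell cores over total-RNA signal
#'
#' Seeded watershed on the smoothed total-RNA landscape: each core grows
#' into surrounding scattered signal, restricted to pixels with non-zero
#' smoothed total signal and to a chamfer geodesic distance
#' `expansion_max_dist_bins` from the core. Cellbins exceeding
#' `max_area_bins` are trimmed by removing their geodesically farthest
#' pixels (ties by larger y, then larger x, removed first); cellbins whose
#' raw total UMI falls below `min_total_umi` are dropped; survivors are
#' renumbered contiguously preserving core order. Distinct cores never
#' merge.
#'
#' @param cores integer core label matrix from [detect_cores()].
#' @param total_smoothed smoothed total-RNA density.
#' @param raw_total raw total-RNA density, used for the UMI floor.
#' @param params a [segmentation_params()].
#' @return Integer cellbin label matrix; attribute `geodesic` carries the
#'   per-pixel chamfer distance from the owning core.
#' @export
expand_cores <- function(cores, total_smoothed, raw_total,
                         params = segmentation_params()) {
  # growth substrate: total-RNA foreground by Otsu on the smoothed map,
  # so expansion absorbs scattered signal around cells without leaking
  # into the diffuse extracellular background (falls back to "any signal"
  # when the map is too flat to threshold)
  thr <- tryCatch(otsu_threshold(total_smoothed), error = function(e) 0)
  substrate <- total_smoothed > thr
  ws <- cpp_watershed(total_smoothed, cores, substrate,
                      as.numeric(params$expansion_max_dist_bins))
  labels <- ws$labels
  geod <- ws$geodesic
  k <- max(labels)
  if (k == 0L) return(labels)
  h <- nrow(labels)
  # area trim: geodesically farthest pixels go first
  sizes <- tabulate(labels[labels > 0L], nbins = k)
  for (id in which(sizes > params$max_area_bins)) {
    idx <- which(labels == id)
    rr <- (idx - 1L) %% h + 1L
    cc <- (idx - 1L) %/% h + 1L
    ord <- order(-geod[idx], -rr, -cc)
    drop <- ord[seq_len(sizes[id] - params$max_area_bins)]
    labels[idx[drop]] <- 0L
  }
  # total-UMI floor, then contiguous relabel preserving core order
  idx <- which(labels > 0L)
  umi <- rep(0, k)
  agg <- vapply(split(raw_total[idx], labels[idx]), sum, numeric(1))
  umi[as.integer(names(agg))] <- agg
  keep_ids <- which(umi >= params$min_total_umi & tabulate(labels[idx], k) > 0L)
  remap <- integer(k)
  remap[keep_ids] <- seq_along(keep_ids)
  out <- matrix(0L, h, ncol(labels))
  out[idx] <- remap[labels[idx]]
  attr(out, "geodesic") <- geod
  out
}

#' Assign spots to cellbins and summarize
#'
#' Each record lands on the label at its bin; label 0 means unassigned.
#' Per-cellbin summaries: `area_bins`, unweighted pixel centroid,
#' `total_umi`, `n_genes` (genes with >= 1 UMI), `mito_umi` and
#' `mito_fraction`. UMI is conserved exactly: assigned + unassigned =
#' input.
#'
#' @param labels integer cellbin label matrix.
#' @param spots a [spot_table()].
#' @return list with `cellbins` (data.table, one row per label 1..K),
#'   `matrix` (a [cellbin_matrix()]), `unassigned` (a [spot_table()]).
#' @export
assign_spots <- function(labels, spots) {
  grid <- attr(spots, "grid")
  if (nrow(labels) != grid$height_bins || ncol(labels) != grid$width_bins)
    stop("label map shape does not match grid")
  k <- max(labels)
  lab <- labels[cbind(spots$y_bin + 1L, spots$x_bin + 1L)]
  assigned <- spots[lab > 0L]
  alab <- lab[lab > 0L]
  unassigned <- spots[lab == 0L]
  setattr(unassigned, "grid", grid)
  setattr(unassigned, "class", class(spots))

  # geometry from the label raster itself (cellbins may contain empty bins)
  idx <- which(labels > 0L)
  h <- nrow(labels)
  geom <- data.table(cellbin_id = labels[idx],
                     y = (idx - 1L) %% h,       # 0-based
                     x = (idx - 1L) %/% h)
  geom <- geom[, .(area_bins = .N, centroid_x = mean(x), centroid_y = mean(y)),
               by = cellbin_id]

  if (nrow(assigned)) {
    expr <- data.table(cellbin_id = alab, gene_id = assigned$gene_id,
                       umi_count = assigned$umi_count,
                       is_mito = assigned$is_mito)
    per <- expr[, .(total_umi = sum(umi_count),
                    n_genes = data.table::uniqueN(gene_id),
                    mito_umi = sum(umi_count[is_mito])), by = cellbin_id]
  } else {
    per <- data.table(cellbin_id = integer(), total_umi = integer(),
                      n_genes = integer(), mito_umi = integer())
  }
  cb <- merge(data.table(cellbin_id = seq_len(k)), geom,
              by = "cellbin_id", all.x = TRUE)
  cb <- merge(cb, per, by = "cellbin_id", all.x = TRUE)
  for (col in c("total_umi", "n_genes", "mito_umi"))
    cb[is.na(get(col)), (col) := 0L]
  cb[, mito_fraction := ifelse(total_umi > 0, mito_umi / total_umi, 0)]
  setorder(cb, cellbin_id)

  genes <- sort(unique(spots$gene_id))
  if (nrow(assigned)) {
    gi <- match(assigned$gene_id, genes)
    counts <- sparseMatrix(i = alab, j = gi, x = assigned$umi_count,
                           dims = c(k, length(genes)),
                           dimnames = list(as.character(seq_len(k)), genes))
  } else {
    counts <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(k, length(genes)),
                           dimnames = list(as.character(seq_len(k)), genes))
  }
  list(cellbins = cb[], matrix = cellbin_matrix(counts, cb),
       unassigned = unassigned[])
}

#' Segment a spot table into cellbins
#'
#' Full composition of the cellbin algorithm: build unspliced and total
#' density maps, Gaussian-smooth both, detect cores on the unspliced
#' channel by watershed, expand them over the total channel under size and
#' count constraints, then aggregate spots per cellbin. Deterministic for
#' fixed inputs and parameters.
#'
#' @param spots a [spot_table()].
#' @param params a [segmentation_params()].
#' @param verbose log per-stage counts to stderr.
#' @return list with `labels`, `cores`, `cellbins`, `matrix`, `unassigned`,
#'   `stats`.
#' @export
segment_cellbins <- function(spots, params = segmentation_params(),
                             verbose = FALSE) {
  if (!nrow(spots)) stop("empty spot table")
  raw_unspl <- build_density(spots, "unspliced")
  raw_total <- build_density(spots, "total")
  sm_unspl <- smooth_density(raw_unspl, params$sigma_bins)
  sm_total <- smooth_density(raw_total, params$sigma_bins)
  cores <- detect_cores(sm_unspl, raw_unspl, params)
  n_cores <- max(cores)
  labels <- expand_cores(cores, sm_total, raw_total, params)
  attr(labels, "geodesic") <- NULL
  res <- assign_spots(labels, spots)
  stats <- list(n_cores = n_cores, n_cellbins = max(labels),
                assigned_umi = sum(res$cellbins$total_umi),
                total_umi = sum(spots$umi_count))
  if (verbose)
    message(sprintf("cores: %d; cellbins: %d; UMI recall: %.3f",
                    stats$n_cores, stats$n_cellbins,
                    stats$assigned_umi / stats$total_umi))
  c(list(labels = labels, cores = cores), res, list(stats = stats))
}
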