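#' Synthetic scene specification
#'
#' Declares a ground-truth tissue scene for end-to-end validation: circular
#' tubules laid out on a lattice, non-overlapping circular cells packed in
#' the annulus between lumen and membrane, nucleus-concentrated unspliced
#' RNA, cytoplasm-scattered spliced RNA, uniform extracellular background,
#' gradient genes whose Poisson rates vary linearly with the cell's
#' distance to the tubule membrane, and designated extracellular-only and
#' mitochondrial genes.
#'
#' Rates are molecules per pixel bin: `unspliced_nuclear_rate` is the
#' nuclear unspliced rate (nuclei additionally emit spliced molecules at a
#' 80:20 unspliced:spliced mix), `spliced_cyto_rate` the cytoplasmic
#' spliced rate (95:5 spliced:unspliced mix), `background_rate` the
#' extracellular rate.
#'
#' @param grid a [grid_spec()] (default 768 x 768 at 250 nm pitch).
#' @param n_tubules,cells_per_tubule scene layout (defaults 5 and 10).
#' @param tubule_radius_bins,lumen_radius_bins tubule outer and lumen radii
#'   (defaults 110 and 30 bins).
#' @param nucleus_radius_bins,cell_radius_bins cell geometry (defaults 10
#'   and 20 bins, i.e. 5 and 10 um diameter at 250 nm pitch).
#' @param unspliced_nuclear_rate,spliced_cyto_rate,background_rate Poisson
#'   intensities per bin (defaults 0.4, 0.3, 0.02).
#' @param n_genes size of the ubiquitous gene pool (default 40).
#' @param gradient_genes data.frame `gene_id`, `slope` (rate change per bin
#'   of membrane distance), `baseline`; cell-wide rate is
#'   `max(0, baseline + slope * distance)`.
#' @param extracellular_genes gene ids emitted only outside cells.
#' @param mito_genes mitochondrial gene ids inside the pool.
#' @param seed integer RNG seed.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(grid = grid_spec(768L, 768L),
                       n_tubules = 5L, cells_per_tubule = 10L,
                       tubule_radius_bins = 110, lumen_radius_bins = 30,
                       nucleus_radius_bins = 10, cell_radius_bins = 20,
                       unspliced_nuclear_rate = 0.4,
                       spliced_cyto_rate = 0.3,
                       background_rate = 0.02,
                       n_genes = 40L,
                       gradient_genes = data.frame(
                         gene_id = c("gradpos1", "gradpos2",
                                     "gradneg1", "gradneg2"),
                         slope = c(0.010, 0.006, -0.010, -0.006),
                         baseline = c(0.02, 0.02, 0.75, 0.50)),
                       extracellular_genes = c("extra1", "extra2"),
                       mito_genes = c("mt-Nd4", "mt-Cytb", "mt-Atp6"),
                       seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"),
            nucleus_radius_bins < cell_radius_bins,
            lumen_radius_bins + 2 * cell_radius_bins < tubule_radius_bins,
            unspliced_nuclear_rate >= 0, spliced_cyto_rate >= 0,
            background_rate >= 0)
  structure(list(grid = grid, n_tubules = as.integer(n_tubules),
                 cells_per_tubule = as.integer(cells_per_tubule),
                 tubule_radius_bins = tubule_radius_bins,
                 lumen_radius_bins = lumen_radius_bins,
                 nucleus_radius_bins = nucleus_radius_bins,
                 cell_radius_bins = cell_radius_bins,
                 unspliced_nuclear_rate = unspliced_nuclear_rate,
                 spliced_cyto_rate = spliced_cyto_rate,
                 background_rate = background_rate,
                 n_genes = as.integer(n_genes),
                 gradient_genes = as.data.frame(gradient_genes),
                 extracellular_genes = extracellular_genes,
                 mito_genes = mito_genes,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# deterministic tubule layout: lattice with spacing 2 * (radius + 8)
tubule_centers <- function(spec) {
  margin <- spec$tubule_radius_bins + 8
  spacing <- 2 * margin
  xs <- seq(margin, spec$grid$width_bins - margin, by = spacing)
  ys <- seq(margin, spec$grid$height_bins - margin, by = spacing)
  if (length(xs) * length(ys) < spec$n_tubules)
    stop("infeasible packing: grid too small for the requested tubules")
  centers <- as.matrix(expand.grid(x = xs, y = ys))[seq_len(spec$n_tubules), ,
                                                    drop = FALSE]
  centers
}

# 0-based (x, y) disk pixel indices around a (possibly fractional) center
disk_bins <- function(cx, cy, r, grid) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(grid$width_bins - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(grid$height_bins - 1L, ceiling(cy + r))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ]
  as.matrix(g)
}

#' Generate a synthetic spatial scene
#'
#' Places cells in tubule annuli by stratified rejection sampling (error
#' after 10^4 failed placements), then draws molecule counts per
#' compartment from Poisson laws and scatters them uniformly over the
#' compartment's bins. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list with `spots` (a [spot_table()]) and `truth` (ground truth:
#'   `labels` cell label map, `cells` table with centers/radii/membrane
#'   distances, `tubules` boundary list, `gene_params`, `spec`).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  grid <- spec$grid
  centers <- tubule_centers(spec)
  rc <- spec$cell_radius_bins

  tubules <- lapply(seq_len(spec$n_tubules), function(i) {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    v <- cbind(round(centers[i, 1] + spec$tubule_radius_bins * cos(th)),
               round(centers[i, 2] + spec$tubule_radius_bins * sin(th)))
    tubule_boundary(i, unique(v), grid)
  })

  # cell placement: stratified angles, alternating inner/outer radial
  # strata (emulating layered germ-cell depths), rejection on overlap with
  # whole-tubule restarts under a total attempt budget of 10^4 per tubule
  r_min <- spec$lumen_radius_bins + rc
  r_max <- spec$tubule_radius_bins - rc - 2
  r_mid <- sqrt((r_min^2 + r_max^2) / 2)   # equal-area split
  cells <- list()
  cid <- 0L
  for (ti in seq_len(spec$n_tubules)) {
    budget <- 10000L
    repeat {
      placed <- matrix(numeric(), 0, 2)
      failed <- FALSE
      for (ci in seq_len(spec$cells_per_tubule)) {
        lo <- if (ci %% 2L == 1L) r_mid else r_min
        hi <- if (ci %% 2L == 1L) r_max else r_mid
        ok <- FALSE
        while (budget > 0L) {
          budget <- budget - 1L
          ang <- 2 * pi * ((ci - 1) + runif(1)) / spec$cells_per_tubule
          rr <- sqrt(runif(1, lo^2, hi^2))
          cx <- centers[ti, 1] + rr * cos(ang)
          cy <- centers[ti, 2] + rr * sin(ang)
          if (nrow(placed) == 0 ||
              min((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >=
                (2 * rc + 2)^2) { ok <- TRUE; break }
          if (budget %% 200L == 0L) break   # restart the tubule layout
        }
        if (!ok) { failed <- TRUE; break }
        placed <- rbind(placed, c(cx, cy))
      }
      if (!failed) break
      if (budget <= 0L)
        stop("infeasible packing: could not place cells within 10^4 tries")
    }
    for (i in seq_len(nrow(placed))) {
      cid <- cid + 1L
      cells[[cid]] <- list(cell_id = cid, tubule_id = ti,
                           cx = placed[i, 1], cy = placed[i, 2])
    }
  }
  cells <- rbindlist(cells)
  cells[, dist_membrane := vapply(seq_len(.N), function(i)
    min_distance_to_boundary(cx[i], cy[i],
                             tubules[[tubule_id[i]]]$pixels), numeric(1))]

  # ground-truth label map
  labels <- matrix(0L, grid$height_bins, grid$width_bins)
  cell_bins <- vector("list", nrow(cells))
  nuc_bins <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cb <- disk_bins(cells$cx[i], cells$cy[i], rc, grid)
    nb <- disk_bins(cells$cx[i], cells$cy[i], spec$nucleus_radius_bins, grid)
    labels[cbind(cb[, 2] + 1L, cb[, 1] + 1L)] <- i
    cell_bins[[i]] <- cb
    nuc_bins[[i]] <- nb
  }

  # gene pool: equal-weight ubiquitous genes plus low-weight mito genes
  pool <- c(sprintf("gene%02d", seq_len(spec$n_genes)), spec$mito_genes)
  w <- c(rep(0.985 / spec$n_genes, spec$n_genes),
         rep(0.015 / max(1, length(spec$mito_genes)),
             length(spec$mito_genes)))

  emit <- function(bins, n, splice, genes, gene_w = NULL) {
    if (n == 0L || nrow(bins) == 0L) return(NULL)
    pick <- bins[sample.int(nrow(bins), n, replace = TRUE), , drop = FALSE]
    data.table(x_bin = pick[, 1], y_bin = pick[, 2],
               gene_id = if (length(genes) == 1L) genes else
                 sample(genes, n, replace = TRUE, prob = gene_w),
               splice_class = splice)
  }

  mol <- list()
  gg <- spec$gradient_genes
  for (i in seq_len(nrow(cells))) {
    nb <- nuc_bins[[i]]
    cb <- cell_bins[[i]]
    cyb <- cb[!paste(cb[, 1], cb[, 2]) %in% paste(nb[, 1], nb[, 2]), ,
              drop = FALSE]
    # nucleus: unspliced at the stated rate, spliced at the 80:20 complement
    n_u <- rpois(1, spec$unspliced_nuclear_rate * nrow(nb))
    n_s <- rpois(1, spec$unspliced_nuclear_rate * (0.2 / 0.8) * nrow(nb))
    # cytoplasm: spliced at the stated rate, unspliced at the 95:5 complement
    c_s <- rpois(1, spec$spliced_cyto_rate * nrow(cyb))
    c_u <- rpois(1, spec$spliced_cyto_rate * (0.05 / 0.95) * nrow(cyb))
    mol[[length(mol) + 1L]] <- emit(nb, n_u, "unspliced", pool, w)
    mol[[length(mol) + 1L]] <- emit(nb, n_s, "spliced", pool, w)
    mol[[length(mol) + 1L]] <- emit(cyb, c_s, "spliced", pool, w)
    mol[[length(mol) + 1L]] <- emit(cyb, c_u, "unspliced", pool, w)
    # gradient genes: whole-cell spliced signal at a distance-dependent rate
    for (gi in seq_len(nrow(gg))) {
      rate <- max(0, gg$baseline[gi] + gg$slope[gi] * cells$dist_membrane[i])
      mol[[length(mol) + 1L]] <-
        emit(cb, rpois(1, rate * nrow(cb)), "spliced", gg$gene_id[gi])
    }
  }

  # background: everything outside cells; 10% of it on extracellular-only
  # genes, the rest from the pool, 90:10 spliced:unspliced
  bg_idx <- which(labels == 0L)
  bg <- cbind(x = (bg_idx - 1L) %/% grid$height_bins,
              y = (bg_idx - 1L) %% grid$height_bins)
  n_bg <- rpois(1, spec$background_rate * nrow(bg))
  if (n_bg > 0) {
    n_ext <- rbinom(1, n_bg, if (length(spec$extracellular_genes)) 0.1 else 0)
    n_rest <- n_bg - n_ext
    n_bg_u <- rbinom(1, n_rest, 0.1)
    mol[[length(mol) + 1L]] <- emit(bg, n_ext, "spliced",
                                    spec$extracellular_genes,
                                    rep(1 / max(1, length(spec$extracellular_genes)),
                                        length(spec$extracellular_genes)))
    mol[[length(mol) + 1L]] <- emit(bg, n_rest - n_bg_u, "spliced", pool, w)
    mol[[length(mol) + 1L]] <- emit(bg, n_bg_u, "unspliced", pool, w)
  }

  mol <- rbindlist(mol)
  agg <- mol[, .(umi_count = .N), by = .(x_bin, y_bin, gene_id, splice_class)]
  setorder(agg, y_bin, x_bin, gene_id, splice_class)
  spots <- spot_table(sprintf("bin_%d_%d", agg$x_bin, agg$y_bin),
                      agg$x_bin, agg$y_bin, agg$gene_id, agg$splice_class,
                      agg$umi_count, grid)
  list(spots = spots,
       truth = list(labels = labels, cells = cells[], tubules = tubules,
                    gene_params = list(pool = pool, pool_weights = w,
                                       gradient = gg,
                                       extracellular = spec$extracellular_genes,
                                       mito = spec$mito_genes),
                    spec = spec))
}

# save/restore the global RNG state so generation is a pure function
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate a segmentation against ground truth
#'
#' Greedy one-to-one matching of predicted cellbins to true cells by
#' descending intersection-over-union (ties by true then predicted id);
#' reports the fraction of true cells matched at the IoU threshold and the
#' relative count error.
#'
#' @param predicted integer predicted label matrix.
#' @param truth_labels integer ground-truth label matrix (same shape).
#' @param iou_threshold matching threshold (default 0.5).
#' @return list `matched_fraction`, `n_true`, `n_pred`, `count_error`,
#'   `matches` (data.table true_id, pred_id, iou).
#' @export
evaluate_segmentation <- function(predicted, truth_labels,
                                  iou_threshold = 0.5) {
  if (!all(dim(predicted) == dim(truth_labels)))
    stop("shape mismatch between predicted and truth label maps")
  n_true <- max(truth_labels); n_pred <- max(predicted)
  if (n_true == 0L) stop("ground truth has no cells")
  both <- data.table(t = as.integer(truth_labels), p = as.integer(predicted))
  sizes_t <- both[t > 0L, .N, by = t]
  sizes_p <- both[p > 0L, .N, by = p]
  inter <- both[t > 0L & p > 0L, .(inter = .N), by = .(t, p)]
  if (nrow(inter)) {
    inter <- merge(inter, setnames(copy(sizes_t), "N", "nt"), by = "t")
    inter <- merge(inter, setnames(copy(sizes_p), "N", "np"), by = "p")
    inter[, iou := inter / (nt + np - inter)]
    setorder(inter, -iou, t, p)
    used_t <- logical(n_true); used_p <- logical(n_pred)
    keep <- logical(nrow(inter))
    for (i in seq_len(nrow(inter))) {
      if (!used_t[inter$t[i]] && !used_p[inter$p[i]]) {
        keep[i] <- TRUE
        used_t[inter$t[i]] <- TRUE
        used_p[inter$p[i]] <- TRUE
      }
    }
    matches <- inter[keep & iou >= iou_threshold,
                     .(true_id = t, pred_id = p, iou)]
  } else {
    matches <- data.table(true_id = integer(), pred_id = integer(),
                          iou = numeric())
  }
  list(matched_fraction = nrow(matches) / n_true,
       n_true = n_true, n_pred = n_pred,
       count_error = (n_pred - n_true) / n_true,
       matches = matches)
}
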