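#' UMI recall rate
#'
#' Fraction of all deduplicated UMIs that fall inside segmented cellbins.
#'
#' @param assigned_umi UMIs inside cellbins.
#' @param total_umi all UMIs.
#' @return `assigned_umi / total_umi` in `[0, 1]`.
#' @export
umi_recall_rate <- function(assigned_umi, total_umi) {
  if (any(total_umi <= 0)) stop("total_umi must be > 0")
  if (any(assigned_umi < 0) || any(assigned_umi > total_umi))
    stop("need 0 <= assigned_umi <= total_umi")
  assigned_umi / total_umi
}

# lower median: for even n, the smaller of the two central order statistics.
# Chosen because reported per-cellbin medians are integers.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Summarize a cellbin set
#'
#' The QC surface reported for a segmentation run: cellbin count, medians
#' of area, UMI, detected genes and mitochondrial fraction (lower median
#' for even n), the UMI recall rate, and optionally sequencing saturation.
#'
#' @param cellbins per-cellbin data.table from [assign_spots()].
#' @param unassigned_umi UMIs outside all cellbins (for the recall rate).
#' @param saturation optional sequencing saturation to carry through.
#' @return list of class `qc_summary`.
#' @export
summarize_cellbins <- function(cellbins, unassigned_umi = 0L,
                               saturation = NA_real_) {
  if (!nrow(cellbins)) stop("empty cellbin set")
  assigned <- sum(cellbins$total_umi)
  structure(list(
    n_cellbins = nrow(cellbins),
    median_area_bins = lower_median(cellbins$area_bins),
    median_umi = lower_median(cellbins$total_umi),
    median_genes = lower_median(cellbins$n_genes),
    median_mito_fraction = lower_median(cellbins$mito_fraction),
    umi_recall_rate = umi_recall_rate(assigned, assigned + unassigned_umi),
    saturation = saturation
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_summary> %d cellbins\n",
    "  median area       : %s bins\n",
    "  median UMI        : %s\n",
    "  median genes      : %s\n",
    "  median mito frac  : %.4f\n",
    "  UMI recall rate   : %.4f\n",
    "  saturation        : %s\n"),
    x$n_cellbins, x$median_area_bins, x$median_umi, x$median_genes,
    x$median_mito_fraction, x$umi_recall_rate,
    ifelse(is.na(x$saturation), "-", sprintf("%.3f", x$saturation))))
  invisible(x)
}

# Exact two-sided binomial p-value: the probability, under
# Binomial(n, p0), of outcomes whose pmf does not exceed that of the
# observed count (with the customary 1 + 1e-7 relative tolerance).
binom_p_two_sided <- function(x, n, p0) {
  if (n == 0L) return(1)
  d <- dbinom(x, n, p0)
  sum(dbinom(0:n, n, p0)[dbinom(0:n, n, p0) <= d * (1 + 1e-7)])
}

#' Classify per-gene recall against the global rate
#'
#' For each gene, tests whether its in-cellbin UMI fraction departs from
#' the global UMI recall rate: exact two-sided binomial test of
#' `umi_in ~ Binomial(umi_total, global_rate)`, Benjamini-Hochberg
#' adjustment across genes. A gene is `recalled` when significantly above
#' the global rate (enriched inside cells), `unrecalled` when significantly
#' below (extracellular-leaning), otherwise `neither`. Genes with zero
#' total UMI get `neither` with `p_adj = 1`.
#'
#' @param gene_id character vector.
#' @param umi_in,umi_total per-gene UMIs inside cellbins and overall.
#' @param global_rate overall UMI recall rate in (0, 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.table with `gene_id`, `umi_in`, `umi_total`, `p_adj`,
#'   `class` in {recalled, unrecalled, neither}.
#' @export
classify_gene_recall <- function(gene_id, umi_in, umi_total,
                                 global_rate, alpha = 0.05) {
  stopifnot(global_rate > 0, global_rate < 1,
            length(umi_in) == length(gene_id),
            length(umi_total) == length(gene_id))
  if (any(umi_in > umi_total) || any(umi_in < 0))
    stop("need 0 <= umi_in <= umi_total")
  p <- mapply(binom_p_two_sided, umi_in, umi_total,
              MoreArgs = list(p0 = global_rate))
  p[umi_total == 0L] <- 1
  p_adj <- p.adjust(p, method = "BH")
  prop <- ifelse(umi_total > 0, umi_in / umi_total, global_rate)
  cls <- ifelse(p_adj < alpha & prop > global_rate, "recalled",
         ifelse(p_adj < alpha & prop < global_rate, "unrecalled", "neither"))
  cls[umi_total == 0L] <- "neither"
  data.table(gene_id = gene_id, umi_in = as.integer(umi_in),
             umi_total = as.integer(umi_total), p_adj = p_adj, class = cls)
}

#' Per-gene recall table from assignment output
#'
#' Convenience wrapper computing `umi_in`/`umi_total` per gene from a
#' segmentation result and classifying with [classify_gene_recall()].
#'
#' @param matrix a [cellbin_matrix()].
#' @param unassigned the unassigned [spot_table()].
#' @param alpha significance level.
#' @return data.table as in [classify_gene_recall()].
#' @export
gene_recall_table <- function(matrix, unassigned, alpha = 0.05) {
  in_cell <- Matrix::colSums(matrix$counts)
  out_dt <- if (nrow(unassigned))
    unassigned[, .(umi_out = sum(umi_count)), by = gene_id] else
    data.table(gene_id = character(), umi_out = numeric())
  dt <- merge(data.table(gene_id = names(in_cell), umi_in = as.numeric(in_cell)),
              out_dt, by = "gene_id", all = TRUE)
  dt[is.na(umi_in), umi_in := 0]
  dt[is.na(umi_out), umi_out := 0]
  total_in <- sum(dt$umi_in); total_all <- total_in + sum(dt$umi_out)
  rate <- umi_recall_rate(total_in, total_all)
  classify_gene_recall(dt$gene_id, dt$umi_in, dt$umi_in + dt$umi_out,
                       rate, alpha)
}
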