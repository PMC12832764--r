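#' Cellbin-by-gene count matrix
#'
#' Container pairing a sparse integer count matrix (rows = cellbins,
#' columns = genes) with the per-cellbin metadata produced by
#' [assign_spots()]. Row totals always equal the metadata `total_umi`.
#'
#' @param counts a `Matrix::sparseMatrix` (or coercible), rows = cellbins.
#' @param cellbins data.table of per-cellbin metadata (see [assign_spots()]).
#' @return An object of class `cellbin_matrix`.
#' @export
cellbin_matrix <- function(counts, cellbins) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != nrow(cellbins))
    stop("counts rows and cellbin metadata rows differ")
  if (any(counts@x < 0)) stop("negative counts")
  rt <- Matrix::rowSums(counts)
  if (!isTRUE(all.equal(unname(rt), as.numeric(cellbins$total_umi))))
    stop("row totals do not match cellbin total_umi")
  structure(list(counts = counts, cellbins = as.data.table(cellbins),
                 genes = colnames(counts)),
            class = "cellbin_matrix")
}

#' @export
print.cellbin_matrix <- function(x, ...) {
  cat(sprintf("<cellbin_matrix> %d cellbins x %d genes, %d UMIs\n",
              nrow(x$counts), ncol(x$counts), as.integer(sum(x$counts))))
  invisible(x)
}

#' Write / read a cellbin matrix directory
#'
#' MatrixMarket coordinate format (`matrix.mtx`) plus `cellbins.tsv`
#' (id, area_bins, centroid_x, centroid_y, total_umi, n_genes,
#' mito_fraction, ...) and `genes.tsv`, mirroring the on-disk layout of
#' common single-cell count-matrix exchanges.
#'
#' @param mat a [cellbin_matrix()].
#' @param dir output directory (created if absent).
#' @return `write_cellbin_matrix` the directory; `read_cellbin_matrix`
#'   a [cellbin_matrix()].
#' @export
write_cellbin_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "cellbin_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  fwrite(mat$cellbins, file.path(dir, "cellbins.tsv"), sep = "\t")
  fwrite(data.table(gene = mat$genes), file.path(dir, "genes.tsv"),
         sep = "\t")
  invisible(dir)
}

#' @rdname write_cellbin_matrix
#' @export
read_cellbin_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
  counts <- Matrix::readMM(mtx)
  cellbins <- fread(file.path(dir, "cellbins.tsv"))
  genes <- fread(file.path(dir, "genes.tsv"))$gene
  colnames(counts) <- genes
  rownames(counts) <- as.character(cellbins$cellbin_id)
  cellbin_matrix(counts, cellbins)
}
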