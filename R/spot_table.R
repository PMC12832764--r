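#' Molecule-level spot table
#'
#' The universal input of the pipeline: one row per deduplicated molecule
#' group, i.e. per distinct (barcode, gene, splice class) at one bin, with
#' `umi_count` distinct UMIs. Coordinates are 0-based bin indices validated
#' against the grid; `is_mito` is derived from the gene id (mouse
#' mitochondrial nomenclature, case-insensitive prefix "mt-").
#'
#' @param barcode_id character, spatial barcode or bin identifier.
#' @param x_bin,y_bin integer 0-based bin coordinates.
#' @param gene_id character gene identifiers.
#' @param splice_class "spliced" or "unspliced".
#' @param umi_count integer >= 1, number of distinct UMIs.
#' @param grid a [grid_spec()] the coordinates must fall inside.
#' @return A `data.table` of class `spot_table` with attribute `grid`.
#' @export
spot_table <- function(barcode_id, x_bin, y_bin, gene_id, splice_class,
                       umi_count, grid) {
  dt <- data.table(
    barcode_id = as.character(barcode_id),
    x_bin = as.integer(x_bin),
    y_bin = as.integer(y_bin),
    gene_id = as.character(gene_id),
    splice_class = as.character(splice_class),
    umi_count = as.integer(umi_count)
  )
  dt[, is_mito := startsWith(tolower(gene_id), "mt-")]
  validate_spot_table(dt, grid)
  setattr(dt, "grid", grid)
  setattr(dt, "class", c("spot_table", class(dt)))
  dt[]
}

setattr <- data.table::setattr

#' Validate a spot table against its grid
#'
#' Checks column presence, coordinate bounds, splice classes and counts.
#' Errors name the first offending row so bad input files are debuggable.
#'
#' @param dt a data.frame/data.table with spot-table columns.
#' @param grid a [grid_spec()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_spot_table <- function(dt, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  need <- c("barcode_id", "x_bin", "y_bin", "gene_id", "splice_class",
            "umi_count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("spot table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(dt$x_bin < 0L | dt$x_bin >= grid$width_bins |
               dt$y_bin < 0L | dt$y_bin >= grid$height_bins)
  if (length(bad))
    stop(sprintf("row %d: coordinate (%d, %d) outside grid %d x %d",
                 bad[1], dt$x_bin[bad[1]], dt$y_bin[bad[1]],
                 grid$width_bins, grid$height_bins))
  bad <- which(!dt$splice_class %in% c("spliced", "unspliced"))
  if (length(bad))
    stop(sprintf("row %d: unknown splice_class '%s'",
                 bad[1], dt$splice_class[bad[1]]))
  bad <- which(dt$umi_count < 1L | !is.finite(dt$umi_count))
  if (length(bad))
    stop(sprintf("row %d: umi_count %s is not an integer >= 1",
                 bad[1], dt$umi_count[bad[1]]))
  invisible(TRUE)
}

#' Read / write spot tables
#'
#' TSV with header `barcode  x_bin  y_bin  gene  splice_class  umi_count`.
#' Reading validates every coordinate against the grid; writing is the
#' exact inverse so the pair round-trips losslessly.
#'
#' @param path file path.
#' @param grid a [grid_spec()].
#' @return `read_spot_table` a [spot_table()]; `write_spot_table` the path.
#' @export
read_spot_table <- function(path, grid) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("barcode", "gene", "splice_class")))
  need <- c("barcode", "x_bin", "y_bin", "gene", "splice_class", "umi_count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("spot table file missing column(s): ", paste(miss, collapse = ", "))
  spot_table(dt$barcode, dt$x_bin, dt$y_bin, dt$gene, dt$splice_class,
             dt$umi_count, grid)
}

#' @param spots a [spot_table()].
#' @rdname read_spot_table
#' @export
write_spot_table <- function(spots, path) {
  out <- data.table(barcode = spots$barcode_id, x_bin = spots$x_bin,
                    y_bin = spots$y_bin, gene = spots$gene_id,
                    splice_class = spots$splice_class,
                    umi_count = spots$umi_count)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
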