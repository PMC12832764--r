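#' Extract the spatial barcode and UMI from a read-1 sequence
#'
#' The chip places the 30-nt spatial barcode (SBC) at 1-based positions
#' 1-30 of read 1 and the 10-nt UMI at positions 88-97; the intervening
#' bases are fixed adapter/linker sequence. Reads shorter than 97 nt
#' cannot carry a complete UMI and are reported as discarded.
#'
#' @param seq1 character vector of read-1 sequences (ACGTN).
#' @return A data.table with columns `sbc`, `umi` and logical `ok`
#'   (`FALSE` with `reason = "short"` for reads under 97 nt).
#' @export
extract_sbc_umi <- function(seq1) {
  n <- nchar(seq1)
  ok <- n >= 97L
  data.table(
    sbc = ifelse(ok, substr(seq1, 1L, 30L), NA_character_),
    umi = ifelse(ok, substr(seq1, 88L, 97L), NA_character_),
    ok = ok,
    reason = ifelse(ok, NA_character_, "short")
  )
}

#' Barcode whitelist lookup
#'
#' Builds an indexed whitelist from chip fabrication data. Barcodes must be
#' unique 30-mers; coordinates must lie inside the grid.
#'
#' @param barcode character vector of 30-mers.
#' @param x_bin,y_bin integer bin coordinates of each barcode.
#' @param grid a [grid_spec()].
#' @return An object of class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(barcode, x_bin, y_bin, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(nchar(barcode) != 30L)) stop("whitelist barcodes must be 30-mers")
  if (anyDuplicated(barcode)) stop("whitelist barcodes must be unique")
  x_bin <- as.integer(x_bin); y_bin <- as.integer(y_bin)
  if (any(x_bin < 0L | x_bin >= grid$width_bins |
          y_bin < 0L | y_bin >= grid$height_bins))
    stop("whitelist coordinate outside grid")
  idx <- new.env(parent = emptyenv(), size = length(barcode))
  for (i in seq_along(barcode)) assign(barcode[i], i, envir = idx)
  structure(list(barcode = barcode, x_bin = x_bin, y_bin = y_bin,
                 grid = grid, index = idx),
            class = "barcode_whitelist")
}

#' @rdname barcode_whitelist
#' @param path TSV file with header `barcode  x_bin  y_bin`.
#' @export
read_barcode_whitelist <- function(path, grid) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = "barcode"))
  barcode_whitelist(dt$barcode, dt$x_bin, dt$y_bin, grid)
}

#' Correct a spatial barcode against the whitelist
#'
#' An exact whitelist hit wins outright. Otherwise every single-base
#' substitution of the query is looked up; if exactly one whitelist entry
#' sits at Hamming distance 1 its coordinates are returned, and ambiguous
#' hits (two or more entries at distance 1) are conservatively dropped.
#' No-match is a value, not an error.
#'
#' @param sbc character vector of 30-mer queries.
#' @param whitelist a [barcode_whitelist()].
#' @return data.table with `x_bin`, `y_bin`, the matched whitelist
#'   `barcode` (all NA when unmatched) and `status` in
#'   {exact, corrected, ambiguous, nomatch}.
#' @export
correct_barcode <- function(sbc, whitelist) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  if (any(!is.na(sbc) & nchar(sbc) != 30L))
    stop("queries must be 30-mers")
  idx <- whitelist$index
  bases <- c("A", "C", "G", "T")
  one <- function(q) {
    if (is.na(q)) return(c(NA_integer_, 3L))
    hit <- get0(q, envir = idx)
    if (!is.null(hit)) return(c(hit, 0L))
    found <- -1L
    nfound <- 0L
    for (p in 1:30) {
      orig <- substr(q, p, p)
      for (b in bases) {
        if (b == orig) next
        cand <- q
        substr(cand, p, p) <- b
        h <- get0(cand, envir = idx)
        if (!is.null(h)) {
          nfound <- nfound + 1L
          if (nfound > 1L) return(c(NA_integer_, 2L))
          found <- h
        }
      }
    }
    if (nfound == 1L) c(found, 1L) else c(NA_integer_, 3L)
  }
  res <- vapply(sbc, one, integer(2), USE.NAMES = FALSE)
  i <- res[1L, ]
  data.table(
    x_bin = ifelse(is.na(i), NA_integer_, whitelist$x_bin[i]),
    y_bin = ifelse(is.na(i), NA_integer_, whitelist$y_bin[i]),
    barcode = ifelse(is.na(i), NA_character_, whitelist$barcode[i]),
    status = c("exact", "corrected", "ambiguous", "nomatch")[res[2L, ] + 1L]
  )
}

#' Deduplicate UMIs into a spot table
#'
#' Reads sharing (barcode, gene, splice class, UMI) are PCR duplicates and
#' collapse to one molecule; `umi_count` is the number of distinct UMIs
#' per (barcode, gene, splice class). Coordinates come from the corrected
#' barcode.
#'
#' @param reads data.frame/data.table with columns `sbc`, `x_bin`, `y_bin`,
#'   `gene_id`, `umi` and optionally `splice_class` (default "spliced").
#' @param grid a [grid_spec()].
#' @return A [spot_table()].
#' @export
dedup_umis <- function(reads, grid) {
  reads <- as.data.table(reads)
  if (!"splice_class" %in% names(reads)) reads[, splice_class := "spliced"]
  reads[is.na(splice_class), splice_class := "spliced"]
  if (nrow(reads) == 0L)
    return(spot_table(character(), integer(), integer(), character(),
                      character(), integer(), grid))
  agg <- unique(reads[, .(sbc, x_bin, y_bin, gene_id, splice_class, umi)])[
    , .(umi_count = .N), by = .(sbc, x_bin, y_bin, gene_id, splice_class)]
  setorder(agg, y_bin, x_bin, gene_id, splice_class)
  spot_table(agg$sbc, agg$x_bin, agg$y_bin, agg$gene_id, agg$splice_class,
             agg$umi_count, grid)
}

#' Sequencing saturation
#'
#' `1 - n_unique_umis / n_reads_assigned`: 0 when every assigned read is a
#' new molecule, approaching 1 as the library is sequenced to exhaustion.
#'
#' @param n_reads_assigned reads assigned to a (barcode, gene).
#' @param n_unique_umis distinct molecules among them.
#' @return Saturation in `[0, 1]`.
#' @export
sequencing_saturation <- function(n_reads_assigned, n_unique_umis) {
  if (any(n_reads_assigned <= 0)) stop("n_reads_assigned must be > 0")
  if (any(n_unique_umis <= 0) || any(n_unique_umis > n_reads_assigned))
    stop("need 0 < n_unique_umis <= n_reads_assigned")
  1 - n_unique_umis / n_reads_assigned
}

#' Demultiplex raw reads into a spot table
#'
#' Full read-1 processing: extract SBC and UMI, correct the SBC against the
#' whitelist (1-bp mismatch tolerance), join externally assigned genes, and
#' deduplicate UMIs. Gene assignment (from read-2 alignment) is an input.
#'
#' @param read_id,seq1 read identifiers and read-1 sequences.
#' @param genes data.frame mapping `read_id` to `gene_id` and optionally
#'   `splice_class`; reads without a gene are dropped.
#' @param whitelist a [barcode_whitelist()].
#' @return list with `spots` (a [spot_table()]) and `stats` (per-fate read
#'   counts plus `saturation` over assigned reads).
#' @export
demux_reads <- function(read_id, seq1, genes, whitelist) {
  ext <- extract_sbc_umi(seq1)
  genes <- as.data.table(genes)
  stopifnot(all(c("read_id", "gene_id") %in% names(genes)))
  dt <- data.table(read_id = read_id, ext)
  corr <- correct_barcode(ifelse(dt$ok, dt$sbc, NA_character_), whitelist)
  # downstream grouping keys off the corrected whitelist barcode
  dt[, sbc := NULL]
  dt <- cbind(dt, setnames(corr, "barcode", "sbc"))
  dt <- merge(dt, genes, by = "read_id", all.x = TRUE, sort = FALSE)
  assigned <- dt[ok & !is.na(x_bin) & !is.na(gene_id)]
  stats <- list(
    n_reads = nrow(dt),
    n_short = sum(!dt$ok),
    n_nomatch = sum(dt$ok & corr$status == "nomatch"),
    n_ambiguous = sum(dt$ok & corr$status == "ambiguous"),
    n_unassigned_gene = sum(dt$ok & !is.na(dt$x_bin) & is.na(dt$gene_id)),
    n_assigned = nrow(assigned)
  )
  spots <- dedup_umis(assigned, whitelist$grid)
  stats$n_unique_umis <- sum(spots$umi_count)
  stats$saturation <- if (stats$n_assigned > 0)
    sequencing_saturation(stats$n_assigned, stats$n_unique_umis) else NA_real_
  list(spots = spots, stats = stats)
}

#' Read a FASTQ file (ids and sequences)
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return data.table with `read_id` and `seq1`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    data.table(read_id = sub("\\s.*$", "", names(ss)),
               seq1 = as.character(ss))
  } else {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
    data.table(read_id = sub("\\s.*$", "", sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
               seq1 = toupper(lines[c(FALSE, TRUE, FALSE, FALSE)]))
  }
}
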