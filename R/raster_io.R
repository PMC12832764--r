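#' Read and write label maps as PGM rasters
#'
#' Label maps (integer matrices, background = 0) are stored as plain-text
#' PGM (P2) with a 16-bit maxval, a portable single-channel raster any
#' image tool can open. Matrices are indexed `[y + 1, x + 1]` so row order
#' in the file matches the top-left origin convention.
#'
#' @param labels integer matrix, values in 0..65535.
#' @param path output file.
#' @return `write_label_map` the path; `read_label_map` an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels))
  v <- as.integer(labels)
  if (any(is.na(v)) || any(v < 0L) || any(v > 65535L))
    stop("label values must be integers in 0..65535")
  maxval <- max(1L, max(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(labels), nrow(labels)),
               as.character(maxval)), con)
  # one raster row per line
  writeLines(apply(matrix(v, nrow(labels)), 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("label map not found: ", path)
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("unsupported raster format (expected plain PGM P2)")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: pixel count mismatch")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a binary mask as an 8-bit raster (0/255)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  write_label_map(matrix(ifelse(mask, 255L, 0L), nrow(mask)), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) read_label_map(path) > 0L
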