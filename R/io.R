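#' Read and write chrom.sizes files
#'
#' Two-column tab-separated files (chromosome, length) as used throughout
#' genome-arithmetic tooling.
#'
#' @param path file path.
#' @return `read_chrom_sizes`: a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         stringsAsFactors = FALSE)
  genome_layout(d$chrom, d$length)
}

#' @rdname read_chrom_sizes
#' @param layout a [genome_layout()].
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write BED interval files
#'
#' Tab-separated, headerless BED3+ with 0-based half-open coordinates.
#' Columns beyond the third are kept: column 4 becomes `name`, column 5
#' `score`, column 6 `strand`; any further columns keep positional names.
#'
#' @param path file path.
#' @param layout optional [genome_layout()] for validation/seqlengths.
#' @return `read_bed_regions`: a `GRanges`.
#' @export
read_bed_regions <- function(path, layout = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  extra <- list()
  if (ncol(d) >= 4) extra$name <- d[[4]]
  if (ncol(d) >= 5) extra$score <- d[[5]]
  gr <- do.call(region_set,
                c(list(chrom = d[[1]], start = d[[2]], end = d[[3]],
                       layout = layout), extra))
  if (ncol(d) >= 6) GenomicRanges::strand(gr) <- d[[6]]
  gr
}

#' @rdname read_bed_regions
#' @param regions a `GRanges` (metadata columns `name` and `score` are
#'   written as BED columns 4-5 when present).
#' @export
write_bed_regions <- function(regions, path) {
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                  start = format(bed_start(regions), scientific = FALSE, trim = TRUE),
                  end = format(bed_end(regions), scientific = FALSE, trim = TRUE),
                  stringsAsFactors = FALSE)
  if (!is.null(regions$name)) {
    d$name <- regions$name
    if (!is.null(regions$score)) d$score <- regions$score
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write cell metadata tables
#'
#' Tab-separated with a header; one row per cell.
#'
#' @param path file path.
#' @return `read_cell_table`: a data frame.
#' @export
read_cell_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  # numeric columns recover their type; "F"/"T" sex codes stay character
  d[] <- lapply(d, function(x) utils::type.convert(x, as.is = TRUE,
                                                   tryLogical = FALSE))
  d
}

#' @rdname read_cell_table
#' @param cells cell metadata data frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write a sparse matrix as MatrixMarket + index files
#'
#' Writes `<prefix>.mtx` together with `<prefix>.rows.txt` and
#' `<prefix>.cols.txt` holding the dimnames, one id per line — the
#' cells-by-features dialect used for single-cell matrices.
#'
#' @param prefix path prefix (without extension).
#' @return `read_accessibility_mtx`: a sparse `dgCMatrix` with dimnames.
#' @export
read_accessibility_mtx <- function(prefix) {
  m <- Matrix::Matrix(Matrix::readMM(paste0(prefix, ".mtx")), sparse = TRUE)
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.txt")),
                      readLines(paste0(prefix, ".cols.txt")))
  m
}

#' @rdname read_accessibility_mtx
#' @param matrix sparse matrix with dimnames (cells x features).
#' @export
write_accessibility_mtx <- function(matrix, prefix) {
  Matrix::writeMM(Matrix::Matrix(matrix, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(matrix), paste0(prefix, ".rows.txt"))
  writeLines(colnames(matrix), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' DARTable to GRanges
#'
#' @param dars a `DARTable` data frame with `chrom`, `start`, `end`; other
#'   columns become metadata.
#' @param layout optional [genome_layout()].
#' @return A `GRanges` with the remaining columns as mcols.
#' @export
dars_to_regions <- function(dars, layout = NULL) {
  assert_columns(dars, c("chrom", "start", "end"), "dars")
  gr <- region_set(dars$chrom, dars$start, dars$end, layout = layout)
  extra <- setdiff(names(dars), c("chrom", "start", "end"))
  for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- dars[[cn]]
  gr
}
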