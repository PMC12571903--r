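#' Read a 10x-style Matrix Market count triplet
#'
#' Reads `matrix.mtx` + `barcodes.tsv` + `features.tsv` into a
#' [cell_counts] object. On disk the matrix follows the 10x convention of
#' genes x cells; in memory cells are rows, so the matrix is transposed on
#' read. Features files with two or three columns are accepted; the second
#' column is taken as the gene symbol when present.
#'
#' @param matrix_path path to the Matrix Market file.
#' @param barcodes_path path to the one-column barcode file.
#' @param features_path path to the 1-3 column features file.
#' @param meta_path optional path to a sidecar cell-annotation TSV keyed by
#'   `barcode` (sample/genotype/condition/organ/subset labels).
#' @return A [cell_counts] object.
#' @export
read_10x_counts <- function(matrix_path, barcodes_path, features_path,
                            meta_path = NULL) {
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)          # genes x cells on disk
  barcodes <- readLines(barcodes_path)
  feats <- utils::read.table(features_path, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             stringsAsFactors = FALSE)
  gene_names <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(m) != length(gene_names)) {
    stop("format error: ", features_path, " has ", length(gene_names),
         " features but the matrix declares ", nrow(m), " rows",
         call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("format error: ", barcodes_path, " has ", length(barcodes),
         " barcodes but the matrix declares ", ncol(m), " columns",
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("format error: duplicate barcodes in ", barcodes_path, call. = FALSE)
  }
  cell_meta <- NULL
  if (!is.null(meta_path)) {
    cell_meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  }
  cell_counts(Matrix::t(m), barcodes = barcodes, gene_names = gene_names,
              cell_meta = cell_meta)
}

#' Write a cell_counts object as a 10x-style triplet
#'
#' Writes `matrix.mtx` (genes x cells, per the on-disk convention),
#' `barcodes.tsv`, `features.tsv` (two columns: id, symbol) and, when the
#' object carries annotations beyond the barcode, `cell_meta.tsv`.
#'
#' @param x a [cell_counts] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x_counts <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = x$gene_names, symbol = x$gene_names),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (ncol(x$cell_meta) > 1) {
    write_result_tsv(x$cell_meta, file.path(dir, "cell_meta.tsv"))
  }
  invisible(dir)
}
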