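#' Construct a cell x gene count matrix with per-cell annotations
#'
#' The central container for digital gene expression: a sparse non-negative
#' integer matrix with cells as rows and genes as columns, plus a per-cell
#' annotation table carrying the experimental design labels
#' (sample, genotype WT/KO, condition naive/infected, organ spleen/lung,
#' T-cell subset).
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   cells x genes.
#' @param barcodes character vector of unique cell identifiers (row names).
#' @param gene_names character vector of unique gene symbols (column names).
#' @param cell_meta optional data.frame keyed by `barcode` with any of the
#'   columns `sample_id`, `genotype`, `condition`, `organ`, `subset`.
#'   Categorical fields are validated case-sensitively against the
#'   controlled vocabularies.
#'
#' @return An object of class `cell_counts`: a list with elements `counts`
#'   (dgCMatrix, cells x genes), `barcodes`, `gene_names`, `cell_meta`.
#' @export
cell_counts <- function(counts, barcodes = rownames(counts),
                        gene_names = colnames(counts), cell_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) || is.null(gene_names)) {
    stop("barcodes and gene_names are required", call. = FALSE)
  }
  barcodes <- as.character(barcodes)
  gene_names <- as.character(gene_names)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  if (anyDuplicated(gene_names)) stop("duplicate gene names", call. = FALSE)
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(gene_names)) {
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match barcodes (", length(barcodes), ") x gene_names (",
         length(gene_names), ")", call. = FALSE)
  }
  v <- counts@x
  if (length(v) && (min(v) < 0 || any(v != round(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(barcodes, gene_names)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  } else {
    cell_meta <- validate_cell_meta(cell_meta, barcodes)
  }
  structure(list(counts = counts, barcodes = barcodes,
                 gene_names = gene_names, cell_meta = cell_meta),
            class = "cell_counts")
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' @export
print.cell_counts <- function(x, ...) {
  cat("cell_counts: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes (", length(x$counts@x), " non-zero entries)\n", sep = "")
  extra <- setdiff(names(x$cell_meta), "barcode")
  if (length(extra)) {
    cat("cell_meta fields:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a cell_counts object by cells
#'
#' @param x a `cell_counts` object.
#' @param cells logical, integer, or character (barcode) index.
#' @return A `cell_counts` with the selected cells, annotations aligned.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "cell_counts"))
  if (is.character(cells)) cells <- match(cells, x$barcodes)
  if (is.logical(cells)) cells <- which(cells)
  if (anyNA(cells)) stop("unknown barcode in cell subset", call. = FALSE)
  cell_counts(x$counts[cells, , drop = FALSE],
              barcodes = x$barcodes[cells],
              gene_names = x$gene_names,
              cell_meta = x$cell_meta[cells, , drop = FALSE])
}
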