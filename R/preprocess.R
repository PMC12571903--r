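#' Quality-control filtering of cells
#'
#' Removes cells whose mitochondrial read fraction is strictly greater than
#' `max_mito_fraction` (default 0.07, i.e. "more than 7 percent") or whose
#' total count is below `min_counts_per_cell`. Mitochondrial genes are
#' identified by the mouse `mt-` name prefix.
#'
#' @param x a [cell_counts] object.
#' @param max_mito_fraction maximum tolerated mitochondrial fraction;
#'   strictly-greater values are removed. Default 0.07.
#' @param min_counts_per_cell minimum total counts; default 1 removes only
#'   empty cells.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return list with `counts` (the filtered [cell_counts]) and `audit`, a
#'   data.frame with one row per input cell: `barcode`, `total_counts`,
#'   `mito_fraction`, `kept`, `reason` ("" when kept).
#' @export
filter_cells <- function(x, max_mito_fraction = 0.07,
                         min_counts_per_cell = 1L, mito_prefix = "mt-") {
  stopifnot(inherits(x, "cell_counts"),
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  totals <- Matrix::rowSums(x$counts)
  mito <- startsWith(x$gene_names, mito_prefix)
  if (!any(mito)) {
    warning("no genes match mitochondrial prefix '", mito_prefix,
            "'; mito filter skipped", call. = FALSE)
    mito_frac <- rep(0, length(totals))
    mito_applied <- FALSE
  } else {
    mito_counts <- Matrix::rowSums(x$counts[, mito, drop = FALSE])
    mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)
    mito_applied <- TRUE
  }
  low <- totals < min_counts_per_cell
  high_mito <- mito_applied & (mito_frac > max_mito_fraction)
  reason <- character(length(totals))
  reason[high_mito] <- "high_mito"
  reason[low] <- ifelse(reason[low] == "", "low_counts",
                        paste0(reason[low], ";low_counts"))
  kept <- !(low | high_mito)
  audit <- data.frame(barcode = x$barcodes,
                      total_counts = as.numeric(totals),
                      mito_fraction = as.numeric(mito_frac),
                      kept = kept, reason = reason,
                      stringsAsFactors = FALSE)
  attr(audit, "mito_filter_applied") <- mito_applied
  list(counts = subset_cells(x, kept), audit = audit)
}

#' Depth-normalize counts to a fixed per-cell total and log-transform
#'
#' Each cell is scaled to `scale_factor` total counts (counts-per-10k by
#' default) and natural-log transformed with a pseudocount of 1:
#' `value = ln(1 + scale_factor * count / total)`. This is the standard
#' single-cell log normalization; the conservation law
#' `sum(expm1(values)) == scale_factor` holds exactly for every cell with a
#' non-zero total and is checked by the tests.
#'
#' @param x a [cell_counts] object.
#' @param scale_factor target per-cell total, default 10000.
#' @return object of class `normalized_matrix`: list with `values`
#'   (dgCMatrix, cells x genes, log scale), `barcodes`, `gene_names`,
#'   `cell_meta`, `scale_factor`, `log_base = "natural"` and
#'   `totals` (the raw per-cell totals).
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "cell_counts"), scale_factor > 0)
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts; ",
            "their normalized rows are all zero", call. = FALSE)
  }
  denom <- ifelse(totals > 0, totals, 1)
  vals <- x$counts
  # operate on the sparse triplet: zeros map to log1p(0) = 0
  tri <- methods::as(vals, "TsparseMatrix")
  tri@x <- log1p(scale_factor * tri@x / denom[tri@i + 1L])
  vals <- methods::as(tri, "CsparseMatrix")
  structure(list(values = vals, barcodes = x$barcodes,
                 gene_names = x$gene_names, cell_meta = x$cell_meta,
                 scale_factor = scale_factor, log_base = "natural",
                 totals = as.numeric(totals)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", nrow(x$values), " cells x ", ncol(x$values),
      " genes; ln(1 + ", format(x$scale_factor), " * count/total)\n",
      sep = "")
  invisible(x)
}

#' Select highly variable genes (mean/dispersion binning)
#'
#' Mean-binned dispersion z-scoring in the style of the classical
#' mean.var.plot ("mvp") selection: per gene, the mean and the dispersion
#' (variance/mean) of the back-transformed normalized values (`expm1`,
#' i.e. the counts-per-10k scale) are computed; genes are binned into
#' `n_bins` equal-frequency bins by mean; the log dispersion is z-scored
#' within each bin; genes with mean inside `[mean_low, mean_high]` and
#' dispersion z-score at least `dispersion_z_min` are returned.
#'
#' @param nm a `normalized_matrix`.
#' @param n_bins number of equal-frequency mean bins (default 20).
#' @param mean_low,mean_high mean window on the back-transformed scale
#'   (defaults 0.1 and 8).
#' @param dispersion_z_min minimum within-bin dispersion z-score (default 1).
#' @return character vector of selected gene names (in input gene order),
#'   with the per-gene statistics attached as attribute `"stats"`.
#' @export
select_hvg <- function(nm, n_bins = 20L, mean_low = 0.1, mean_high = 8,
                       dispersion_z_min = 1) {
  stopifnot(inherits(nm, "normalized_matrix"), mean_low < mean_high,
            n_bins >= 1)
  expr <- nm$values
  n <- nrow(expr)
  # back-transform to the cpk scale without densifying the full matrix
  tri <- methods::as(expr, "TsparseMatrix")
  tri@x <- expm1(tri@x)
  bt <- methods::as(tri, "CsparseMatrix")
  mu <- Matrix::colMeans(bt)
  ex2 <- Matrix::colMeans(bt^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  usable <- which(mu > 0 & disp > 0)
  if (length(usable) < n_bins) {
    stop("fewer genes with nonzero mean (", length(usable),
         ") than bins (", n_bins, ")", call. = FALSE)
  }
  log_disp <- rep(NA_real_, length(mu))
  log_disp[usable] <- log(disp[usable])
  breaks <- unique(stats::quantile(mu[usable],
                                   probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE, type = 7))
  bin <- rep(NA_integer_, length(mu))
  bin[usable] <- findInterval(mu[usable], breaks, rightmost.closed = TRUE,
                              all.inside = TRUE)
  z <- rep(NA_real_, length(mu))
  dropped_bins <- 0L
  for (b in unique(bin[usable])) {
    idx <- which(bin == b)
    if (length(idx) < 2) {
      dropped_bins <- dropped_bins + 1L
      next
    }
    m <- mean(log_disp[idx]); s <- stats::sd(log_disp[idx])
    z[idx] <- if (s > 0) (log_disp[idx] - m) / s else 0
  }
  if (dropped_bins > 0) {
    warning(dropped_bins, " mean bin(s) with fewer than 2 genes; ",
            "their genes were excluded", call. = FALSE)
  }
  sel <- !is.na(z) & mu >= mean_low & mu <= mean_high & z >= dispersion_z_min
  stats_df <- data.frame(gene = nm$gene_names, mean = mu, dispersion = disp,
                         dispersion_z = z, selected = sel,
                         stringsAsFactors = FALSE)
  structure(nm$gene_names[sel], stats = stats_df)
}

#' Scale genes to unit variance without centering
#'
#' Divides each requested gene's normalized values by its sample standard
#' deviation (n - 1 denominator) without subtracting the mean, so that
#' zeros stay zero and signs are preserved. Genes with zero variance are
#' set to all-zero and flagged rather than producing infinities.
#'
#' @param nm a `normalized_matrix`.
#' @param genes character vector of gene names to scale; genes absent from
#'   the matrix are dropped with a warning.
#' @param center subtract the mean first (default FALSE, the convention for
#'   signature scoring).
#' @return dense numeric matrix (cells x genes) with attribute
#'   `"degenerate_genes"` naming zero-variance genes.
#' @export
scale_unit_variance <- function(nm, genes, center = FALSE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  genes <- as.character(genes)
  missing <- setdiff(genes, nm$gene_names)
  if (length(missing)) {
    warning("gene(s) not in matrix dropped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) {
    out <- matrix(0, nrow = nrow(nm$values), ncol = 0,
                  dimnames = list(nm$barcodes, NULL))
    attr(out, "degenerate_genes") <- character(0)
    return(out)
  }
  sub <- as.matrix(nm$values[, genes, drop = FALSE])
  if (center) sub <- sweep(sub, 2, colMeans(sub), "-")
  sds <- apply(sub, 2, stats::sd)
  degenerate <- genes[sds == 0 | is.na(sds)]
  sds[sds == 0 | is.na(sds)] <- Inf   # divide degenerate genes to zero
  out <- sweep(sub, 2, sds, "/")
  dimnames(out) <- list(nm$barcodes, genes)
  attr(out, "degenerate_genes") <- degenerate
  out
}
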