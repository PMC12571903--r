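#' Default tissue-repair gene signature
#'
#' The named members of the curated tissue-repair program used throughout
#' the analyses: *Areg* and *Batf* (tissue-repair Treg markers), *Klf10*
#' and *Tgfb1* (broad repair-associated genes), *Ikzf2* (Helios,
#' thymically derived Tregs), *Hif1a* and *Prdm1* (Blimp-1). Any user list
#' can be supplied instead via [gene_signature()].
#'
#' @return a `gene_signature` list with `name` and `genes`.
#' @export
default_repair_signature <- function() {
  gene_signature("tissue_repair",
                 c("Areg", "Batf", "Klf10", "Tgfb1", "Ikzf2", "Hif1a",
                   "Prdm1"))
}

#' Define a gene signature
#'
#' @param name signature label.
#' @param genes character vector of gene symbols, no duplicates.
#' @param allow_empty permit an empty gene list (scores will be 0).
#' @return a `gene_signature` list.
#' @export
gene_signature <- function(name, genes, allow_empty = FALSE) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate signature genes", call. = FALSE)
  if (!length(genes) && !allow_empty) {
    stop("empty signature (set allow_empty = TRUE if intended)",
         call. = FALSE)
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Per-cell repair score
#'
#' Sums, for every cell, the unit-variance-scaled (uncentered) normalized
#' expression of the signature genes, as produced by
#' [scale_unit_variance()]. Degenerate (zero-variance) genes contribute 0;
#' an empty signature yields a score of exactly 0 for every cell.
#'
#' @param scaled dense matrix from [scale_unit_variance()] restricted to
#'   the signature genes.
#' @return data.frame with `barcode`, `repair_score`,
#'   `n_signature_genes_present` (non-degenerate genes summed).
#' @export
repair_score <- function(scaled) {
  stopifnot(is.matrix(scaled))
  degenerate <- attr(scaled, "degenerate_genes") %||% character(0)
  n_present <- ncol(scaled) - length(degenerate)
  score <- if (ncol(scaled)) rowSums(scaled) else rep(0, nrow(scaled))
  data.frame(barcode = rownames(scaled) %||% as.character(seq_len(nrow(scaled))),
             repair_score = as.numeric(score),
             n_signature_genes_present = n_present,
             stringsAsFactors = FALSE)
}

#' Signature coexpression heat-map matrices per cell type
#'
#' For each cell group (by default the T-cell subset), computes the
#' pairwise Pearson correlation of single-cell normalized expression over
#' the signature genes plus the marker gene (*Tigit*), and orders the
#' genes by average-linkage hierarchical clustering on distance 1 - r.
#' Genes are sorted lexicographically before clustering so that tie-breaks
#' are deterministic. Constant genes get r = 0 against all others and are
#' flagged.
#'
#' @param nm a `normalized_matrix`.
#' @param signature a `gene_signature`.
#' @param marker_gene gene to include alongside the signature
#'   (default "Tigit").
#' @param group_by cell_meta column(s) defining the groups
#'   (default "subset").
#' @param min_cells groups with fewer cells are skipped with a warning
#'   (default 3).
#' @return named list of `correlation_heatmap` objects, each a list with
#'   `gene_labels`, `r_matrix`, `leaf_order`, `cell_subset`, `condition`,
#'   `n_cells`, `constant_genes`.
#' @export
signature_correlation <- function(nm, signature = default_repair_signature(),
                                  marker_gene = "Tigit",
                                  group_by = "subset", min_cells = 3L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  genes <- unique(c(signature$genes, marker_gene))
  genes <- intersect(genes, nm$gene_names)
  if (length(genes) < 2) stop("need at least 2 genes present", call. = FALSE)
  genes <- sort(genes)   # lexicographic: deterministic dendrogram ties
  meta <- nm$cell_meta
  if (!all(group_by %in% names(meta))) {
    stop("group_by column(s) missing from cell_meta", call. = FALSE)
  }
  key <- interaction(meta[group_by], drop = TRUE, sep = ".")
  out <- list()
  for (g in levels(key)) {
    cells <- which(key == g)
    if (length(cells) < min_cells) {
      warning("group '", g, "' has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    X <- as.matrix(nm$values[cells, genes, drop = FALSE])
    sds <- apply(X, 2, stats::sd)
    constant <- genes[sds == 0]
    R <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
    ok <- sds > 0
    if (sum(ok) >= 2) R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
    diag(R) <- 1
    hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
    sub_val <- if ("subset" %in% group_by)
      unique(meta$subset[cells]) else "all"
    cond_val <- if ("condition" %in% names(meta) &&
                    length(unique(meta$condition[cells])) == 1)
      unique(meta$condition[cells]) else "all"
    out[[g]] <- structure(
      list(gene_labels = genes, r_matrix = R,
           leaf_order = genes[hc$order],
           cell_subset = sub_val, condition = cond_val,
           n_cells = length(cells), constant_genes = constant),
      class = "correlation_heatmap")
  }
  out
}

#' Split cells into pseudo-replicate pools and average expression
#'
#' Randomly splits each stratum (genotype x condition by default) into
#' `n_pools` near-equal "technical replicate" cell pools, then computes per
#' pool and gene `log10(mean counts-per-10k + 1)` (averaging on the cpk
#' scale, then logging; the pseudocount keeps all-zero pools at 0).
#' Optionally also averages a per-cell score (e.g. the repair score) per
#' pool.
#'
#' @param x a [cell_counts] object (raw counts; cpk is recomputed here).
#' @param n_pools number of pools per stratum (default 10).
#' @param group_by cell_meta columns defining strata
#'   (default genotype and condition).
#' @param genes genes to report (default: all genes).
#' @param cell_scores optional named numeric vector (names = barcodes) of
#'   per-cell scores to average per pool into a `repair_score` column.
#' @param seed RNG seed for the random split.
#' @return data.frame with `pool_id`, the stratum columns,
#'   `n_cells_in_pool`, one column per gene, and `repair_score` when
#'   `cell_scores` is given. Pool sizes within a stratum differ by at most
#'   one cell.
#' @export
pseudo_replicate_pools <- function(x, n_pools = 10L,
                                   group_by = c("genotype", "condition"),
                                   genes = NULL, cell_scores = NULL,
                                   seed = 1L) {
  stopifnot(inherits(x, "cell_counts"), n_pools >= 1)
  meta <- x$cell_meta
  group_by <- intersect(group_by, names(meta))
  key <- if (length(group_by)) {
    interaction(meta[group_by], drop = TRUE, sep = ".")
  } else factor(rep("all", nrow(meta)))
  genes <- genes %||% x$gene_names
  missing <- setdiff(genes, x$gene_names)
  if (length(missing)) stop("unknown gene(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  totals <- Matrix::rowSums(x$counts)
  denom <- ifelse(totals > 0, totals, 1)
  cpk <- x$counts[, genes, drop = FALSE] * (1e4 / denom)
  rows <- list()
  with_seed(seed, {
    for (g in levels(key)) {
      cells <- which(key == g)
      if (length(cells) < n_pools) {
        stop("group '", g, "' has ", length(cells),
             " cells, fewer than n_pools = ", n_pools, call. = FALSE)
      }
      shuffled <- sample(cells)
      assignment <- rep_len(seq_len(n_pools), length(cells))
      for (p in seq_len(n_pools)) {
        pool_cells <- shuffled[assignment == p]
        vals <- Matrix::colMeans(cpk[pool_cells, , drop = FALSE])
        row <- data.frame(pool_id = p, stringsAsFactors = FALSE)
        for (col in group_by) row[[col]] <- unique(meta[[col]][cells])
        row$n_cells_in_pool <- length(pool_cells)
        for (gn in genes) row[[gn]] <- log10(vals[[gn]] + 1)
        if (!is.null(cell_scores)) {
          row$repair_score <-
            mean(cell_scores[x$barcodes[pool_cells]])
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  })
  do.call(rbind, rows)
}

#' Pearson correlation across pseudo-replicate pools
#'
#' Correlates two pooled variables across pools and reports the two-sided
#' p value from the t transform `t = r * sqrt((n-2)/(1-r^2))` with n-2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param pooled data.frame from [pseudo_replicate_pools()].
#' @param x_var,y_var column names to correlate.
#' @param split_by optional column(s) to compute the correlation within
#'   (e.g. subset or genotype).
#' @return data.frame with one row per split: `r`, `p_two_sided`, `n`,
#'   `degenerate` (TRUE when either variable has zero variance, in which
#'   case r is NA).
#' @export
pool_correlation <- function(pooled, x_var, y_var, split_by = NULL) {
  stopifnot(all(c(x_var, y_var) %in% names(pooled)))
  key <- if (is.null(split_by)) factor(rep("all", nrow(pooled)))
         else interaction(pooled[split_by], drop = TRUE, sep = ".")
  res <- lapply(levels(key), function(g) {
    idx <- which(key == g)
    xs <- pooled[[x_var]][idx]; ys <- pooled[[y_var]][idx]
    if (length(idx) < 3) {
      stop("split '", g, "' has fewer than 3 pooled points", call. = FALSE)
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(data.frame(split = g, r = NA_real_, p_two_sided = NA_real_,
                        n = length(idx), degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(xs, ys, method = "pearson",
                          alternative = "two.sided")
    data.frame(split = g, r = unname(ct$estimate),
               p_two_sided = ct$p.value, n = length(idx),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
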