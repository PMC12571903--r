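# Fixtures and independent oracles shared across the test files.

# Small random count matrix with full annotations.
toy_counts <- function(n_cells = 12, n_genes = 8, seed = 1,
                       gene_names = NULL) {
  set.seed(seed)
  genes <- gene_names %||% paste0("G", seq_len(n_genes))
  m <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
  meta <- data.frame(
    barcode = paste0("BC", seq_len(n_cells)),
    sample_id = "S1",
    genotype = rep(c("WT", "KO"), length.out = n_cells),
    condition = rep(c("naive", "infected"), each = ceiling(n_cells / 2),
                    length.out = n_cells),
    organ = "spleen",
    subset = rep(c("Treg", "CD8"), length.out = n_cells),
    stringsAsFactors = FALSE)
  cell_counts(m, barcodes = meta$barcode, gene_names = genes,
              cell_meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contig table builder: one row per (barcode, chain, aa, nt).
toy_contigs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(barcode = r[[1]], chain = r[[2]], cdr3_aa = r[[3]],
               cdr3_nt = r[[4]] %||% paste0(r[[3]], "NT"),
               v_gene = "TRV1", j_gene = "TRJ1", umis = 1L,
               raw_clonotype_id = NA_character_, stringsAsFactors = FALSE)
  }))
}

# Independent naive recount of expansion statistics from a cells table:
# dictionary-of-sets approach, no shared code with classify_expansion.
naive_expansion_recount <- function(cells_df) {
  groups <- split(cells_df$barcode, cells_df$clonotype_id)
  sizes <- vapply(groups, function(b) length(unique(b)), integer(1))
  list(n_cells = length(unique(cells_df$barcode)),
       n_clones = length(sizes),
       n_expanded = sum(sizes >= 2),
       expanded_cell_fraction =
         sum(sizes[sizes >= 2]) / length(unique(cells_df$barcode)))
}

# Hand-rolled Holm step-down, independent of stats::p.adjust.
naive_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}
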