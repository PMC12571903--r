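test_that("repair score is the row sum of the scaled signature matrix", {
  m <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  attr(m, "degenerate_genes") <- character(0)
  expect_equal(repair_score(m)$repair_score, c(3, 7))
  single <- m[, 1, drop = FALSE]
  attr(single, "degenerate_genes") <- character(0)
  expect_equal(repair_score(single)$repair_score, m[, 1],
               ignore_attr = TRUE)
  empty <- matrix(0, 2, 0, dimnames = list(c("c1", "c2"), NULL))
  attr(empty, "degenerate_genes") <- character(0)
  expect_equal(repair_score(empty)$repair_score, c(0, 0))
})

test_that("repair score is additive over disjoint signature blocks", {
  x <- toy_counts(n_cells = 40, n_genes = 10, seed = 21)
  nm <- normalize_counts(x)
  g1 <- x$gene_names[1:4]; g2 <- x$gene_names[5:8]
  s_union <- repair_score(scale_unit_variance(nm, c(g1, g2)))
  s1 <- repair_score(scale_unit_variance(nm, g1))
  s2 <- repair_score(scale_unit_variance(nm, g2))
  expect_equal(s_union$repair_score, s1$repair_score + s2$repair_score)
})

test_that("scores match an independent naive per-cell loop", {
  for (seed in 1:20) {
    x <- toy_counts(n_cells = 10 + seed, n_genes = 6, seed = seed)
    nm <- normalize_counts(x)
    sc <- scale_unit_variance(nm, x$gene_names[1:4])
    got <- repair_score(sc)$repair_score
    want <- vapply(seq_len(nrow(sc)), function(i) {
      s <- 0
      for (j in seq_len(ncol(sc))) s <- s + sc[i, j]
      s
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("correlation heatmaps are symmetric with deterministic leaf order", {
  x <- simulate_expression(n_cells_per_stratum = 120, genotypes = "WT",
                           conditions = "infected", organs = "spleen",
                           subsets = c("Treg", "CD8"),
                           latent_coupling = 0.5, seed = 31)
  nm <- normalize_counts(x)
  heat <- signature_correlation(nm)
  expect_named(heat, c("CD8", "Treg"), ignore.order = TRUE)
  for (h in heat) {
    expect_equal(h$r_matrix, t(h$r_matrix))
    expect_equal(unname(diag(h$r_matrix)), rep(1, nrow(h$r_matrix)))
    expect_setequal(h$leaf_order, h$gene_labels)
  }
  heat2 <- signature_correlation(nm)
  expect_identical(heat$Treg$leaf_order, heat2$Treg$leaf_order)
})

test_that("a duplicated gene correlates at 1 and sits adjacent in the dendrogram", {
  x <- toy_counts(n_cells = 60, n_genes = 6, seed = 41)
  counts <- cbind(as.matrix(x$counts), Dup = as.matrix(x$counts)[, 1])
  meta <- x$cell_meta; meta$subset <- "Treg"
  y <- cell_counts(counts, barcodes = x$barcodes,
                   gene_names = c(x$gene_names, "Dup"), cell_meta = meta)
  nm <- normalize_counts(y)
  sig <- gene_signature("dup_test", c(x$gene_names[1], "Dup",
                                      x$gene_names[2:4]))
  heat <- signature_correlation(nm, sig, marker_gene = x$gene_names[5])
  h <- heat$Treg
  expect_equal(h$r_matrix[x$gene_names[1], "Dup"], 1)
  pos <- match(c(x$gene_names[1], "Dup"), h$leaf_order)
  expect_equal(abs(diff(pos)), 1)
})

test_that("independent genes show near-zero off-diagonal correlations", {
  set.seed(51)
  n <- 5000
  # 200 background genes so per-cell depth normalization does not induce
  # compositional correlation among the 8 genes under test
  m <- matrix(rpois(n * 208, 6), n, 208)
  meta <- data.frame(barcode = paste0("c", 1:n), subset = "CD8",
                     stringsAsFactors = FALSE)
  x <- cell_counts(m, barcodes = meta$barcode,
                   gene_names = paste0("G", 1:208), cell_meta = meta)
  heat <- signature_correlation(normalize_counts(x),
                                gene_signature("null", paste0("G", 1:7)),
                                marker_gene = "G8")
  R <- heat$CD8$r_matrix
  expect_lt(max(abs(R[upper.tri(R)])), 0.07)
})

test_that("groups with fewer than 3 cells are skipped with a warning", {
  x <- toy_counts(n_cells = 8, n_genes = 5, seed = 6)
  x$cell_meta$subset <- c(rep("Treg", 6), "CD8", "CD8")
  nm <- normalize_counts(x)
  nm$cell_meta <- x$cell_meta
  expect_warning(heat <- signature_correlation(
    nm, gene_signature("s", x$gene_names[1:3]),
    marker_gene = x$gene_names[4]), "CD8")
  expect_named(heat, "Treg")
})

test_that("pseudo-replicate pools partition each stratum near-equally", {
  x <- toy_counts(n_cells = 43, n_genes = 5, seed = 61)
  x$cell_meta$genotype <- "WT"; x$cell_meta$condition <- "infected"
  pooled <- pseudo_replicate_pools(x, n_pools = 10, seed = 3)
  expect_equal(nrow(pooled), 10)
  expect_equal(sum(pooled$n_cells_in_pool), 43)
  expect_lte(diff(range(pooled$n_cells_in_pool)), 1)
})

test_that("pooled values match a brute-force recomputation of log10(mean cpk + 1)", {
  x <- toy_counts(n_cells = 4, n_genes = 3, seed = 71)
  x$cell_meta$genotype <- "WT"; x$cell_meta$condition <- "naive"
  pooled <- pseudo_replicate_pools(x, n_pools = 2, seed = 9)
  expect_equal(sort(pooled$n_cells_in_pool), c(2, 2))
  # brute force: recompute cpk and pool means from the raw counts, using
  # the same seeded shuffle
  counts <- as.matrix(x$counts)
  cpk <- sweep(counts, 1, rowSums(counts), "/") * 1e4
  assign_pools <- tcellrepair:::with_seed(9, {
    shuffled <- sample(1:4)
    split(shuffled, rep_len(1:2, 4))
  })
  for (p in 1:2) {
    want <- log10(colMeans(cpk[assign_pools[[p]], , drop = FALSE]) + 1)
    got <- unlist(pooled[pooled$pool_id == p, x$gene_names])
    expect_equal(unname(got), unname(want))
  }
})

test_that("a single pool reproduces the whole-group mean", {
  x <- toy_counts(n_cells = 6, n_genes = 4, seed = 81)
  x$cell_meta$genotype <- "WT"; x$cell_meta$condition <- "naive"
  pooled <- pseudo_replicate_pools(x, n_pools = 1, seed = 1)
  counts <- as.matrix(x$counts)
  cpk <- sweep(counts, 1, rowSums(counts), "/") * 1e4
  expect_equal(unname(unlist(pooled[1, x$gene_names])),
               unname(log10(colMeans(cpk) + 1)))
})

test_that("groups smaller than the pool count raise an error naming the group", {
  x <- toy_counts(n_cells = 6, n_genes = 4, seed = 91)
  expect_error(pseudo_replicate_pools(x, n_pools = 10),
               "fewer than n_pools")
})

test_that("pool correlation matches the closed-form Pearson t transform", {
  pooled <- data.frame(pool_id = 1:3, x = c(1, 2, 3), y = c(1, 2, 4))
  res <- pool_correlation(pooled, "x", "y")
  expect_equal(res$r, 0.981980506, tolerance = 1e-8)
  r <- res$r; n <- 3
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p_two_sided, 2 * pt(-abs(t_stat), df = n - 2))
  perfect <- pool_correlation(data.frame(pool_id = 1:4,
                                         x = 1:4, y = 1:4), "x", "y")
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_two_sided, 1e-10)
})

test_that("zero-variance pooled variables are flagged degenerate", {
  pooled <- data.frame(pool_id = 1:4, x = rep(2, 4), y = 1:4)
  res <- pool_correlation(pooled, "x", "y")
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
})

test_that("null pool correlations give roughly uniform p values", {
  set.seed(101)
  ps <- replicate(300, {
    pool_correlation(data.frame(pool_id = 1:10, x = rnorm(10),
                                y = rnorm(10)), "x", "y")$p_two_sided
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("pooled marker-vs-score correlation exceeds the single-cell one", {
  x <- simulate_expression(n_cells_per_stratum = 1500, genotypes = "WT",
                           conditions = c("naive", "infected"),
                           organs = "spleen", subsets = "Treg",
                           latent_coupling = 0.6, seed = 91)
  nm <- normalize_counts(x)
  sig <- default_repair_signature()
  scores <- repair_score(scale_unit_variance(nm, sig$genes))
  mk <- as.numeric(nm$values[, "Tigit"])
  r_single <- cor(mk, scores$repair_score)
  pooled <- pseudo_replicate_pools(
    x, n_pools = 10, group_by = "condition", genes = "Tigit",
    cell_scores = setNames(scores$repair_score, scores$barcode),
    seed = 92)
  r_pooled <- pool_correlation(pooled, "Tigit", "repair_score")$r
  expect_gt(r_pooled, r_single)
})
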