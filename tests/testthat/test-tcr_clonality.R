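test_that("cells sharing all chain nucleotide CDR3s form one clonotype", {
  contigs <- toy_contigs(
    list("b1", "TRA", "CAVR", "nt-a1"), list("b1", "TRB", "CASSL", "nt-b1"),
    list("b2", "TRA", "CAVR", "nt-a1"), list("b2", "TRB", "CASSL", "nt-b1"),
    list("b3", "TRA", "CAVX", "nt-a2"), list("b3", "TRB", "CASSL", "nt-b1"))
  ct <- assemble_clonotypes(contigs, key_mode = "all_chain_nt")
  expect_equal(nrow(ct$clonotypes), 2)
  sizes <- sort(ct$clonotypes$clone_size)
  expect_equal(sizes, c(1L, 2L))
  # same TRB aa but different TRA: merged under cdr3b_aa keying
  ct2 <- assemble_clonotypes(contigs, key_mode = "cdr3b_aa")
  expect_equal(nrow(ct2$clonotypes), 1)
  expect_equal(ct2$clonotypes$clone_size, 3L)
})

test_that("cells without usable chains are dropped to the audit", {
  contigs <- toy_contigs(list("b1", "TRB", "CASSL", "nt1"),
                         list("b2", "other", "CARDY", "nt2"))
  ct <- assemble_clonotypes(contigs)
  expect_equal(ct$audit$barcode, "b2")
  expect_equal(nrow(ct$cells), 1)
  # cdr3b mode additionally drops TRA-only cells
  contigs2 <- toy_contigs(list("b1", "TRB", "CASSL", "nt1"),
                          list("b3", "TRA", "CAVR", "nt3"))
  ct2 <- assemble_clonotypes(contigs2, key_mode = "cdr3b_aa")
  expect_true("b3" %in% ct2$audit$barcode)
})

test_that("blacklisted transgenic receptors are excluded clone-wide", {
  contigs <- toy_contigs(
    list("b1", "TRA", "CAVR", "nt-a"), list("b1", "TRB", "CASSP14F", "nt-b"),
    list("b2", "TRA", "CAVR", "nt-a"), list("b2", "TRB", "CASSP14F", "nt-b"),
    list("b3", "TRA", "CAVT", "nt-c"), list("b3", "TRB", "CASSX", "nt-d"))
  ct <- assemble_clonotypes(contigs)
  out <- exclude_blacklisted(ct, "CASSP14F")
  expect_equal(nrow(out$cells), 1)
  expect_equal(out$cells$barcode, "b3")
  expect_true(all(c("b1", "b2") %in%
                    out$audit$barcode[out$audit$reason == "blacklisted"]))
  expect_identical(exclude_blacklisted(ct, character(0))$cells, ct$cells)
})

test_that("simulated spike-ins are removed exactly by the blacklist", {
  sim <- simulate_repertoire(n_cells = 300, seed = 7,
                             chain_anomaly_rate = 0)
  k <- sum(sim$truth$spike_label != "")
  expect_gt(k, 0)
  ct <- assemble_clonotypes(sim$contigs)
  out <- exclude_blacklisted(ct, sim$blacklist)
  expect_equal(nrow(ct$cells) - nrow(out$cells), k)
})

test_that("single-pair filter keeps exactly one-TRA/one-TRB clonotypes", {
  contigs <- toy_contigs(
    list("b1", "TRA", "CAVR", "a1"), list("b1", "TRB", "CASS1", "b1n"),
    list("b2", "TRB", "CASS2", "b2n"), list("b2", "TRB", "CASS3", "b3n"),
    list("b2", "TRA", "CAVX", "a2"),
    list("b3", "TRA", "CAVY", "a3"))
  ct <- assemble_clonotypes(contigs)
  out <- filter_single_pair(ct)
  expect_equal(out$cells$barcode, "b1")
  reasons <- out$audit$reason[out$audit$barcode %in% c("b2", "b3")]
  expect_true(all(reasons == "not_single_pair"))
})

test_that("simulated chain anomalies are removed exactly by the single-pair filter", {
  sim <- simulate_repertoire(n_cells = 500, chain_anomaly_rate = 0.1,
                             transgenic_spike = NULL, seed = 11)
  n_anom <- sum(sim$truth$anomaly != "")
  ct <- assemble_clonotypes(sim$contigs)
  out <- filter_single_pair(ct)
  expect_equal(nrow(ct$cells) - nrow(out$cells), n_anom)
  zero <- simulate_repertoire(n_cells = 200, chain_anomaly_rate = 0,
                              transgenic_spike = NULL, seed = 12)
  ct0 <- assemble_clonotypes(zero$contigs)
  expect_equal(nrow(filter_single_pair(ct0)$cells), nrow(ct0$cells))
})

test_that("expansion summary counts clones of size >= 2", {
  contigs <- toy_contigs(
    list("b1", "TRB", "CASSA", "n1"), list("b2", "TRB", "CASSA", "n1"),
    list("b3", "TRB", "CASSA", "n1"), list("b4", "TRB", "CASSB", "n2"),
    list("b5", "TRB", "CASSC", "n3"))
  ct <- assemble_clonotypes(contigs)
  ex <- classify_expansion(ct)
  expect_equal(ex$summary$n_clones, 3)
  expect_equal(ex$summary$n_expanded_clones, 1)
  expect_equal(ex$summary$expanded_cell_fraction, 0.6)
  expect_equal(ex$top_clones$clone_size[1], 3)
})

test_that("top-expanded ranking is size-descending with lexicographic ties", {
  contigs <- toy_contigs(
    list("b1", "TRB", "CASSZ", "zz"), list("b2", "TRB", "CASSZ", "zz"),
    list("b3", "TRB", "CASSA", "aa"), list("b4", "TRB", "CASSA", "aa"),
    list("b5", "TRB", "CASSM", "mm"), list("b6", "TRB", "CASSM", "mm"),
    list("b7", "TRB", "CASSM", "mm"))
  ct <- assemble_clonotypes(contigs)
  top <- classify_expansion(ct, top_n = 2)$top_clones
  expect_equal(nrow(top), 2)
  expect_equal(top$clone_size, c(3L, 2L))
  # the two size-2 clones tie; the lexicographically smaller key wins
  expect_equal(top$key[2], "TRB:aa")
})

test_that("geometric p = 1 gives all singletons and zero expansion", {
  sim <- simulate_repertoire(n_cells = 150, clone_geom_p = 1,
                             shared_clone_rate = 0,
                             transgenic_spike = NULL, seed = 21)
  expect_true(all(sim$truth$clone_size == 1))
  ct <- assemble_clonotypes(sim$contigs)
  ex <- classify_expansion(ct)
  expect_equal(ex$summary$n_expanded_clones, 0)
  expect_equal(ex$summary$expanded_cell_fraction, 0)
})

test_that("expansion summaries match the naive recount on random repertoires", {
  for (seed in 1:50) {
    sim <- simulate_repertoire(n_cells = sample(20:60, 1),
                               clone_geom_p = runif(1, 0.3, 1),
                               shared_clone_rate = 0,
                               transgenic_spike = NULL, seed = seed)
    ct <- assemble_clonotypes(sim$contigs)
    ex <- classify_expansion(ct)
    want <- naive_expansion_recount(ct$cells)
    expect_equal(ex$summary$n_cells, want$n_cells)
    expect_equal(ex$summary$n_clones, want$n_clones)
    expect_equal(ex$summary$n_expanded_clones, want$n_expanded)
    expect_equal(ex$summary$expanded_cell_fraction,
                 want$expanded_cell_fraction)
  }
})

test_that("marker splits flag cells by raw count threshold", {
  sim <- simulate_repertoire(n_cells = 200, seed = 31)
  ct <- assemble_clonotypes(sim$contigs)
  marks <- split_by_marker(ct, sim$marker_counts)
  truth <- sim$truth[match(marks$barcode, sim$truth$barcode), ]
  expect_equal(marks$Tigit_pos, truth$tigit_pos)
  expect_equal(marks$Areg_pos, truth$areg_pos)
  expect_error(split_by_marker(ct, sim$marker_counts,
                               markers = "Foxp3"), "Foxp3")
  # zero counts are negative, count 1 is positive
  m <- cell_counts(matrix(c(0L, 1L), 2, 1),
                   barcodes = marks$barcode[1:2], gene_names = "Tigit")
  flags <- split_by_marker(
    assemble_clonotypes(sim$contigs[sim$contigs$barcode %in%
                                      marks$barcode[1:2], ]),
    m, markers = "Tigit")
  expect_equal(flags$Tigit_pos[match(marks$barcode[1:2], flags$barcode)],
               c(FALSE, TRUE))
})

test_that("expansion within marker strata matches a per-stratum recount", {
  sim <- simulate_repertoire(n_cells = 400, seed = 41)
  ct <- exclude_blacklisted(assemble_clonotypes(sim$contigs),
                            sim$blacklist)
  marks <- split_by_marker(ct, sim$marker_counts)
  ex <- classify_expansion(ct, cell_meta = marks)
  key <- interaction(marks[c("Tigit_pos", "Areg_pos")], drop = TRUE,
                     sep = ".")
  for (g in levels(key)) {
    cells_g <- ct$cells[ct$cells$barcode %in%
                          marks$barcode[key == g], ]
    want <- naive_expansion_recount(cells_g)
    row <- ex$summary[ex$summary$stratum == g, ]
    expect_equal(row$n_cells, want$n_cells)
    expect_equal(row$expanded_cell_fraction,
                 want$expanded_cell_fraction)
  }
})

test_that("Jaccard overlap matches direct set arithmetic", {
  expect_equal(jaccard_overlap(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_overlap(c("a"), c("b")), 0)
  empty <- jaccard_overlap(character(0), character(0))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "degenerate"))
})

test_that("adding shared clones monotonically increases overlap", {
  A <- paste0("K", 1:10)
  B <- paste0("L", 1:10)
  j <- vapply(0:5, function(k) {
    jaccard_overlap(A, c(B, A[seq_len(k)]))
  }, numeric(1))
  expect_true(all(diff(j) > 0))
})

test_that("overlap matrices are symmetric with unit diagonal", {
  sims <- lapply(1:3, function(i) {
    simulate_repertoire(n_cells = 150, shared_clone_rate = 0.2,
                        transgenic_spike = NULL, sample_id = paste0("S", i),
                        seed = 100 + i)
  })
  reps <- lapply(sims, function(s) assemble_clonotypes(s$contigs))
  names(reps) <- paste0("S", 1:3)
  M <- overlap_matrix(reps, require_single_pair = FALSE)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))
  # identical repertoires overlap completely
  M2 <- overlap_matrix(list(a = reps[[1]], b = reps[[1]]),
                       require_single_pair = FALSE)
  expect_true(all(M2 == 1))
})

test_that("samples without shared clones have zero overlap", {
  sims <- lapply(1:2, function(i) {
    simulate_repertoire(n_cells = 200, shared_clone_rate = 0,
                        transgenic_spike = NULL, sample_id = paste0("S", i),
                        seed = 200 + i)
  })
  reps <- lapply(sims, function(s) assemble_clonotypes(s$contigs))
  names(reps) <- c("S1", "S2")
  M <- overlap_matrix(reps, require_single_pair = FALSE)
  expect_equal(M["S1", "S2"], 0)
})

test_that("clone sizes always sum to the cell count after each filter", {
  sim <- simulate_repertoire(n_cells = 300, chain_anomaly_rate = 0.1,
                             seed = 51)
  ct <- assemble_clonotypes(sim$contigs)
  for (step in list(ct, exclude_blacklisted(ct, sim$blacklist),
                    filter_single_pair(ct))) {
    expect_equal(sum(step$clonotypes$clone_size), nrow(step$cells))
  }
})
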