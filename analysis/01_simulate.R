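#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study data.
#
# Emulates the experimental design of the tissue-repair study: WT and
# Tigit-KO mice, naive and LCMV-infected, spleen and lung, with
# Treg/CD4conv/CD8 subsets. Writes the count matrix as a 10x-style MTX
# triplet, per-sample TCR contig CSVs with their truth tables, and the
# regulon activity matrix, all under results/.

suppressPackageStartupMessages(library(tcellrepair))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"

cfg <- default_pipeline_config()

message("Simulating expression (", cfg$simulate$expression$n_cells_per_stratum,
        " cells per stratum, latent coupling rho = ",
        cfg$simulate$expression$latent_coupling, ") ...")
counts <- do.call(simulate_expression,
                  c(cfg$simulate$expression, list(seed = seed)))
write_10x_counts(counts, file.path(out, "counts"))
truth <- attr(counts, "truth")
message("  ", nrow(counts$counts), " cells x ", ncol(counts$counts),
        " genes; calibrated lambda = ", round(truth$lambda, 3),
        "; ", length(truth$high_mito_barcodes), " planted high-mito cells")

message("Simulating regulon activities (", cfg$simulate$regulons$n_regulons,
        " regulons, ", cfg$simulate$regulons$n_shifted_regulons,
        " shifted by ", cfg$simulate$regulons$shift, ") ...")
ra <- do.call(simulate_regulon_activity,
              c(cfg$simulate$regulons, list(seed = seed + 1L)))
act <- data.frame(barcode = ra$cell_meta$barcode, ra$activity,
                  check.names = FALSE)
write.csv(act, file.path(out, "regulon_activity.csv"), row.names = FALSE)
write.table(ra$cell_meta, file.path(out, "regulon_cell_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(attr(ra, "truth")$shifted_regulons,
           file.path(out, "regulon_truth_shifted.txt"))

message("Simulating TCR repertoires ...")
samples <- paste(rep(c("WT", "KO"), each = 2), rep(c("spleen", "lung"), 2),
                 sep = "_")
for (i in seq_along(samples)) {
  sim <- simulate_repertoire(
    n_cells = cfg$simulate$repertoire$n_cells_per_sample,
    clone_geom_p = cfg$simulate$repertoire$clone_geom_p,
    shared_clone_rate = cfg$simulate$repertoire$shared_clone_rate,
    chain_anomaly_rate = cfg$simulate$repertoire$chain_anomaly_rate,
    sample_id = samples[i], seed = seed + 10L + i)
  write_contigs(sim$contigs,
                file.path(out, paste0("contigs_", samples[i], ".csv")))
  write.table(sim$truth,
              file.path(out, paste0("tcr_truth_", samples[i], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_10x_counts(sim$marker_counts,
                   file.path(out, paste0("markers_", samples[i])))
  if (i == 1) {
    write.table(sim$blacklist, file.path(out, "tcr_blacklist.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("  ", samples[i], ": ", nrow(sim$truth), " cells, ",
          length(unique(sim$truth$clone_id)), " clones, ",
          sum(sim$truth$spike_label != ""), " transgenic spike-in cells")
}
message("Done; inputs for stages 2-4 are under ", out, "/")
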