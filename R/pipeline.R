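#' Default pipeline configuration
#'
#' The configuration mirrors the study design the simulators emulate: two
#' genotypes (WT, Tigit-KO) x two conditions (naive, infected) x two
#' organs (spleen, lung) with Treg/CD4conv/CD8 subsets; 7 percent
#' mitochondrial QC cutoff; counts-per-10k log normalization; ten
#' pseudo-replicate pools; randomized 5,000-cell subsets, a 70 percent
#' zero-fraction regulon filter and 10,000 permutations with
#' Holm-Bonferroni correction; geometric clone sizes with transgenic
#' spike-ins and exact-CDR3b Jaccard overlap.
#'
#' @return nested named list; see the YAML written by [run_pipeline()]'s
#'   manifest for the flattened form.
#' @export
default_pipeline_config <- function() {
  list(
    stages = list(simulate = TRUE, preprocess = TRUE, score = TRUE,
                  regulon_test = TRUE, tcr = TRUE),
    simulate = list(
      expression = list(n_cells_per_stratum = 840L, n_genes = 300L,
                        latent_coupling = 0.6, ko_marker_silenced = TRUE,
                        nb_dispersion = 0.4, mito_gene_fraction = 0.05,
                        high_mito_cell_fraction = 0.05),
      regulons = list(n_regulons = 100L, n_shifted_regulons = 10L,
                      shift = 0.2, zero_inflation = 0.3,
                      n_cells_per_group = 1250L),
      repertoire = list(n_cells_per_sample = 1000L, clone_geom_p = 0.5,
                        shared_clone_rate = 0.1,
                        chain_anomaly_rate = 0.05)),
    preprocess = list(max_mito_fraction = 0.07, min_counts_per_cell = 1L,
                      mito_prefix = "mt-",
                      hvg = list(n_bins = 20L, mean_low = 0.1,
                                 mean_high = 8, dispersion_z_min = 1)),
    score = list(marker_gene = "Tigit", n_pools = 10L),
    regulon_test = list(n_permutations = 10000L,
                        exhaustive_threshold = 10000L, alpha = 0.05,
                        zero_fraction_cutoff = 0.70, subsample_n = 5000L),
    tcr = list(key_mode = "all_chain_nt", top_n_expanded = 50L,
               min_marker_count = 1L, require_single_pair_overlap = TRUE))
}

# Recursively check that every key in `config` exists in `template`.
validate_config <- function(config, template = default_pipeline_config(),
                            path = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(config[[k]])) {
        stop("configuration key ", path, k, " must be a section",
             call. = FALSE)
      }
      validate_config(config[[k]], template[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

# Deep-merge user config over the defaults (after validation).
merge_config <- function(user, template = default_pipeline_config()) {
  validate_config(user, template)
  for (k in names(user)) {
    template[[k]] <- if (is.list(template[[k]]) &&
                         !is.null(names(template[[k]]))) {
      merge_config(user[[k]], template[[k]])
    } else user[[k]]
  }
  template
}

#' Read and validate a pipeline configuration YAML file
#'
#' Unknown keys are rejected by name; omitted keys fall back to
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(user %||% list())
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in fixed order — simulate, preprocess,
#' score, regulon-test, tcr — and writes every result as a plain TSV
#' under `out_dir`, plus a machine-readable `manifest.json` recording the
#' seed, full configuration, stage order and package version. The run is
#' a pure function of (config, seed): rerunning with the same inputs
#' produces byte-identical result tables.
#'
#' @param config configuration list (see [default_pipeline_config()]);
#'   partial lists are merged over the defaults.
#' @param out_dir output directory, created if needed.
#' @param seed master seed; every stage derives its own stream from it.
#' @param config_file optional YAML file, merged over the defaults
#'   (ignored when `config` is given explicitly alongside; the file wins
#'   for keys it sets).
#' @return (invisibly) a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L,
                         config_file = NULL) {
  if (!is.null(config_file)) {
    config <- merge_config(yaml::read_yaml(config_file) %||% list(),
                           merge_config(config))
  } else {
    config <- merge_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  counts <- NULL
  if (isTRUE(config$stages$simulate)) {
    counts <- stage("simulate", do.call(simulate_expression, c(
      config$simulate$expression, list(seed = derive_seed(seed, 1L)))))
    write_10x_counts(counts, file.path(out_dir, "counts"))
    results$counts <- counts
  }

  nm <- NULL
  if (isTRUE(config$stages$preprocess)) {
    if (is.null(counts)) stop("pipeline stage 'preprocess' failed: no ",
                              "count matrix (enable simulate or supply ",
                              "one)", call. = FALSE)
    pp <- config$preprocess
    qc <- stage("preprocess",
                filter_cells(counts, pp$max_mito_fraction,
                             pp$min_counts_per_cell, pp$mito_prefix))
    write_result_tsv(qc$audit, file.path(out_dir, "qc_audit.tsv"))
    nm <- stage("preprocess", normalize_counts(qc$counts))
    hvg <- stage("preprocess",
                 select_hvg(nm, pp$hvg$n_bins, pp$hvg$mean_low,
                            pp$hvg$mean_high, pp$hvg$dispersion_z_min))
    write_result_tsv(data.frame(gene = as.character(hvg)),
                     file.path(out_dir, "hvg.tsv"))
    results$qc <- qc; results$normalized <- nm; results$hvg <- hvg
  }

  if (isTRUE(config$stages$score)) {
    if (is.null(nm)) stop("pipeline stage 'score' failed: preprocess ",
                          "stage is required", call. = FALSE)
    sc <- config$score
    sig <- default_repair_signature()
    scaled <- stage("score", scale_unit_variance(nm, sig$genes))
    scores <- stage("score", repair_score(scaled))
    write_result_tsv(scores, file.path(out_dir, "repair_scores.tsv"))
    heat <- stage("score",
                  signature_correlation(nm, sig, sc$marker_gene))
    heat_df <- do.call(rbind, lapply(names(heat), function(g) {
      h <- heat[[g]]
      data.frame(group = g,
                 gene_a = rep(h$gene_labels,
                              times = length(h$gene_labels)),
                 gene_b = rep(h$gene_labels,
                              each = length(h$gene_labels)),
                 r = as.vector(h$r_matrix), stringsAsFactors = FALSE)
    }))
    write_result_tsv(heat_df, file.path(out_dir,
                                        "signature_correlation.tsv"))
    leaf_df <- do.call(rbind, lapply(names(heat), function(g) {
      data.frame(group = g, position = seq_along(heat[[g]]$leaf_order),
                 gene = heat[[g]]$leaf_order, stringsAsFactors = FALSE)
    }))
    write_result_tsv(leaf_df, file.path(out_dir, "leaf_order.tsv"))
    score_vec <- stats::setNames(scores$repair_score, scores$barcode)
    # the marker-vs-score scatter is read from WT cells (the marker is
    # a knockout zero in KO cells), pooled within condition x subset
    wt <- results$qc$counts$cell_meta$genotype == "WT"
    pooled <- stage("score", pseudo_replicate_pools(
      subset_cells(results$qc$counts, wt), n_pools = sc$n_pools,
      group_by = c("condition", "subset"),
      genes = intersect(c(sc$marker_gene, sig$genes),
                        results$qc$counts$gene_names),
      cell_scores = score_vec, seed = derive_seed(seed, 2L)))
    write_result_tsv(pooled, file.path(out_dir, "pooled_expression.tsv"))
    pc <- stage("score", pool_correlation(pooled, sc$marker_gene,
                                          "repair_score",
                                          split_by = "subset"))
    write_result_tsv(pc, file.path(out_dir, "pool_correlation.tsv"))
    results$scores <- scores; results$heatmaps <- heat
    results$pooled <- pooled; results$pool_correlation <- pc
  }

  if (isTRUE(config$stages$regulon_test)) {
    rt <- config$regulon_test
    ra <- stage("regulon-test", do.call(simulate_regulon_activity, c(
      config$simulate$regulons, list(seed = derive_seed(seed, 3L)))))
    res <- stage("regulon-test", regulon_differential(
      ra, n_permutations = rt$n_permutations,
      exhaustive_threshold = rt$exhaustive_threshold, alpha = rt$alpha,
      zero_fraction_cutoff = rt$zero_fraction_cutoff,
      subsample_n = rt$subsample_n, seed = derive_seed(seed, 4L)))
    write_result_tsv(res, file.path(out_dir, "regulon_results.tsv"))
    results$regulon_truth <- attr(ra, "truth")
    results$regulon_results <- res
  }

  if (isTRUE(config$stages$tcr)) {
    tc <- config$tcr
    rp <- config$simulate$repertoire
    sample_ids <- paste(rep(c("WT", "KO"), each = 2),
                        rep(c("spleen", "lung"), 2), sep = "_")
    sims <- stage("tcr", lapply(seq_along(sample_ids), function(i) {
      simulate_repertoire(
        n_cells = rp$n_cells_per_sample, clone_geom_p = rp$clone_geom_p,
        shared_clone_rate = rp$shared_clone_rate,
        chain_anomaly_rate = rp$chain_anomaly_rate,
        sample_id = sample_ids[i], seed = derive_seed(seed, 50L + i))
    }))
    names(sims) <- sample_ids
    reps <- stage("tcr", lapply(sims, function(s) {
      ct <- assemble_clonotypes(s$contigs, key_mode = tc$key_mode)
      exclude_blacklisted(ct, s$blacklist)
    }))
    expansion <- stage("tcr", lapply(sample_ids, function(sid) {
      marks <- split_by_marker(reps[[sid]], sims[[sid]]$marker_counts,
                               min_count = tc$min_marker_count)
      ex <- classify_expansion(reps[[sid]], cell_meta = marks,
                               top_n = tc$top_n_expanded)
      ex$summary <- cbind(sample_id = sid, ex$summary)
      ex$top_clones <- cbind(sample_id = sid, ex$top_clones)
      ex
    }))
    summary_df <- do.call(rbind, lapply(expansion, `[[`, "summary"))
    top_df <- do.call(rbind, lapply(expansion, `[[`, "top_clones"))
    write_result_tsv(summary_df, file.path(out_dir,
                                           "expansion_summary.tsv"))
    write_result_tsv(top_df, file.path(out_dir, "top_clones.tsv"))
    M <- stage("tcr", overlap_matrix(
      reps, require_single_pair = tc$require_single_pair_overlap))
    write_result_tsv(cbind(data.frame(repertoire = rownames(M)),
                           as.data.frame(M)),
                     file.path(out_dir, "overlap_matrix.tsv"))
    results$repertoires <- reps
    results$repertoire_truth <- lapply(sims, `[[`, "truth")
    results$expansion <- summary_df
    results$overlap <- M
  }

  manifest <- list(
    seed = as.integer(seed),
    package = "tcellrepair",
    package_version = as.character(utils::packageVersion("tcellrepair")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stage_order = c("simulate", "preprocess", "score", "regulon_test",
                    "tcr"),
    tcr_filter_order = c("assemble", "exclude_blacklist",
                         "single_pair_for_overlap_only", "expansion"),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$out_dir <- out_dir
  invisible(results)
}
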