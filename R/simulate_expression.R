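#' Simulate a single-cell count matrix with a planted activation axis
#'
#' Generates negative-binomial counts for a full factorial design
#' (genotype x condition x organ x subset) mimicking T cells from naive
#' and virus-infected wild-type and *Tigit*-knockout mice. Each cell
#' carries a latent activation factor `a ~ Normal(mu_cond, 1)` (shifted
#' upward in infected cells); the marker gene (*Tigit*) and the
#' tissue-repair signature genes have their expected expression modulated
#' by `exp(lambda * a - lambda^2/2)`, which couples them along a single
#' activation axis. `lambda` is calibrated by Monte-Carlo bisection so
#' that the realized single-cell Pearson correlation between the
#' normalized marker expression and the mean normalized signature
#' expression hits the target `latent_coupling`.
#'
#' Library sizes are log-normal; a fraction of genes carries the mouse
#' mitochondrial `mt-` prefix, and a fraction of cells is given an
#' elevated mitochondrial share (above the 7 percent QC cutoff) so the
#' quality-control filter has true positives to find. When
#' `ko_marker_silenced` is TRUE, KO cells have their marker counts forced
#' to zero (a transcript-level knockout).
#'
#' @param n_cells_per_stratum cells per genotype x condition x organ x
#'   subset stratum.
#' @param genotypes,conditions,organs,subsets design levels (subsets of
#'   the controlled vocabularies).
#' @param n_genes total genes, including marker, signature and
#'   mitochondrial genes.
#' @param signature_genes tissue-repair signature gene names.
#' @param marker_gene the coupled marker (default "Tigit").
#' @param latent_coupling target correlation `rho` in [-1, 1] between
#'   marker and mean signature normalized expression (0 = independent).
#' @param ko_marker_silenced force marker counts to zero in KO cells.
#' @param activation_shift_infected mean shift of the latent factor in
#'   infected cells (default 0.5).
#' @param library_size_log_mean,library_size_log_sd log-normal library
#'   size parameters (defaults log(5000) and 0.35).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2; default 0.4).
#' @param mito_gene_fraction fraction of genes given the `mt-` prefix.
#' @param high_mito_cell_fraction fraction of cells with an elevated
#'   mitochondrial share.
#' @param high_mito_range uniform range of the mitochondrial share for
#'   high-mito cells (default 0.10-0.25, all above the 0.07 cutoff).
#' @param baseline_mito_share mitochondrial share of ordinary cells
#'   (default 0.02).
#' @param calibration_cells cells used per calibration evaluation
#'   (default 2000).
#' @param seed RNG seed; the whole simulation (calibration included) is a
#'   pure function of config + seed.
#' @return a [cell_counts] object with full annotations and a `"truth"`
#'   attribute (latent factors, calibrated lambda, coupled genes, mito
#'   genes, high-mito barcodes, library sizes).
#' @export
simulate_expression <- function(n_cells_per_stratum = 100L,
                                genotypes = c("WT", "KO"),
                                conditions = c("naive", "infected"),
                                organs = c("spleen", "lung"),
                                subsets = c("Treg", "CD4conv", "CD8"),
                                n_genes = 300L,
                                signature_genes =
                                  default_repair_signature()$genes,
                                marker_gene = "Tigit",
                                latent_coupling = 0.6,
                                ko_marker_silenced = TRUE,
                                activation_shift_infected = 0.5,
                                library_size_log_mean = log(5000),
                                library_size_log_sd = 0.35,
                                nb_dispersion = 0.4,
                                mito_gene_fraction = 0.05,
                                high_mito_cell_fraction = 0.05,
                                high_mito_range = c(0.10, 0.25),
                                baseline_mito_share = 0.02,
                                calibration_cells = 2000L,
                                seed = 1L) {
  stopifnot(abs(latent_coupling) <= 1,
            mito_gene_fraction >= 0, mito_gene_fraction <= 1,
            high_mito_cell_fraction >= 0, high_mito_cell_fraction <= 1,
            nb_dispersion > 0,
            length(signature_genes) + 1L < n_genes)
  design <- expand.grid(genotype = genotypes, condition = conditions,
                        organ = organs, subset = subsets,
                        stringsAsFactors = FALSE)
  genes <- build_gene_panel(n_genes, signature_genes, marker_gene,
                            mito_gene_fraction)
  lambda <- if (latent_coupling == 0) 0 else {
    calibrate_latent_coupling(
      rho = latent_coupling, genes = genes, conditions = conditions,
      activation_shift_infected = activation_shift_infected,
      library_size_log_mean = library_size_log_mean,
      library_size_log_sd = library_size_log_sd,
      nb_dispersion = nb_dispersion,
      baseline_mito_share = baseline_mito_share,
      n_calibration = calibration_cells,
      seed = derive_seed(seed, 7L))
  }
  n_total <- nrow(design) * n_cells_per_stratum
  meta <- design[rep(seq_len(nrow(design)), each = n_cells_per_stratum), ,
                 drop = FALSE]
  meta$sample_id <- paste(meta$genotype, meta$condition, meta$organ,
                          sep = "_")
  meta$barcode <- sprintf("CELL%06d", seq_len(n_total))
  rownames(meta) <- NULL
  with_seed(derive_seed(seed, 11L), {
    a <- stats::rnorm(n_total) +
      ifelse(meta$condition == "infected", activation_shift_infected, 0)
    lib <- stats::rlnorm(n_total, library_size_log_mean,
                         library_size_log_sd)
    n_high <- round(high_mito_cell_fraction * n_total)
    high_cells <- if (n_high > 0) sample.int(n_total, n_high) else integer(0)
    mito_share <- rep(baseline_mito_share, n_total)
    mito_share[high_cells] <- stats::runif(n_high, high_mito_range[1],
                                           high_mito_range[2])
    counts <- draw_nb_counts(genes, a, lib, mito_share, lambda,
                             nb_dispersion)
  })
  if (ko_marker_silenced) {
    counts[meta$genotype == "KO", genes$marker] <- 0
  }
  out <- cell_counts(counts, barcodes = meta$barcode,
                     gene_names = genes$names,
                     cell_meta = meta[, c("barcode", "sample_id", "genotype",
                                          "condition", "organ", "subset")])
  attr(out, "truth") <- list(
    latent = stats::setNames(a, meta$barcode), lambda = lambda,
    coupled_genes = genes$coupled, marker_gene = genes$marker,
    signature_genes = intersect(genes$coupled, signature_genes),
    mito_genes = genes$names[genes$mito],
    high_mito_barcodes = meta$barcode[sort(high_cells)],
    library_sizes = stats::setNames(lib, meta$barcode))
  out
}

# Assemble the gene panel: marker + signature genes (the coupled block,
# given an elevated baseline weight so their expression is measurable),
# mitochondrial genes, and log-normal filler genes.
build_gene_panel <- function(n_genes, signature_genes, marker_gene,
                             mito_gene_fraction) {
  n_mito <- round(mito_gene_fraction * n_genes)
  coupled <- unique(c(marker_gene, signature_genes))
  n_filler <- n_genes - length(coupled) - n_mito
  if (n_filler < 1) stop("n_genes too small for the panel", call. = FALSE)
  mito_names <- if (n_mito > 0) {
    canon <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp6",
               "mt-Co3", "mt-Nd3", "mt-Nd4", "mt-Nd5", "mt-Cytb")
    if (n_mito <= length(canon)) canon[seq_len(n_mito)]
    else c(canon, sprintf("mt-g%02d", seq_len(n_mito - length(canon))))
  } else character(0)
  filler <- sprintf("Gene%04d", seq_len(n_filler))
  names_all <- c(coupled, mito_names, filler)
  # baseline relative expression weights, fixed (not seed-dependent):
  # coupled genes moderately expressed, fillers spread over two decades
  w <- c(rep(3, length(coupled)),
         rep(1, length(mito_names)),
         exp(stats::qnorm(stats::ppoints(n_filler))))  # deterministic spread
  list(names = names_all, weights = w, coupled = coupled,
       marker = marker_gene, mito = startsWith(names_all, "mt-"))
}

# Draw the NB count matrix for given latent factors, library sizes and
# per-cell mitochondrial shares. Assumes the RNG state is already set.
draw_nb_counts <- function(genes, a, lib, mito_share, lambda, phi) {
  n_cells <- length(a); n_genes <- length(genes$names)
  R <- matrix(genes$weights, n_cells, n_genes, byrow = TRUE)
  coupled_idx <- match(genes$coupled, genes$names)
  if (lambda != 0) {
    mult <- exp(abs(lambda) * a - lambda^2 / 2)
    marker_idx <- match(genes$marker, genes$names)
    R[, coupled_idx] <- R[, coupled_idx] * mult
    if (lambda < 0) {
      # anti-coupling: marker moves against the signature
      R[, marker_idx] <- genes$weights[marker_idx] * exp(lambda * a -
                                                           lambda^2 / 2)
    }
  }
  mito_idx <- which(genes$mito)
  other_idx <- setdiff(seq_len(n_genes), mito_idx)
  other_sum <- rowSums(R[, other_idx, drop = FALSE])
  if (length(mito_idx)) {
    mito_sum <- rowSums(R[, mito_idx, drop = FALSE])
    R[, mito_idx] <- R[, mito_idx] * (mito_share / mito_sum)
    R[, other_idx] <- R[, other_idx] * ((1 - mito_share) / other_sum)
  } else {
    R[, other_idx] <- R[, other_idx] / other_sum
  }
  mu <- R * lib
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
                   n_cells, n_genes)
  colnames(counts) <- genes$names
  counts
}

#' Single-cell correlation between marker and mean signature expression
#'
#' The coupling readout used by the simulator's calibration and the
#' coexpression-recovery checks: Pearson r between the normalized marker
#' expression and the per-cell mean of the normalized signature-gene
#' expression, over cells where the marker is not silenced (WT cells when
#' a genotype label is present).
#'
#' @param x a [cell_counts] object.
#' @param signature_genes signature gene names (default: the repair
#'   signature members present in the matrix).
#' @param marker_gene marker gene name (default "Tigit").
#' @return Pearson correlation coefficient.
#' @export
marker_signature_correlation <- function(x,
                                         signature_genes =
                                           default_repair_signature()$genes,
                                         marker_gene = "Tigit") {
  stopifnot(inherits(x, "cell_counts"))
  keep <- if ("genotype" %in% names(x$cell_meta)) {
    x$cell_meta$genotype == "WT"
  } else rep(TRUE, nrow(x$counts))
  nm <- normalize_counts(subset_cells(x, keep))
  sig <- intersect(setdiff(signature_genes, marker_gene), nm$gene_names)
  if (!length(sig) || !(marker_gene %in% nm$gene_names)) {
    stop("marker or signature genes absent", call. = FALSE)
  }
  mk <- as.numeric(nm$values[, marker_gene])
  sg <- Matrix::rowMeans(nm$values[, sig, drop = FALSE])
  stats::cor(mk, as.numeric(sg))
}

#' Calibrate the latent-coupling strength for a target correlation
#'
#' Monte-Carlo bisection on the latent-factor loading `lambda`: simulates
#' a WT-only calibration population with common random numbers, measures
#' the realized marker-vs-mean-signature correlation with
#' [marker_signature_correlation()], and bisects until the target `rho`
#' is met within `tol`. Errors if the target is infeasible for the chosen
#' dispersion.
#'
#' @param rho target correlation (sign handled by the caller's simulator).
#' @param genes gene panel from the simulator (internal structure).
#' @param conditions,activation_shift_infected,library_size_log_mean,library_size_log_sd,nb_dispersion,baseline_mito_share
#'   simulation parameters matching the main draw.
#' @param n_calibration cells per evaluation (default 2000).
#' @param tol correlation tolerance (default 0.01).
#' @param max_iter bisection iterations (default 25).
#' @param seed RNG seed (shared across evaluations, so the bisected
#'   function is smooth and the result deterministic).
#' @return calibrated lambda (sign of `rho`).
#' @export
calibrate_latent_coupling <- function(rho, genes, conditions = "infected",
                                      activation_shift_infected = 0.5,
                                      library_size_log_mean = log(5000),
                                      library_size_log_sd = 0.35,
                                      nb_dispersion = 0.4,
                                      baseline_mito_share = 0.02,
                                      n_calibration = 2000L, tol = 0.01,
                                      max_iter = 25L, seed = 1L) {
  stopifnot(abs(rho) <= 1, rho != 0)
  target <- abs(rho)
  eval_r <- function(lambda) {
    with_seed(seed, {
      cond <- rep(conditions, length.out = n_calibration)
      a <- stats::rnorm(n_calibration) +
        ifelse(cond == "infected", activation_shift_infected, 0)
      lib <- stats::rlnorm(n_calibration, library_size_log_mean,
                           library_size_log_sd)
      counts <- draw_nb_counts(genes, a, lib,
                               rep(baseline_mito_share, n_calibration),
                               lambda, nb_dispersion)
      x <- cell_counts(counts,
                       barcodes = sprintf("CAL%05d",
                                          seq_len(n_calibration)),
                       gene_names = genes$names)
      marker_signature_correlation(x,
                                   signature_genes =
                                     setdiff(genes$coupled, genes$marker),
                                   marker_gene = genes$marker)
    })
  }
  lo <- 0; hi <- 1.5
  r_hi <- eval_r(hi)
  while (r_hi < target && hi < 6) {
    hi <- hi * 2
    r_hi <- eval_r(hi)
  }
  if (r_hi < target) {
    stop("latent coupling target rho = ", rho,
         " infeasible for this dispersion (max achievable ~ ",
         round(r_hi, 3), ")", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- eval_r(mid)
    if (abs(r_mid - target) < tol) return(sign(rho) * mid)
    if (r_mid < target) lo <- mid else hi <- mid
  }
  sign(rho) * (lo + hi) / 2
}
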