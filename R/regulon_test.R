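#' Construct a cell x regulon activity matrix
#'
#' Container for per-cell regulon activities (AUCell-style area-under-
#' recovery-curve scores in [0, 1]) with the same annotation axes as the
#' count matrix.
#'
#' @param activity numeric matrix, cells x regulons, values in [0, 1].
#' @param regulon_names unique regulon labels.
#' @param cell_meta per-cell annotation data.frame keyed by `barcode`.
#' @return object of class `regulon_activity`.
#' @export
regulon_activity <- function(activity,
                             regulon_names = colnames(activity),
                             cell_meta) {
  activity <- as.matrix(activity)
  regulon_names <- as.character(regulon_names)
  if (anyDuplicated(regulon_names)) {
    stop("duplicate regulon names", call. = FALSE)
  }
  if (ncol(activity) != length(regulon_names)) {
    stop("activity columns do not match regulon_names", call. = FALSE)
  }
  if (any(activity < 0) || any(activity > 1)) {
    stop("activity values must lie in [0, 1]", call. = FALSE)
  }
  cell_meta <- validate_cell_meta(cell_meta, cell_meta$barcode)
  if (nrow(activity) != nrow(cell_meta)) {
    stop("activity rows do not match cell_meta", call. = FALSE)
  }
  dimnames(activity) <- list(cell_meta$barcode, regulon_names)
  structure(list(activity = activity, regulon_names = regulon_names,
                 cell_meta = cell_meta),
            class = "regulon_activity")
}

#' @export
print.regulon_activity <- function(x, ...) {
  cat("regulon_activity: ", nrow(x$activity), " cells x ",
      ncol(x$activity), " regulons\n", sep = "")
  invisible(x)
}

#' Stratified proportional subsampling of cells
#'
#' Draws `n` cells without replacement, allocated across the strata
#' proportionally to stratum size by largest-remainder rounding (mirroring
#' the randomized 5,000-cell subsets drawn across infection and genotype
#' conditions). If fewer than `n` cells exist, all are returned with a
#' warning.
#'
#' @param x a `regulon_activity` or [cell_counts] object.
#' @param n target number of cells (default 5000).
#' @param strata cell_meta columns defining the strata
#'   (default condition and genotype).
#' @param seed RNG seed.
#' @return object of the same class restricted to the sampled cells.
#' @export
subsample_cells <- function(x, n = 5000L, strata = c("condition", "genotype"),
                            seed = 1L) {
  meta <- x$cell_meta
  if (nrow(meta) == 0) stop("empty input", call. = FALSE)
  stopifnot(n >= 1)
  if (nrow(meta) <= n) {
    if (nrow(meta) < n) {
      warning("only ", nrow(meta), " cells available (requested ", n,
              "); returning all", call. = FALSE)
    }
    return(x)
  }
  strata <- intersect(strata, names(meta))
  key <- if (length(strata)) interaction(meta[strata], drop = TRUE, sep = ".")
         else factor(rep("all", nrow(meta)))
  sizes <- table(key)
  quota <- n * as.numeric(sizes) / nrow(meta)
  base <- floor(quota)
  rem <- n - sum(base)
  # largest remainder; ties broken by stratum name for determinism
  ord <- order(quota - base, names(sizes), decreasing = c(TRUE, FALSE),
               method = "radix")
  alloc <- base
  if (rem > 0) alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(sizes), function(i) {
      cells <- which(key == names(sizes)[i])
      sort(sample(cells, alloc[i]))
    }))
  })
  idx <- sort(idx)
  if (inherits(x, "cell_counts")) return(subset_cells(x, idx))
  regulon_activity(x$activity[idx, , drop = FALSE], x$regulon_names,
                   x$cell_meta[idx, , drop = FALSE])
}

#' Remove regulons that are near-silent in every condition
#'
#' A regulon is removed if and only if, in EVERY condition stratum, the
#' fraction of cells with zero activity (|a| < 1e-12) strictly exceeds
#' `zero_fraction_cutoff`. A regulon active in even one condition is kept.
#'
#' @param ra a `regulon_activity` object.
#' @param zero_fraction_cutoff default 0.70 ("more than 70 percent zeros").
#' @param condition_col cell_meta column defining the condition strata.
#' @return list with `kept`, `removed` (character vectors of regulon
#'   names) and `zero_fractions` (regulon x condition matrix).
#' @export
filter_regulons <- function(ra, zero_fraction_cutoff = 0.70,
                            condition_col = "condition") {
  stopifnot(inherits(ra, "regulon_activity"))
  conds <- unique(ra$cell_meta[[condition_col]])
  if (is.null(conds)) stop("condition labels missing", call. = FALSE)
  zf <- sapply(conds, function(cc) {
    rows <- ra$cell_meta[[condition_col]] == cc
    colMeans(abs(ra$activity[rows, , drop = FALSE]) < 1e-12)
  })
  zf <- matrix(zf, ncol = length(conds),
               dimnames = list(ra$regulon_names, conds))
  removed <- rowSums(zf > zero_fraction_cutoff) == length(conds)
  list(kept = ra$regulon_names[!removed],
       removed = ra$regulon_names[removed],
       zero_fractions = zf)
}

# Draw a matrix of Monte-Carlo permutation index sets: each column holds
# the indices (into the pooled vector of length n) relabelled as group 1.
draw_permutation_indices <- function(n, n1, B, seed) {
  with_seed(seed, {
    vapply(seq_len(B), function(i) sample.int(n, n1), integer(n1))
  })
}

#' Two-sided permutation test for a difference in group means
#'
#' Tests the difference in mean activity between two groups (WT minus KO)
#' against the permutation null obtained by relabelling the pooled values.
#' When the number of distinct label arrangements `choose(n1+n2, n1)` is at
#' most `exhaustive_threshold` the null is enumerated exactly and
#' `p = #(|T_perm| >= |T_obs|) / total`; otherwise `n_permutations` random
#' relabelings are drawn and the add-one estimator
#' `p = (1 + #(|T_perm| >= |T_obs|)) / (1 + B)` is used, which never
#' returns 0.
#'
#' @param values_wt,values_ko numeric vectors of per-cell activities.
#' @param n_permutations Monte-Carlo sample size B (default 10000).
#' @param exhaustive_threshold enumerate exactly when the number of
#'   arrangements is at most this (default 10000).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @param perm_indices optional precomputed index matrix from
#'   `draw_permutation_indices()` (n1 rows), letting one set of
#'   relabelings be shared across many regulons of the same stratum.
#' @return list with `stat_observed` (mean WT - mean KO), `p_raw`,
#'   `exhaustive` (logical), `n_permutations_used`.
#' @export
permutation_test <- function(values_wt, values_ko, n_permutations = 10000L,
                             exhaustive_threshold = 10000L, seed = 1L,
                             perm_indices = NULL) {
  n1 <- length(values_wt); n2 <- length(values_ko)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  t_obs <- mean(values_wt) - mean(values_ko)
  pooled <- c(values_wt, values_ko)
  n <- n1 + n2
  total <- sum(pooled)
  tol <- 1e-12 * max(1, abs(t_obs))
  n_arrangements <- choose(n, n1)
  if (is.null(perm_indices) && n_arrangements <= exhaustive_threshold) {
    combs <- utils::combn(n, n1)
    s1 <- colSums(matrix(pooled[combs], nrow = n1))
    t_perm <- s1 / n1 - (total - s1) / n2
    p <- sum(abs(t_perm) >= abs(t_obs) - tol) / ncol(combs)
    return(list(stat_observed = t_obs, p_raw = p, exhaustive = TRUE,
                n_permutations_used = ncol(combs)))
  }
  idx <- perm_indices %||%
    draw_permutation_indices(n, n1, n_permutations, seed)
  stopifnot(nrow(idx) == n1)
  B <- ncol(idx)
  s1 <- colSums(matrix(pooled[idx], nrow = n1))
  t_perm <- s1 / n1 - (total - s1) / n2
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (1 + B)
  list(stat_observed = t_obs, p_raw = p, exhaustive = FALSE,
       n_permutations_used = B)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error-rate correction: with raw p values sorted ascending,
#' `adjusted(i) = max_{j <= i} min(1, (m - j + 1) * p(j))`, returned in the
#' original order (computed via [stats::p.adjust()]).
#'
#' @param p numeric vector of raw p values in (0, 1].
#' @return adjusted p values, same length and order.
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Log fold-change of mean activity between genotypes
#'
#' `log_base((mean_WT + eps) / (mean_KO + eps))`; the pseudocount guards
#' zero means, and the result is flagged degenerate when either mean is
#' below `10 * eps`.
#'
#' @param values_wt,values_ko numeric vectors.
#' @param base logarithm base (default 2).
#' @param eps pseudocount (default 1e-9).
#' @return numeric log fold-change with logical attribute `"degenerate"`.
#' @export
effect_size_logfc <- function(values_wt, values_ko, base = 2, eps = 1e-9) {
  if (!length(values_wt) || !length(values_ko)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  m1 <- mean(values_wt); m2 <- mean(values_ko)
  out <- log((m1 + eps) / (m2 + eps), base = base)
  attr(out, "degenerate") <- (m1 < 10 * eps) || (m2 < 10 * eps)
  out
}

#' Differential regulon activity between genotypes, per subset x condition
#'
#' The full testing pipeline: within each cell subset the near-silent
#' regulons (more than `zero_fraction_cutoff` zeros in every condition)
#' are removed; then for each (subset, condition) stratum every kept
#' regulon is permutation-tested between WT and KO cells, the
#' Holm-Bonferroni correction is applied within that stratum's family,
#' and the log fold-change effect size is attached. One set of random
#' relabelings (seeded) is shared across the regulons of a stratum, which
#' preserves the per-regulon null and keeps the run deterministic and
#' fast.
#'
#' @param ra a `regulon_activity` object with genotype, condition and
#'   subset labels.
#' @param n_permutations Monte-Carlo sample size (default 10000).
#' @param exhaustive_threshold see [permutation_test()].
#' @param alpha family-wise significance level used for the `significant`
#'   column (default 0.05).
#' @param zero_fraction_cutoff see [filter_regulons()] (default 0.70).
#' @param subsample_n optional stratified subsample size applied before
#'   testing (e.g. 5000); NULL tests all cells.
#' @param logfc_base,logfc_eps effect-size parameters.
#' @param seed RNG seed (subsampling and permutations).
#' @return data.frame with one row per kept (regulon, subset, condition):
#'   `regulon`, `cell_subset`, `condition`, `kept_after_filter`,
#'   `stat_observed`, `p_raw`, `p_adjusted`, `log_fc`, `logfc_degenerate`,
#'   `n_WT`, `n_KO`, `n_permutations_used`, `exhaustive`, `significant`.
#'   Regulons removed by the filter are recorded in the
#'   `"removed_regulons"` attribute (per subset).
#' @export
regulon_differential <- function(ra, n_permutations = 10000L,
                                 exhaustive_threshold = 10000L,
                                 alpha = 0.05, zero_fraction_cutoff = 0.70,
                                 subsample_n = NULL, logfc_base = 2,
                                 logfc_eps = 1e-9, seed = 1L) {
  stopifnot(inherits(ra, "regulon_activity"))
  meta <- ra$cell_meta
  need <- c("genotype", "condition", "subset")
  if (!all(need %in% names(meta))) {
    stop("cell_meta must have genotype, condition and subset labels",
         call. = FALSE)
  }
  if (!is.null(subsample_n)) {
    ra <- subsample_cells(ra, n = subsample_n,
                          strata = c("condition", "genotype"),
                          seed = derive_seed(seed, 101L))
    meta <- ra$cell_meta
  }
  removed_by_subset <- list()
  rows <- list()
  stratum_i <- 0L
  for (sub in sort(unique(meta$subset))) {
    sub_rows <- meta$subset == sub
    ra_sub <- regulon_activity(ra$activity[sub_rows, , drop = FALSE],
                               ra$regulon_names,
                               meta[sub_rows, , drop = FALSE])
    filt <- filter_regulons(ra_sub, zero_fraction_cutoff)
    removed_by_subset[[sub]] <- filt$removed
    for (cond in sort(unique(ra_sub$cell_meta$condition))) {
      stratum_i <- stratum_i + 1L
      in_cond <- ra_sub$cell_meta$condition == cond
      gt <- ra_sub$cell_meta$genotype[in_cond]
      if (!all(c("WT", "KO") %in% gt)) {
        warning("stratum ", sub, "/", cond,
                " lacks one genotype; skipped", call. = FALSE)
        next
      }
      act <- ra_sub$activity[in_cond, filt$kept, drop = FALSE]
      wt_rows <- gt == "WT"; ko_rows <- gt == "KO"
      n1 <- sum(wt_rows); n2 <- sum(ko_rows); n <- n1 + n2
      use_mc <- choose(n, n1) > exhaustive_threshold
      if (use_mc && length(filt$kept)) {
        # one set of relabelings per stratum, applied to every regulon at
        # once through a sparse indicator product
        idx <- draw_permutation_indices(n, n1, n_permutations,
                                        derive_seed(seed,
                                                    200L + stratum_i))
        B <- ncol(idx)
        P <- Matrix::sparseMatrix(i = rep(seq_len(B), each = n1),
                                  j = as.vector(idx), x = 1,
                                  dims = c(B, n))
        pooled <- rbind(act[wt_rows, , drop = FALSE],
                        act[ko_rows, , drop = FALSE])
        tot <- colSums(pooled)
        s1 <- as.matrix(P %*% pooled)               # B x regulons
        t_perm <- s1 / n1 - sweep(-s1, 2, tot, "+") / n2
        t_obs <- colMeans(act[wt_rows, , drop = FALSE]) -
          colMeans(act[ko_rows, , drop = FALSE])
        tol <- 1e-12 * pmax(1, abs(t_obs))
        exceed <- colSums(sweep(abs(t_perm), 2, abs(t_obs) - tol, ">="))
        p_raw <- (1 + exceed) / (1 + B)
        fam <- do.call(rbind, lapply(seq_along(filt$kept), function(j) {
          rg <- filt$kept[j]
          fc <- effect_size_logfc(act[wt_rows, rg], act[ko_rows, rg],
                                  base = logfc_base, eps = logfc_eps)
          data.frame(regulon = rg, cell_subset = sub, condition = cond,
                     kept_after_filter = TRUE,
                     stat_observed = t_obs[j], p_raw = p_raw[j],
                     log_fc = as.numeric(fc),
                     logfc_degenerate = attr(fc, "degenerate"),
                     n_WT = n1, n_KO = n2, n_permutations_used = B,
                     exhaustive = FALSE, stringsAsFactors = FALSE)
        }))
      } else {
        res <- lapply(filt$kept, function(rg) {
          wt <- act[wt_rows, rg]; ko <- act[ko_rows, rg]
          pt <- permutation_test(wt, ko, n_permutations,
                                 exhaustive_threshold,
                                 seed = derive_seed(seed,
                                                    200L + stratum_i))
          fc <- effect_size_logfc(wt, ko, base = logfc_base,
                                  eps = logfc_eps)
          data.frame(regulon = rg, cell_subset = sub, condition = cond,
                     kept_after_filter = TRUE,
                     stat_observed = pt$stat_observed, p_raw = pt$p_raw,
                     log_fc = as.numeric(fc),
                     logfc_degenerate = attr(fc, "degenerate"),
                     n_WT = n1, n_KO = n2,
                     n_permutations_used = pt$n_permutations_used,
                     exhaustive = pt$exhaustive, stringsAsFactors = FALSE)
        })
        fam <- do.call(rbind, res)
      }
      if (is.null(fam) || !nrow(fam)) next
      fam$p_adjusted <- holm_bonferroni(fam$p_raw)
      fam$significant <- fam$p_adjusted <= alpha
      rows[[length(rows) + 1L]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame()
  } else {
    out <- out[, c("regulon", "cell_subset", "condition",
                   "kept_after_filter", "stat_observed", "p_raw",
                   "p_adjusted", "log_fc", "logfc_degenerate", "n_WT",
                   "n_KO", "n_permutations_used", "exhaustive",
                   "significant")]
    rownames(out) <- NULL
  }
  attr(out, "removed_regulons") <- removed_by_subset
  out
}
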