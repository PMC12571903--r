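#' Simulate zero-inflated regulon activities with planted genotype shifts
#'
#' Generates an AUCell-style cell x regulon activity matrix: each entry is
#' 0 with probability `zero_inflation`, and otherwise Beta-distributed on
#' (0, 1]. For a chosen set of "shifted" regulons the overall mean
#' activity (zeros included) of WT cells exceeds that of KO cells by
#' `shift` in every stratum; this is planted exactly by raising the WT
#' Beta mean to `base_mean + shift / (1 - zero_inflation)`, so the
#' realized overall difference converges to `shift`. The shifted regulon
#' identities are recorded in the `"truth"` attribute for recovery tests.
#'
#' @param n_regulons total number of regulons.
#' @param n_shifted_regulons number with a planted WT-KO shift.
#' @param shift difference in overall mean activity (WT minus KO), on the
#'   activity scale.
#' @param zero_inflation probability pi of an exact zero.
#' @param base_mean Beta mean of the non-zero component for KO (and for
#'   unshifted regulons; default 0.3).
#' @param base_concentration Beta concentration a+b (default 10).
#' @param n_cells_per_group cells per genotype x condition x subset cell.
#' @param genotypes,conditions,subsets design levels.
#' @param seed RNG seed.
#' @return a `regulon_activity` object with a `"truth"` attribute
#'   (`shifted_regulons`, `shift`, `zero_inflation`, Beta parameters).
#' @export
simulate_regulon_activity <- function(n_regulons = 100L,
                                      n_shifted_regulons = 10L,
                                      shift = 0.2,
                                      zero_inflation = 0.3,
                                      base_mean = 0.3,
                                      base_concentration = 10,
                                      n_cells_per_group = 500L,
                                      genotypes = c("WT", "KO"),
                                      conditions = c("naive", "infected"),
                                      subsets = c("Treg", "CD8"),
                                      seed = 1L) {
  stopifnot(n_shifted_regulons <= n_regulons,
            zero_inflation >= 0, zero_inflation <= 1,
            base_mean > 0, base_mean < 1, base_concentration > 0)
  if (shift != 0 && zero_inflation < 1) {
    m_wt <- base_mean + shift / (1 - zero_inflation)
    if (m_wt >= 1 || m_wt <= 0) {
      stop("shift = ", shift, " incompatible with the (0,1] activity ",
           "support at zero_inflation = ", zero_inflation,
           " (required non-zero mean ", round(m_wt, 3), ")", call. = FALSE)
    }
  } else {
    m_wt <- base_mean
  }
  if (shift != 0 && zero_inflation == 1) {
    stop("shift cannot be planted when zero_inflation = 1", call. = FALSE)
  }
  design <- expand.grid(genotype = genotypes, condition = conditions,
                        subset = subsets, stringsAsFactors = FALSE)
  n_total <- nrow(design) * n_cells_per_group
  meta <- design[rep(seq_len(nrow(design)), each = n_cells_per_group), ,
                 drop = FALSE]
  meta$barcode <- sprintf("RCELL%06d", seq_len(n_total))
  meta$sample_id <- paste(meta$genotype, meta$condition, sep = "_")
  rownames(meta) <- NULL
  regulon_names <- sprintf("Regulon%03d", seq_len(n_regulons))
  act <- with_seed(derive_seed(seed, 23L), {
    shifted <- if (n_shifted_regulons > 0) {
      sort(sample.int(n_regulons, n_shifted_regulons))
    } else integer(0)
    means <- matrix(base_mean, n_total, n_regulons)
    means[meta$genotype == "WT", shifted] <- m_wt
    A <- matrix(0, n_total, n_regulons)
    if (zero_inflation < 1) {
      nonzero <- matrix(stats::runif(n_total * n_regulons) >=
                          zero_inflation, n_total, n_regulons)
      mm <- means[nonzero]
      A[nonzero] <- stats::rbeta(sum(nonzero),
                                 shape1 = mm * base_concentration,
                                 shape2 = (1 - mm) * base_concentration)
    }
    attr(A, "shifted") <- shifted
    A
  })
  shifted <- attr(act, "shifted")
  attr(act, "shifted") <- NULL
  out <- regulon_activity(act, regulon_names,
                          meta[, c("barcode", "sample_id", "genotype",
                                   "condition", "subset")])
  attr(out, "truth") <- list(
    shifted_regulons = regulon_names[shifted], shift = shift,
    zero_inflation = zero_inflation, base_mean = base_mean,
    wt_nonzero_mean = m_wt, base_concentration = base_concentration)
  out
}
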