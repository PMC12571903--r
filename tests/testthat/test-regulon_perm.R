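test_that("exhaustive permutation p matches full enumeration", {
  pt <- permutation_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(pt$exhaustive)
  expect_equal(pt$n_permutations_used, 20)
  expect_equal(pt$stat_observed, -3)
  expect_equal(pt$p_raw, 0.1)   # |T| = 3 attained by 2 of 20 arrangements
})

test_that("Monte-Carlo p converges to the exhaustive p within binomial error", {
  wt <- c(1, 2, 3, 7); ko <- c(4, 5, 6, 9)
  p_exh <- permutation_test(wt, ko)$p_raw
  p_mc <- permutation_test(wt, ko, n_permutations = 10000,
                           exhaustive_threshold = 1, seed = 5)$p_raw
  expect_false(permutation_test(wt, ko, exhaustive_threshold = 1,
                                seed = 5)$exhaustive)
  se <- sqrt(p_exh * (1 - p_exh) / 10000)
  expect_lt(abs(p_mc - p_exh), 3 * se + 1e-4)
})

test_that("the add-one estimator never returns 0 and caps at 1", {
  set.seed(9)
  wt <- rnorm(30, 10); ko <- rnorm(30)   # overwhelming separation
  pt <- permutation_test(wt, ko, n_permutations = 1000, seed = 2)
  expect_gte(pt$p_raw, 1 / 1001)
  expect_lte(pt$p_raw, 1)
  same <- permutation_test(rep(2, 5), rep(2, 6))
  expect_equal(same$stat_observed, 0)
  expect_equal(same$p_raw, 1)
})

test_that("permutation test is shift-invariant and label-swap equivariant", {
  set.seed(21)
  wt <- rnorm(8); ko <- rnorm(9, 0.5)
  a <- permutation_test(wt, ko, n_permutations = 2000, seed = 7,
                        exhaustive_threshold = 1)
  b <- permutation_test(wt + 100, ko + 100, n_permutations = 2000,
                        seed = 7, exhaustive_threshold = 1)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$stat_observed + 100 - 100, b$stat_observed)
  # exhaustive mode so the swap comparison is exact
  wt <- wt[1:6]; ko <- ko[1:6]
  swapped <- permutation_test(ko, wt)
  orig <- permutation_test(wt, ko)
  expect_true(orig$exhaustive)
  expect_equal(swapped$stat_observed, -orig$stat_observed)
  expect_equal(swapped$p_raw, orig$p_raw)
})

test_that("empty groups are rejected", {
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("raw p is super-uniform under label exchangeability", {
  set.seed(31)
  B <- 400
  ps <- replicate(400, {
    v <- rnorm(16)
    permutation_test(v[1:8], v[9:16], n_permutations = B,
                     exhaustive_threshold = 1,
                     seed = sample.int(1e6, 1))$p_raw
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha),
               alpha + 1 / (B + 1) + 3 * sqrt(alpha * (1 - alpha) / 400))
  }
})

test_that("Holm step-down reproduces the worked example and naive oracle", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(holm_bonferroni(p), naive_holm(p))
  }
})

test_that("Holm adjustments dominate raw p and are bounded by Bonferroni", {
  set.seed(51)
  p <- runif(15)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(adj <= pmin(1, length(p) * p)))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= 0))
  expect_error(holm_bonferroni(c(0.5, 0)), "0, 1")
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("log fold-change evaluates the guarded ratio of means", {
  expect_equal(as.numeric(effect_size_logfc(c(2, 2), c(1, 1))), 1,
               tolerance = 1e-8)
  expect_equal(as.numeric(effect_size_logfc(1:3, 1:3)), 0)
  zero_ko <- effect_size_logfc(c(1, 1), c(0, 0))
  expect_gt(as.numeric(zero_ko), 20)
  expect_true(attr(zero_ko, "degenerate"))
})

test_that("regulons are removed only when every condition exceeds 70% zeros", {
  make_ra <- function(zfrac_by_cond) {
    # 100 cells per condition; zfrac_by_cond gives the zero fraction
    vals <- unlist(lapply(zfrac_by_cond, function(z) {
      c(rep(0, round(100 * z)), runif(100 - round(100 * z), 0.2, 0.8))
    }))
    meta <- data.frame(barcode = paste0("c", seq_along(vals)),
                       condition = rep(names(zfrac_by_cond), each = 100),
                       stringsAsFactors = FALSE)
    regulon_activity(matrix(vals, ncol = 1), "R1", meta)
  }
  removed <- filter_regulons(make_ra(c(naive = 0.71, infected = 0.71)))
  expect_equal(removed$removed, "R1")
  kept <- filter_regulons(make_ra(c(naive = 0.71, infected = 0.50)))
  expect_equal(kept$kept, "R1")
  all_on <- filter_regulons(make_ra(c(naive = 0, infected = 0)))
  expect_equal(all_on$kept, "R1")
  # exactly at the cutoff: strictly-greater rule keeps the regulon
  at_cut <- filter_regulons(make_ra(c(naive = 0.70, infected = 0.70)))
  expect_equal(at_cut$kept, "R1")
})

test_that("stratified subsampling uses largest-remainder proportional quotas", {
  ra <- simulate_regulon_activity(n_regulons = 5, n_shifted_regulons = 0,
                                  shift = 0, n_cells_per_group = 300,
                                  seed = 3)
  sub <- subsample_cells(ra, n = 500, seed = 7)
  expect_equal(nrow(sub$activity), 500)
  tab <- table(paste(sub$cell_meta$condition, sub$cell_meta$genotype))
  # 4 condition x genotype strata of 600 -> quotas 125 exactly
  expect_true(all(tab == 125))
  expect_equal(sum(tab), 500)
  sub2 <- subsample_cells(ra, n = 500, seed = 7)
  expect_identical(sub$cell_meta$barcode, sub2$cell_meta$barcode)
  expect_warning(all_back <- subsample_cells(ra, n = 1e6), "returning all")
  expect_equal(nrow(all_back$activity), nrow(ra$activity))
})

test_that("differential testing recovers planted shifts and stays deterministic", {
  ra <- simulate_regulon_activity(n_regulons = 40, n_shifted_regulons = 5,
                                  shift = 0.2, zero_inflation = 0.3,
                                  n_cells_per_group = 300,
                                  conditions = "infected",
                                  subsets = "Treg", seed = 13)
  truth <- attr(ra, "truth")
  res <- regulon_differential(ra, n_permutations = 2000, seed = 17)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
  hits <- res$regulon[res$significant]
  expect_setequal(hits, truth$shifted_regulons)
  res2 <- regulon_differential(ra, n_permutations = 2000, seed = 17)
  expect_identical(res, res2)
})

test_that("strata missing a genotype are skipped with a warning", {
  ra <- simulate_regulon_activity(n_regulons = 3, n_shifted_regulons = 0,
                                  shift = 0, n_cells_per_group = 50,
                                  conditions = "infected",
                                  subsets = "Treg", seed = 5)
  keep <- ra$cell_meta$genotype == "WT"
  solo <- regulon_activity(ra$activity[keep, ], ra$regulon_names,
                           ra$cell_meta[keep, ])
  expect_warning(res <- regulon_differential(solo, n_permutations = 100,
                                             seed = 1),
                 "lacks one genotype")
  expect_equal(nrow(res), 0)
})
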