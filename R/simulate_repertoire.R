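.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fixed codon per amino acid: deterministic aa -> nt back-translation.
.aa_codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# Random CDR3 amino-acid string, length 8-20, canonical C...F frame.
random_cdr3 <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    len <- sample(8:20, 1)
    paste0("C", paste(sample(.aa_alphabet, len - 2, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

aa_to_nt <- function(aa) {
  vapply(aa, function(s) {
    paste(.aa_codon[strsplit(s, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# The cross-sample shared clone pool: a fixed set of TRA/TRB CDR3 pairs
# generated from its own seed so that every sample draws from the same
# pool (public clones).
shared_clone_pool <- function(n_pool, pool_seed = 20260101L) {
  with_seed(pool_seed, {
    data.frame(pool_id = sprintf("SH%03d", seq_len(n_pool)),
               cdr3_tra_aa = random_cdr3(n_pool),
               cdr3_trb_aa = random_cdr3(n_pool),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a single-cell TCR repertoire with known clonal structure
#'
#' Builds one sample's repertoire: clone sizes are drawn from a geometric
#' law (`size = 1 + Geom(p)`, so `clone_geom_p = 1` gives all singletons)
#' until `n_cells` is reached (the last clone is truncated); each clone
#' receives one TRA and one TRB CDR3 (random amino-acid strings, length
#' 8-20, back-translated to nucleotides with a fixed codon table). A
#' clone is drawn from the fixed cross-sample shared pool with
#' probability `shared_clone_rate` (public clones, shared across samples
#' through a common pool seed). Transgenic spike-in clones (Smarta-1/P14
#' analogs) are appended verbatim with fixed CDR3s. Chain-pairing
#' anomalies (a dropped or duplicated TRA/TRB chain) are injected per
#' cell at `chain_anomaly_rate`. Marker positivity (*Tigit*, *Areg*) is
#' drawn per cell with expansion-status-dependent rates, and a matching
#' two-gene count matrix is emitted so the marker-split step can be run
#' end to end.
#'
#' The returned truth table is sufficient to score every downstream step:
#' clone membership and size, expansion status, anomaly and spike flags,
#' and marker flags per cell.
#'
#' @param n_cells total cells in the sample (spike-ins included).
#' @param clone_geom_p geometric success parameter in (0, 1].
#' @param shared_clone_rate probability a clone is public.
#' @param n_shared_pool size of the shared pool (default 50).
#' @param pool_seed seed of the shared pool; keep identical across
#'   samples so that their public clones actually match.
#' @param transgenic_spike data.frame with columns `label`,
#'   `cdr3_tra_aa`, `cdr3_trb_aa`, `n_cells`; NULL for none. Use
#'   [default_transgenic_spikes()] for Smarta-1/P14-like clones.
#' @param chain_anomaly_rate per-cell probability of a chain anomaly.
#' @param tigit_pos_rate,areg_pos_rate named vectors
#'   `c(unexpanded = ., expanded = .)` of marker-positivity rates.
#' @param sample_id sample label used in barcodes.
#' @param seed RNG seed.
#' @return list with `contigs` (one row per chain), `truth` (one row per
#'   cell), `marker_counts` (a [cell_counts] with genes Tigit/Areg) and
#'   `blacklist` (label + CDR3 rows for the spiked transgenic receptors).
#' @export
simulate_repertoire <- function(n_cells = 1000L, clone_geom_p = 0.5,
                                shared_clone_rate = 0.1,
                                n_shared_pool = 50L,
                                pool_seed = 20260101L,
                                transgenic_spike =
                                  default_transgenic_spikes(),
                                chain_anomaly_rate = 0,
                                tigit_pos_rate = c(unexpanded = 0.2,
                                                   expanded = 0.6),
                                areg_pos_rate = c(unexpanded = 0.1,
                                                  expanded = 0.4),
                                sample_id = "S1", seed = 1L) {
  stopifnot(clone_geom_p > 0, clone_geom_p <= 1,
            shared_clone_rate >= 0, shared_clone_rate <= 1,
            chain_anomaly_rate >= 0, chain_anomaly_rate <= 1)
  n_spike <- if (is.null(transgenic_spike)) 0L
             else sum(transgenic_spike$n_cells)
  if (n_spike > n_cells) {
    stop("n_cells (", n_cells, ") smaller than total spike-in cells (",
         n_spike, ")", call. = FALSE)
  }
  n_regular <- n_cells - n_spike
  pool <- shared_clone_pool(n_shared_pool, pool_seed)
  with_seed(derive_seed(seed, 31L), {
    # clone sizes until the sample is full
    sizes <- integer(0)
    while (n_regular > 0 && sum(sizes) < n_regular) {
      sizes <- c(sizes, 1L + stats::rgeom(max(64L, n_regular %/% 2L),
                                          clone_geom_p))
    }
    if (n_regular > 0) {
      cum <- cumsum(sizes)
      k <- which(cum >= n_regular)[1]
      sizes <- sizes[seq_len(k)]
      sizes[k] <- sizes[k] - (cum[k] - n_regular)
      sizes <- sizes[sizes > 0]
    }
    n_clones <- length(sizes)
    is_shared <- stats::runif(n_clones) < shared_clone_rate
    n_shared <- sum(is_shared)
    # public clones are drawn with replacement: two draws landing on the
    # same pool entry are the same clonotype and merge below
    pool_pick <- rep(NA_integer_, n_clones)
    pool_pick[is_shared] <- sample.int(nrow(pool), n_shared,
                                       replace = TRUE)
    clone_id <- ifelse(is_shared, pool$pool_id[pool_pick],
                       sprintf("%s_C%04d", sample_id, seq_len(n_clones)))
    tra <- ifelse(is_shared, pool$cdr3_tra_aa[pool_pick],
                  random_cdr3(n_clones))
    trb <- ifelse(is_shared, pool$cdr3_trb_aa[pool_pick],
                  random_cdr3(n_clones))
    if (n_spike > 0) {
      clone_id <- c(clone_id, paste0("spike_", transgenic_spike$label))
      tra <- c(tra, transgenic_spike$cdr3_tra_aa)
      trb <- c(trb, transgenic_spike$cdr3_trb_aa)
      sizes <- c(sizes, transgenic_spike$n_cells)
      is_shared <- c(is_shared, rep(FALSE, nrow(transgenic_spike)))
    }
    cell_clone <- rep(seq_along(sizes), times = sizes)
    n_total <- length(cell_clone)
    stopifnot(n_total == n_cells)
    barcode <- sprintf("%s_BC%05d", sample_id, seq_len(n_total))
    # clone size counts cells per clonotype id, so convergent draws of
    # the same public clone are counted as one clone
    id_per_cell <- clone_id[cell_clone]
    clone_size <- as.integer(table(id_per_cell)[id_per_cell])
    expanded <- clone_size >= 2L
    spike_label <- rep("", n_total)
    if (n_spike > 0) {
      spike_rows <- cell_clone > n_clones
      spike_label[spike_rows] <-
        sub("^spike_", "", clone_id[cell_clone[spike_rows]])
    }
    anomaly <- rep("", n_total)
    hit <- stats::runif(n_total) < chain_anomaly_rate
    anomaly[hit] <- sample(c("drop_TRA", "drop_TRB", "extra_TRA",
                             "extra_TRB"), sum(hit), replace = TRUE)
    status <- ifelse(expanded, "expanded", "unexpanded")
    tigit_pos <- stats::runif(n_total) < tigit_pos_rate[status]
    areg_pos <- stats::runif(n_total) < areg_pos_rate[status]
    truth <- data.frame(
      barcode = barcode, sample_id = sample_id,
      clone_id = clone_id[cell_clone], clone_size = clone_size,
      expanded = expanded, shared = is_shared[cell_clone],
      spike_label = spike_label, anomaly = anomaly,
      tigit_pos = tigit_pos, areg_pos = areg_pos,
      cdr3_tra_aa = tra[cell_clone], cdr3_trb_aa = trb[cell_clone],
      stringsAsFactors = FALSE)
    contigs <- build_contigs(truth)
    marker_counts <- cell_counts(
      cbind(Tigit = ifelse(tigit_pos, 1L + stats::rpois(n_total, 1), 0L),
            Areg = ifelse(areg_pos, 1L + stats::rpois(n_total, 1), 0L)),
      barcodes = barcode, gene_names = c("Tigit", "Areg"))
    blacklist <- if (n_spike > 0) {
      data.frame(
        label = rep(transgenic_spike$label, 2),
        cdr3 = c(transgenic_spike$cdr3_tra_aa,
                 transgenic_spike$cdr3_trb_aa),
        stringsAsFactors = FALSE)
    } else data.frame(label = character(0), cdr3 = character(0))
    list(contigs = contigs, truth = truth, marker_counts = marker_counts,
         blacklist = blacklist)
  })
}

# Expand the per-cell truth into contig rows, applying chain anomalies.
# Assumes the RNG state is already set (extra chains get fresh CDR3s).
build_contigs <- function(truth) {
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    chains <- data.frame(
      chain = c("TRA", "TRB"),
      cdr3_aa = c(truth$cdr3_tra_aa[i], truth$cdr3_trb_aa[i]),
      stringsAsFactors = FALSE)
    an <- truth$anomaly[i]
    if (an == "drop_TRA") chains <- chains[chains$chain != "TRA", ]
    if (an == "drop_TRB") chains <- chains[chains$chain != "TRB", ]
    if (an %in% c("extra_TRA", "extra_TRB")) {
      extra_chain <- sub("^extra_", "", an)
      chains <- rbind(chains, data.frame(chain = extra_chain,
                                         cdr3_aa = random_cdr3(1),
                                         stringsAsFactors = FALSE))
    }
    if (!nrow(chains)) next
    rows[[i]] <- data.frame(
      barcode = truth$barcode[i], chain = chains$chain,
      cdr3_aa = chains$cdr3_aa, cdr3_nt = aa_to_nt(chains$cdr3_aa),
      v_gene = paste0(substr(chains$chain, 1, 3), "V1"),
      j_gene = paste0(substr(chains$chain, 1, 3), "J1"),
      umis = 1L + stats::rpois(nrow(chains), 3),
      raw_clonotype_id = truth$clone_id[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transgenic spike-in clones used by default in the repertoire simulator
#'
#' Two fixed receptor pairs standing in for the adoptively transferred
#' LCMV-specific transgenic clones (Smarta-1-like CD4 and P14-like CD8
#' TCRs). These are synthetic sequences, not the real transgenic CDR3s;
#' they exist so the blacklist-exclusion step has known targets.
#'
#' @param n_cells_each cells per spiked clone (default 20).
#' @return data.frame with `label`, `cdr3_tra_aa`, `cdr3_trb_aa`,
#'   `n_cells`.
#' @export
default_transgenic_spikes <- function(n_cells_each = 20L) {
  data.frame(label = c("Smarta1", "P14"),
             cdr3_tra_aa = c("CAASMARTAGGSF", "CAAPGGSNYKF"),
             cdr3_trb_aa = c("CASSMARTAETLYF", "CASSPGGELFF"),
             n_cells = rep(n_cells_each, 2),
             stringsAsFactors = FALSE)
}
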