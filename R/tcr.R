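#' Assemble cells into clonotypes
#'
#' Groups cells by a receptor identity key. The default key,
#' `"all_chain_nt"`, is the sorted multiset of (chain, CDR3 nucleotide)
#' records across the cell's chains — a deterministic proxy for default
#' whole-receptor clonotyping. The alternative `"cdr3b_aa"` keys cells on
#' their TRB CDR3 amino-acid sequence(s) only, the resolution used for
#' cross-repertoire matching. Cells with no usable chain (all `"other"`,
#' or no TRB in `cdr3b_aa` mode) are dropped with an audit entry.
#'
#' @param contigs contig data.frame from [read_contigs()] or
#'   [simulate_repertoire()].
#' @param key_mode `"all_chain_nt"` (default) or `"cdr3b_aa"`.
#' @return object of class `clonotype_table`: list with
#'   `clonotypes` (clonotype_id, key, clone_size, expanded, n_tra, n_trb),
#'   `cells` (barcode, clonotype_id), `chains` (distinct chain records per
#'   clonotype) and `audit` (dropped barcodes with reasons).
#' @export
assemble_clonotypes <- function(contigs,
                                key_mode = c("all_chain_nt", "cdr3b_aa")) {
  key_mode <- match.arg(key_mode)
  stopifnot(all(c("barcode", "chain", "cdr3_aa", "cdr3_nt") %in%
                  names(contigs)))
  usable <- contigs[contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  dropped <- setdiff(unique(contigs$barcode), unique(usable$barcode))
  audit <- if (length(dropped)) {
    data.frame(barcode = dropped, reason = "no_recognizable_chain",
               stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  if (key_mode == "cdr3b_aa") {
    has_trb <- unique(usable$barcode[usable$chain == "TRB"])
    no_trb <- setdiff(unique(usable$barcode), has_trb)
    if (length(no_trb)) {
      audit <- rbind(audit, data.frame(barcode = no_trb,
                                       reason = "no_TRB_chain",
                                       stringsAsFactors = FALSE))
      usable <- usable[usable$barcode %in% has_trb, , drop = FALSE]
    }
  }
  keys <- vapply(split(usable, usable$barcode), function(df) {
    if (key_mode == "all_chain_nt") {
      paste(sort(paste(df$chain, df$cdr3_nt, sep = ":")), collapse = "|")
    } else {
      paste(sort(unique(df$cdr3_aa[df$chain == "TRB"])), collapse = "|")
    }
  }, character(1))
  barcodes <- names(keys)
  uk <- sort(unique(keys))
  ids <- sprintf("CT%05d", match(keys, uk))
  cells <- data.frame(barcode = barcodes, clonotype_id = ids,
                      key = unname(keys), stringsAsFactors = FALSE)
  sizes <- table(cells$clonotype_id)
  clon <- data.frame(clonotype_id = names(sizes),
                     clone_size = as.integer(sizes),
                     stringsAsFactors = FALSE)
  clon$key <- cells$key[match(clon$clonotype_id, cells$clonotype_id)]
  clon$expanded <- clon$clone_size >= 2L
  # distinct chain records per clonotype (for single-pair filtering)
  ch <- usable[, c("barcode", "chain", "cdr3_aa", "cdr3_nt")]
  ch$clonotype_id <- cells$clonotype_id[match(ch$barcode, cells$barcode)]
  ch <- unique(ch[, c("clonotype_id", "chain", "cdr3_aa", "cdr3_nt")])
  ch <- ch[order(ch$clonotype_id, ch$chain, ch$cdr3_nt), , drop = FALSE]
  rownames(ch) <- NULL
  clon$n_tra <- as.integer(
    table(factor(ch$clonotype_id[ch$chain == "TRA"],
                 levels = clon$clonotype_id)))
  clon$n_trb <- as.integer(
    table(factor(ch$clonotype_id[ch$chain == "TRB"],
                 levels = clon$clonotype_id)))
  clon <- clon[, c("clonotype_id", "key", "clone_size", "expanded",
                   "n_tra", "n_trb")]
  structure(list(clonotypes = clon,
                 cells = cells[, c("barcode", "clonotype_id")],
                 chains = ch, audit = audit, key_mode = key_mode),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat("clonotype_table: ", nrow(x$cells), " cells in ",
      nrow(x$clonotypes), " clonotypes (key: ", x$key_mode, "); ",
      sum(x$clonotypes$expanded), " expanded\n", sep = "")
  invisible(x)
}

# Internal: rebuild a clonotype_table after removing clonotype ids.
drop_clonotypes <- function(ct, drop_ids, reason) {
  keep <- !ct$clonotypes$clonotype_id %in% drop_ids
  removed_cells <- ct$cells[ct$cells$clonotype_id %in% drop_ids, ,
                            drop = FALSE]
  audit <- ct$audit
  if (nrow(removed_cells)) {
    audit <- rbind(audit, data.frame(barcode = removed_cells$barcode,
                                     reason = reason,
                                     stringsAsFactors = FALSE))
  }
  structure(list(clonotypes = ct$clonotypes[keep, , drop = FALSE],
                 cells = ct$cells[!ct$cells$clonotype_id %in% drop_ids, ,
                                  drop = FALSE],
                 chains = ct$chains[!ct$chains$clonotype_id %in% drop_ids, ,
                                    drop = FALSE],
                 audit = audit, key_mode = ct$key_mode),
            class = "clonotype_table")
}

#' Exclude blacklisted (e.g. transgenic Smarta-1 / P14) receptors
#'
#' Removes every clonotype any of whose chains matches a blacklisted CDR3
#' exactly (amino-acid or nucleotide). Used to exclude the adoptively
#' transferred transgenic TCRs from repertoire analysis.
#'
#' @param ct a `clonotype_table`.
#' @param blacklist character vector of CDR3 sequences, or a data.frame
#'   with columns `label` and `cdr3`.
#' @return filtered `clonotype_table`; removed cells are appended to the
#'   audit with reason `"blacklisted"`.
#' @export
exclude_blacklisted <- function(ct, blacklist) {
  stopifnot(inherits(ct, "clonotype_table"))
  seqs <- if (is.data.frame(blacklist)) blacklist$cdr3 else blacklist
  seqs <- unique(as.character(seqs))
  if (!length(seqs)) return(ct)
  hit <- ct$chains$cdr3_aa %in% seqs | ct$chains$cdr3_nt %in% seqs
  drop_clonotypes(ct, unique(ct$chains$clonotype_id[hit]), "blacklisted")
}

#' Keep only clonotypes with exactly one TRA and one TRB chain
#'
#' Applied before cross-dataset repertoire overlap, where receptor
#' identity must be unambiguous; clonotypes with missing or surplus
#' chains are removed.
#'
#' @param ct a `clonotype_table`.
#' @return filtered `clonotype_table` (audit reason
#'   `"not_single_pair"`).
#' @export
filter_single_pair <- function(ct) {
  stopifnot(inherits(ct, "clonotype_table"))
  bad <- ct$clonotypes$clonotype_id[ct$clonotypes$n_tra != 1L |
                                      ct$clonotypes$n_trb != 1L]
  drop_clonotypes(ct, bad, "not_single_pair")
}

#' Clonal-expansion summary per stratum
#'
#' Classifies clones as expanded (two or more member cells) or unexpanded
#' (a single cell) and summarizes per stratum: cell and clone counts,
#' number of expanded clones, the fraction of cells sitting in expanded
#' clones, and the most-expanded clones (up to `top_n`, ties broken by
#' lexicographic clonotype key). When `cell_meta` is given, clone sizes
#' are recomputed within each stratum so that, e.g., per-sample or
#' per-marker expansion is measured on that group's own repertoire.
#'
#' @param ct a `clonotype_table`.
#' @param cell_meta optional data.frame keyed by `barcode` with stratum
#'   columns (e.g. sample_id, subset, marker flags).
#' @param group_by columns of `cell_meta` defining strata; ignored when
#'   `cell_meta` is NULL (a single "all" stratum).
#' @param top_n length of the top-expanded clone list (default 50).
#' @return list with `summary` (one row per stratum: `stratum`, `n_cells`,
#'   `n_clones`, `n_expanded_clones`, `expanded_cell_fraction`) and
#'   `top_clones` (`stratum`, `rank`, `clonotype_id`, `key`,
#'   `clone_size`).
#' @export
classify_expansion <- function(ct, cell_meta = NULL, group_by = NULL,
                               top_n = 50L) {
  stopifnot(inherits(ct, "clonotype_table"), top_n >= 1)
  cells <- ct$cells
  if (is.null(cell_meta)) {
    key <- factor(rep("all", nrow(cells)))
  } else {
    stopifnot("barcode" %in% names(cell_meta))
    m <- cell_meta[match(cells$barcode, cell_meta$barcode), , drop = FALSE]
    group_by <- group_by %||% setdiff(names(cell_meta), "barcode")
    key <- interaction(m[group_by], drop = TRUE, sep = ".")
  }
  summaries <- list(); tops <- list()
  for (g in levels(key)) {
    sub <- cells[which(key == g), , drop = FALSE]
    sizes <- table(sub$clonotype_id)
    sizes <- sizes[sizes > 0]
    n_cells <- nrow(sub)
    expanded <- sizes >= 2
    summaries[[g]] <- data.frame(
      stratum = g, n_cells = n_cells, n_clones = length(sizes),
      n_expanded_clones = sum(expanded),
      expanded_cell_fraction = if (n_cells) sum(sizes[expanded]) / n_cells
                               else 0,
      stringsAsFactors = FALSE)
    keys <- ct$clonotypes$key[match(names(sizes),
                                    ct$clonotypes$clonotype_id)]
    ord <- order(-as.integer(sizes), keys, method = "radix")
    take <- ord[seq_len(min(top_n, length(ord)))]
    tops[[g]] <- data.frame(stratum = g, rank = seq_along(take),
                            clonotype_id = names(sizes)[take],
                            key = keys[take],
                            clone_size = as.integer(sizes)[take],
                            stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
       top_clones = do.call(rbind, c(tops, make.row.names = FALSE)))
}

#' Flag repertoire cells as marker-positive from raw counts
#'
#' A cell is positive for a marker gene (default *Tigit* and *Areg*) when
#' its raw count is at least `min_count` (default 1). Barcodes absent from
#' the count matrix get NA flags with a warning.
#'
#' @param ct a `clonotype_table`.
#' @param counts a [cell_counts] object containing the marker genes.
#' @param markers character vector of marker gene names.
#' @param min_count positivity threshold on the raw count (default 1).
#' @return data.frame keyed by `barcode` with one logical column
#'   `<marker>_pos` per marker, suitable as `cell_meta` for
#'   [classify_expansion()].
#' @export
split_by_marker <- function(ct, counts, markers = c("Tigit", "Areg"),
                            min_count = 1L) {
  stopifnot(inherits(ct, "clonotype_table"), inherits(counts, "cell_counts"))
  absent <- setdiff(markers, counts$gene_names)
  if (length(absent)) {
    stop("marker gene(s) absent from count matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  bc <- ct$cells$barcode
  idx <- match(bc, counts$barcodes)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " repertoire barcode(s) missing from the ",
            "count matrix; their marker flags are NA", call. = FALSE)
  }
  out <- data.frame(barcode = bc, stringsAsFactors = FALSE)
  for (mk in markers) {
    v <- rep(NA, length(bc))
    ok <- !is.na(idx)
    v[ok] <- as.numeric(counts$counts[idx[ok], mk]) >= min_count
    out[[paste0(mk, "_pos")]] <- v
  }
  out
}

#' Jaccard overlap between two repertoires
#'
#' `J = |A intersect B| / |A union B|` over unique clone keys — by default
#' exact CDR3-beta amino-acid matches. Two empty repertoires give 0 with a
#' `"degenerate"` attribute.
#'
#' @param a,b `clonotype_table` objects or character vectors of keys.
#' @param key `"cdr3b_aa"` (unique TRB CDR3 aa sequences) or
#'   `"clonotype_key"` (the table's own assembly key).
#' @return numeric Jaccard index in [0, 1].
#' @export
jaccard_overlap <- function(a, b, key = "cdr3b_aa") {
  A <- repertoire_keys(a, key); B <- repertoire_keys(b, key)
  u <- union(A, B)
  if (!length(u)) {
    return(structure(0, degenerate = TRUE))
  }
  length(intersect(A, B)) / length(u)
}

#' Extract the unique clone keys of a repertoire
#'
#' @param x a `clonotype_table` or character vector (returned as unique).
#' @param key `"cdr3b_aa"` or `"clonotype_key"`.
#' @return character vector of unique keys.
#' @export
repertoire_keys <- function(x, key = c("cdr3b_aa", "clonotype_key")) {
  key <- match.arg(key)
  if (is.character(x)) return(unique(x))
  stopifnot(inherits(x, "clonotype_table"))
  if (key == "clonotype_key") return(unique(x$clonotypes$key))
  unique(x$chains$cdr3_aa[x$chains$chain == "TRB"])
}

#' Pairwise Jaccard overlap matrix across repertoires
#'
#' Computes the symmetric matrix of Jaccard indices between every pair of
#' repertoires. For cross-dataset comparison the single-pair filter is
#' applied to each repertoire first (the default), restricting to clones
#' with exactly one TRA and one TRB chain.
#'
#' @param repertoires named list of `clonotype_table` objects.
#' @param key see [jaccard_overlap()].
#' @param require_single_pair apply [filter_single_pair()] to each
#'   repertoire first (default TRUE).
#' @return numeric matrix in [0, 1], symmetric, unit diagonal for
#'   non-empty repertoires.
#' @export
overlap_matrix <- function(repertoires, key = "cdr3b_aa",
                           require_single_pair = TRUE) {
  stopifnot(length(repertoires) >= 2)
  nm <- names(repertoires) %||% paste0("rep", seq_along(repertoires))
  if (require_single_pair) {
    repertoires <- lapply(repertoires, function(r) {
      if (inherits(r, "clonotype_table")) filter_single_pair(r) else r
    })
  }
  keysets <- lapply(repertoires, repertoire_keys, key = key)
  k <- length(keysets)
  M <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    M[i, i] <- if (length(keysets[[i]])) 1 else 0
    if (i < k) for (j in seq((i + 1), k)) {
      J <- jaccard_overlap(keysets[[i]], keysets[[j]], key = key)
      M[i, j] <- J; M[j, i] <- J
    }
  }
  M
}
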