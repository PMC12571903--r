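#' Read single-cell TCR contig annotations
#'
#' Parses either the 10x `filtered_contig_annotations.csv` dialect or an
#' AIRR Rearrangement TSV into a uniform contig table. Chain labels are
#' normalized to `TRA`/`TRB`; any other locus (e.g. IGH) is kept as
#' `"other"` with a warning so the clonotyping step can audit it.
#'
#' @param path input file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return data.frame with columns `barcode`, `chain`, `cdr3_aa`, `cdr3_nt`,
#'   `v_gene`, `j_gene`, `umis`, `raw_clonotype_id` (one row per contig).
#' @export
read_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- switch(dialect,
    tenx_csv = c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene",
                 "umis", "raw_clonotype_id"),
    airr_tsv = c("cell_id", "locus", "junction_aa", "junction", "v_call",
                 "j_call"))
  df <- if (dialect == "tenx_csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- if (dialect == "tenx_csv") {
    data.frame(barcode = df$barcode, chain = df$chain,
               cdr3_aa = df$cdr3, cdr3_nt = df$cdr3_nt,
               v_gene = df$v_gene, j_gene = df$j_gene,
               umis = as.integer(df$umis),
               raw_clonotype_id = as.character(df$raw_clonotype_id),
               stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = df$cell_id, chain = df$locus,
               cdr3_aa = df$junction_aa, cdr3_nt = df$junction,
               v_gene = df$v_call, j_gene = df$j_call,
               umis = if ("umi_count" %in% names(df))
                 as.integer(df$umi_count) else NA_integer_,
               raw_clonotype_id = if ("clone_id" %in% names(df))
                 as.character(df$clone_id) else NA_character_,
               stringsAsFactors = FALSE)
  }
  foreign <- !out$chain %in% c("TRA", "TRB")
  if (any(foreign)) {
    warning(sum(foreign), " contig(s) with non-TRA/TRB chain labels (",
            paste(unique(out$chain[foreign]), collapse = ", "),
            ") normalized to 'other'", call. = FALSE)
    out$chain[foreign] <- "other"
  }
  if (any(out$umis < 0, na.rm = TRUE)) {
    stop("format error: negative UMI counts", call. = FALSE)
  }
  out
}

#' Write contigs in the 10x filtered-contig CSV dialect
#'
#' @param contigs contig data.frame as returned by [read_contigs()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(barcode = contigs$barcode, chain = contigs$chain,
                    cdr3 = contigs$cdr3_aa, cdr3_nt = contigs$cdr3_nt,
                    v_gene = contigs$v_gene, j_gene = contigs$j_gene,
                    umis = contigs$umis,
                    raw_clonotype_id = contigs$raw_clonotype_id,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
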