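# Internal helpers shared across modules.

# Controlled vocabularies for cell annotations. Case-sensitive: silent label
# mismatch would corrupt every stratified analysis downstream.
.vocab <- list(
  genotype  = c("WT", "KO"),
  condition = c("naive", "infected"),
  organ     = c("spleen", "lung"),
  subset    = c("Treg", "CD4conv", "CD8", "other")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded internals never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 599999L) * 3001L + as.integer(offset)
}

# Deterministic TSV writer used for all result tables.
write_result_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Validate a per-cell annotation data.frame against the controlled
# vocabularies; `barcodes` gives the expected key set and order.
validate_cell_meta <- function(cell_meta, barcodes) {
  stopifnot(is.data.frame(cell_meta))
  if (!"barcode" %in% names(cell_meta)) {
    stop("cell_meta must contain a 'barcode' column", call. = FALSE)
  }
  if (anyDuplicated(cell_meta$barcode)) {
    stop("cell_meta barcodes are not unique", call. = FALSE)
  }
  missing <- setdiff(barcodes, cell_meta$barcode)
  if (length(missing)) {
    stop("cell_meta is missing ", length(missing), " barcode(s), e.g. ",
         missing[1], call. = FALSE)
  }
  cell_meta <- cell_meta[match(barcodes, cell_meta$barcode), , drop = FALSE]
  rownames(cell_meta) <- NULL
  for (field in names(.vocab)) {
    if (field %in% names(cell_meta)) {
      bad <- setdiff(unique(as.character(cell_meta[[field]])), .vocab[[field]])
      if (length(bad)) {
        stop("invalid ", field, " label(s): ",
             paste(bad, collapse = ", "),
             " (allowed: ", paste(.vocab[[field]], collapse = ", "), ")",
             call. = FALSE)
      }
      cell_meta[[field]] <- as.character(cell_meta[[field]])
    }
  }
  cell_meta
}
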