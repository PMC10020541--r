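#' @importFrom rlang %||%
NULL

# Absolute Pearson correlation matrix across rows of `x` (genes x samples),
# with the package-wide convention that undefined correlations (zero-variance
# rows) count as 0. Warnings from `cor()` about zero variance are silenced
# because the convention makes the result well defined.
abs_cor_rows <- function(x) {
  stopifnot(is.matrix(x))
  cc <- suppressWarnings(cor(t(x)))
  cc[!is.finite(cc)] <- 0
  abs(cc)
}

# Validate gene identifiers: non-empty tokens without whitespace.
check_gene_ids <- function(ids, what = "gene identifier") {
  ids <- as.character(ids)
  bad <- !nzchar(ids) | grepl("\\s", ids) | is.na(ids)
  if (any(bad)) {
    abort(glue("invalid {what}(s): {toString(head(ids[bad], 5))}"),
          class = "dnbsle_invalid_gene_id")
  }
  ids
}

# Deterministic integer sub-seed, kept within 32-bit range so downstream
# `set.seed()` calls are portable.
derive_seed <- function(seed, salt) {
  (as.integer(seed) + as.integer(salt) * 10007L) %% .Machine$integer.max
}

first_col_as_genes <- function(df) {
  genes <- check_gene_ids(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}
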