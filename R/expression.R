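#' Assemble a time-course expression dataset
#'
#' Bundles a genes x samples expression matrix with per-sample metadata
#' (time label and reference/case group). Values must be finite with no
#' missing entries; gene identifiers must be unique. Inputs are assumed to
#' be pre-normalised expression (no library-size correction is applied).
#'
#' Time labels are ordered by their first appearance in `metadata` (or by
#' factor levels when `time` is a factor); that order defines "earlier" for
#' tie-breaking in tipping-point detection.
#'
#' @param values Either a numeric matrix with gene identifiers as rownames,
#'   or a data frame whose first column holds gene identifiers and remaining
#'   columns hold one sample each.
#' @param metadata Data frame with columns `sample_id`, `time`, `group`;
#'   `group` must be `"reference"` or `"case"` (the synonyms `"control"` and
#'   `"treatment"` are accepted and mapped).
#' @return A `dnb_dataset` object.
#' @export
dnb_dataset <- function(values, metadata) {
  if (is.data.frame(values)) values <- first_col_as_genes(values)
  stopifnot(is.matrix(values), is.numeric(values))
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "time", "group")
  if (!all(need %in% names(metadata))) {
    abort(glue("metadata must have columns {toString(need)}"))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("expression values contain missing or non-finite entries",
          class = "dnbsle_invalid_data")
  }
  genes <- check_gene_ids(rownames(values))
  if (anyDuplicated(genes)) {
    abort("duplicate gene identifiers in expression matrix",
          class = "dnbsle_invalid_data")
  }
  time_levels <- if (is.factor(metadata$time)) {
    levels(metadata$time)
  } else {
    unique(as.character(metadata$time))
  }
  metadata <- dplyr::mutate(
    metadata,
    sample_id = as.character(.data$sample_id),
    time = as.character(.data$time),
    group = dplyr::recode(as.character(.data$group),
                          control = "reference", treatment = "case")
  )
  if (!all(metadata$group %in% c("reference", "case"))) {
    abort("metadata group labels must be 'reference' or 'case'",
          class = "dnbsle_invalid_data")
  }
  if (is.null(colnames(values))) {
    abort("expression matrix must have sample identifiers as column names")
  }
  if (!setequal(colnames(values), metadata$sample_id) ||
      anyDuplicated(metadata$sample_id)) {
    abort("metadata sample_id must match expression columns one-to-one",
          class = "dnbsle_invalid_data")
  }
  values <- values[, metadata$sample_id, drop = FALSE]

  n_ref <- sum(metadata$group == "reference")
  if (n_ref < 3) {
    abort("need at least 3 reference samples (Pearson correlation on fewer points is meaningless)",
          class = "dnbsle_invalid_data")
  }
  case_times <- unique(metadata$time[metadata$group == "case"])
  if (length(case_times) == 0) {
    abort("dataset holds no case samples", class = "dnbsle_invalid_data")
  }

  structure(
    list(values = values, metadata = metadata, time_levels = time_levels),
    class = "dnb_dataset"
  )
}

#' Read expression values and sample metadata from TSV files
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column and one sample per remaining column; the metadata file has columns
#' `sample_id`, `time`, `group`.
#'
#' @param values_path,metadata_path File paths.
#' @return A [dnb_dataset()].
#' @export
read_expression <- function(values_path, metadata_path) {
  vals <- readr::read_tsv(values_path, show_col_types = FALSE, comment = "#")
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, comment = "#")
  dnb_dataset(vals, meta)
}

#' @export
print.dnb_dataset <- function(x, ...) {
  tl <- x$time_levels
  cat(sprintf(
    "<dnb_dataset> %d genes x %d samples; %d time point(s): %s\n",
    nrow(x$values), ncol(x$values), length(tl), toString(tl)))
  tab <- table(x$metadata$group)
  cat(sprintf("  reference: %d, case: %d\n",
              tab[["reference"]] %||% 0L, tab[["case"]] %||% 0L))
  invisible(x)
}

#' Accessors for a `dnb_dataset`
#'
#' @param data A `dnb_dataset`.
#' @return `dataset_genes()`: character vector; `dataset_values()`: numeric
#'   matrix; `dataset_metadata()`: tibble; `dataset_times()`: ordered time
#'   labels.
#' @export
dataset_genes <- function(data) rownames(data$values)

#' @rdname dataset_genes
#' @export
dataset_values <- function(data) data$values

#' @rdname dataset_genes
#' @export
dataset_metadata <- function(data) data$metadata

#' @rdname dataset_genes
#' @export
dataset_times <- function(data) data$time_levels

# Sample ids for a (time, group) cohort.
cohort_samples <- function(data, time = NULL, group = NULL) {
  md <- data$metadata
  if (!is.null(time)) md <- md[md$time %in% time, , drop = FALSE]
  if (!is.null(group)) md <- md[md$group %in% group, , drop = FALSE]
  md$sample_id
}

# Resolve the reference cohort columns used for entropy scoring at time t.
#  - control_group: all reference-group samples measured at t (the default,
#    matching a per-time untreated control design);
#  - baseline_time: every sample (both groups) measured at the baseline time.
reference_columns <- function(data, time,
                              reference_spec = c("control_group", "baseline_time"),
                              baseline_time = NULL) {
  reference_spec <- match.arg(reference_spec)
  ids <- switch(reference_spec,
    control_group = cohort_samples(data, time = time, group = "reference"),
    baseline_time = {
      bt <- baseline_time %||% data$time_levels[1]
      if (!bt %in% data$time_levels) {
        abort(glue("baseline time '{bt}' not present in the dataset"))
      }
      cohort_samples(data, time = bt)
    }
  )
  if (length(ids) < 3) {
    abort(glue("reference cohort at time '{time}' has {length(ids)} sample(s); need >= 3"),
          class = "dnbsle_invalid_data")
  }
  ids
}
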