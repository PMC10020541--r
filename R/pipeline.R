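#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML key-value file. Required keys: `network`,
#' `expression`, `metadata`, `output_dir`. Optional: `tf`, `deg`,
#' `pathways` (annotation tables; the core-gene stage is skipped with a
#' warning when absent), `score_cutoff`, `reference_spec`
#' (`control_group`/`baseline_time`), `baseline_time`, `divisor`
#' (`scoreable`/`all`), `selection_rule` + `selection_parameter`, `topk`,
#' `select`, `weights` (named list of five), `seed`. Relative paths are
#' resolved against the configuration file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(glue("config file not found: {path}"), class = "dnbsle_config_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("network", "expression", "metadata", "tf", "deg", "pathways")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  if (!is.null(cfg$output_dir) && !grepl("^/", cfg$output_dir)) {
    cfg$output_dir <- file.path(base, cfg$output_dir)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list of configuration values.
#' @export
validate_run_config <- function(config) {
  req <- c("network", "expression", "metadata", "output_dir")
  for (key in req) {
    if (is.null(config[[key]])) {
      abort(glue("config field '{key}' is required"), class = "dnbsle_config_error")
    }
  }
  for (key in c("network", "expression", "metadata", "tf", "deg", "pathways")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort(glue("config field '{key}': file not found ({config[[key]]})"),
            class = "dnbsle_config_error")
    }
  }
  defaults <- list(reference_spec = "control_group", divisor = "scoreable",
                   selection_rule = "top_fraction", topk = 100, select = 8,
                   seed = 1)
  for (key in names(defaults)) {
    config[[key]] <- config[[key]] %||% defaults[[key]]
  }
  if (!config$reference_spec %in% c("control_group", "baseline_time")) {
    abort("config field 'reference_spec' must be control_group or baseline_time",
          class = "dnbsle_config_error")
  }
  if (!config$divisor %in% c("scoreable", "all")) {
    abort("config field 'divisor' must be scoreable or all",
          class = "dnbsle_config_error")
  }
  if (!config$selection_rule %in% c("top_fraction", "score_quantile", "knee")) {
    abort("config field 'selection_rule' is unknown", class = "dnbsle_config_error")
  }
  if (config$selection_rule != "knee") {
    sp <- config$selection_parameter
    if (is.null(sp) || !is.numeric(sp) || sp <= 0 || sp > 1) {
      abort("config field 'selection_parameter' must be in (0, 1]",
            class = "dnbsle_config_error")
    }
  }
  if (!is.numeric(config$topk) || config$topk < 1) {
    abort("config field 'topk' must be a positive count", class = "dnbsle_config_error")
  }
  structure(config, class = "run_config")
}

#' Run the end-to-end DNB analysis
#'
#' Sequences the full pipeline: read the template network and expression
#' data, restrict to measured genes, compute the SLE curve, detect the
#' tipping point, rank local scores and select DNB members, verify the
#' three DNB conditions, and (when annotation tables are configured) run
#' the five-criterion core-gene screen. Writes `curve.tsv`,
#' `local_scores.tsv`, `dnb_members.tsv`, `condition_report.json`,
#' `core_genes.tsv` and `summary.json` into the configured output
#' directory; every output carries a header comment with the package
#' version and a configuration hash, and re-running with the same inputs
#' reproduces the files byte for byte.
#'
#' @param config A `run_config` (from [read_run_config()] or
#'   [validate_run_config()]).
#' @return A `run_summary` object (invisible components: the curve, DNB
#'   result, condition report and core-gene table).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  t0 <- Sys.time()
  stage <- function(msg) inform(glue("[dnbsle] {msg}"))

  stage("reading template network")
  network <- read_edge_list(config$network, score_cutoff = config$score_cutoff)
  stage("reading expression data")
  data <- read_expression(config$expression, config$metadata)

  stage("computing SLE curve")
  curve <- sle_curve(network, data,
                     reference_spec = config$reference_spec,
                     baseline_time = config$baseline_time,
                     divisor = config$divisor)
  t_star <- curve$critical_time
  stage(glue("tipping point detected at {t_star}"))

  ranked <- rank_local_scores(curve)
  dnb <- select_dnb_members(ranked, rule = config$selection_rule,
                            parameter = config$selection_parameter,
                            critical_time = t_star)
  stage(glue("{nrow(dnb$members)} DNB member(s) selected"))

  report <- verify_dnb_conditions(data, dnb$members$gene, t_star)

  core <- NULL
  have_ann <- !is.null(config$tf) || !is.null(config$deg) || !is.null(config$pathways)
  if (have_ann) {
    core <- tryCatch({
      tables <- read_annotation_tables(config$tf, config$deg, config$pathways)
      sc <- score_core_genes(dnb, restrict_to_measured(network, dataset_genes(data)),
                             tables, topk = config$topk)
      w <- config$weights
      if (!is.null(w)) w <- unlist(w)
      ranked_core <- if (is.null(w)) composite_rank(sc, select = config$select)
                     else composite_rank(sc, weights = w, select = config$select)
      dplyr::left_join(ranked_core, sc, by = "gene")
    }, error = function(e) {
      warn(glue("core-gene stage skipped: {conditionMessage(e)}"))
      NULL
    })
  } else {
    warn("no annotation tables configured; core-gene stage skipped")
  }

  stage("writing outputs")
  hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  write_stamped_tsv(curve$summary, out("curve.tsv"), hash)
  write_stamped_tsv(
    dplyr::rename(ranked, local_sle = "score"), out("local_scores.tsv"), hash)
  write_stamped_tsv(dnb$members, out("dnb_members.tsv"), hash)
  write_stamped_tsv(core %||% tibble::tibble(), out("core_genes.tsv"), hash)
  jsonlite::write_json(
    list(config_hash = hash, version = as.character(packageVersion("dnbsle")),
         t_star = report$t_star, cohort = report$cohort,
         passed = report$passed,
         conditions = report$conditions, stats = report$stats),
    out("condition_report.json"), auto_unbox = TRUE, digits = NA)

  summary <- structure(
    list(critical_time = t_star,
         curve = curve$summary,
         n_members = nrow(dnb$members),
         conditions_passed = report$passed,
         core_genes = if (is.null(core)) character() else core$gene,
         config_hash = hash,
         version = as.character(packageVersion("dnbsle")),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_summary")

  jsonlite::write_json(
    summary[c("critical_time", "curve", "n_members", "conditions_passed",
              "core_genes", "config_hash", "version")],
    out("summary.json"), auto_unbox = TRUE, digits = NA)
  stage(glue("done in {round(summary$elapsed_s, 2)} s"))

  attr(summary, "curve") <- curve
  attr(summary, "dnb") <- dnb
  attr(summary, "report") <- report
  attr(summary, "core") <- core
  invisible(summary)
}

write_stamped_tsv <- function(df, path, hash) {
  header <- glue("# dnbsle {packageVersion('dnbsle')} config_hash={hash}")
  body <- sub("\n$", "", readr::format_tsv(df))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> dnbsle %s\n", x$version))
  cat(sprintf("  critical time: %s; DNB members: %d; conditions %s\n",
              x$critical_time, x$n_members,
              if (x$conditions_passed) "hold" else "not all met"))
  if (length(x$core_genes) > 0) {
    cat(sprintf("  core genes: %s\n", toString(x$core_genes)))
  }
  invisible(x)
}
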