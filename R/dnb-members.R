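#' Rank genes by local SLE perturbation at a time point
#'
#' Averages each gene's local perturbation score over the case replicates
#' at one time point (by default the curve's detected critical time) and
#' sorts descending; ties are broken lexicographically so rankings are
#' deterministic.
#'
#' @param curve An [sle_curve()].
#' @param time Time label; defaults to the curve's critical time.
#' @return Tibble with columns `gene`, `score` (mean local `delta_h`) and
#'   `rank`.
#' @export
rank_local_scores <- function(curve, time = NULL) {
  stopifnot(inherits(curve, "sle_curve"))
  time <- time %||% curve$critical_time
  loc <- curve$locals[curve$locals$time == time, , drop = FALSE]
  if (nrow(loc) == 0) abort(glue("no local scores at time '{time}'"))
  per_sample <- split(loc$center, loc$sample_id)
  base <- sort(per_sample[[1]])
  same <- vapply(per_sample, function(g) identical(sort(g), base), logical(1))
  if (!all(same)) {
    abort("case samples cover inconsistent gene sets", class = "dnbsle_invalid_data")
  }
  loc |>
    dplyr::group_by(gene = .data$center) |>
    dplyr::summarise(score = mean(.data$delta_h), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Select DNB member genes from a ranked score list
#'
#' Three explicit selection rules are provided (none is canonical in the
#' DNB literature, so the rule and its parameter are recorded in the
#' result):
#' * `top_fraction`: keep the top `ceiling(parameter * n)` genes;
#' * `score_quantile`: keep genes whose score is strictly above the
#'   `parameter` quantile of all scores;
#' * `knee`: keep genes scoring strictly above the maximum-curvature point
#'   of the descending score profile (argmax of the discrete second
#'   difference); `parameter` is ignored.
#'
#' @param ranked Tibble from [rank_local_scores()] (columns `gene`,
#'   `score`).
#' @param rule `"top_fraction"`, `"score_quantile"` or `"knee"`.
#' @param parameter Rule parameter in `(0, 1]` (required for the first two
#'   rules).
#' @param critical_time Optional time label carried into the result.
#' @return A `dnb_result` object with `members` (tibble `gene`, `score`,
#'   `rank`), `rule`, `parameter`, `critical_time`.
#' @export
select_dnb_members <- function(ranked,
                               rule = c("top_fraction", "score_quantile", "knee"),
                               parameter = NULL, critical_time = NULL) {
  rule <- match.arg(rule)
  ranked <- tibble::as_tibble(ranked)
  if (nrow(ranked) == 0) abort("empty ranking")
  if (!all(c("gene", "score") %in% names(ranked))) {
    abort("`ranked` needs columns gene and score")
  }
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$score), .data$gene)
  ranked$rank <- seq_len(nrow(ranked))

  members <- switch(rule,
    top_fraction = {
      check_unit_param(parameter)
      utils::head(ranked, ceiling(parameter * nrow(ranked)))
    },
    score_quantile = {
      check_unit_param(parameter)
      thr <- quantile(ranked$score, parameter, names = FALSE)
      sel <- ranked[ranked$score > thr, , drop = FALSE]
      if (nrow(sel) == 0) {
        warn("no gene scores strictly above the quantile threshold; empty DNB set")
      }
      sel
    },
    knee = {
      s <- ranked$score
      if (length(s) < 3) abort("knee rule needs at least 3 genes")
      d2 <- s[1:(length(s) - 2)] - 2 * s[2:(length(s) - 1)] + s[3:length(s)]
      knee <- which.max(d2) + 1L          # index of the maximum-curvature point
      ranked[ranked$score > s[knee], , drop = FALSE]
    }
  )
  structure(
    list(members = members, rule = rule,
         parameter = if (rule == "knee") NA_real_ else parameter,
         critical_time = critical_time),
    class = "dnb_result"
  )
}

check_unit_param <- function(parameter) {
  if (is.null(parameter) || !is.numeric(parameter) ||
      parameter <= 0 || parameter > 1) {
    abort("`parameter` must be a number in (0, 1]", class = "dnbsle_bad_param")
  }
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("<dnb_result> %d member gene(s); rule %s%s%s\n",
              nrow(x$members), x$rule,
              if (is.na(x$parameter)) "" else sprintf(" (%.3g)", x$parameter),
              if (is.null(x$critical_time)) "" else
                sprintf("; critical time %s", x$critical_time)))
  invisible(x)
}

#' DNB condition statistics of a gene group at one time point
#'
#' The three statistics underlying the dynamic-network-biomarker criteria:
#' `sd_in`, the mean sample standard deviation of the group genes;
#' `pcc_in`, the mean absolute Pearson correlation over within-group gene
#' pairs; and `pcc_out`, the mean absolute correlation between group genes
#' and all non-group genes. The composite index `sd_in * pcc_in / pcc_out`
#' (infinite when `pcc_out` is 0) summarises all three; it is a
#' convenience from classical DNB practice, not part of the condition
#' definitions. Zero-variance genes use the `|PCC| = 0` convention.
#'
#' @param data A [dnb_dataset()].
#' @param group Character vector of group genes (`>= 2`).
#' @param time Time label.
#' @param cohort `"case"` (default; the transition happens in the treated
#'   cells) or `"all"` samples at that time.
#' @return One-row tibble: `time`, `n_samples`, `sd_in`, `pcc_in`,
#'   `pcc_out`, `composite`.
#' @export
dnb_condition_stats <- function(data, group, time, cohort = c("case", "all")) {
  stopifnot(inherits(data, "dnb_dataset"))
  cohort <- match.arg(cohort)
  group <- unique(check_gene_ids(group))
  if (length(group) < 2) abort("group needs at least 2 genes")
  miss <- setdiff(group, dataset_genes(data))
  if (length(miss) > 0) {
    abort(glue("group gene(s) not in the dataset: {toString(head(miss, 5))}"))
  }
  ids <- cohort_samples(data, time = time,
                        group = if (cohort == "case") "case" else NULL)
  if (length(ids) < 3) {
    abort(glue("cohort at time '{time}' has {length(ids)} sample(s); need >= 3"))
  }
  x <- dataset_values(data)[, ids, drop = FALSE]
  out_genes <- setdiff(dataset_genes(data), group)
  cc <- abs_cor_rows(x)
  gi <- match(group, rownames(x))
  sd_in <- mean(apply(x[gi, , drop = FALSE], 1, sd))
  pcc_in <- if (length(gi) > 1) {
    cin <- cc[gi, gi, drop = FALSE]
    mean(cin[upper.tri(cin)])
  } else NA_real_
  pcc_out <- if (length(out_genes) > 0) {
    mean(cc[gi, match(out_genes, rownames(x)), drop = FALSE])
  } else NA_real_
  composite <- if (is.na(pcc_out)) NA_real_
               else if (pcc_out == 0) Inf
               else sd_in * pcc_in / pcc_out
  tibble::tibble(time = time, n_samples = length(ids),
                 sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out,
                 composite = composite)
}

#' Verify the three DNB conditions for a candidate group
#'
#' At the tipping point a dynamic network biomarker group must show, versus
#' every other time point: (1) markedly increased within-group standard
#' deviation; (2) sharply increased within-group correlation; and (3)
#' rapidly decreasing correlation between the group and the rest of the
#' network. The report records the statistic at `t_star`, the extreme of
#' the comparator times, and a strict-inequality verdict per condition,
#' plus the composite index per time.
#'
#' @param data A [dnb_dataset()].
#' @param group Candidate DNB gene set.
#' @param t_star Candidate critical time label.
#' @param cohort Sample cohort, see [dnb_condition_stats()].
#' @return A `dnb_condition_report`: list with `stats` (per-time tibble),
#'   `conditions` (tibble with `condition`, `at_t_star`, `comparator`,
#'   `passed`), `t_star`, `passed` (all three).
#' @export
verify_dnb_conditions <- function(data, group, t_star,
                                  cohort = c("case", "all")) {
  cohort <- match.arg(cohort)
  times <- dataset_times(data)
  has_cohort <- vapply(times, function(tt) {
    length(cohort_samples(data, time = tt,
                          group = if (cohort == "case") "case" else NULL)) >= 3
  }, logical(1))
  times <- times[has_cohort]
  if (!t_star %in% times) {
    abort(glue("t_star '{t_star}' has no scoreable cohort"))
  }
  if (length(times) < 2) abort("need at least 2 time points to compare")
  stats <- dplyr::bind_rows(lapply(times, function(tt) {
    dnb_condition_stats(data, group, tt, cohort)
  }))
  at <- stats[stats$time == t_star, ]
  others <- stats[stats$time != t_star, ]
  conditions <- tibble::tibble(
    condition = c("sd_in_increases", "pcc_in_increases", "pcc_out_decreases"),
    at_t_star = c(at$sd_in, at$pcc_in, at$pcc_out),
    comparator = c(max(others$sd_in), max(others$pcc_in), min(others$pcc_out)),
    passed = c(at$sd_in > max(others$sd_in),
               at$pcc_in > max(others$pcc_in),
               at$pcc_out < min(others$pcc_out))
  )
  structure(
    list(stats = stats, conditions = conditions, t_star = t_star,
         cohort = cohort, passed = all(conditions$passed)),
    class = "dnb_condition_report"
  )
}

#' @export
print.dnb_condition_report <- function(x, ...) {
  cat(sprintf("<dnb_condition_report> t* = %s (%s cohort): %s\n",
              x$t_star, x$cohort,
              if (x$passed) "all three conditions hold" else "conditions NOT all met"))
  print(x$conditions)
  invisible(x)
}
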