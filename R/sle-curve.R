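#' Global SLE score of one case sample
#'
#' Averages the local perturbation scores over the K scoreable local
#' networks of the template:
#' \deqn{\Delta H(t) = \frac{1}{K} \sum_{x=1}^{K} \Delta H(x, t).}
#' Centers with fewer than two neighbours carry no entropy information
#' (`M = 0` is undefined, `M = 1` contributes identically 0); by default
#' they are excluded from both the sum and the divisor K
#' (`divisor = "scoreable"`). Set `divisor = "all"` to divide by the full
#' gene count instead.
#'
#' @param network A `dnb_network`, already restricted to measured genes.
#' @param ref Numeric genes x samples reference matrix (`n >= 3` columns);
#'   rownames must cover the network's nodes.
#' @param case Named numeric vector: one case sample.
#' @param divisor `"scoreable"` (default) or `"all"`.
#' @return List with `score` (the global SLE score) and `locals`, a tibble
#'   of per-center components (`center`, `m`, `h_ref`, `h_mix`, `delta_sd`,
#'   `delta_h`).
#' @export
global_sle <- function(network, ref, case, divisor = c("scoreable", "all")) {
  divisor <- match.arg(divisor)
  res <- global_sle_prepared(prepare_sle(network, rownames(ref)), ref, case)
  k <- switch(divisor, scoreable = sum(res$m >= 2), all = nrow(res))
  if (k == 0) {
    abort("no scoreable local network (every gene has fewer than 2 neighbours)",
          class = "dnbsle_no_scoreable_local")
  }
  list(score = sum(res$delta_h[res$m >= 2]) / k, locals = res)
}

# Precompute the neighbourhood index structure once per dataset.
prepare_sle <- function(network, genes) {
  miss <- setdiff(network_nodes(network), genes)
  if (length(miss) > 0) {
    abort(glue("network gene(s) absent from the expression matrix: {toString(head(miss, 5))}; restrict_to_measured() first"))
  }
  locals <- suppressMessages(local_networks(network))
  centers <- locals$center
  idx <- setNames(seq_along(centers), centers)
  nb_idx <- lapply(locals$neighbors, function(nb) unname(idx[nb]))
  list(centers = centers, nb_idx = nb_idx, m = locals$m)
}

global_sle_prepared <- function(prep, ref, case) {
  refm <- ref[prep$centers, , drop = FALSE]
  Cref <- abs_cor_rows(refm)
  mixm <- cbind(refm, case[prep$centers])
  Cmix <- abs_cor_rows(mixm)
  sd_ref <- apply(refm, 1, sd)
  sd_mix <- apply(mixm, 1, sd)
  dsd <- abs(sd_mix - sd_ref)
  parts <- sle_locals_fast(Cref, Cmix, dsd, prep$nb_idx)
  tibble::tibble(
    center = prep$centers, m = prep$m,
    h_ref = parts$h_ref, h_mix = parts$h_mix,
    delta_sd = dsd, delta_h = parts$delta_h
  )
}

#' Single-sample landscape entropy curve over time
#'
#' Scores every case sample at every time point against its reference
#' cohort and aggregates per time (mean and standard error across case
#' replicates). The time at which the mean global SLE score peaks is the
#' candidate tipping point (see [detect_tipping_point()]).
#'
#' Two reference cohort conventions are supported: `"control_group"`
#' (default) scores the case samples at time t against the reference-group
#' samples measured at the same t; `"baseline_time"` scores every case
#' sample against all samples measured at a fixed baseline time.
#'
#' @param network A `dnb_network`; genes absent from the dataset are
#'   dropped via [restrict_to_measured()].
#' @param data A [dnb_dataset()].
#' @param reference_spec `"control_group"` or `"baseline_time"`.
#' @param baseline_time Time label for `reference_spec = "baseline_time"`;
#'   defaults to the first time level.
#' @param divisor Divisor convention for the global score, see
#'   [global_sle()].
#' @return An object of class `sle_curve` with components:
#'   * `scores`: tibble (`time`, `sample_id`, `score`), one row per case
#'     sample;
#'   * `summary`: tibble (`time`, `mean`, `sem`, `n_case`);
#'   * `locals`: tibble of per-gene local scores per case sample
#'     (`time`, `sample_id`, `center`, `m`, `delta_h`);
#'   * `k`: number of scoreable local networks; `critical_time`: the
#'     detected peak time.
#' @export
sle_curve <- function(network, data,
                      reference_spec = c("control_group", "baseline_time"),
                      baseline_time = NULL,
                      divisor = c("scoreable", "all")) {
  stopifnot(inherits(data, "dnb_dataset"))
  reference_spec <- match.arg(reference_spec)
  divisor <- match.arg(divisor)
  network <- suppressMessages(restrict_to_measured(network, dataset_genes(data)))
  prep <- prepare_sle(network, dataset_genes(data))
  k_div_all <- length(prep$centers)
  k <- sum(prep$m >= 2)
  if (k == 0) {
    abort("no scoreable local network after restriction to measured genes",
          class = "dnbsle_no_scoreable_local")
  }
  kk <- switch(divisor, scoreable = k, all = k_div_all)

  md <- dataset_metadata(data)
  vals <- dataset_values(data)
  times <- dataset_times(data)
  case_times <- times[times %in% md$time[md$group == "case"]]
  no_case <- setdiff(times, case_times)
  if (length(no_case) > 0) {
    abort(glue("time label(s) without case samples: {toString(no_case)}"),
          class = "dnbsle_invalid_data")
  }

  scores <- list(); locals <- list()
  for (tt in case_times) {
    ref_ids <- reference_columns(data, tt, reference_spec, baseline_time)
    refm <- vals[, ref_ids, drop = FALSE]
    case_ids <- cohort_samples(data, time = tt, group = "case")
    for (sid in case_ids) {
      loc <- global_sle_prepared(prep, refm, vals[, sid])
      keep <- loc$m >= 2
      scores[[length(scores) + 1]] <- tibble::tibble(
        time = tt, sample_id = sid, score = sum(loc$delta_h[keep]) / kk)
      locals[[length(locals) + 1]] <- tibble::tibble(
        time = tt, sample_id = sid,
        center = loc$center, m = loc$m, delta_h = loc$delta_h)
    }
  }
  scores <- dplyr::bind_rows(scores)
  summary <- scores |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean = mean(.data$score),
      sem = if (dplyr::n() > 1) sd(.data$score) / sqrt(dplyr::n()) else 0,
      n_case = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$time, times))

  out <- structure(
    list(scores = scores, summary = summary,
         locals = dplyr::bind_rows(locals),
         k = kk, time_levels = times,
         reference_spec = reference_spec, divisor = divisor,
         critical_time = NA_character_),
    class = "sle_curve"
  )
  out$critical_time <- detect_tipping_point(out, quiet = TRUE)
  out
}

#' Detect the tipping point of an SLE curve
#'
#' The critical (pre-transition) time point is the time label at which the
#' mean global SLE score peaks. Ties are broken toward the earliest time in
#' the dataset's time order, with a warning.
#'
#' @param curve An [sle_curve()].
#' @param quiet Suppress the tie warning.
#' @return A single time label.
#' @export
detect_tipping_point <- function(curve, quiet = FALSE) {
  stopifnot(inherits(curve, "sle_curve"))
  sm <- curve$summary
  if (nrow(sm) < 1) abort("empty curve")
  best <- max(sm$mean)
  at <- sm$time[sm$mean == best]
  if (length(at) > 1 && !quiet) {
    warn(glue("tie for the peak SLE score among times {toString(at)}; taking the earliest"))
  }
  at[order(match(at, curve$time_levels))][1]
}

#' Permutation test for the SLE peak height
#'
#' Optional significance check for the detected peak: case/reference group
#' labels are shuffled within each time point (preserving group sizes), the
#' curve is recomputed, and the p-value is the fraction of permutations
#' whose maximal mean score reaches the observed peak. This is an extension
#' for exploratory use; the peak-detection rule itself attaches no p-value.
#'
#' @param network,data,reference_spec,baseline_time,divisor As in
#'   [sle_curve()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed making the permutations reproducible.
#' @return List with `observed` (peak mean score), `p_value`, and
#'   `perm_peaks` (the permutation distribution).
#' @export
peak_significance <- function(network, data, n_perm = 100, seed = 1,
                              reference_spec = c("control_group", "baseline_time"),
                              baseline_time = NULL,
                              divisor = c("scoreable", "all")) {
  reference_spec <- match.arg(reference_spec)
  divisor <- match.arg(divisor)
  obs <- sle_curve(network, data, reference_spec, baseline_time, divisor)
  observed <- max(obs$summary$mean)
  md <- dataset_metadata(data)
  peaks <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- md |>
        dplyr::group_by(.data$time) |>
        dplyr::mutate(group = sample(.data$group)) |>
        dplyr::ungroup()
      pd <- dnb_dataset(dataset_values(data), perm)
      pc <- try(sle_curve(network, pd, reference_spec, baseline_time, divisor),
                silent = TRUE)
      if (inherits(pc, "try-error")) NA_real_ else max(pc$summary$mean)
    }, numeric(1))
  })
  peaks <- peaks[!is.na(peaks)]
  list(observed = observed,
       p_value = (1 + sum(peaks >= observed)) / (1 + length(peaks)),
       perm_peaks = peaks)
}
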