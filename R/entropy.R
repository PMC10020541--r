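#' Absolute Pearson correlation with a zero-variance convention
#'
#' Returns `|r|` for two equal-length vectors. When either vector has zero
#' variance Pearson's r is undefined; the package-wide convention is to
#' return 0 in that case, which keeps the neighbour-weight normalisation
#' total.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A number in `[0, 1]`.
#' @examples
#' pearson_abs(c(1, 2, 3), c(3, 2, 1))  # 1
#' pearson_abs(c(1, 1, 1), c(1, 2, 3))  # 0 by convention
#' @export
pearson_abs <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  r <- suppressWarnings(cor(x, y))
  if (!is.finite(r)) return(0)
  abs(r)
}

#' Neighbour weight vector of a local network
#'
#' For a local network centred on `center` with neighbours `neighbors`, the
#' weight of neighbour i is its absolute Pearson correlation with the
#' center, normalised to sum to one across neighbours:
#' \deqn{p_i = |PCC(g_i, g^x)| / \sum_j |PCC(g_j, g^x)|.}
#' When every `|PCC|` is 0 (normalisation denominator 0) the weights fall
#' back to the uniform distribution `1/M`.
#'
#' @param values Numeric genes x samples matrix (rownames are genes)
#'   holding the cohort over which correlations are computed; at least 3
#'   samples.
#' @param center Center gene identifier.
#' @param neighbors Character vector of neighbour gene identifiers
#'   (`M >= 1`).
#' @return Named numeric vector `p` of length `M`, non-negative, summing
#'   to 1.
#' @export
neighbor_weights <- function(values, center, neighbors) {
  if (length(neighbors) == 0) {
    abort("local network has no neighbours (M = 0); cannot form weights")
  }
  miss <- setdiff(c(center, neighbors), rownames(values))
  if (length(miss) > 0) {
    abort(glue("gene(s) missing from expression matrix: {toString(head(miss, 5))}"))
  }
  if (ncol(values) < 3) abort("need at least 3 samples")
  r <- vapply(neighbors, function(nb) {
    pearson_abs(values[center, ], values[nb, ])
  }, numeric(1))
  weights_from_abs_cor(r)
}

# Shared normalisation (vector of |PCC| -> weights), with uniform fallback.
weights_from_abs_cor <- function(r) {
  s <- sum(r)
  if (s == 0) {
    rep(1 / length(r), length(r))
  } else {
    r / s
  }
}

#' Normalised local network entropy
#'
#' Shannon entropy of the neighbour weight vector, normalised by `log M` so
#' the value lies in `[0, 1]` regardless of neighbourhood size (the log
#' base cancels; natural log is used):
#' \deqn{H = -\frac{1}{\log M} \sum_{i=1}^{M} p_i \log p_i.}
#' Terms with `p_i = 0` contribute 0. For `M = 1` the normaliser vanishes
#' and the entropy is defined as 0.
#'
#' @param p Weight vector summing to 1 (within `1e-9`).
#' @return Entropy in `[0, 1]`.
#' @examples
#' local_entropy(c(0.5, 0.5))  # 1
#' local_entropy(c(1, 0))      # 0
#' @export
local_entropy <- function(p) {
  if (length(p) == 0) abort("empty weight vector")
  if (any(p < 0)) abort("weights must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(glue("weights must sum to 1 (got {format(sum(p), digits = 12)})"))
  }
  if (length(p) == 1) return(0)
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(length(p))
}

#' Standard-deviation shift induced by one case sample
#'
#' `|SD(ref + case) - SD(ref)|`, where both are sample standard deviations
#' (denominator `count - 1`). This is the weight attached to the entropy
#' difference of a local network: it grows when the case value lies far
#' outside the reference spread of the center gene.
#'
#' @param center_values_ref Numeric vector of the center gene's reference
#'   expression values (`n >= 3`).
#' @param case_value Single expression value of the case sample.
#' @return Non-negative number.
#' @export
delta_sd <- function(center_values_ref, case_value) {
  if (length(center_values_ref) < 3) abort("need at least 3 reference values")
  stopifnot(length(case_value) == 1, is.finite(case_value))
  abs(sd(c(center_values_ref, case_value)) - sd(center_values_ref))
}

#' Local single-sample perturbation score of one local network
#'
#' Computes the pair of normalised local entropies -- over the n reference
#' samples and over the n+1 mixed samples obtained by appending the case
#' sample -- and the SD-weighted perturbation
#' \deqn{\Delta H = \Delta SD \; |H^{n+1} - H^{n}|.}
#'
#' @param ref Numeric genes x samples reference matrix (`n >= 3` columns).
#' @param case Named numeric vector: the case sample's expression, covering
#'   center and neighbours.
#' @param center Center gene identifier.
#' @param neighbors Neighbour identifiers (`M >= 2` for a non-trivial
#'   entropy; `M = 1` yields both entropies 0).
#' @return One-row tibble: `center`, `m`, `h_ref`, `h_mix`, `delta_sd`,
#'   `delta_h`.
#' @export
local_perturbation <- function(ref, case, center, neighbors) {
  if (ncol(ref) < 3) abort("need at least 3 reference samples")
  genes <- c(center, neighbors)
  miss <- setdiff(genes, rownames(ref))
  if (length(miss) > 0) {
    abort(glue("gene(s) missing from reference matrix: {toString(head(miss, 5))}"))
  }
  if (!all(genes %in% names(case))) {
    abort("case sample must cover the center and all neighbours")
  }
  mix <- cbind(ref[genes, , drop = FALSE], case[genes])
  h_ref <- local_entropy(neighbor_weights(ref[genes, , drop = FALSE], center, neighbors))
  h_mix <- local_entropy(neighbor_weights(mix, center, neighbors))
  dsd <- delta_sd(ref[center, ], case[[center]])
  tibble::tibble(
    center = center, m = length(neighbors),
    h_ref = h_ref, h_mix = h_mix,
    delta_sd = dsd, delta_h = dsd * abs(h_mix - h_ref)
  )
}

# Fast path used by the curve computation: given precomputed |cor| matrices
# for the reference and mixed cohorts, per-center SD shifts, and an index
# list of neighbourhoods, return per-center delta_h components.
sle_locals_fast <- function(Cref, Cmix, dsd, nb_idx) {
  k <- length(nb_idx)
  h_ref <- h_mix <- numeric(k)
  for (i in seq_len(k)) {
    nb <- nb_idx[[i]]
    h_ref[i] <- entropy_from_r(Cref[i, nb])
    h_mix[i] <- entropy_from_r(Cmix[i, nb])
  }
  list(h_ref = h_ref, h_mix = h_mix, delta_h = dsd * abs(h_mix - h_ref))
}

entropy_from_r <- function(r) {
  m <- length(r)
  if (m < 2) return(0)
  s <- sum(r)
  if (s == 0) return(1)                 # uniform fallback maximises entropy
  p <- r / s
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(m)
}
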