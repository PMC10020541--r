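# Independent, loop-based oracles used across the suite. These deliberately
# avoid the package's own code paths: plain base-R loops transcribing the
# definitions, so agreement is evidence rather than tautology.

# |Pearson r| with the zero-variance-is-zero convention.
oracle_abs_pcc <- function(x, y) {
  r <- suppressWarnings(cor(x, y))
  if (!is.finite(r)) 0 else abs(r)
}

# Normalised local entropy from a weight vector.
oracle_entropy <- function(p) {
  if (length(p) < 2) return(0)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h / log(length(p))
}

# Straight-line transcription of the single-sample landscape entropy score:
# local entropies on the reference and mixed cohorts, SD-shift weights, and
# the mean over centers with at least two neighbours.
# `edges` is a 2-column character matrix; `ref` a genes x n matrix with
# rownames; `case` a named vector.
oracle_global_sle <- function(edges, ref, case) {
  genes <- rownames(ref)
  neighbors_of <- function(g) {
    sort(unique(c(edges[edges[, 1] == g, 2], edges[edges[, 2] == g, 1])))
  }
  entropy_of <- function(mat, center, nbs) {
    r <- vapply(nbs, function(nb) oracle_abs_pcc(mat[center, ], mat[nb, ]),
                numeric(1))
    p <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
    oracle_entropy(p)
  }
  mix <- cbind(ref, case[genes])
  total <- 0; k <- 0
  locals <- list()
  for (g in genes) {
    nbs <- intersect(neighbors_of(g), genes)
    if (length(nbs) < 2) next
    h_ref <- entropy_of(ref, g, nbs)
    h_mix <- entropy_of(mix, g, nbs)
    dsd <- abs(sd(c(ref[g, ], case[[g]])) - sd(ref[g, ]))
    dh <- dsd * abs(h_mix - h_ref)
    locals[[g]] <- dh
    total <- total + dh
    k <- k + 1
  }
  list(score = total / k, k = k, delta_h = unlist(locals))
}

# Random connected-ish test instance: a small random graph plus random
# expression. Returns the pieces both the pipeline and the oracle consume.
random_sle_instance <- function(seed, n_genes = NULL, n_ref = NULL) {
  set.seed(seed)
  n_genes <- n_genes %||% sample(4:12, 1)
  n_ref <- n_ref %||% sample(3:6, 1)
  genes <- sprintf("g%02d", seq_len(n_genes))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.5
  # guarantee at least one scoreable center (two edges at the first gene)
  keep[1:2] <- TRUE
  edges <- pairs[keep, , drop = FALSE]
  ref <- matrix(rnorm(n_genes * n_ref, 10, 2), n_genes,
                dimnames = list(genes, paste0("r", seq_len(n_ref))))
  case <- setNames(rnorm(n_genes, 10, 2), genes)
  list(edges = edges, ref = ref, case = case,
       network = as_dnb_network(as.data.frame(edges)))
}

# Rank-sum AUROC of a score vector against a logical label.
oracle_auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small seeded synthetic study shared by tests.
tiny_study <- function(seed = 7, ...) {
  simulate_dnb_study(synthetic_config(seed = seed, ...))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
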