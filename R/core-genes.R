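#' Annotation tables for core-gene screening
#'
#' Bundles the precomputed annotations the five-criterion core-gene screen
#' consumes: a transcription-factor gene list, a differentially-expressed
#' gene (DEG) list, and a pathway-membership table with a per-pathway
#' significance flag (significance is decided upstream, e.g. enrichment
#' adjusted p < 0.05; this package performs no enrichment testing).
#'
#' @param tf_genes Character vector of TF gene identifiers (may be empty).
#' @param deg_genes Character vector of DEG identifiers (may be empty).
#' @param pathways Data frame with columns `pathway`, `gene`,
#'   `significant` (logical); may have zero rows.
#' @return An `annotation_tables` object.
#' @export
annotation_tables <- function(tf_genes = character(),
                              deg_genes = character(),
                              pathways = NULL) {
  if (is.null(pathways)) {
    pathways <- tibble::tibble(pathway = character(), gene = character(),
                               significant = logical())
  }
  pathways <- tibble::as_tibble(pathways)
  need <- c("pathway", "gene", "significant")
  if (!all(need %in% names(pathways))) {
    abort(glue("pathway table must have columns {toString(need)}"))
  }
  flag <- unique(pathways[, c("pathway", "significant")])
  if (anyDuplicated(flag$pathway)) {
    abort("inconsistent significance flags within a pathway")
  }
  structure(
    list(tf_genes = unique(as.character(tf_genes)),
         deg_genes = unique(as.character(deg_genes)),
         pathways = dplyr::mutate(pathways,
                                  pathway = as.character(.data$pathway),
                                  gene = as.character(.data$gene),
                                  significant = as.logical(.data$significant))),
    class = "annotation_tables"
  )
}

#' Read annotation tables from TSV files
#'
#' Gene lists are single-column files (header optional when the column is
#' named `gene`); the pathway table has columns `pathway`, `gene`,
#' `significant`. Any path may be `NULL` for a missing annotation source.
#'
#' @param tf_path,deg_path,pathway_path File paths or `NULL`.
#' @return An [annotation_tables()] object.
#' @export
read_annotation_tables <- function(tf_path = NULL, deg_path = NULL,
                                   pathway_path = NULL) {
  read_list <- function(path) {
    if (is.null(path)) return(character())
    x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_names = FALSE)
    v <- as.character(x[[1]])
    v[tolower(v) != "gene"]
  }
  pathways <- if (is.null(pathway_path)) NULL else {
    readr::read_tsv(pathway_path, show_col_types = FALSE, comment = "#")
  }
  annotation_tables(read_list(tf_path), read_list(deg_path), pathways)
}

#' Score DNB members on the five core-gene criteria
#'
#' For each DNB member the screen records: (1) `is_tf` -- transcription
#' factor identity; (2) `in_ppi_topk` -- membership in the `topk`
#' highest-ranked genes of a topological analysis of the DNB-member
#' induced subgraph; (3) `kegg_score` -- `ln(1 + c3)` where `c3` counts,
#' summed over significant pathways, the genes of the member's first-order
#' neighbourhood (member included) that lie in the pathway and in the
#' DNB-plus-neighbours universe; (4) `is_deg` -- DEG identity; and (5)
#' `deg_neighbor_score` -- `ln(1 + c5)` where `c5` is the number of DEGs
#' among the member's first-order neighbours. The `ln(1 + count)` form
#' keeps zero-count genes finite.
#'
#' @param dnb A `dnb_result` (or a tibble/character vector of member
#'   genes).
#' @param network A `dnb_network` containing the members (violations are
#'   logged and the genes scored without topology).
#' @param tables An [annotation_tables()] object.
#' @param topk Cutoff for criterion 2 (default 100).
#' @param rank_method Topological score for criterion 2, see
#'   [topological_rank()].
#' @return Tibble with one row per member: `gene`, `is_tf`, `in_ppi_topk`,
#'   `kegg_score`, `is_deg`, `deg_neighbor_score`.
#' @export
score_core_genes <- function(dnb, network, tables, topk = 100,
                             rank_method = c("degree", "mcc")) {
  rank_method <- match.arg(rank_method)
  members <- dnb_member_genes(dnb)
  if (length(members) == 0) abort("empty DNB member list")
  stopifnot(inherits(network, "dnb_network"), inherits(tables, "annotation_tables"))
  nodes <- igraph::V(network$graph)$name
  off_net <- setdiff(members, nodes)
  if (length(off_net) > 0) {
    inform(glue("{length(off_net)} DNB member(s) absent from the network; scored without topology"))
  }
  in_net <- intersect(members, nodes)

  topg <- if (length(in_net) > 0) {
    rk <- topological_rank(network, in_net, method = rank_method)
    utils::head(rk$gene, topk)
  } else character()

  dnb_neighbors <- suppressMessages(first_order_neighbors(network, members))
  universe <- union(members, dnb_neighbors)
  sig_paths <- tables$pathways[tables$pathways$significant, , drop = FALSE]
  path_sets <- split(sig_paths$gene, sig_paths$pathway)

  per_gene <- lapply(members, function(g) {
    nb <- if (g %in% nodes) {
      suppressMessages(first_order_neighbors(network, g))
    } else character()
    hood <- intersect(union(g, nb), universe)
    c3 <- sum(vapply(path_sets, function(pg) length(intersect(pg, hood)),
                     numeric(1)))
    c5 <- length(intersect(nb, tables$deg_genes))
    tibble::tibble(
      gene = g,
      is_tf = g %in% tables$tf_genes,
      in_ppi_topk = g %in% topg,
      kegg_score = log1p(c3),
      is_deg = g %in% tables$deg_genes,
      deg_neighbor_score = log1p(c5)
    )
  })
  dplyr::bind_rows(per_gene)
}

dnb_member_genes <- function(dnb) {
  if (inherits(dnb, "dnb_result")) return(dnb$members$gene)
  if (is.data.frame(dnb)) return(as.character(dnb$gene))
  as.character(dnb)
}

#' Composite ranking of core-gene scores
#'
#' Combines the five criteria into one priority score: boolean criteria
#' contribute 0/1, the two `ln(1 + count)` scores are min-max normalised
#' to `[0, 1]` across the list (a constant column normalises to 0), and
#' the weighted sum is sorted descending. Ties are broken by higher
#' `kegg_score`, then lexicographically. With non-negative weights, adding
#' an annotation to a gene can never lower its composite.
#'
#' @param scores Tibble from [score_core_genes()].
#' @param weights Named numeric vector of non-negative weights for
#'   `is_tf`, `in_ppi_topk`, `kegg_score`, `is_deg`,
#'   `deg_neighbor_score`; default all 1.
#' @param select How many top genes to return (default 8).
#' @return Tibble with `gene`, `composite`, `rank`, the top `select` rows.
#' @export
composite_rank <- function(scores,
                           weights = c(is_tf = 1, in_ppi_topk = 1,
                                       kegg_score = 1, is_deg = 1,
                                       deg_neighbor_score = 1),
                           select = 8) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) abort("empty score list")
  if (select < 1) abort("`select` must be at least 1")
  crit <- c("is_tf", "in_ppi_topk", "kegg_score", "is_deg", "deg_neighbor_score")
  if (!all(crit %in% names(scores))) {
    abort(glue("scores must have columns {toString(crit)}"))
  }
  w <- weights[crit]
  if (anyNA(w) || any(w < 0)) abort("weights must be non-negative and named for all five criteria")

  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  comp <- w[["is_tf"]] * as.numeric(scores$is_tf) +
    w[["in_ppi_topk"]] * as.numeric(scores$in_ppi_topk) +
    w[["kegg_score"]] * minmax(scores$kegg_score) +
    w[["is_deg"]] * as.numeric(scores$is_deg) +
    w[["deg_neighbor_score"]] * minmax(scores$deg_neighbor_score)

  out <- tibble::tibble(gene = scores$gene, composite = comp,
                        kegg_score = scores$kegg_score)
  if (all(out$composite == 0)) {
    warn("all composite scores are zero; returning lexicographic order")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$composite),
                        dplyr::desc(.data$kegg_score), .data$gene)
  out$rank <- seq_len(nrow(out))
  utils::head(dplyr::select(out, "gene", "composite", "rank"), select)
}
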