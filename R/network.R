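#' Build a template interaction network from an edge table
#'
#' A template network is the fixed, undirected gene-interaction graph (for
#' example a STRING protein-protein interaction export) over which local
#' entropies are computed. Self-loops are dropped and duplicate edges --
#' including the same pair listed in swapped order -- are collapsed; when a
#' score column is present, a collapsed edge keeps the maximum score seen.
#'
#' @param edges Data frame with two or three columns: interactor A,
#'   interactor B and an optional numeric confidence score (STRING-style
#'   combined score in `[0, 1000]`).
#' @param score_cutoff Optional numeric; edges with `score < score_cutoff`
#'   are excluded. Requires a score column (ignored, with a warning,
#'   otherwise).
#' @return A `dnb_network` object.
#' @examples
#' net <- as_dnb_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' network_nodes(net)
#' @export
as_dnb_network <- function(edges, score_cutoff = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    abort("edge table needs at least two columns", class = "dnbsle_parse_error")
  }
  a <- check_gene_ids(edges[[1]])
  b <- check_gene_ids(edges[[2]])
  score <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else NULL

  if (!is.null(score_cutoff)) {
    if (is.null(score)) {
      warn("score_cutoff given but the edge table has no score column; ignoring")
    } else {
      keep <- !is.na(score) & score >= score_cutoff
      a <- a[keep]; b <- b[keep]; score <- score[keep]
    }
  }

  keep <- a != b                        # drop self-loops
  a <- a[keep]; b <- b[keep]
  if (!is.null(score)) score <- score[keep]
  if (length(a) == 0) {
    abort("no edges left after filtering; empty network",
          class = "dnbsle_empty_network")
  }

  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (!is.null(score)) {
    mx <- tapply(score, key, max)       # duplicate edge keeps max score
    score <- as.numeric(mx[key[!dup]])
  }
  lo <- lo[!dup]; hi <- hi[!dup]

  el <- cbind(lo, hi)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (!is.null(score)) igraph::E(g)$score <- score
  new_dnb_network(g)
}

new_dnb_network <- function(graph) {
  structure(list(graph = graph), class = "dnb_network")
}

#' Read a template network from an edge-list file
#'
#' Accepts the STRING-export dialect: two or three whitespace- or
#' tab-separated columns (gene A, gene B, optional combined score). A header
#' row is auto-detected (non-numeric third column, or first-row tokens that
#' look like column names such as `gene`, `node`, `protein`, `score`); use
#' `header` to override the guess.
#'
#' @param path Path to the edge-list text file.
#' @param score_cutoff Optional score threshold, see [as_dnb_network()].
#' @param header One of `"auto"`, `"yes"`, `"no"`.
#' @return A `dnb_network`.
#' @export
read_edge_list <- function(path, score_cutoff = NULL,
                           header = c("auto", "yes", "no")) {
  header <- match.arg(header)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    abort("empty edge-list file", class = "dnbsle_empty_network")
  }
  toks <- strsplit(trimws(lines), "[\t ]+")
  nt <- lengths(toks)
  bad <- which(nt < 2 | nt > 3)
  if (length(bad) > 0) {
    abort(glue("malformed edge-list line {bad[1]}: expected 2-3 fields, got {nt[bad[1]]}"),
          class = "dnbsle_parse_error")
  }
  if (header == "auto") {
    first <- tolower(toks[[1]])
    namey <- any(grepl("gene|node|protein|item|interactor|score", first))
    third_nonnum <- length(toks[[1]]) == 3 &&
      is.na(suppressWarnings(as.numeric(toks[[1]][3])))
    header <- if (namey || third_nonnum) "yes" else "no"
  }
  if (header == "yes") {
    toks <- toks[-1]
    if (length(toks) == 0) {
      abort("edge-list file holds only a header row", class = "dnbsle_empty_network")
    }
  }
  n3 <- all(lengths(toks) == 3)
  df <- data.frame(
    a = vapply(toks, `[[`, character(1), 1),
    b = vapply(toks, `[[`, character(1), 2)
  )
  if (n3) df$score <- as.numeric(vapply(toks, `[[`, character(1), 3))
  as_dnb_network(df, score_cutoff = score_cutoff)
}

#' @export
print.dnb_network <- function(x, ...) {
  cat(sprintf("<dnb_network> %d genes, %d interactions%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (!is.null(igraph::E(x$graph)$score)) " (scored)" else ""))
  invisible(x)
}

#' Nodes and edges of a template network
#'
#' @param network A `dnb_network`.
#' @return `network_nodes()`: character vector of gene identifiers, sorted.
#'   `network_edges()`: tibble with columns `from`, `to` (and `score` when
#'   present), each edge once with `from < to`.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "dnb_network"))
  sort(igraph::V(network$graph)$name)
}

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "dnb_network"))
  el <- igraph::as_edgelist(network$graph)
  out <- tibble::tibble(from = pmin(el[, 1], el[, 2]),
                        to = pmax(el[, 1], el[, 2]))
  sc <- igraph::E(network$graph)$score
  if (!is.null(sc)) out$score <- sc
  dplyr::arrange(out, .data$from, .data$to)
}

#' Restrict a template network to measured genes
#'
#' Maps a measured gene set onto the template by taking the induced subgraph
#' on the intersection. Genes measured but absent from the template are
#' reported via a message, not an error; an empty intersection is an error.
#' The operation is idempotent.
#'
#' @param network A `dnb_network`.
#' @param measured Character vector of measured gene identifiers.
#' @return The induced `dnb_network`.
#' @export
restrict_to_measured <- function(network, measured) {
  stopifnot(inherits(network, "dnb_network"))
  measured <- unique(check_gene_ids(measured))
  if (length(measured) == 0) abort("`measured` is empty")
  nodes <- igraph::V(network$graph)$name
  keep <- intersect(nodes, measured)
  if (length(keep) == 0) {
    abort("no measured gene occurs in the template network",
          class = "dnbsle_empty_network")
  }
  missing <- setdiff(measured, nodes)
  if (length(missing) > 0) {
    inform(glue("{length(missing)} measured gene(s) absent from the template network (e.g. {toString(head(missing, 3))})"))
  }
  new_dnb_network(igraph::induced_subgraph(network$graph, keep))
}

#' Extract all local networks
#'
#' A local network is one center gene plus its first-order neighbours in the
#' template network; with K genes in the template there are K local
#' networks. Isolated centers (`m = 0`) are kept in the listing (they are
#' excluded later from entropy scoring, where the normalisation is
#' undefined).
#'
#' @param network A `dnb_network`.
#' @return Tibble with columns `center`, `neighbors` (list column, each a
#'   lexicographically sorted character vector) and `m` (neighbour count),
#'   one row per gene, ordered by `center`.
#' @export
local_networks <- function(network) {
  stopifnot(inherits(network, "dnb_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0) abort("empty network")
  centers <- sort(igraph::V(g)$name)
  nbs <- lapply(centers, function(v) {
    sort(igraph::V(g)$name[igraph::neighbors(g, v)])
  })
  out <- tibble::tibble(center = centers, neighbors = nbs, m = lengths(nbs))
  n_iso <- sum(out$m == 0)
  if (n_iso > 0) {
    inform(glue("{n_iso} isolated gene(s) (no neighbours) will not be entropy-scored"))
  }
  out
}

#' First-order neighbour genes of a query set
#'
#' Returns the union of template-network neighbours of all query genes,
#' minus the query genes themselves. Query genes missing from the network
#' are logged and skipped.
#'
#' @param network A `dnb_network`.
#' @param genes Character vector of query gene identifiers.
#' @return Sorted character vector of neighbour genes.
#' @export
first_order_neighbors <- function(network, genes) {
  stopifnot(inherits(network, "dnb_network"))
  genes <- unique(check_gene_ids(genes))
  nodes <- igraph::V(network$graph)$name
  absent <- setdiff(genes, nodes)
  if (length(absent) > 0) {
    inform(glue("{length(absent)} query gene(s) not in the network; skipped"))
  }
  present <- intersect(genes, nodes)
  if (length(present) == 0) return(character(0))
  nb <- unlist(lapply(present, function(v) {
    igraph::V(network$graph)$name[igraph::neighbors(network$graph, v)]
  }))
  sort(setdiff(unique(nb), genes))
}

#' Topological ranking of a gene set
#'
#' Ranks genes by a hub-ness score computed on the induced subgraph of the
#' query set: `degree` (default) is the within-subgraph node degree; `mcc`
#' is Maximal Clique Centrality, the sum over maximal cliques containing the
#' node of `(clique size - 1)!`. Ties are broken lexicographically. MCC
#' enumeration is limited to subgraphs of at most 5000 nodes.
#'
#' @param network A `dnb_network`.
#' @param genes Character vector of genes to rank; defaults to all nodes.
#' @param method `"degree"` or `"mcc"`.
#' @return Tibble with columns `gene`, `score`, `rank`, sorted by
#'   descending score.
#' @export
topological_rank <- function(network, genes = NULL,
                             method = c("degree", "mcc")) {
  stopifnot(inherits(network, "dnb_network"))
  method <- match.arg(method)
  nodes <- igraph::V(network$graph)$name
  genes <- if (is.null(genes)) nodes else unique(check_gene_ids(genes))
  absent <- setdiff(genes, nodes)
  if (length(absent) > 0) {
    abort(glue("gene(s) not in the network: {toString(head(absent, 5))}"))
  }
  sub <- igraph::induced_subgraph(network$graph, genes)
  score <- switch(method,
    degree = igraph::degree(sub),
    mcc = mcc_scores(sub)
  )
  out <- tibble::tibble(gene = igraph::V(sub)$name, score = as.numeric(score))
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

# Maximal Clique Centrality: MCC(v) = sum over maximal cliques C containing v
# of (|C| - 1)!. Isolated nodes score 0.
mcc_scores <- function(g) {
  if (igraph::vcount(g) > 5000) {
    abort("MCC ranking limited to networks of at most 5000 nodes")
  }
  score <- setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  if (igraph::ecount(g) == 0) return(score)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1)
    nm <- igraph::V(g)$name[cl]
    score[nm] <- score[nm] + w
  }
  score
}

#' Write a network back out as an edge-list TSV
#'
#' @param network A `dnb_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network_edges(network), path)
  invisible(path)
}
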