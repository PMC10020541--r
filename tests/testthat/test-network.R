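edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge-list parsing drops self-loops, applies score cutoffs and detects headers", {
  net <- read_edge_list(edge_file(c("A\tB", "B\tC", "A\tA")))
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_equal(nrow(network_edges(net)), 2)

  net <- read_edge_list(edge_file(c("A\tB\t900", "B\tC\t150")), score_cutoff = 400)
  expect_equal(network_edges(net)$from, "A")
  expect_equal(network_edges(net)$to, "B")

  with_header <- read_edge_list(edge_file(c("gene1\tgene2\tcombined_score",
                                            "A\tB\t800", "B\tC\t700")))
  expect_setequal(network_nodes(with_header), c("A", "B", "C"))

  # space-separated dialect is accepted too
  net <- read_edge_list(edge_file(c("A B", "B C")))
  expect_equal(nrow(network_edges(net)), 2)
})

test_that("malformed and empty edge lists raise informative errors", {
  expect_error(read_edge_list(edge_file(c("A\tB", "A"))), "line 2")
  expect_error(read_edge_list(edge_file(c("A\tB\t1\t9"))), "line 1")
  expect_error(read_edge_list(edge_file("A\tA")), class = "dnbsle_empty_network")
  expect_error(read_edge_list(edge_file(c("A\tB\t10")), score_cutoff = 400),
               class = "dnbsle_empty_network")
})

test_that("duplicate edges, including swapped order, collapse to unique undirected pairs", {
  set.seed(42)
  genes <- sprintf("G%02d", 1:15)
  pairs <- t(combn(genes, 2))
  pick <- pairs[sample(nrow(pairs), 40), , drop = FALSE]
  dups <- pick[sample(40, 10), c(2, 1)]            # swapped duplicates
  lines <- apply(rbind(pick, dups), 1, paste, collapse = "\t")
  net <- read_edge_list(edge_file(sample(lines)))
  # brute-force dedup oracle on sorted pairs
  key <- unique(paste(pmin(pick[, 1], pick[, 2]), pmax(pick[, 1], pick[, 2])))
  expect_equal(nrow(network_edges(net)), length(key))
  expect_equal(nrow(network_edges(net)), 40)
})

test_that("restriction to measured genes is an induced subgraph and idempotent", {
  net <- as_dnb_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  sub <- suppressMessages(restrict_to_measured(net, c("A", "B")))
  expect_equal(network_edges(sub)$from, "A")
  expect_error(suppressMessages(restrict_to_measured(net, c("X", "Y"))),
               class = "dnbsle_empty_network")

  set.seed(9)
  genes <- sprintf("n%03d", 1:100)
  pairs <- t(combn(genes, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.05, , drop = FALSE]
  big <- as_dnb_network(as.data.frame(sel))
  measured <- sample(genes, 60)
  sub <- suppressMessages(restrict_to_measured(big, measured))
  # independent recount of the induced subgraph
  in_sub <- sel[sel[, 1] %in% measured & sel[, 2] %in% measured, , drop = FALSE]
  expect_equal(nrow(network_edges(sub)), nrow(in_sub))
  expect_setequal(network_nodes(sub),
                  intersect(measured, unique(c(sel))))
  again <- suppressMessages(restrict_to_measured(sub, measured))
  expect_equal(network_edges(again), network_edges(sub))
})

test_that("local networks enumerate every center with sorted neighbours", {
  net <- as_dnb_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  loc <- local_networks(net)
  expect_equal(loc$center, c("A", "B", "C"))
  expect_equal(loc$m, c(1L, 2L, 1L))
  expect_equal(loc$neighbors[[2]], c("A", "C"))

  # restriction can isolate a node; it is kept with m = 0 and flagged
  net2 <- as_dnb_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  iso <- suppressMessages(restrict_to_measured(net2, c("A", "B", "D")))
  expect_message(loc2 <- local_networks(iso), "isolated")
  expect_equal(loc2$m[loc2$center == "D"], 0L)
})

test_that("neighbour counts satisfy the handshake identity on random graphs", {
  for (seed in 1:5) {
    inst <- random_sle_instance(seed)
    loc <- suppressMessages(local_networks(inst$network))
    expect_equal(sum(loc$m), 2 * nrow(network_edges(inst$network)))
    # degree oracle from the raw edge list
    deg <- table(c(inst$edges))
    expect_equal(loc$m[match(names(deg), loc$center)], as.integer(deg),
                 ignore_attr = TRUE)
  }
})

test_that("first-order neighbourhoods exclude the query genes", {
  star <- as_dnb_network(data.frame(a = "X", b = c("a", "b", "c")))
  expect_equal(first_order_neighbors(star, "X"), c("a", "b", "c"))
  expect_equal(first_order_neighbors(star, c("a", "b")), "X")

  for (seed in 6:10) {
    inst <- random_sle_instance(seed)
    genes <- rownames(inst$ref)
    query <- sample(genes, 3)
    got <- first_order_neighbors(inst$network, query)
    # brute-force edge scan
    want <- character()
    for (i in seq_len(nrow(inst$edges))) {
      e <- inst$edges[i, ]
      if (e[1] %in% query) want <- c(want, e[2])
      if (e[2] %in% query) want <- c(want, e[1])
    }
    expect_equal(got, sort(setdiff(unique(want), query)))
    expect_length(intersect(got, query), 0)
  }
})

test_that("topological ranking orders by degree or MCC with lexicographic ties", {
  net <- as_dnb_network(data.frame(a = c("A", "B", "C", "D"),
                                   b = c("B", "C", "A", "A")))
  rk <- topological_rank(net, method = "degree")
  expect_equal(rk$gene[1], "A")
  expect_equal(rk$score[1], 3)

  one <- as_dnb_network(data.frame(a = "A", b = "B"))
  solo <- topological_rank(one, genes = "A", method = "degree")
  expect_equal(nrow(solo), 1)
  expect_equal(solo$score, 0)

  # triangle + pendant: MCC(A) = 2! + 1! = 3, B = C = 2, D = 1
  mcc <- topological_rank(net, method = "mcc")
  expect_equal(setNames(mcc$score, mcc$gene),
               c(A = 3, B = 2, C = 2, D = 1))

  set.seed(3)
  genes <- sprintf("v%02d", 1:20)
  pairs <- t(combn(genes, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.2, , drop = FALSE]
  g20 <- as_dnb_network(as.data.frame(sel))
  rk20 <- topological_rank(g20, method = "degree")
  deg <- table(c(sel))
  ord <- order(-as.integer(deg), names(deg))
  expect_equal(rk20$gene, names(deg)[ord])

  expect_error(topological_rank(net, method = "pagerank"))
})
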