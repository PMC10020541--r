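toy_screen <- function() {
  # star: hub H with leaves l1..l3, plus pair A-B off to the side
  net <- as_dnb_network(data.frame(
    a = c("H", "H", "H", "A"),
    b = c("l1", "l2", "l3", "B")))
  tables <- annotation_tables(
    tf_genes = "H",
    deg_genes = c("l1", "l2", "l3"),
    pathways = tibble::tibble(
      pathway = c("p1", "p1", "p1", "p2"),
      gene = c("H", "l1", "l2", "B"),
      significant = c(TRUE, TRUE, TRUE, FALSE)))
  list(net = net, tables = tables)
}

test_that("core-gene criteria count annotations over first-order neighbourhoods", {
  s <- toy_screen()
  sc <- suppressMessages(
    score_core_genes(c("H", "A"), s$net, s$tables, topk = 1))
  h <- sc[sc$gene == "H", ]
  a <- sc[sc$gene == "A", ]

  # gene with no annotations anywhere: all flags false, both ln-scores 0
  expect_false(a$is_tf); expect_false(a$is_deg)
  expect_equal(a$kegg_score, 0)
  expect_equal(a$deg_neighbor_score, 0)

  # hub: 3 DEG neighbours -> ln(1 + 3); significant pathway p1 covers
  # H, l1, l2 inside its neighbourhood -> ln(1 + 3); p2 is not significant
  expect_true(h$is_tf)
  expect_equal(h$deg_neighbor_score, log(4))
  expect_equal(h$kegg_score, log(4))
  expect_error(score_core_genes(character(), s$net, s$tables), "empty")
})

test_that("criterion counts match brute-force set arithmetic on a random fixture", {
  set.seed(21)
  genes <- sprintf("G%02d", 1:20)
  pairs <- t(combn(genes, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.15, , drop = FALSE]
  net <- as_dnb_network(as.data.frame(sel))
  members <- sample(intersect(genes, network_nodes(net)), 8)
  pw <- tibble::tibble(
    pathway = rep(c("p1", "p2", "p3"), each = 7),
    gene = sample(genes, 21, replace = TRUE),
    significant = rep(c(TRUE, TRUE, FALSE), each = 7)) |>
    dplyr::distinct(pathway, gene, .keep_all = TRUE)
  tables <- annotation_tables(sample(genes, 5), sample(genes, 9), pw)
  sc <- suppressMessages(score_core_genes(members, net, tables, topk = 3))

  nb_of <- function(g) sort(unique(c(sel[sel[, 1] == g, 2], sel[sel[, 2] == g, 1])))
  all_nb <- setdiff(unique(unlist(lapply(members, nb_of))), members)
  universe <- union(members, all_nb)
  for (g in members) {
    hood <- intersect(union(g, nb_of(g)), universe)
    c3 <- 0
    for (p in c("p1", "p2")) {
      c3 <- c3 + length(intersect(pw$gene[pw$pathway == p], hood))
    }
    c5 <- length(intersect(nb_of(g), tables$deg_genes))
    expect_equal(sc$kegg_score[sc$gene == g], log1p(c3))
    expect_equal(sc$deg_neighbor_score[sc$gene == g], log1p(c5))
  }
  expect_equal(sum(sc$in_ppi_topk), 3)
})

test_that("composite ranking is a weighted, normalised sum with documented ties", {
  sc <- tibble::tibble(
    gene = c("big", "mid", "zed"),
    is_tf = c(TRUE, FALSE, FALSE),
    in_ppi_topk = c(TRUE, TRUE, FALSE),
    kegg_score = c(2, 1, 0),
    is_deg = c(TRUE, FALSE, FALSE),
    deg_neighbor_score = c(1.5, 0.5, 0))
  out <- composite_rank(sc, select = 3)
  expect_equal(out$gene, c("big", "mid", "zed"))
  expect_equal(out$composite[1], 5)       # all criteria maximal
  expect_equal(out$composite[3], 0)

  # identical records tie and resolve lexicographically
  tie <- sc[c(1, 1), ]; tie$gene <- c("bbb", "aaa")
  out2 <- composite_rank(tie, select = 2)
  expect_equal(out2$gene, c("aaa", "bbb"))

  expect_warning(
    zeroes <- composite_rank(dplyr::mutate(sc, is_tf = FALSE,
                                           in_ppi_topk = FALSE,
                                           kegg_score = 0, is_deg = FALSE,
                                           deg_neighbor_score = 0)),
    "zero")
  expect_equal(zeroes$gene, sort(sc$gene))
})

test_that("adding an annotation never lowers a gene's composite", {
  set.seed(33)
  sc <- tibble::tibble(
    gene = sprintf("g%02d", 1:12),
    is_tf = runif(12) < 0.4,
    in_ppi_topk = runif(12) < 0.4,
    kegg_score = round(runif(12, 0, 3), 2),
    is_deg = runif(12) < 0.4,
    deg_neighbor_score = round(runif(12, 0, 2), 2))
  base <- composite_rank(sc, select = 12)
  for (g in sc$gene[!sc$is_tf][1:3]) {
    bumped <- dplyr::mutate(sc, is_tf = is_tf | gene == g)
    after <- composite_rank(bumped, select = 12)
    expect_gte(after$composite[after$gene == g],
               base$composite[base$gene == g])
  }
})

test_that("a 30-record seeded fixture matches a spreadsheet-style recomputation", {
  set.seed(44)
  sc <- tibble::tibble(
    gene = sprintf("g%02d", 1:30),
    is_tf = runif(30) < 0.3,
    in_ppi_topk = runif(30) < 0.3,
    kegg_score = round(runif(30, 0, 4), 3),
    is_deg = runif(30) < 0.3,
    deg_neighbor_score = round(runif(30, 0, 3), 3))
  out <- composite_rank(sc, select = 30)
  mm <- function(x) (x - min(x)) / (max(x) - min(x))
  manual <- sc$is_tf + sc$in_ppi_topk + mm(sc$kegg_score) + sc$is_deg +
    mm(sc$deg_neighbor_score)
  ord <- order(-manual, -sc$kegg_score, sc$gene)
  expect_equal(out$gene, sc$gene[ord])
  expect_equal(out$composite, manual[ord], tolerance = 1e-12)
})

test_that("annotation readers accept gene lists and a pathway table", {
  dir <- withr::local_tempdir()
  writeLines(c("gene", "A", "B"), file.path(dir, "tf.tsv"))
  writeLines(c("C"), file.path(dir, "deg.tsv"))
  readr::write_tsv(tibble::tibble(pathway = "p1", gene = c("A", "C"),
                                  significant = TRUE),
                   file.path(dir, "pw.tsv"))
  tab <- read_annotation_tables(file.path(dir, "tf.tsv"),
                                file.path(dir, "deg.tsv"),
                                file.path(dir, "pw.tsv"))
  expect_setequal(tab$tf_genes, c("A", "B"))
  expect_equal(tab$deg_genes, "C")
  expect_equal(nrow(tab$pathways), 2)
  expect_error(annotation_tables(pathways = tibble::tibble(
    pathway = c("p", "p"), gene = c("A", "B"), significant = c(TRUE, FALSE))),
    "inconsistent")
})
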