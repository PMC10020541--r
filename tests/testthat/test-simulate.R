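test_that("configuration invariants are enforced", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(m = 1))
  expect_error(synthetic_config(m = 60, K = 60))
  expect_error(synthetic_config(t_star = 6, T = 5))
  expect_error(synthetic_config(sigma_z_peak = 0.2))    # must exceed base
  expect_error(synthetic_config(b_peak = 0.9))          # must drop below base
  expect_error(synthetic_config(n_ref = 2))
})

test_that("network generation is seed-deterministic and plants a connected clique module", {
  cfg <- synthetic_config(K = 10, m = 3, seed = 5)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(network_edges(g1$network), network_edges(g2$network))
  expect_identical(g1$module, g2$module)

  # m = K - 1 on a connected graph succeeds
  big <- generate_network(synthetic_config(K = 8, m = 7, seed = 1))
  expect_length(big$module, 7)

  # connectivity of the planted subgraph, by BFS on the raw edge list
  for (seed in 1:10) {
    gen <- generate_network(synthetic_config(seed = seed))
    el <- as.matrix(network_edges(gen$network)[, c("from", "to")])
    mod <- gen$module
    sub <- el[el[, 1] %in% mod & el[, 2] %in% mod, , drop = FALSE]
    seen <- mod[1]; frontier <- mod[1]
    while (length(frontier) > 0) {
      nxt <- unique(c(sub[sub[, 1] %in% frontier, 2],
                      sub[sub[, 2] %in% frontier, 1]))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    expect_setequal(seen, mod)
    # clique wiring: every module pair is an edge
    want <- t(combn(sort(mod), 2))
    key <- paste(el[, 1], el[, 2])
    expect_true(all(paste(want[, 1], want[, 2]) %in% key))
  }
})

test_that("the closed-form module correlation has the documented limits", {
  expect_equal(expected_module_pcc(1, 2, 0.1, 1), 4.01 / 5.01)
  expect_equal(expected_module_pcc(1, 1, 0.5, 1e-8), 1, tolerance = 1e-6)
  expect_equal(expected_module_pcc(0, 1, 0, 1), 0)
})

test_that("time-course simulation is byte-deterministic and honours the design", {
  cfg <- synthetic_config(K = 20, m = 4, seed = 13)
  gen <- generate_network(cfg)
  a <- simulate_timecourse(gen$network, gen$module, cfg)
  b <- simulate_timecourse(gen$network, gen$module, cfg)
  expect_identical(dataset_values(a$dataset), dataset_values(b$dataset))
  expect_identical(a$truth, b$truth)

  md <- dataset_metadata(a$dataset)
  expect_equal(nrow(md), 5 * (4 + 4))
  expect_equal(a$truth$t_star, "t3")
  expect_equal(a$truth$expected_pcc_peak,
               expected_module_pcc(cfg$a, cfg$sigma_z_peak, cfg$b_peak,
                                   cfg$sigma_eps))
})

test_that("reference samples are drawn from a time-invariant distribution", {
  # large reference cohorts so empirical moments are tight
  cfg <- synthetic_config(K = 10, m = 3, T = 2, t_star = 2,
                          n_ref = 300, n_case = 3, seed = 17)
  study <- simulate_dnb_study(cfg)
  md <- dataset_metadata(study$dataset)
  vals <- dataset_values(study$dataset)
  r1 <- vals[, md$sample_id[md$time == "t1" & md$group == "reference"]]
  r2 <- vals[, md$sample_id[md$time == "t2" & md$group == "reference"]]
  # per-gene means and SDs agree within a few standard errors
  se_mean <- sqrt(2) * apply(vals, 1, sd)[1] / sqrt(300)
  expect_lt(max(abs(rowMeans(r1) - rowMeans(r2))), 6 * se_mean)
  expect_lt(max(abs(apply(r1, 1, sd) - apply(r2, 1, sd))), 0.3)
})

test_that("annotation fixtures are seeded and enrich the module as configured", {
  genes <- sprintf("g%02d", 1:30)
  mod <- genes[1:6]
  a <- make_annotation_fixture(genes, mod, seed = 3)
  b <- make_annotation_fixture(genes, mod, seed = 3)
  expect_identical(a$tf_genes, b$tf_genes)
  expect_identical(a$pathways, b$pathways)
  expect_equal(sort(unique(a$pathways$pathway)), c("pw1", "pw2", "pw3"))
  expect_true(all(mod %in% a$pathways$gene[a$pathways$pathway == "pw1"]))

  none <- make_annotation_fixture(genes, character(), seed = 4)
  expect_s3_class(none, "annotation_tables")

  # realised enrichment: P(TF | module) = 0.5 across 100 seeds
  rate <- mean(vapply(1:100, function(s) {
    fx <- make_annotation_fixture(genes, mod, seed = s)
    mean(mod %in% fx$tf_genes)
  }, numeric(1)))
  expect_lt(abs(rate - 0.5), 0.05)
})

test_that("fixture export writes the pipeline-ready text formats", {
  dir <- withr::local_tempdir()
  study <- tiny_study(seed = 19, K = 12, m = 3, T = 2, t_star = 1)
  write_synthetic_fixture(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "network.tsv", "expression.tsv", "metadata.tsv", "tf.tsv", "deg.tsv",
    "pathways.tsv", "truth.json", "config.yaml")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$t_star, study$truth$t_star)
  reread <- read_expression(file.path(dir, "expression.tsv"),
                            file.path(dir, "metadata.tsv"))
  expect_equal(dataset_values(reread), dataset_values(study$dataset))
})
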