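#' Configuration of the planted-module simulator
#'
#' The simulator draws a K-gene template network, plants a connected
#' m-gene module (additionally wired into a clique so module locals contain
#' module neighbours), and generates a T-point time course from a linear
#' two-factor Gaussian model
#' \deqn{x_{ij} = \mu_i + a \lambda_i z_j + b_i(t) w_j + \epsilon_{ij},}
#' where `z ~ N(0, sigma_z(t)^2)` is shared by module genes within a
#' sample, `w ~ N(0, 1)` is shared by all genes, and `eps ~ N(0,
#' sigma_eps^2)` is independent noise. At the planted critical time
#' `t_star` the module factor SD jumps (`sigma_z_base -> sigma_z_peak`)
#' while the module's loading on the global background drops (`b_base ->
#' b_peak`), which simultaneously raises within-module SD, raises
#' within-module correlation, and lowers module-to-outside correlation --
#' the three DNB conditions. Reference-group samples are always drawn with
#' off-peak parameters (untreated controls never transition).
#'
#' Defaults describe a desk-scale study: 60 genes, a 10-gene module, 5
#' time points with the transition planted at the third, and 4 replicates
#' per group per time.
#'
#' @param K Total gene count.
#' @param m Planted module size (`2 <= m < K`).
#' @param T Number of time points (labels `t1 ... tT`).
#' @param t_star Planted critical time index (1-based, `1 <= t_star <= T`).
#' @param n_ref,n_case Replicates per time per group (`>= 3`).
#' @param a Module factor loading.
#' @param sigma_z_base,sigma_z_peak Module factor SD off/at the critical
#'   time (`sigma_z_peak > sigma_z_base > 0`).
#' @param sigma_eps Independent gene noise SD.
#' @param b_base,b_peak Background loading of module genes off/at the
#'   critical time (`b_peak < b_base`); non-module genes always load
#'   `b_base`.
#' @param network_model `"barabasi_albert"` (default; preferential
#'   attachment, 2 edges per new node, giving the heavy-tailed degree
#'   distribution typical of PPI networks) or `"erdos_renyi"` (random
#'   graph matched to the same expected edge count).
#' @param seed Integer seed; one seed reproduces the dataset byte for
#'   byte.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(K = 60, m = 10, T = 5, t_star = 3,
                             n_ref = 4, n_case = 4,
                             a = 1, sigma_z_base = 0.3, sigma_z_peak = 2,
                             sigma_eps = 1, b_base = 0.8, b_peak = 0.1,
                             network_model = c("barabasi_albert", "erdos_renyi"),
                             seed = 7) {
  network_model <- match.arg(network_model)
  stopifnot(m >= 2, m < K, T >= 1, t_star >= 1, t_star <= T,
            n_ref >= 3, n_case >= 3,
            sigma_z_peak > sigma_z_base, sigma_z_base > 0,
            sigma_eps > 0, b_peak < b_base)
  structure(
    list(K = as.integer(K), m = as.integer(m), T = as.integer(T),
         t_star = as.integer(t_star),
         n_ref = as.integer(n_ref), n_case = as.integer(n_case),
         a = a, sigma_z_base = sigma_z_base, sigma_z_peak = sigma_z_peak,
         sigma_eps = sigma_eps, b_base = b_base, b_peak = b_peak,
         network_model = network_model, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the synthetic template network and planted module
#'
#' Draws a seeded K-node graph from the configured random-graph model,
#' picks the module as the first m genes of a breadth-first search from a
#' random start node (guaranteeing a connected planted subgraph), and
#' wires the module into a clique. Gene identifiers are zero-padded
#' (`g01`, `g02`, ...).
#'
#' @param config A [synthetic_config()].
#' @return List with `network` (a `dnb_network`) and `module` (character
#'   vector of planted genes).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    K <- config$K
    g <- switch(config$network_model,
      barabasi_albert = igraph::sample_pa(K, m = 2, directed = FALSE),
      erdos_renyi = igraph::sample_gnm(K, min(2 * K - 3, choose(K, 2)))
    )
    igraph::V(g)$name <- sprintf(paste0("g%0", nchar(K), "d"), seq_len(K))
    module <- NULL
    for (try in seq_len(50)) {
      start <- sample(K, 1)
      ord <- igraph::bfs(g, start, unreachable = FALSE)$order
      ord <- ord[!is.na(ord)]
      if (length(ord) >= config$m) {
        module <- igraph::V(g)$name[ord[seq_len(config$m)]]
        break
      }
    }
    if (is.null(module)) {
      abort("graph too sparse to host a connected planted module",
            class = "dnbsle_simulation_error")
    }
    clique <- t(utils::combn(module, 2))
    existing <- igraph::as_edgelist(g)
    have <- paste(pmin(existing[, 1], existing[, 2]),
                  pmax(existing[, 1], existing[, 2]))
    want <- paste(pmin(clique[, 1], clique[, 2]),
                  pmax(clique[, 1], clique[, 2]))
    add <- clique[!(want %in% have), , drop = FALSE]
    if (nrow(add) > 0) g <- igraph::add_edges(g, t(add))
    list(network = new_dnb_network(g), module = sort(module))
  })
}

#' Simulate the planted-transition time course
#'
#' Draws the expression dataset under the two-factor model of
#' [synthetic_config()]. Case samples at `t_star` use the peak parameters;
#' all other case samples and every reference sample use the base
#' parameters, so the reference distribution is time-invariant by
#' construction.
#'
#' @param network,module Output of [generate_network()].
#' @param config The same [synthetic_config()].
#' @return List with `dataset` (a [dnb_dataset()]) and `truth` (list:
#'   `module`, `t_star` label, and the closed-form expected within-module
#'   correlations at and off the peak).
#' @export
simulate_timecourse <- function(network, module, config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- sort(igraph::V(network$graph)$name)
  K <- length(genes)
  is_mod <- genes %in% module
  times <- paste0("t", seq_len(config$T))
  t_star_label <- times[config$t_star]

  withr::with_seed(derive_seed(config$seed, 2L), {
    mu <- rnorm(K, 10, 2)                   # log-scale-like gene baselines
    cols <- list(); meta <- list()
    for (ti in seq_len(config$T)) {
      for (grp in c("reference", "case")) {
        n <- if (grp == "reference") config$n_ref else config$n_case
        peaked <- grp == "case" && ti == config$t_star
        sz <- if (peaked) config$sigma_z_peak else config$sigma_z_base
        b_mod <- if (peaked) config$b_peak else config$b_base
        bvec <- ifelse(is_mod, b_mod, config$b_base)
        lam <- ifelse(is_mod, config$a, 0)
        for (s in seq_len(n)) {
          z <- rnorm(1, 0, sz)
          w <- rnorm(1)
          eps <- rnorm(K, 0, config$sigma_eps)
          id <- sprintf("%s_%s_%d", times[ti],
                        if (grp == "reference") "ref" else "case", s)
          cols[[id]] <- mu + lam * z + bvec * w + eps
          meta[[id]] <- tibble::tibble(sample_id = id, time = times[ti],
                                       group = grp)
        }
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    dataset <- dnb_dataset(values, dplyr::bind_rows(meta))
    truth <- list(
      module = sort(module),
      t_star = t_star_label,
      expected_pcc_peak = expected_module_pcc(
        config$a, config$sigma_z_peak, config$b_peak, config$sigma_eps),
      expected_pcc_base = expected_module_pcc(
        config$a, config$sigma_z_base, config$b_base, config$sigma_eps)
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Closed-form within-module correlation of the factor model
#'
#' Under the two-factor model, any two module genes share the factors
#' `a z` and `b w`, so their exact Pearson correlation is
#' \deqn{r = \frac{a^2 \sigma_z^2 + b^2}{a^2 \sigma_z^2 + b^2 + \sigma_\epsilon^2}.}
#'
#' @param a Module factor loading.
#' @param sigma_z Module factor SD.
#' @param b Background loading of module genes.
#' @param sigma_eps Independent noise SD.
#' @return The model correlation in `[0, 1)`.
#' @examples
#' expected_module_pcc(1, 2, 0.1, 1)  # 4.01 / 5.01
#' @export
expected_module_pcc <- function(a, sigma_z, b, sigma_eps) {
  stopifnot(sigma_z > 0, sigma_eps > 0)
  shared <- a^2 * sigma_z^2 + b^2
  shared / (shared + sigma_eps^2)
}

#' Seeded annotation fixture for core-gene screening
#'
#' Draws TF and DEG flags with module genes enriched (by default
#' `P(TF | module) = 0.5` vs 0.1 background, `P(DEG | module) = 0.7` vs
#' 0.15), plus three synthetic pathways: one significant pathway built
#' around the module and its vicinity, one significant random pathway, and
#' one non-significant random pathway.
#'
#' @param genes All gene identifiers.
#' @param module Planted module genes (may be empty: background
#'   probabilities apply everywhere).
#' @param seed Integer seed.
#' @param p_tf_module,p_tf_background TF probabilities.
#' @param p_deg_module,p_deg_background DEG probabilities.
#' @return An [annotation_tables()] object.
#' @export
make_annotation_fixture <- function(genes, module = character(), seed = 1,
                                    p_tf_module = 0.5, p_tf_background = 0.1,
                                    p_deg_module = 0.7, p_deg_background = 0.15) {
  genes <- unique(check_gene_ids(genes))
  is_mod <- genes %in% module
  withr::with_seed(derive_seed(seed, 3L), {
    tf <- genes[rbinom(length(genes), 1,
                       ifelse(is_mod, p_tf_module, p_tf_background)) == 1]
    deg <- genes[rbinom(length(genes), 1,
                        ifelse(is_mod, p_deg_module, p_deg_background)) == 1]
    bg <- setdiff(genes, module)
    pw1 <- union(module, sample(bg, min(length(bg), 5)))
    pw2 <- sample(genes, min(length(genes), 8))
    pw3 <- sample(genes, min(length(genes), 8))
    pathways <- dplyr::bind_rows(
      tibble::tibble(pathway = "pw1", gene = pw1, significant = TRUE),
      tibble::tibble(pathway = "pw2", gene = pw2, significant = TRUE),
      tibble::tibble(pathway = "pw3", gene = pw3, significant = FALSE)
    )
    annotation_tables(tf, deg, pathways)
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: network + module, time course, ground truth and
#' annotation fixture, all from one configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return List: `network`, `module`, `dataset`, `truth`, `annotations`,
#'   `config`.
#' @export
simulate_dnb_study <- function(config = synthetic_config()) {
  net <- generate_network(config)
  tc <- simulate_timecourse(net$network, net$module, config)
  ann <- make_annotation_fixture(sort(igraph::V(net$network$graph)$name),
                                 net$module, seed = config$seed)
  list(network = net$network, module = net$module,
       dataset = tc$dataset, truth = tc$truth,
       annotations = ann, config = config)
}

#' Write a synthetic study to disk as pipeline-ready text files
#'
#' Emits the TSV formats the pipeline reads (network edge list, expression
#' matrix, sample metadata, TF/DEG lists, pathway table), the ground truth
#' as JSON, and a ready-to-run pipeline configuration YAML.
#'
#' @param study Output of [simulate_dnb_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_edge_list(study$network, p("network.tsv"))
  vals <- tibble::as_tibble(study$dataset$values, rownames = "gene")
  readr::write_tsv(vals, p("expression.tsv"))
  readr::write_tsv(dataset_metadata(study$dataset), p("metadata.tsv"))
  readr::write_tsv(tibble::tibble(gene = study$annotations$tf_genes), p("tf.tsv"))
  readr::write_tsv(tibble::tibble(gene = study$annotations$deg_genes), p("deg.tsv"))
  readr::write_tsv(study$annotations$pathways, p("pathways.tsv"))
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- list(
    network = "network.tsv", expression = "expression.tsv",
    metadata = "metadata.tsv", tf = "tf.tsv", deg = "deg.tsv",
    pathways = "pathways.tsv", output_dir = "results",
    reference_spec = "control_group", divisor = "scoreable",
    selection_rule = "top_fraction",
    selection_parameter = study$config$m / study$config$K,
    topk = 100, select = 8, seed = study$config$seed
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
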