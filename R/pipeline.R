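# ---- format plumbing and pipeline orchestration ----

#' Read a compound-target edge table
#'
#' Tab-separated with header: `compound_id`, `target_id`, `score` and
#' optionally `source`.
#'
#' @param path TSV file path.
#' @return edge data frame.
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_edges(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a reference-ligand score table
#'
#' Tab-separated with header: `target_id`, `ref_score`.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_reference_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "ref_score") %in% names(x)))
  x
}

#' Read a target-disease link table
#'
#' Tab-separated with header: `target_id`, `disease`.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_disease_links <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "disease") %in% names(x)))
  x
}

# write a table with stable column order and floats at 6 significant digits
write_table <- function(x, path, sep = ",") {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a bipartite network as GraphML
#'
#' Nodes carry a `partition` attribute (`"compound"`/`"target"`), edges
#' their `score`.
#'
#' @param network graph from [build_network()].
#' @param path output file.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Run the full synthetic-library analysis pipeline
#'
#' Generates a synthetic library under `config`, then runs every stage:
#' descriptor profiling and Rule-of-Five categories, chemical-space PCA,
#' docking-score network construction at the stringent cutoff with
#' centrality, component and scale-free analysis, virtual-screening hit
#' rates, and docking-score-weighted indication prediction. All outputs
#' plus a machine-readable run manifest are written under `out_dir`; the
#' manifest records the seed, configuration and package version, so any
#' output file can be recreated from the manifest alone.
#'
#' @param config [generator_config()] object.
#' @param out_dir output directory (created if needed).
#' @param threshold docking admissibility cutoff for the network and
#'   predictor (default 9).
#' @param screening_threshold permissive cutoff used only for the reported
#'   hit rate (default 7).
#' @param top_k rows of the prediction table to report (default 20).
#' @param pca_k retained principal components (default 3).
#' @return (invisibly) list with every stage result: `descriptors`, `ro5`,
#'   `summary`, `pca`, `scores`, `network`, `stats`, `centrality`,
#'   `ranking`, `power_law`, `hit_rate`, `predictions`, `truth`.
#' @export
run_pipeline <- function(config, out_dir, threshold = 9,
                         screening_threshold = 7, top_k = 20, pca_k = 3) {
  stopifnot(inherits(config, "np_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  # descriptors + drug-likeness
  gen <- gen_descriptor_table(config)
  desc <- gen$descriptors
  write_table(desc, pth("descriptors.csv"))
  ro5 <- ro5_evaluate(desc)
  write_table(ro5, pth("ro5.csv"))
  summ <- library_summary(desc)
  jsonlite::write_json(
    list(n_molecules = summ$n_molecules,
         descriptor_stats = summ$descriptor_stats,
         ro5_categories = as.list(summ$ro5_categories)),
    pth("summary.json"), auto_unbox = TRUE, digits = NA)

  # chemical space
  X <- as.matrix(desc[DESCRIPTOR_COLS])
  pca <- fit_pca(X, k = pca_k)
  scores <- pca_project(pca, X)
  write_table(data.frame(id = desc$id, scores), pth("pca_scores.csv"))
  jsonlite::write_json(
    list(loadings = pca$loadings,
         explained_variance_fraction = pca$explained_variance_fraction,
         training_means = as.list(pca$training_means)),
    pth("pca_model.json"), digits = NA)

  # docking network
  dm <- gen_disease_map(config)
  write_table(dm$edges, pth("docking_scores.tsv"), sep = "\t")
  write_table(dm$reference, pth("reference_scores.tsv"), sep = "\t")
  write_table(dm$links, pth("disease_links.tsv"), sep = "\t")
  net <- build_network(dm$edges, threshold = threshold,
                       reference_scores = dm$reference)
  stats <- network_stats(net)
  centr <- node_centrality(net)
  write_table(centr, pth("centrality.csv"))
  write_network_graphml(net, pth("network.graphml"))
  ranking <- rank_hubs_bottlenecks(centr, top_k = top_k)
  pl <- fit_power_law(centr$degree)
  hr <- hit_rate(dm$edges, screening_threshold, dm$reference)
  hr_strict <- hit_rate(dm$edges, threshold, dm$reference)
  jsonlite::write_json(
    c(stats, list(power_law = unclass(pl),
                  hit_rate_screening = hr, hit_rate_network = hr_strict)),
    pth("network_stats.json"), auto_unbox = TRUE, digits = NA)

  # indication prediction
  pred <- predict_indications(dm$edges, dm$reference, dm$links,
                              threshold = threshold)
  write_table(pred, pth("predictions.csv"))
  write_table(top_predictions(pred, top_k), pth("predictions_top.csv"))

  manifest <- list(
    package = "npnet",
    version = as.character(utils::packageVersion("npnet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = config[setdiff(names(config), "descriptor_params")],
    descriptor_params = config$descriptor_params,
    threshold = threshold,
    screening_threshold = screening_threshold,
    top_k = top_k,
    pca_k = pca_k,
    outputs = c("descriptors.csv", "ro5.csv", "summary.json",
                "pca_scores.csv", "pca_model.json", "docking_scores.tsv",
                "reference_scores.tsv", "disease_links.tsv",
                "centrality.csv", "network.graphml", "network_stats.json",
                "predictions.csv", "predictions_top.csv")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(descriptors = desc, ro5 = ro5, summary = summ, pca = pca,
                 scores = scores, network = net, stats = stats,
                 centrality = centr, ranking = ranking, power_law = pl,
                 hit_rate = c(screening = hr, network = hr_strict),
                 predictions = pred, truth = dm$truth))
}
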