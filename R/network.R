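# ---- bipartite compound-target networks ----

check_edges <- function(edges) {
  stopifnot(is.data.frame(edges))
  need <- c("compound_id", "target_id", "score")
  if (!all(need %in% names(edges))) {
    stop("edge table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(edges) == 0) stop("edge table is empty", call. = FALSE)
  edges
}

# collapse duplicate (compound, target) rows, keeping the best score
aggregate_edges <- function(edges) {
  key <- paste(edges$compound_id, edges$target_id, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  best <- tapply(edges$score, key, max)
  first <- edges[!duplicated(key), , drop = FALSE]
  first$score <- as.numeric(best[paste(first$compound_id, first$target_id,
                                       sep = "\r")])
  rownames(first) <- NULL
  first
}

admissible_edges <- function(edges, threshold, reference_scores) {
  edges <- aggregate_edges(check_edges(edges))
  if (is.null(threshold)) return(edges)
  stopifnot(is.data.frame(reference_scores),
            all(c("target_id", "ref_score") %in% names(reference_scores)))
  miss <- setdiff(unique(edges$target_id), reference_scores$target_id)
  if (length(miss)) {
    stop("no reference score for target(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  ref <- reference_scores$ref_score[match(edges$target_id,
                                          reference_scores$target_id)]
  edges[edges$score > threshold & edges$score > ref, , drop = FALSE]
}

#' Build a bipartite compound-target network
#'
#' Connects compounds to targets from a scored interaction table. With a
#' `threshold`, an edge is admitted only if its score strictly exceeds both
#' the threshold and the reference-ligand score of its target — the
#' admissibility rule used for docking campaigns, where the co-crystallized
#' ligand sets a per-target bar. Duplicate (compound, target) rows are
#' collapsed to their best score first; nodes without any admitted edge are
#' dropped.
#'
#' @param edges data frame with `compound_id`, `target_id`, `score`
#'   (positive, higher = stronger) and optionally `source`.
#' @param threshold admissibility cutoff, or `NULL` (default) to admit all
#'   edges.
#' @param reference_scores data frame `target_id`, `ref_score`; required
#'   when `threshold` is given and must cover every target in `edges`.
#' @return an undirected [igraph] graph with vertex attributes `name`,
#'   `partition` (`"compound"`/`"target"`) and `type` (logical, `TRUE` for
#'   targets), and edge attribute `score`.
#' @export
build_network <- function(edges, threshold = NULL, reference_scores = NULL) {
  adm <- admissible_edges(edges, threshold, reference_scores)
  compounds <- unique(adm$compound_id)
  targets <- unique(adm$target_id)
  clash <- intersect(compounds, targets)
  if (length(clash)) {
    stop("identifiers used for both compounds and targets: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  verts <- data.frame(
    name = c(compounds, targets),
    partition = rep(c("compound", "target"),
                    c(length(compounds), length(targets))),
    type = rep(c(FALSE, TRUE), c(length(compounds), length(targets))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    data.frame(from = adm$compound_id, to = adm$target_id, score = adm$score),
    directed = FALSE, vertices = verts)
}

#' Virtual-screening hit rate
#'
#' Fraction of all distinct compounds in a score table with at least one
#' admissible interaction (score strictly above both the threshold and the
#' target's reference-ligand score).
#'
#' @inheritParams build_network
#' @return a fraction in `[0, 1]`.
#' @export
hit_rate <- function(edges, threshold, reference_scores) {
  all_compounds <- unique(check_edges(edges)$compound_id)
  adm <- admissible_edges(edges, threshold, reference_scores)
  length(unique(adm$compound_id)) / length(all_compounds)
}

#' Degree and betweenness centrality of every node
#'
#' Degree is the neighbor count; betweenness is Brandes shortest-path
#' betweenness normalized by \eqn{(N-1)(N-2)/2}, computed on the full graph
#' so that node pairs in different components simply contribute nothing.
#'
#' @param network graph from [build_network()].
#' @return data frame `node_id`, `partition`, `degree`, `betweenness`.
#' @export
node_centrality <- function(network) {
  stopifnot(igraph::vcount(network) > 0)
  n <- igraph::vcount(network)
  btw <- if (n < 3) rep(0, n) else
    igraph::betweenness(network, directed = FALSE, normalized = TRUE)
  data.frame(
    node_id = igraph::V(network)$name,
    partition = igraph::V(network)$partition,
    degree = as.integer(igraph::degree(network)),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Connected components and giant-component fraction
#'
#' @param network igraph graph.
#' @return list with `sizes` (component sizes, largest first; equal sizes
#'   ordered by their smallest member's node id), `n_components`,
#'   `giant_fraction` and `membership` (named component index per node,
#'   renumbered to the sorted order).
#' @export
graph_components <- function(network) {
  stopifnot(igraph::vcount(network) > 0)
  comp <- igraph::components(network)
  nm <- igraph::V(network)$name
  first_member <- vapply(seq_len(comp$no),
                         function(i) min(nm[comp$membership == i]), character(1))
  ord <- order(-comp$csize, first_member)
  sizes <- comp$csize[ord]
  remap <- match(seq_len(comp$no), ord)
  membership <- stats::setNames(remap[comp$membership], nm)
  list(sizes = as.integer(sizes), n_components = comp$no,
       giant_fraction = max(comp$csize) / igraph::vcount(network),
       membership = membership)
}

#' Mean shortest-path length over connected pairs
#'
#' Unweighted breadth-first distances averaged over all connected unordered
#' node pairs; pairs in different components are excluded, so the value is
#' finite for fragmented networks.
#'
#' @param network igraph graph.
#' @return mean geodesic distance.
#' @export
mean_shortest_path <- function(network) {
  stopifnot(igraph::vcount(network) > 0)
  m <- igraph::mean_distance(network, directed = FALSE, unconnected = TRUE)
  if (!is.finite(m)) stop("network has no connected node pairs", call. = FALSE)
  m
}

#' Network density (general-graph convention)
#'
#' \eqn{2E / (N(N-1))} over all nodes of both partitions, i.e. the density
#' of the graph viewed as a general undirected graph, not the
#' bipartite-specific \eqn{E/(n_c n_t)}.
#'
#' @param network igraph graph with at least two nodes.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(network) {
  stopifnot(igraph::vcount(network) >= 2)
  igraph::edge_density(network)
}

#' Summary statistics of a compound-target network
#'
#' @param network graph from [build_network()].
#' @return list: `n_compounds`, `n_targets`, `n_edges`, `mean_degree`,
#'   `mean_shortest_path`, `density`, `n_components`, `giant_fraction`,
#'   `mean_targets_per_compound`, `mean_hits_per_target`.
#' @export
network_stats <- function(network) {
  part <- igraph::V(network)$partition
  n_c <- sum(part == "compound"); n_t <- sum(part == "target")
  n <- igraph::vcount(network); e <- igraph::ecount(network)
  comp <- graph_components(network)
  list(
    n_compounds = n_c,
    n_targets = n_t,
    n_edges = e,
    mean_degree = 2 * e / n,
    mean_shortest_path = mean_shortest_path(network),
    density = network_density(network),
    n_components = comp$n_components,
    giant_fraction = comp$giant_fraction,
    mean_targets_per_compound = e / n_c,
    mean_hits_per_target = e / n_t
  )
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of `log10(frequency)` on `log10(degree)` over the
#' degrees with nonzero frequency — the conventional log-log regression
#' used to report scale-free behavior of drug-target networks, yielding
#' \eqn{P(x) = a x^{\gamma}}. The exponent is returned with its sign as
#' fitted (negative for decaying distributions).
#'
#' @param degrees integer vector of node degrees (e.g. from
#'   [node_centrality()]; restrict to one partition by subsetting first).
#'   Zero degrees are ignored.
#' @return object of class `np_powerlaw`: `a` (coefficient,
#'   `10^intercept`), `gamma` (slope), `r` (Pearson correlation of the
#'   log-log points), `n_points`.
#' @export
fit_power_law <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) {
    stop("need at least 3 distinct degree values to fit", call. = FALSE)
  }
  lx <- log10(as.numeric(names(tab)))
  ly <- log10(as.numeric(tab))
  fit <- stats::lm(ly ~ lx)
  structure(list(a = 10^unname(stats::coef(fit)[1]),
                 gamma = unname(stats::coef(fit)[2]),
                 r = stats::cor(lx, ly),
                 n_points = length(tab)),
            class = "np_powerlaw")
}

#' @export
print.np_powerlaw <- function(x, ...) {
  cat(sprintf("degree distribution P(x) = %.2f * x^(%.3f), r = %.2f (%d points)\n",
              x$a, x$gamma, abs(x$r), x$n_points))
  invisible(x)
}

#' Rank hubs and bottlenecks
#'
#' Hubs are ranked by degree (ties by betweenness, then id); bottlenecks by
#' betweenness (ties by degree, then id). By default only compound nodes
#' are ranked, the lead-discovery question being which compounds act most
#' promiscuously and most centrally.
#'
#' @param centrality data frame from [node_centrality()].
#' @param top_k rows to return per ranking (default 10).
#' @param partition `"compound"`, `"target"` or `"all"`.
#' @return list with data frames `hubs` and `bottlenecks`.
#' @export
rank_hubs_bottlenecks <- function(centrality, top_k = 10, partition = "compound") {
  stopifnot(is.data.frame(centrality), nrow(centrality) > 0, top_k >= 1)
  partition <- match.arg(partition, c("compound", "target", "all"))
  x <- if (partition == "all") centrality
       else centrality[centrality$partition == partition, , drop = FALSE]
  hub <- x[order(-x$degree, -x$betweenness, x$node_id), , drop = FALSE]
  bot <- x[order(-x$betweenness, -x$degree, x$node_id), , drop = FALSE]
  rownames(hub) <- rownames(bot) <- NULL
  list(hubs = utils::head(hub, top_k), bottlenecks = utils::head(bot, top_k))
}

# ---- analytic identities for published network characteristics ----

#' Density implied by node count and mean degree
#'
#' For any undirected graph, density \eqn{= 2E/(N(N-1))} and mean degree
#' \eqn{= 2E/N}, so density \eqn{=} mean degree \eqn{/(N-1)}. Useful as a
#' consistency check on published network summary tables.
#'
#' @param n_nodes total node count (both partitions).
#' @param mean_degree mean node degree.
#' @return implied density.
#' @export
implied_density <- function(n_nodes, mean_degree) {
  stopifnot(n_nodes >= 2)
  mean_degree / (n_nodes - 1)
}

#' Mean hits per target implied by the edge-count identity
#'
#' In a bipartite network the edge count can be written either way:
#' `mean_targets_per_compound * n_compounds = mean_hits_per_target *
#' n_targets`.
#'
#' @param mean_targets_per_compound mean degree on the compound side.
#' @param n_compounds,n_targets partition sizes.
#' @return implied mean hits per target.
#' @export
implied_hits_per_target <- function(mean_targets_per_compound, n_compounds,
                                    n_targets) {
  mean_targets_per_compound * n_compounds / n_targets
}

#' Published summary characteristics of three drug-target networks
#'
#' Reference values reported in the source study of the UNPD natural-product
#' library for its docking-based network (DTNd), its experimental-affinity
#' network (DTNe) and the approved-drug pharmacological network, used here
#' for analytic consistency checks (see [implied_density()] and
#' [implied_hits_per_target()]).
#'
#' @format data frame with one row per network: `network`, `n_compounds`,
#'   `n_targets`, `mean_degree`, `mean_shortest_path`, `density`,
#'   `mean_targets_per_compound`, `mean_hits_per_target` (the last two are
#'   `NA` where not reported).
#' @export
dtn_reference_stats <- data.frame(
  network = c("DTNd", "DTNe", "DTN_drugs"),
  n_compounds = c(2884, 2840, 1279),
  n_targets = c(243, 1413, 1328),
  mean_degree = c(3.96, 3.56, 3.68),
  mean_shortest_path = c(4.30, 5.95, 7.16),
  density = c(0.0013, 0.0008, 0.0014),
  mean_targets_per_compound = c(2.14, 2.66, NA),
  mean_hits_per_target = c(25, 5.35, NA),
  stringsAsFactors = FALSE
)
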