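# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph's centrality routines): betweenness
# is recomputed from adjacency-matrix walk counts, which equal shortest-path
# counts at the geodesic length.

# normalized shortest-path betweenness via matrix powers; x is an adjacency
# matrix or an igraph graph with at most ~12 nodes
brute_betweenness <- function(x) {
  A <- if (inherits(x, "igraph")) {
    as.matrix(igraph::as_adjacency_matrix(x))
  } else as.matrix(x)
  n <- nrow(A)
  powers <- vector("list", n)
  powers[[1]] <- A
  for (m in seq_len(n - 1)[-1]) powers[[m]] <- powers[[m - 1]] %*% A
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (m in seq_len(n - 1)) {
    newly <- is.infinite(D) & powers[[m]] > 0
    D[newly] <- m
  }
  sigma <- function(i, j) {
    if (i == j) return(1)
    powers[[D[i, j]]][i, j]
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq((s + 1), n)) {
        if (s == v || t == v || is.infinite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
        }
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# random bipartite edge table (guaranteed non-empty)
random_bipartite_edges <- function(n_c, n_t, p = 0.4) {
  grid <- expand.grid(ci = seq_len(n_c), ti = seq_len(n_t))
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) keep[sample.int(nrow(grid), 1)] <- TRUE
  data.frame(
    compound_id = sprintf("c%02d", grid$ci[keep]),
    target_id = sprintf("t%02d", grid$ti[keep]),
    score = stats::runif(sum(keep), 1, 10),
    stringsAsFactors = FALSE
  )
}

write_smiles_file <- function(smiles, ids = NULL, path = tempfile(fileext = ".smi")) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids)
  writeLines(lines, path)
  path
}
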