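#' Global efficiency
#'
#' Mean over all ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0. An integration measure: 1 for a complete
#' graph, 0 for an edgeless one.
#'
#' @param graph `binary_graph` or 0/1 adjacency matrix.
#' @return A number in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  adj <- .bg_adj(graph)
  n <- nrow(adj)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- igraph::distances(.bg_igraph(adj))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (0 for nodes with fewer than 2 neighbors); the system value is
#' the mean over nodes. A segregation measure in the Latora-Marchiori
#' neighborhood-subgraph convention.
#'
#' @param graph `binary_graph` or 0/1 adjacency matrix.
#' @param per_node return the per-node vector instead of the mean?
#' @return The system mean (default) or a per-node numeric vector.
#' @export
local_efficiency <- function(graph, per_node = FALSE) {
  adj <- .bg_adj(graph)
  n <- nrow(adj)
  if (n < 2) stop("local efficiency needs at least 2 nodes")
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  if (per_node) eff else mean(eff)
}

#' Clustering coefficient
#'
#' Per-node fraction of a node's neighbor pairs that are themselves connected
#' (0 for degree < 2), plus the system mean.
#'
#' @param graph `binary_graph` or 0/1 adjacency matrix.
#' @return A list with `per_node` (numeric vector) and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  adj <- .bg_adj(graph)
  if (nrow(adj) < 2) stop("clustering coefficient needs at least 2 nodes")
  cc <- igraph::transitivity(.bg_igraph(adj), type = "localundirected",
                             isolates = "zero")
  cc[is.na(cc)] <- 0
  list(per_node = cc, mean = mean(cc))
}

#' Integration-segregation balance
#'
#' `(e_glob - e_loc) / (e_glob + e_loc)`: positive values indicate a
#' predominance of integrative (global) over segregated (local) processing.
#'
#' @param e_glob global efficiency, >= 0.
#' @param e_loc local efficiency, >= 0.
#' @return A number in \[-1, 1\].
#' @export
system_balance <- function(e_glob, e_loc) {
  if (e_glob < 0 || e_loc < 0) stop("efficiencies must be nonnegative")
  if (e_glob + e_loc == 0)
    stop("balance undefined: both efficiencies are zero")
  (e_glob - e_loc) / (e_glob + e_loc)
}

#' Efficiency profile of a graph at one density
#'
#' Convenience bundle of the system-level metrics used for density selection
#' and lifespan modeling.
#'
#' @param graph `binary_graph`.
#' @return A one-row data.frame: density, e_glob, e_loc, clust_coeff,
#'   balance, lcc_fraction.
#' @export
efficiency_profile <- function(graph) {
  eg <- global_efficiency(graph)
  el <- local_efficiency(graph)
  cc <- clustering_coefficient(graph)$mean
  data.frame(
    density = if (inherits(graph, "binary_graph")) graph$density else NA_real_,
    e_glob = eg, e_loc = el, clust_coeff = cc,
    balance = system_balance(eg, el),
    lcc_fraction = lcc_fraction(graph)
  )
}

#' Select the density balancing integration and modularity
#'
#' Across a sweep of sparsity levels, min-max normalizes the global-efficiency
#' and clustering-coefficient curves over the sweep and returns the density at
#' which the two normalized curves are closest (the crossing point of an
#' increasing integration curve and a decreasing segregation curve). Ties go
#' to the lower density.
#'
#' @param profiles data.frame with columns `density`, `e_glob`, `clust_coeff`
#'   (e.g. rbind of [efficiency_profile()] rows), one row per density.
#' @return The selected density.
#' @export
select_density <- function(profiles) {
  need <- c("density", "e_glob", "clust_coeff")
  if (!all(need %in% names(profiles)))
    stop("profiles must have columns density, e_glob, clust_coeff")
  if (nrow(profiles) < 3)
    stop("density selection needs profiles for at least 3 densities")
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  gap <- abs(norm01(profiles$e_glob) - norm01(profiles$clust_coeff))
  ord <- order(gap, profiles$density)  # ties -> lower density
  profiles$density[ord[1]]
}
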