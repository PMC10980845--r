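# Run fn with a temporary RNG state seeded by `seed` (NULL = leave RNG alone).
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Relabel module ids to 1..K, ordered by decreasing size (ties: first node).
.relabel_modules <- function(assignment) {
  sizes <- table(assignment)
  first <- tapply(seq_along(assignment), assignment, min)
  ord <- names(sizes)[order(-as.integer(sizes), as.integer(first))]
  out <- match(as.character(assignment), ord)
  names(out) <- names(assignment)
  out
}

#' Louvain community detection
#'
#' Partitions a binary (or weighted) graph by greedy Newman-Girvan modularity
#' maximization at resolution `gamma`. Node visitation order is randomized,
#' so `seed` controls the (reproducible) outcome.
#'
#' @param graph `binary_graph`, adjacency matrix, or nonnegative weighted
#'   symmetric matrix.
#' @param gamma resolution parameter (> 0); the pipeline default 1.295
#'   targets resting-state-network granularity on 131-ROI connectomes.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return An object of class `partition`: `assignment` (integer vector,
#'   module ids contiguous from 1), `n_modules`, `gamma`, `quality`
#'   (modularity at `gamma`).
#' @export
louvain_partition <- function(graph, gamma = 1.295, seed = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  adj <- .bg_adj(graph)
  if (nrow(adj) == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE, weighted = TRUE)
  w <- igraph::E(g)$weight
  cl <- .with_seed(seed, function()
    igraph::cluster_louvain(g, weights = w, resolution = gamma))
  assignment <- .relabel_modules(as.integer(igraph::membership(cl)))
  names(assignment) <- rownames(adj)
  structure(
    list(assignment = assignment,
         n_modules = max(assignment),
         gamma = gamma,
         quality = igraph::modularity(g, assignment, weights = w,
                                      resolution = gamma)),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d modules (gamma=%.3f, Q=%.4f)\n",
              length(x$assignment), x$n_modules, x$gamma, x$quality))
  invisible(x)
}

# Co-assignment frequency matrix from a list of assignment vectors.
.coassignment <- function(assignments) {
  n <- length(assignments[[1]])
  acc <- matrix(0, n, n)
  for (a in assignments) {
    acc <- acc + outer(a, a, "==")
  }
  acc / length(assignments)
}

# Iteratively threshold + recluster a co-assignment matrix until it is
# binary and all runs agree (Lancichinetti-Fortunato convention; the
# thresholded matrix is treated as a weighted graph and reclustered at
# resolution 1).
.consensus_iterate <- function(coassign, n_runs, tau, seed, max_iter = 100) {
  n <- nrow(coassign)
  converged <- FALSE
  iter <- 0
  assignments <- NULL
  repeat {
    iter <- iter + 1
    d <- coassign
    d[d < tau] <- 0  # closed threshold: entries >= tau survive
    diag(d) <- 1
    assignments <- lapply(seq_len(n_runs), function(r) {
      p <- louvain_partition(d, gamma = 1,
                             seed = if (is.null(seed)) NULL
                                    else seed + 7919L * iter + r)
      p$assignment
    })
    coassign <- .coassignment(assignments)
    binary <- all(coassign %in% c(0, 1))
    if (binary) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  assignment <- .relabel_modules(assignments[[1]])
  names(assignment) <- rownames(coassign)
  list(assignment = assignment, coassignment = coassign,
       converged = converged, n_iterations = iter)
}

#' Subject-level consensus clustering
#'
#' Runs Louvain `n_runs` times, aggregates the frequency with which node
#' pairs co-assign to the same module, zeroes co-assignment entries below
#' `tau`, and reclusters the thresholded matrix (as a weighted graph, at
#' resolution 1) until the co-assignment matrix is binary and identical
#' across runs.
#'
#' @param graph `binary_graph` or adjacency matrix.
#' @param gamma resolution for the initial Louvain runs (default 1.295).
#' @param n_runs number of Louvain runs per stage (>= 2).
#' @param tau co-assignment threshold in (0, 1); entries below `tau` are
#'   set to 0 (nodes that co-assigned in fewer than `tau` of runs).
#' @param seed integer seed for the whole procedure.
#' @param max_iter cap on consensus iterations; non-convergence returns the
#'   current best with `converged = FALSE`.
#' @return An object of class `consensus_partition` (also a `partition`):
#'   adds `coassignment`, `tau`, `n_iterations`, `converged`.
#' @export
consensus_cluster <- function(graph, gamma = 1.295, n_runs = 100, tau = 0.5,
                              seed = NULL, max_iter = 100) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  adj <- .bg_adj(graph)
  runs <- lapply(seq_len(n_runs), function(r) {
    louvain_partition(adj, gamma = gamma,
                      seed = if (is.null(seed)) NULL else seed + r)$assignment
  })
  coassign <- .coassignment(runs)
  dimnames(coassign) <- dimnames(adj)
  res <- .consensus_iterate(coassign, n_runs = n_runs, tau = tau,
                            seed = seed, max_iter = max_iter)
  structure(
    list(assignment = res$assignment,
         n_modules = max(res$assignment),
         gamma = gamma, quality = NA_real_,
         coassignment = coassign, tau = tau,
         n_iterations = res$n_iterations, converged = res$converged),
    class = c("consensus_partition", "partition")
  )
}

#' Group-level consensus partition
#'
#' Aggregates subject-level partitions into a node x node co-assignment
#' frequency matrix (fraction of subjects assigning a node pair to the same
#' module), thresholds it at `tau`, and reclusters to convergence as in
#' [consensus_cluster()].
#'
#' @param partitions list of `partition` objects (or assignment vectors) over
#'   the same node set.
#' @param tau co-assignment threshold in (0, 1).
#' @param n_runs Louvain runs per reclustering stage.
#' @param seed integer seed.
#' @param max_iter consensus iteration cap.
#' @return A `consensus_partition`.
#' @export
group_consensus <- function(partitions, tau = 0.5, n_runs = 100, seed = NULL,
                            max_iter = 100) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  assignments <- lapply(partitions, function(p) {
    if (inherits(p, "partition")) p$assignment else p
  })
  ns <- vapply(assignments, length, integer(1))
  if (length(unique(ns)) != 1) stop("partitions cover different node sets")
  nms <- lapply(assignments, names)
  if (!is.null(nms[[1]]) &&
      !all(vapply(nms, identical, logical(1), nms[[1]])))
    stop("partitions cover different node sets (names differ)")
  coassign <- .coassignment(assignments)
  if (!is.null(nms[[1]]))
    dimnames(coassign) <- list(nms[[1]], nms[[1]])
  res <- .consensus_iterate(coassign, n_runs = n_runs, tau = tau,
                            seed = seed, max_iter = max_iter)
  structure(
    list(assignment = res$assignment,
         n_modules = max(res$assignment),
         gamma = NA_real_, quality = NA_real_,
         coassignment = coassign, tau = tau,
         n_iterations = res$n_iterations, converged = res$converged),
    class = c("consensus_partition", "partition")
  )
}

#' Resting-state-network composition of subsystems
#'
#' For each module of a partition, the percentage contribution of each
#' resting-state network (RSN), weighting every member node by its percent
#' overlap with its primary RSN. Percentages sum to 100 within each module.
#'
#' @param partition `partition` over the annotated nodes.
#' @param annotation data.frame with columns `roi`, `primary_rsn`,
#'   `percent_overlap` covering every node.
#' @return data.frame: `module`, `rsn`, `percent` (summing to 100 per module).
#' @export
subsystem_composition <- function(partition, annotation) {
  need <- c("roi", "primary_rsn", "percent_overlap")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns roi, primary_rsn, percent_overlap")
  a <- partition$assignment
  rois <- names(a)
  if (is.null(rois)) stop("partition assignment must carry ROI names")
  idx <- match(rois, annotation$roi)
  if (any(is.na(idx))) stop("annotation missing for some ROIs")
  ov <- annotation$percent_overlap[idx]
  if (any(is.na(ov)) || all(ov == 0)) stop("percent_overlap missing or all zero")
  rsn <- annotation$primary_rsn[idx]
  out <- do.call(rbind, lapply(sort(unique(a)), function(m) {
    sel <- a == m
    tot <- sum(ov[sel])
    shares <- tapply(ov[sel], rsn[sel], sum) / tot * 100
    data.frame(module = m, rsn = names(shares), percent = as.numeric(shares),
               row.names = NULL)
  }))
  out
}

#' Drop modules below a minimum size
#'
#' Reporting filter for unstable tiny subsystems: nodes belonging to modules
#' smaller than `min_size` are removed and the remaining module ids
#' relabelled contiguously from 1 (largest first).
#'
#' @param partition `partition` or assignment vector.
#' @param min_size smallest module size kept (default 4).
#' @return Named integer assignment vector over the retained nodes.
#' @export
drop_small_modules <- function(partition, min_size = 4) {
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  sizes <- table(a)
  keep_mods <- as.integer(names(sizes)[sizes >= min_size])
  if (length(keep_mods) == 0) stop("no module reaches min_size")
  out <- a[a %in% keep_mods]
  relab <- .relabel_modules(out)
  names(relab) <- names(out)
  relab
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same node set;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' Used to score recovery of planted modular structure.
#'
#' @param a,b assignment vectors (or `partition` objects) of equal length.
#' @return A number <= 1.
#' @export
adjusted_rand <- function(a, b) {
  if (inherits(a, "partition")) a <- a$assignment
  if (inherits(b, "partition")) b <- b$assignment
  if (length(a) != length(b)) stop("partitions have different lengths")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
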