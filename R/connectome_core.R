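#' Connectivity-matrix container
#'
#' Bundle a subject's symmetric ROI x ROI Fisher-z connectivity matrix with
#' its metadata. The matrix must be square with finite entries; it is checked
#' for symmetry (tolerance `1e-8`) but otherwise stored as given, so a raw
#' matrix (possibly with negative weights) can be wrapped before cleaning.
#'
#' @param values square numeric matrix of Fisher-z correlations.
#' @param roi_labels character vector of ROI names; defaults to the matrix
#'   dimnames or `roi_001 ...` when absent.
#' @param subject_id subject identifier.
#' @param age age in years.
#' @param sex sex code (0/1 or "F"/"M"); stored, not interpreted.
#' @param tiv total intracranial volume (arbitrary positive units).
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, roi_labels = NULL, subject_id = NA_character_,
                        age = NA_real_, sex = NA, tiv = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square")
  if (any(!is.finite(values)))
    stop("connectivity matrix contains non-finite entries")
  n <- nrow(values)
  if (is.null(roi_labels)) {
    roi_labels <- rownames(values)
    if (is.null(roi_labels)) roi_labels <- sprintf("roi_%03d", seq_len(n))
  }
  if (length(roi_labels) != n) stop("roi_labels length != matrix dimension")
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(
    list(values = values, roi_labels = roi_labels, subject_id = subject_id,
         age = age, sex = sex, tiv = tiv),
    class = "conn_matrix"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> subject=%s  %d x %d ROIs  age=%s\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              format(x$age)))
  invisible(x)
}

# Accept either a conn_matrix or a bare matrix; return the numeric matrix.
.cm_values <- function(x) {
  if (inherits(x, "conn_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a `conn_matrix` or a numeric matrix")
}

#' Clean a raw connectivity matrix
#'
#' Zeroes negative correlations, zeroes the diagonal, and symmetrizes by
#' averaging when the asymmetry is within float tolerance. Idempotent: a
#' cleaned matrix passes through unchanged.
#'
#' @param raw square numeric matrix (or `conn_matrix`) of Fisher-z weights.
#' @param asym_tol maximum tolerated `max|A - t(A)|` before averaging;
#'   larger asymmetries abort.
#' @param ... metadata passed on to [conn_matrix()] when `raw` is bare.
#' @return A `conn_matrix` with all entries >= 0 and zero diagonal.
#' @export
clean_matrix <- function(raw, asym_tol = 1e-6, ...) {
  meta <- if (inherits(raw, "conn_matrix")) raw else NULL
  v <- .cm_values(raw)
  if (nrow(v) != ncol(v)) stop("matrix must be square")
  if (any(!is.finite(v))) stop("matrix contains NaN/Inf entries")
  asym <- max(abs(v - t(v)))
  if (asym > asym_tol)
    stop(sprintf("matrix is grossly asymmetric (max|A - t(A)| = %.3g > %.3g)",
                 asym, asym_tol))
  v <- (v + t(v)) / 2
  v[v < 0] <- 0
  diag(v) <- 0
  if (!is.null(meta)) {
    conn_matrix(v, roi_labels = meta$roi_labels, subject_id = meta$subject_id,
                age = meta$age, sex = meta$sex, tiv = meta$tiv)
  } else {
    conn_matrix(v, ...)
  }
}

#' Mean functional connectivity
#'
#' Average of the strictly positive entries of the upper triangle of the
#' unthresholded matrix; the standard per-subject confound covariate for
#' overall coupling strength. Returns 0 when no entry is positive.
#'
#' @param matrix square numeric matrix or `conn_matrix` (cleaned or raw).
#' @return A single number.
#' @export
mean_fc <- function(matrix) {
  v <- .cm_values(matrix)
  ut <- v[upper.tri(v)]
  pos <- ut[ut > 0]
  if (length(pos) == 0) return(0)
  mean(pos)
}

#' Binarized graph at a fixed edge density
#'
#' @param adjacency 0/1 symmetric matrix with zero diagonal.
#' @param density requested edge density.
#' @param n_edges_retained retained edge count in the full-off-diagonal
#'   (directed-entry) convention, i.e. twice the number of undirected pairs.
#' @return An object of class `binary_graph`.
#' @keywords internal
new_binary_graph <- function(adjacency, density, n_edges_retained) {
  structure(
    list(adjacency = adjacency, density = density,
         n_edges_retained = n_edges_retained,
         lcc_fraction = lcc_fraction(adjacency)),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d directed entries (density %.3f), LCC %.1f%%\n",
              nrow(x$adjacency), x$n_edges_retained, x$density,
              100 * x$lcc_fraction))
  invisible(x)
}

.bg_adj <- function(x) {
  if (inherits(x, "binary_graph")) x$adjacency
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a `binary_graph` or a numeric adjacency matrix")
}

.bg_igraph <- function(x) {
  igraph::graph_from_adjacency_matrix(.bg_adj(x), mode = "undirected",
                                      diag = FALSE)
}

#' Proportional threshold and binarize
#'
#' Retains the strongest edges of a cleaned connectivity matrix up to a target
#' count and binarizes. The target follows the full-off-diagonal counting
#' convention: `floor(density * N * (N-1))` directed entries, i.e. that number
#' divided by two (rounded down) undirected pairs. For N = 131 at 15% density
#' this retains 2554 directed entries (1277 undirected edges). Ties at the cut
#' are broken deterministically in (row, column) order.
#'
#' @param matrix cleaned `conn_matrix` or nonnegative symmetric matrix.
#' @param density target edge density in (0, 1).
#' @return A `binary_graph`; its `n_edges_retained` field uses the
#'   directed-entry convention.
#' @export
proportional_threshold <- function(matrix, density) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density >= 1)
    stop("`density` must be a single number in (0, 1)")
  v <- .cm_values(matrix)
  n <- nrow(v)
  if (any(v < 0)) stop("matrix has negative entries; run clean_matrix() first")
  target_directed <- floor(density * n * (n - 1))
  target_pairs <- target_directed %/% 2

  ut_idx <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[upper.tri(v)]
  pos <- which(w > 0)
  if (length(pos) < target_pairs) {
    warning(sprintf(
      "only %d positive edges available for a target of %d; keeping all",
      length(pos), target_pairs))
    keep <- pos
  } else {
    # order by weight desc, then (row, col) for deterministic tie-breaks
    o <- order(-w[pos], ut_idx[pos, 1], ut_idx[pos, 2])
    keep <- pos[o[seq_len(target_pairs)]]
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(v))
  adj[ut_idx[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  new_binary_graph(adj, density = density,
                   n_edges_retained = 2L * length(keep))
}

#' Largest-connected-component fraction
#'
#' Fraction of nodes belonging to the largest connected component of a binary
#' graph. The analysis pipeline flags subjects whose graphs fall below 0.8.
#'
#' @param graph `binary_graph` or 0/1 adjacency matrix.
#' @return A proportion in (0, 1].
#' @export
lcc_fraction <- function(graph) {
  adj <- .bg_adj(graph)
  n <- nrow(adj)
  if (n == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  max(comp$csize) / n
}
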