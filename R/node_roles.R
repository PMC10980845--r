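.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Standardize with population SD; all-equal vectors map to 0.
.standardize <- function(x) {
  s <- .pop_sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Within-module degree z-score (WMZ)
#'
#' For each node, its degree inside its own module standardized against the
#' within-module degree distribution of that module (population SD). High
#' values mark local hubs; modules with zero degree spread (including
#' singletons) yield 0.
#'
#' @param graph `binary_graph` or adjacency matrix.
#' @param partition `partition` (or assignment vector) covering all nodes.
#' @return Per-node numeric vector.
#' @export
within_module_zscore <- function(graph, partition) {
  adj <- .bg_adj(graph)
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  n <- nrow(adj)
  if (length(a) != n) stop("partition does not cover all nodes")
  if (any(table(a) == 1))
    warning("singleton module(s): their nodes get WMZ = 0")
  within_deg <- vapply(seq_len(n), function(i) sum(adj[i, a == a[i]]),
                       numeric(1))
  z <- numeric(n)
  for (m in unique(a)) {
    sel <- a == m
    s <- .pop_sd(within_deg[sel])
    z[sel] <- if (s == 0) 0 else (within_deg[sel] - mean(within_deg[sel])) / s
  }
  names(z) <- rownames(adj)
  z
}

#' Raw participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2`, the dispersion of node i's edges across
#' modules: 0 when all edges stay within one module, approaching `1 - 1/M`
#' when spread evenly over M modules. Isolated nodes get 0 with a warning.
#'
#' @inheritParams within_module_zscore
#' @return Per-node numeric vector in \[0, 1).
#' @export
participation_coefficient <- function(graph, partition) {
  adj <- .bg_adj(graph)
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  n <- nrow(adj)
  if (length(a) != n) stop("partition does not cover all nodes")
  deg <- rowSums(adj)
  if (any(deg == 0)) warning("isolated node(s): PC defined as 0")
  mods <- sort(unique(a))
  # n x M matrix of per-module degrees
  kis <- sapply(mods, function(m) rowSums(adj[, a == m, drop = FALSE]))
  pc <- ifelse(deg == 0, 0, 1 - rowSums((kis / pmax(deg, 1))^2))
  names(pc) <- rownames(adj)
  pc
}

#' Normalized participation coefficient
#'
#' Raw participation coefficient minus its mean under a module-size-preserving
#' null: module labels are randomly permuted across nodes `n_null` times and
#' the raw PC recomputed, removing the bias that large modules mechanically
#' induce in PC.
#'
#' @inheritParams within_module_zscore
#' @param n_null number of label permutations (>= 1; default 100).
#' @param seed integer seed for the permutation null.
#' @return Per-node numeric vector (raw PC minus null-mean PC).
#' @export
participation_coefficient_norm <- function(graph, partition, n_null = 100,
                                           seed = NULL) {
  if (n_null < 1) stop("n_null must be >= 1")
  adj <- .bg_adj(graph)
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  pc <- suppressWarnings(participation_coefficient(adj, a))
  null_mean <- .with_seed(seed, function() {
    acc <- numeric(length(a))
    for (b in seq_len(n_null)) {
      perm <- sample(a)
      acc <- acc + suppressWarnings(participation_coefficient(adj, perm))
    }
    acc / n_null
  })
  out <- pc - null_mean
  names(out) <- rownames(adj)
  out
}

.role_levels <- c("connector", "provincial", "satellite", "peripheral")

#' Assign topological roles
#'
#' Standardizes WMZ and normalized PC across a subject's nodes (population
#' SD) and classifies each node into one of four mutually exclusive roles by
#' threshold quadrants:
#' connector (`z_pc >= 0`, `z_wmz >= 1e-5`), provincial (`z_pc < 0`,
#' `z_wmz >= 1e-5`), satellite (`z_pc >= 0`, `z_wmz < 1e-5`), peripheral
#' (`z_pc < 0`, `z_wmz < 1e-5`). The `1e-5` guard on the standardized WMZ is
#' an "effectively zero" cut kept verbatim from the field's convention.
#'
#' @param wmz per-node within-module degree z-scores.
#' @param pc_norm per-node normalized participation coefficients.
#' @param standardize standardize the two metrics across nodes first
#'   (default TRUE; set FALSE if inputs are already z-scored).
#' @return data.frame: `roi`, `wmz`, `pc_norm`, `z_wmz`, `z_pc_norm`,
#'   `role` (factor with the four role levels).
#' @export
assign_roles <- function(wmz, pc_norm, standardize = TRUE) {
  if (length(wmz) != length(pc_norm))
    stop("wmz and pc_norm differ in length")
  rois <- names(wmz)
  if (is.null(rois)) rois <- sprintf("roi_%03d", seq_along(wmz))
  z_wmz <- if (standardize) .standardize(wmz) else wmz
  z_pc <- if (standardize) .standardize(pc_norm) else pc_norm
  role <- ifelse(z_pc >= 0,
                 ifelse(z_wmz >= 1e-5, "connector", "satellite"),
                 ifelse(z_wmz >= 1e-5, "provincial", "peripheral"))
  data.frame(
    roi = rois, wmz = unname(wmz), pc_norm = unname(pc_norm),
    z_wmz = unname(z_wmz), z_pc_norm = unname(z_pc),
    role = factor(role, levels = .role_levels),
    row.names = NULL
  )
}

#' Compositional role proportions
#'
#' Role counts divided by node counts, at the whole-connectome level and,
#' when a partition is supplied, per subsystem. Each scope's four proportions
#' sum to 1.
#'
#' @param roles data.frame from [assign_roles()].
#' @param partition optional `partition` (or assignment vector) for
#'   per-subsystem scopes.
#' @return data.frame: `scope` ("system" or "module_k"), one column per role,
#'   `n_nodes`.
#' @export
role_composition <- function(roles, partition = NULL) {
  props <- function(r, scope, n) {
    tab <- table(factor(r, levels = .role_levels)) / length(r)
    cbind(data.frame(scope = scope), as.data.frame.matrix(t(as.matrix(tab))),
          data.frame(n_nodes = n))
  }
  out <- props(roles$role, "system", nrow(roles))
  if (!is.null(partition)) {
    a <- if (inherits(partition, "partition")) partition$assignment
         else partition
    if (length(a) != nrow(roles)) stop("partition does not match role table")
    for (m in sort(unique(a))) {
      sel <- a == m
      out <- rbind(out, props(roles$role[sel], sprintf("module_%d", m),
                              sum(sel)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Full nodal role pipeline for one subject
#'
#' Convenience wrapper: WMZ + normalized PC on a common partition, role
#' assignment, and compositional proportions.
#'
#' @inheritParams participation_coefficient_norm
#' @return list with `roles` (per-node table) and `composition`
#'   (per-scope proportions).
#' @export
node_role_profile <- function(graph, partition, n_null = 100, seed = NULL) {
  wmz <- suppressWarnings(within_module_zscore(graph, partition))
  pcn <- participation_coefficient_norm(graph, partition, n_null = n_null,
                                        seed = seed)
  roles <- assign_roles(wmz, pcn)
  a <- if (inherits(partition, "partition")) partition$assignment else partition
  roles$module_id <- as.integer(a)
  list(roles = roles, composition = role_composition(roles, partition))
}
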