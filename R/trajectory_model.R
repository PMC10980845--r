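#' Age-group assignment
#'
#' Bins integer ages into the three lifespan groups used by the trajectory
#' model: younger 18-44, middle-aged 45-55, older > 55 (closed bounds as
#' printed; age 44 is younger, 45 and 55 middle, 56 older).
#'
#' @param ages ages in years.
#' @return factor with levels `younger`, `middle`, `older`.
#' @export
age_group <- function(ages) {
  out <- ifelse(ages <= 44, "younger", ifelse(ages <= 55, "middle", "older"))
  factor(out, levels = c("younger", "middle", "older"))
}

#' Role frequencies per region and age group
#'
#' Empirical fraction of subjects holding each topological role, for each
#' region within each age group.
#'
#' @param role_matrix subjects x regions matrix (or data.frame) of role
#'   labels (`connector`, `provincial`, `satellite`, `peripheral`).
#' @param ages per-subject ages (same order as rows).
#' @return 3-D array `[region, group, role]` of class `role_freq_cube`;
#'   frequencies over roles sum to 1 within each region x group cell.
#' @export
role_frequencies <- function(role_matrix, ages) {
  rm_ <- as.matrix(role_matrix)
  if (nrow(rm_) != length(ages)) stop("ages do not match subjects")
  grp <- age_group(ages)
  if (any(table(grp) == 0))
    stop(sprintf("empty age bin(s): %s",
                 paste(levels(grp)[table(grp) == 0], collapse = ", ")))
  regions <- colnames(rm_)
  if (is.null(regions)) regions <- sprintf("roi_%03d", seq_len(ncol(rm_)))
  cube <- array(
    0, dim = c(ncol(rm_), 3, 4),
    dimnames = list(region = regions, group = levels(grp),
                    role = .role_levels))
  for (g in levels(grp)) {
    sub <- rm_[grp == g, , drop = FALSE]
    for (j in seq_len(ncol(rm_))) {
      tab <- table(factor(sub[, j], levels = .role_levels))
      cube[j, g, ] <- as.numeric(tab) / nrow(sub)
    }
  }
  class(cube) <- c("role_freq_cube", class(cube))
  cube
}

#' Probabilities of role trajectories across age groups
#'
#' For each region, the probability of every role trajectory
#' `r1 -> r2 -> r3` (role in younger, middle, older group) as the outer
#' product of the three group frequency vectors:
#' `P = f_younger(r1) * f_middle(r2) * f_older(r3)`. With 4 roles this gives
#' 16 two-group and 64 three-group trajectories; the 64 probabilities sum to
#' 1 per region.
#'
#' @param cube `role_freq_cube` from [role_frequencies()].
#' @return data.frame of class `trajectory_table`: `region`, `r1`, `r2`,
#'   `r3`, `probability` (64 rows per region).
#' @export
trajectory_probabilities <- function(cube) {
  if (!inherits(cube, "role_freq_cube")) stop("expected a role_freq_cube")
  regions <- dimnames(cube)$region
  grid <- expand.grid(r1 = .role_levels, r2 = .role_levels,
                      r3 = .role_levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_along(regions), function(j) {
    p <- cube[j, "younger", grid$r1] * cube[j, "middle", grid$r2] *
      cube[j, "older", grid$r3]
    data.frame(region = regions[j], grid, probability = as.numeric(p),
               row.names = NULL)
  }))
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Select the most likely trajectories per region
#'
#' Keeps, for each region, the maximum-probability trajectory plus every
#' trajectory whose probability falls within `tolerance` of that maximum.
#' The tolerance is read as an absolute probability-point difference
#' (`p_max - p <= tolerance`) by default; set `relative = TRUE` for the
#' proportional reading (`p >= (1 - tolerance) * p_max`).
#'
#' @param table `trajectory_table` from [trajectory_probabilities()].
#' @param tolerance selection band (default 0.05).
#' @param relative use the relative reading of the band?
#' @return The table with a logical `selected` column; the argmax is always
#'   selected, ties all kept.
#' @export
select_trajectories <- function(table, tolerance = 0.05, relative = FALSE) {
  if (!inherits(table, "trajectory_table")) stop("expected a trajectory_table")
  sel <- logical(nrow(table))
  for (reg in unique(table$region)) {
    i <- which(table$region == reg)
    p <- table$probability[i]
    pmax_ <- max(p)
    keep <- if (relative) p >= (1 - tolerance) * pmax_
            else pmax_ - p <= tolerance
    sel[i] <- keep
  }
  table$selected <- sel
  table
}

#' Summarize topological reconfiguration
#'
#' From the selected trajectories, flags regions whose role changes across
#' age groups and aggregates reconfiguration shares globally and (when a
#' partition is given) per subsystem. A region "reconfigures" when any of
#' its selected trajectories is non-constant; counts based on the argmax
#' trajectory alone are reported alongside, and transition classes
#' (e.g. provincial -> connector) are tallied over non-constant selected
#' trajectories together with the share of reconfigurations gaining each
#' role.
#'
#' @param table `trajectory_table` with a `selected` column
#'   (see [select_trajectories()]).
#' @param partition optional `partition`/assignment over the regions for
#'   per-subsystem shares.
#' @return list: `regions` (per-region flags), `fraction_reconfiguring`,
#'   `n_reconfiguring`, `fraction_reconfiguring_argmax`, `n_selected`,
#'   `per_module` (data.frame or NULL), `transition_classes` (counts of
#'   r1 -> r3 transitions among non-constant selected trajectories),
#'   `role_gain_shares` (share of reconfiguring regions whose argmax
#'   trajectory ends in each role after a change).
#' @export
summarize_reconfiguration <- function(table, partition = NULL) {
  if (is.null(table$selected))
    stop("run select_trajectories() first")
  is_const <- table$r1 == table$r2 & table$r2 == table$r3
  regions <- unique(table$region)
  per_region <- do.call(rbind, lapply(regions, function(reg) {
    i <- which(table$region == reg & table$selected)
    j <- i[which.max(table$probability[i])]
    data.frame(
      region = reg,
      reconfigures = any(!is_const[i]),
      reconfigures_argmax = !is_const[j],
      argmax_r1 = table$r1[j], argmax_r3 = table$r3[j],
      n_selected = length(i),
      row.names = NULL
    )
  }))
  nonconst_sel <- table$selected & !is_const
  trans <- table(paste(table$r1[nonconst_sel], "->", table$r3[nonconst_sel]))
  gain <- per_region[per_region$reconfigures_argmax, , drop = FALSE]
  gain_tab <- if (nrow(gain))
    table(factor(gain$argmax_r3, levels = .role_levels)) / nrow(gain)
  else table(factor(character(0), levels = .role_levels))
  per_module <- NULL
  if (!is.null(partition)) {
    a <- if (inherits(partition, "partition")) partition$assignment
         else partition
    if (is.null(names(a))) stop("partition must carry region names")
    idx <- match(per_region$region, names(a))
    if (any(is.na(idx))) stop("partition does not cover all regions")
    mod <- a[idx]
    per_module <- do.call(rbind, lapply(sort(unique(mod)), function(m) {
      sel <- mod == m
      data.frame(module = m,
                 n_regions = sum(sel),
                 fraction_reconfiguring =
                   mean(per_region$reconfigures[sel]),
                 row.names = NULL)
    }))
  }
  list(
    regions = per_region,
    fraction_reconfiguring = mean(per_region$reconfigures),
    n_reconfiguring = sum(per_region$reconfigures),
    fraction_reconfiguring_argmax = mean(per_region$reconfigures_argmax),
    n_selected = sum(table$selected),
    per_module = per_module,
    transition_classes = trans,
    role_gain_shares = gain_tab
  )
}
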