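#!/usr/bin/env Rscript
# Probabilistic role trajectories: per-region role frequencies within the
# younger (18-44), middle-aged (45-55) and older (>55) groups, outer-product
# probabilities over the 64 role trajectories, selection within the 5%
# band, and the reconfiguration summary.

library(lifeconn)

roles <- read.delim("results/roles.tsv")
participants <- read.delim("results/cohort/participants.tsv")
part_df <- read.delim("results/partition.tsv")
partition <- part_df$module_id
names(partition) <- part_df$roi

role_mat <- do.call(rbind, lapply(split(roles, roles$subject_id),
                                  function(d) d$role[order(d$roi)]))
colnames(role_mat) <- sort(unique(roles$roi))
ages <- participants$age[match(rownames(role_mat),
                               participants$subject_id)]

cube <- role_frequencies(role_mat, ages)
traj <- select_trajectories(trajectory_probabilities(cube), tolerance = 0.05)
summ <- summarize_reconfiguration(traj, partition)

write.table(traj, "results/trajectories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ$regions, "results/reconfiguration_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(summ$per_module))
  write.table(summ$per_module, "results/reconfiguration_summary.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Regions reconfiguring (any selected trajectory non-constant): %d/%d (%.1f%%)\n",
            summ$n_reconfiguring, nrow(summ$regions),
            100 * summ$fraction_reconfiguring))
cat(sprintf("Regions reconfiguring by argmax trajectory only: %.1f%%\n",
            100 * summ$fraction_reconfiguring_argmax))
cat(sprintf("Selected trajectories in total (5%% band): %d\n",
            summ$n_selected))
if (!is.null(summ$per_module)) {
  for (i in seq_len(nrow(summ$per_module)))
    cat(sprintf("  module %d: %.1f%% of %d regions reconfigure\n",
                summ$per_module$module[i],
                100 * summ$per_module$fraction_reconfiguring[i],
                summ$per_module$n_regions[i]))
}
if (length(summ$transition_classes)) {
  cat("Top transition classes:\n")
  tc <- sort(summ$transition_classes, decreasing = TRUE)
  for (i in seq_len(min(4, length(tc))))
    cat(sprintf("  %s: %d\n", names(tc)[i], tc[i]))
}
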