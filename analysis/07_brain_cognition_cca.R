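#!/usr/bin/env Rscript
# Brain-cognition canonical correlation analysis: the brain set holds the
# per-subsystem log-odds role proportions plus the system balance; the
# cognitive set holds the eight z-scored task scores with two orthogonal
# midlife age contrasts prepended. Both sets are confound-residualized
# (mean FC, sex, TIV); robustness via 10-fold cross-validation and
# bootstrap intervals; named neural mechanisms are scored as structure-
# coefficient differences.

library(lifeconn)

comp <- read.delim("results/composition.tsv")
metrics <- read.delim("results/metrics.tsv")
participants <- read.delim("results/cohort/participants.tsv")
cognition <- read.delim("results/cohort/cognition.tsv")
rsn <- read.delim("results/composition_rsn.tsv")
density <- as.numeric(readLines("results/selected_density.txt"))
roles4 <- c("connector", "provincial", "satellite", "peripheral")

## brain matrix: per-module log-odds role proportions + balance ------------
mods <- sort(unique(comp$scope[grepl("^module_", comp$scope) &
                                 comp$n_nodes >= 4]))
wide <- NULL
ids <- sort(unique(comp$subject_id))
for (m in mods) {
  d <- comp[comp$scope == m, ]
  d <- d[match(ids, d$subject_id), ]
  imp <- impute_zero_proportions(as.matrix(d[, roles4]))
  cols <- logodds(imp)
  colnames(cols) <- paste(m, roles4, sep = ":")
  wide <- cbind(wide, cols)
}
m15 <- metrics[metrics$density == density, ]
X <- cbind(wide, balance = m15$balance[match(ids, m15$subject_id)])

## cognitive matrix: exclusion, imputation, z-scoring, age contrasts -------
ages_all <- participants$age[match(cognition$subject_id,
                                   participants$subject_id)]
prep <- prepare_cognitive(cognition, ages_all)
keep <- match(prep$subject_id, ids)
X <- X[keep[!is.na(keep)], , drop = FALSE]
retained <- prep$subject_id[!is.na(keep)]
Yt <- prep$matrix[!is.na(keep), , drop = FALSE]
ages <- prep$ages[!is.na(keep)]
contrasts <- build_age_contrasts(ages)

## confound residualization -------------------------------------------------
pinfo <- participants[match(retained, participants$subject_id), ]
conf <- cbind(mean_fc = m15$mean_fc[match(retained, m15$subject_id)],
              sex = pinfo$sex, tiv = pinfo$tiv)
Xr <- residualize_confounds(X, conf)
Yr <- cbind(contrasts, residualize_confounds(Yt, conf))

fit <- fit_cca(Xr, Yr)
val <- validate_cca(Xr, Yr, folds = 10, boots = 1000, seed = 99)

## mechanisms: map modules to their dominant RSN ----------------------------
dom <- sapply(split(rsn, rsn$module), function(d) d$rsn[which.max(d$percent)])
mech <- list()
dmn_mod <- names(dom)[dom == "DMN"][1]
fpn_mod <- names(dom)[dom == "FPN"][1]
if (!is.na(dmn_mod))
  mech$dmn_deactivation <- paste0("module_", dmn_mod, ":",
                                  c("peripheral", "satellite"))
if (!is.na(fpn_mod))
  mech$fpn_integration <- paste0("module_", fpn_mod, ":",
                                 c("connector", "provincial"))
ms <- if (length(mech)) mechanism_scores(fit, mech) else NULL

## outputs ------------------------------------------------------------------
dir.create("results", showWarnings = FALSE)
cca_json <- list(rc = fit$rc, wilks = fit$wilks, p_values = fit$p_values,
                 cv_mean_oof = val$cv_mean)
jsonlite::write_json(cca_json, "results/cca_model.json", auto_unbox = TRUE,
                     digits = NA)
sc <- data.frame(variable = rownames(fit$structure_x), set = "brain",
                 fit$structure_x, check.names = FALSE)
sc <- rbind(sc, data.frame(variable = rownames(fit$structure_y),
                           set = "cognitive", fit$structure_y,
                           check.names = FALSE))
write.table(sc, "results/structure_coefficients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(ms))
  write.table(ms, "results/mechanisms.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)

cat(sprintf("CCA on %d subjects: pX=%d, pY=%d, %d canonical functions\n",
            nrow(Xr), ncol(Xr), ncol(Yr), length(fit$rc)))
for (j in 1:3)
  cat(sprintf("  cf%d: Rc=%.3f (Rc^2=%.1f%%), Wilks=%.3f, p=%.3g, out-of-fold Rc=%.3f\n",
              j, fit$rc[j], 100 * fit$rc[j]^2, fit$wilks[j],
              fit$p_values[j], val$cv_mean[j]))
if (!is.null(ms)) {
  cat("Mechanism scores (structure-coefficient differences), cf1/cf2:\n")
  for (nm in unique(ms$mechanism)) {
    d <- ms[ms$mechanism == nm, ]
    cat(sprintf("  %s: %.3f / %.3f\n", nm, d$score[1], d$score[2]))
  }
}
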