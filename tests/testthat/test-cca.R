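test_that("cognitive preparation applies exclusion, imputation and z-scoring", {
  set.seed(12)
  n <- 60
  scores <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       matrix(rnorm(n * 8, 10, 3), n, 8))
  names(scores)[-1] <- sprintf("task%d", 1:8)
  ages <- sort(round(runif(n, 18, 88)))
  scores[1, 2:5] <- NA                      # 4 missing -> excluded
  scores[2, 2] <- NA                        # 1 missing -> imputed

  prep <- prepare_cognitive(scores, ages)
  expect_equal(prep$excluded$subject_id, "s01")
  expect_equal(prep$excluded$n_missing, 4)
  expect_equal(nrow(prep$matrix), n - 1)
  expect_equal(prep$n_imputed, 1L)
  expect_equal(unname(colMeans(prep$matrix)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(prep$matrix, 2, sd)), rep(1, 8), tolerance = 1e-12)

  # imputed value equals the age-decile median of the retained sample
  kept <- scores[-1, ]; kept_ages <- ages[-1]
  qs <- quantile(kept_ages, probs = seq(0, 1, 0.1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  dec <- cut(kept_ages, breaks = unique(qs), include.lowest = TRUE)
  med <- median(kept$task1[dec == dec[1]], na.rm = TRUE)
  # reconstruct on the raw scale: z * sd + mean over the post-imputation column
  col <- kept$task1; col[1] <- med
  expect_equal(unname(prep$matrix[1, "task1"]), (med - mean(col)) / sd(col))

  # complete data: imputation is the identity
  complete <- scores[-(1:2), ]
  prep2 <- prepare_cognitive(complete, ages[-(1:2)])
  expect_equal(prep2$n_imputed, 0L)
  expect_equal(nrow(prep2$excluded), 0)
})

test_that("midlife age contrasts follow the published coding and orthogonality", {
  out <- build_age_contrasts(c(47, 53, 58, 30))
  # raw codes (-1,-1,+2,0) and (-1,+1,0,0) are already centered here
  expect_equal(unname(out[, "contrast1"]), c(-1, -1, 2, 0))
  expect_equal(unname(out[, "contrast2"]), c(-1, 1, 0, 0))

  # balanced design: centered columns orthogonal
  ages <- rep(c(47, 53, 58, 30), each = 5)
  outb <- build_age_contrasts(ages)
  expect_equal(sum(outb[, 1] * outb[, 2]), 0, tolerance = 1e-12)
  expect_equal(mean(outb[, 1]), 0, tolerance = 1e-12)

  expect_error(build_age_contrasts(c(20, 30, 70)), "degenerate")
})

test_that("confound residualization orthogonalizes against the confounds", {
  set.seed(7)
  n <- 100
  conf <- cbind(mean_fc = rnorm(n), sex = rbinom(n, 1, 0.5),
                tiv = rnorm(n, 1500, 100))
  # column that is an exact linear function of tiv -> residual ~ 0
  m <- cbind(a = rnorm(n), b = 2 * conf[, "tiv"] - 5)
  res <- residualize_confounds(m, conf)
  expect_lt(max(abs(res[, "b"])), 1e-8)
  # residuals orthogonal to each confound
  for (j in 1:3) {
    expect_lt(abs(sum(res[, "a"] * scale(conf[, j], scale = FALSE))), 1e-8)
  }
  # column orthogonal to confounds passes through (centered)
  ortho <- residuals(lm(rnorm(n) ~ conf))
  res2 <- residualize_confounds(cbind(o = ortho), conf)
  expect_equal(unname(res2[, 1]), unname(ortho), tolerance = 1e-10)
  expect_error(residualize_confounds(m, cbind(conf, conf[, 1])), "collinear")
})

test_that("CCA matches stats::cancor and its own invariants on random data", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rnorm(n * 3), n, 3)
  fit <- fit_cca(X, Y)
  ref <- cancor(scale(X), scale(Y))
  expect_equal(fit$rc, ref$cor, tolerance = 1e-10)
  expect_equal(length(fit$rc), 3)
  expect_true(all(diff(fit$rc) <= 1e-12))

  # Wilks identity
  expect_equal(fit$wilks, rev(cumprod(rev(1 - fit$rc^2))), tolerance = 1e-10)

  # structure coefficients are plain correlations with the variates
  expect_equal(unname(fit$structure_x), unname(cor(X, fit$x_variates)), tolerance = 1e-12)
  expect_equal(unname(fit$structure_y), unname(cor(Y, fit$y_variates)), tolerance = 1e-12)
  expect_equal(unname(fit$cross), unname(cor(X, fit$y_variates)), tolerance = 1e-12)
  expect_true(all(abs(fit$structure_x) <= 1 + 1e-12))

  # invariance to invertible linear rescaling within a set
  A <- diag(c(2, -1, 0.5, 3, 1)) ; A[1, 2] <- 0.3
  fit2 <- fit_cca(X %*% A, Y)
  expect_equal(fit2$rc, fit$rc, tolerance = 1e-8)

  # shared column forces Rc1 = 1
  Y2 <- cbind(X[, 1], matrix(rnorm(n * 2), n, 2))
  expect_equal(fit_cca(X, Y2)$rc[1], 1, tolerance = 1e-8)

  expect_error(fit_cca(X[1:4, ], Y[1:4, ]), "too few")
  expect_error(fit_cca(cbind(X, X[, 1]), Y), "rank-deficient")
})

test_that("variate sign convention orients the leading cognitive variable positively", {
  set.seed(33)
  sim <- simulate_cca_data(300, latent_r = 0.6, seed = 33)
  fit <- fit_cca(sim$X, sim$Y)
  for (j in seq_along(fit$rc)) {
    lead <- which.max(abs(fit$structure_y[, j]))
    expect_gte(fit$structure_y[lead, j], 0)
  }
})

test_that("mechanism scores are structure-coefficient differences with sign symmetry", {
  set.seed(44)
  sim <- simulate_cca_data(200, px = 4, py = 3, seed = 44)
  colnames(sim$X) <- c("net1_connector", "net1_provincial", "net4_connector",
                       "net4_peripheral")
  fit <- fit_cca(sim$X, sim$Y)
  ms <- mechanism_scores(fit, list(
    net1_integration = c("net1_connector", "net1_provincial")))
  expect_equal(ms$score,
               unname(fit$structure_x["net1_connector", ] -
                        fit$structure_x["net1_provincial", ]))
  # flipping a variate's sign flips the score
  flipped <- fit
  flipped$structure_x[, 1] <- -flipped$structure_x[, 1]
  flipped$cross[, 1] <- -flipped$cross[, 1]
  ms2 <- mechanism_scores(flipped, list(
    net1_integration = c("net1_connector", "net1_provincial")))
  expect_equal(ms2$score[1], -ms$score[1])
  expect_equal(ms2$score[-1], ms$score[-1])
  expect_error(mechanism_scores(fit, list(bad = c("nope", "net1_connector"))),
               "unknown")
})

test_that("cross-validation and bootstrap behave on planted and degenerate cases", {
  sim <- simulate_cca_data(500, latent_r = 0.6, seed = 55)
  fit <- fit_cca(sim$X, sim$Y)
  val <- validate_cca(sim$X, sim$Y, folds = 10, boots = 50, seed = 56)
  expect_lt(abs(val$cv_mean[1] - fit$rc[1]), 0.1)
  expect_true(all(dim(val$rc_ci) == c(3, 2)))
  expect_true(val$rc_ci[1, 1] <= fit$rc[1] + 0.05)

  # boots = 1: interval collapses to the single resample's estimate
  val1 <- validate_cca(sim$X, sim$Y, folds = 5, boots = 1, seed = 57)
  expect_equal(val1$rc_ci[, 1], val1$rc_ci[, 2])
})
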