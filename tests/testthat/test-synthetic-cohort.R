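test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(1), "n_subjects")
  expect_error(cohort_spec(10, module_sizes = c(100, 40)), "exceeds")
  expect_error(cohort_spec(10, ts_length = 1), "ts_length")
  expect_error(cohort_spec(10, missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(10,
                           within_coupling = function(a) 0.2,
                           between_coupling = function(a) 0.4),
               "degenerate coupling")
  spec <- cohort_spec(5, seed = 3)
  expect_equal(sum(spec$module_sizes), 128)
  lab <- planted_modules(spec)
  expect_equal(sum(lab == 0), 3)
  expect_equal(unname(table(lab[lab > 0])), c(40, 34, 32, 22),
               ignore_attr = TRUE)
})

test_that("the noise-free, decoupled limit is the exact factor model", {
  sp <- cohort_spec(2, noise_sd = 0, between_coupling = function(a) 0,
                    module_sizes = c(60, 60), n_rois = 120, seed = 1)
  m <- generate_connectome(sp, 40, seed = 7)
  r <- tanh(m$values)
  within1 <- r[1:60, 1:60][upper.tri(matrix(0, 60, 60))]
  expect_true(all(within1 > 0.999))
  off <- r[1:60, 61:120]
  expect_lt(max(abs(off)), 0.25)          # independent factors, finite series
  expect_lt(abs(mean(off)), 0.05)
  expect_true(isSymmetric(m$values))
  expect_equal(unname(diag(m$values)), rep(0, 120))
})

test_that("connectome generation is seed-deterministic and validates inputs", {
  sp <- cohort_spec(2, seed = 5)
  m1 <- generate_connectome(sp, 50, seed = 11)
  m2 <- generate_connectome(sp, 50, seed = 11)
  expect_identical(m1$values, m2$values)
  m3 <- generate_connectome(sp, 50, seed = 12)
  expect_false(identical(m1$values, m3$values))
  expect_error(generate_connectome(sp, 99, seed = 1), "range")
  expect_error(generate_connectome(sp, 50, seed = 1, coupling_shift = 0.5),
               "degenerate coupling")
})

test_that("mean within-block correlation matches the analytic factor value", {
  w <- 0.8; b <- 0.2; noise <- 0.5
  sp <- cohort_spec(2, ts_length = 500, noise_sd = noise,
                    cross_loading_sd = 0,
                    within_coupling = function(a) w,
                    between_coupling = function(a) b,
                    module_sizes = c(40, 40, 40), n_rois = 120, seed = 2)
  # analytic oracle: same-module nodes share w*f + b*g
  r_analytic <- (w^2 + b^2) / (w^2 + b^2 + noise^2)
  m <- generate_connectome(sp, 40, seed = 21)
  r <- tanh(m$values)
  blocks <- planted_modules(sp)
  vals <- c()
  for (k in 1:3) {
    blk <- r[blocks == k, blocks == k]
    vals <- c(vals, blk[upper.tri(blk)])
  }
  expect_lt(abs(mean(vals) - r_analytic), 0.05)
})

test_that("cognition reproduces the latent factors in the noiseless identity case", {
  L <- rbind(c(1, 0), c(0, 1), matrix(0, 6, 2))
  rownames(L) <- sprintf("t%d", 1:8)
  sp <- cohort_spec(2, cognitive_noise_sd = 0, missing_rate = 0,
                    cognitive_loading = L, seed = 4)
  sc <- generate_cognition(sp, list(domain_general = 0.2, semantic = -0.1),
                           age = 40, seed = 9)
  latent <- attr(sc, "latent")
  expect_equal(unname(sc[1]), unname(latent["domain_general"]))
  expect_equal(unname(sc[2]), unname(latent["semantic"]))
  expect_false(anyNA(sc))
  expect_error(cohort_spec(2, cognitive_loading = matrix(1, 3, 2)), "8 x 2")
})

test_that("a loaded task tracks its planted factor across a cohort", {
  L <- matrix(c(rep(1, 8), rep(0, 8)), 8, 2)
  sp <- cohort_spec(2, cognitive_noise_sd = 0.2, missing_rate = 0,
                    cognitive_loading = L, seed = 10)
  set.seed(100)
  ages <- runif(400, 18, 88)
  f1 <- numeric(400); task <- numeric(400)
  for (i in 1:400) {
    sc <- generate_cognition(sp, list(domain_general = 0, semantic = 0),
                             ages[i], seed = 1000 + i)
    f1[i] <- attr(sc, "latent")["domain_general"]
    task[i] <- sc[1]
  }
  expect_gte(cor(f1, task), 0.9)
})

test_that("cohorts are reproducible file-for-file and well-formed on disk", {
  spec <- cohort_spec(4, seed = 31, ts_length = 60)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  co <- generate_cohort(spec, out_dir = d1)
  generate_cohort(spec, out_dir = d2)
  expect_length(co, 4)
  files <- c("participants.tsv", "cognition.tsv", "roi_annotation.tsv",
             sprintf("sub-%04d_matrix.tsv", 1:4))
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_cohort(d1)
  expect_equal(nrow(back$participants), 4)
  expect_equal(back$matrices[[1]]$values, co[[1]]$matrix$values,
               tolerance = 1e-10)
  expect_equal(back$matrices[[2]]$age, co[[2]]$age)
  expect_equal(nrow(back$roi_annotation), 131)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort ages are uniform over the range (KS check)", {
  # discrete CDF oracle for round(runif(18, 88))
  cdf <- function(k) pmin(pmax((k + 0.5 - 18) / 70, 0), 1)
  ok <- 0; reps <- 100
  crit <- 1.358 / sqrt(200)
  for (r in 1:reps) {
    spec <- cohort_spec(200, seed = 5000 + r)
    ages <- cohort_demographics(spec)$age
    emp <- ecdf(ages)
    ks <- max(abs(emp(18:88) - cdf(18:88)))
    if (ks < crit) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.90)
})

test_that("role-composition generator plants the requested trends", {
  sim <- simulate_role_compositions(500, seed = 77)
  expect_equal(rowSums(sim$compositions), rep(1, 500), tolerance = 1e-12)
  expect_true(all(sim$compositions > 0))
  # noise-free logits reproduce slope signs via regression on scaled age
  a01 <- (sim$ages - 18) / 70
  for (r in 1:4) {
    b <- unname(coef(lm(sim$logits[, r] ~ a01))[2])
    expect_equal(sign(b), sign(c(0.5, -0.8, -0.2, 0.3)[r]))
  }
  sim2 <- simulate_role_compositions(500, seed = 77)
  expect_identical(sim, sim2)
})
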