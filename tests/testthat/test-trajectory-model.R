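roles4 <- c("connector", "provincial", "satellite", "peripheral")

make_cube <- function(freqs) {
  # freqs: list of 3 matrices (region x role), one per group
  n_reg <- nrow(freqs[[1]])
  cube <- array(0, dim = c(n_reg, 3, 4),
                dimnames = list(region = sprintf("r%02d", seq_len(n_reg)),
                                group = c("younger", "middle", "older"),
                                role = roles4))
  for (g in 1:3) cube[, g, ] <- freqs[[g]]
  class(cube) <- c("role_freq_cube", class(cube))
  cube
}

test_that("age groups use the printed closed bounds", {
  expect_equal(as.character(age_group(c(18, 44, 45, 55, 56, 88))),
               c("younger", "younger", "middle", "middle", "older", "older"))
})

test_that("role frequencies are empirical counts per region and group", {
  rm_ <- rbind(c("connector", "provincial"),
               c("connector", "provincial"),
               c("provincial", "provincial"),
               c("satellite", "provincial"))
  rm_ <- rbind(rm_, rm_, rm_)  # same 4 subjects in each age group
  ages <- rep(c(30, 50, 70), each = 4)
  colnames(rm_) <- c("rA", "rB")
  cube <- role_frequencies(rm_, ages)
  expect_equal(unname(cube["rA", "younger", ]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(cube["rB", "middle", ]), c(0, 1, 0, 0))
  expect_equal(apply(cube, c(1, 2), sum),
               matrix(1, 2, 3, dimnames = dimnames(cube)[1:2]),
               tolerance = 1e-12)
  expect_error(role_frequencies(rm_[1:4, ], rep(30, 4)), "empty age bin")
})

test_that("trajectory probabilities are outer products over the 64-cell space", {
  # worked example: provincial 0.75 in younger, connector 0.30 in middle
  f_young <- matrix(c(0.25, 0.75, 0, 0), 1)
  f_mid <- matrix(c(0.30, 0.30, 0.25, 0.15), 1)
  f_old <- matrix(c(0.4, 0.3, 0.2, 0.1), 1)
  cube <- make_cube(list(f_young, f_mid, f_old))
  tab <- trajectory_probabilities(cube)
  expect_equal(nrow(tab), 64)
  two_group <- sum(tab$probability[tab$r1 == "provincial" &
                                     tab$r2 == "connector"])
  expect_equal(two_group, 0.75 * 0.30)
  expect_equal(sum(tab$probability), 1, tolerance = 1e-12)

  # degenerate cube: single certain trajectory
  d <- make_cube(list(matrix(c(1, 0, 0, 0), 1), matrix(c(0, 1, 0, 0), 1),
                      matrix(c(0, 0, 0, 1), 1)))
  td <- trajectory_probabilities(d)
  expect_equal(sum(td$probability == 1), 1)
  expect_equal(sum(td$probability), 1)

  # random cube vs explicit triple loop
  set.seed(123)
  fr <- lapply(1:3, function(g) {
    m <- matrix(rexp(5 * 4), 5)
    m / rowSums(m)
  })
  cr <- make_cube(fr)
  tr <- trajectory_probabilities(cr)
  for (reg in 1:5) for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expected <- fr[[1]][reg, i] * fr[[2]][reg, j] * fr[[3]][reg, k]
    got <- tr$probability[tr$region == sprintf("r%02d", reg) &
                            tr$r1 == roles4[i] & tr$r2 == roles4[j] &
                            tr$r3 == roles4[k]]
    expect_equal(got, expected)
  }
  sums <- tapply(tr$probability, tr$region, sum)
  expect_equal(as.numeric(sums), rep(1, 5), tolerance = 1e-12)
})

test_that("trajectory probabilities are invariant to subject and region order", {
  set.seed(31)
  rm_ <- matrix(sample(roles4, 60 * 6, replace = TRUE), 60, 6,
                dimnames = list(NULL, sprintf("r%02d", 1:6)))
  ages <- rep(c(30, 50, 70), 20)
  t1 <- trajectory_probabilities(role_frequencies(rm_, ages))
  perm_s <- sample(60); perm_r <- sample(6)
  t2 <- trajectory_probabilities(
    role_frequencies(rm_[perm_s, perm_r], ages[perm_s]))
  m1 <- t1[order(t1$region, t1$r1, t1$r2, t1$r3), ]
  m2 <- t2[order(t2$region, t2$r1, t2$r2, t2$r3), ]
  expect_equal(m1$probability, m2$probability)
})

test_that("trajectory selection keeps the band around the maximum", {
  probs <- c(0.30, 0.27, 0.20, rep((1 - 0.77) / 61, 61))
  cube <- make_cube(list(matrix(c(1, 0, 0, 0), 1), matrix(c(1, 0, 0, 0), 1),
                         matrix(c(1, 0, 0, 0), 1)))
  tab <- trajectory_probabilities(cube)
  tab$probability <- probs
  sel <- select_trajectories(tab, tolerance = 0.05)
  expect_equal(sum(sel$selected), 2)
  expect_true(sel$selected[which.max(sel$probability)])

  # unique far-above maximum -> singleton
  tab2 <- tab; tab2$probability <- c(0.9, rep(0.1 / 63, 63))
  expect_equal(sum(select_trajectories(tab2)$selected), 1)

  # random tables match the filter oracle under both readings
  set.seed(9)
  for (i in 1:20) {
    p <- rexp(64); p <- p / sum(p)
    t3 <- tab; t3$probability <- p
    abs_sel <- select_trajectories(t3, 0.05)$selected
    expect_equal(abs_sel, max(p) - p <= 0.05)
    rel_sel <- select_trajectories(t3, 0.05, relative = TRUE)$selected
    expect_equal(rel_sel, p >= 0.95 * max(p))
  }
})

test_that("reconfiguration summary counts non-constant selected trajectories", {
  # all regions constant
  const_cube <- make_cube(list(matrix(c(1, 0, 0, 0), 2, 4, byrow = FALSE),
                               matrix(c(1, 0, 0, 0), 2, 4, byrow = FALSE),
                               matrix(c(1, 0, 0, 0), 2, 4, byrow = FALSE)))
  const_cube[, , ] <- 0; const_cube[, , 1] <- 1
  tabc <- select_trajectories(trajectory_probabilities(const_cube))
  sumc <- summarize_reconfiguration(tabc)
  expect_equal(sumc$fraction_reconfiguring, 0)

  # 46 of 131 regions with a planted switch -> 35.1%
  freqs <- matrix(0, 131, 4); freqs[, 2] <- 1      # all provincial when young
  f_mid <- freqs; f_old <- freqs
  switchers <- 1:46
  f_old[switchers, ] <- 0; f_old[switchers, 1] <- 1  # become connector
  cube131 <- make_cube(list(freqs, f_mid, f_old))
  tab131 <- select_trajectories(trajectory_probabilities(cube131))
  s131 <- summarize_reconfiguration(tab131)
  expect_equal(s131$n_reconfiguring, 46)
  expect_equal(round(100 * s131$fraction_reconfiguring, 1), 35.1)
  expect_equal(unname(s131$transition_classes[["provincial -> connector"]]), 46)
  expect_equal(unname(s131$role_gain_shares[["connector"]]), 1)

  # per-module shares with a named partition
  part <- c(rep(1, 50), rep(2, 81))
  names(part) <- sprintf("r%03d", 1:131)
  dimnames(cube131)[[1]] <- names(part)
  tabp <- select_trajectories(trajectory_probabilities(cube131))
  sp <- summarize_reconfiguration(tabp, part)
  expect_equal(sp$per_module$fraction_reconfiguring, c(46 / 50, 0))
})

test_that("planted role dynamics are recovered from sampled cohorts", {
  set.seed(17)
  n_reg <- 20
  planted <- array(0, c(n_reg, 3, 4))
  argmax_planted <- matrix(0L, n_reg, 3)
  for (j in 1:n_reg) for (g in 1:3) {
    lead <- sample(1:4, 1)
    p <- rep(0.2, 4); p[lead] <- 0.4   # frequency gap of 0.2 to the runner-up
    planted[j, g, ] <- p
    argmax_planted[j, g] <- lead
  }
  dimnames(planted) <- list(region = sprintf("r%02d", 1:n_reg),
                            group = c("younger", "middle", "older"),
                            role = roles4)
  class(planted) <- c("role_freq_cube", class(planted))
  sim <- simulate_role_cohort(planted, n_per_group = 300, seed = 99)
  cube <- role_frequencies(sim$role_matrix, sim$ages)
  tab <- trajectory_probabilities(cube)
  hits <- 0
  for (j in 1:n_reg) {
    i <- which(tab$region == sprintf("r%02d", j))
    best <- i[which.max(tab$probability[i])]
    want <- roles4[argmax_planted[j, ]]
    if (tab$r1[best] == want[1] && tab$r2[best] == want[2] &&
        tab$r3[best] == want[3]) hits <- hits + 1
  }
  expect_gte(hits / n_reg, 0.95)
})
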