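test_that("entry log-likelihood matches hand-computed binomials", {
  expect_equal(loglik_entry(0, 0, 1, 0.5, 0.5), 0)       # no data
  expect_equal(loglik_entry(2, 2, 1, 0.01, 0.5), log(0.25))
  expect_equal(loglik_entry(1, 3, 0, 0.01, 0.5),
               log(3 * 0.01 * 0.99^2))
  expect_error(loglik_entry(1, 2, 1, 0.5, 1), "inside")
  expect_error(loglik_entry(3, 2, 1, 0.5, 0.5), "A <= D")
})

# single covered position, one cell, two clones differing at that position
worked_gd <- function() {
  A <- matrix(2, 1, 1); D <- matrix(2, 1, 1)
  omega <- cbind(C1 = 0, C2 = 1)
  make_cmd(A, D, omega)
}

test_that("cluster-to-clone conditional matches the two-term normalization", {
  gd <- gibbs_data(worked_gd())
  state <- list(I = 1L, T = 1L, C = gd$omega, theta0 = 0.01,
                theta = 0.5, xi = 0.1)
  pr <- clone_assignment_probs(state, gd)
  # lik(clone2) = Binom(2;2,0.5) = 0.25; lik(clone1) = 0.01^2 = 1e-4
  expect_equal(unname(pr[1, 2]), 0.25 / (0.25 + 1e-4), tolerance = 1e-12)

  # identical genotype columns: exactly uniform
  state$C <- cbind(C1 = 1L, C2 = 1L)
  expect_equal(unname(clone_assignment_probs(state, gd)[1, ]), c(0.5, 0.5))
})

test_that("an empty cluster draws its clone from the uniform prior", {
  # two clusters, the second empty under the corrected clustering
  A <- matrix(c(2, 0), 1, 2); D <- matrix(c(2, 1), 1, 2)
  cmd <- make_cmd(A, D, cbind(0, 1), cluster = c("q1", "q2"))
  gd <- gibbs_data(cmd)
  state <- list(I = c(1L, 1L), T = c(1L, 1L), C = gd$omega, theta0 = 0.01,
                theta = 0.5, xi = 0.1)
  pr <- clone_assignment_probs(state, gd)
  expect_equal(unname(pr[2, ]), c(0.5, 0.5))
})

test_that("sufficient statistics split reads by carried status", {
  # 2 cells, 2 positions, both cells in clusters assigned to a clone with
  # genotype column (1, 0)
  A <- rbind(c(1, 0), c(2, 1))
  D <- rbind(c(2, 1), c(2, 2))
  cmd <- make_cmd(A, D, cbind(k1 = c(1, 0), k2 = c(0, 1)),
                  cluster = c("q1", "q1"))
  gd <- gibbs_data(cmd)
  state <- list(I = 1L, T = c(1L, 1L), C = gd$omega, theta0 = 0.01,
                theta = c(0.5, 0.5), xi = 0.1)
  st <- theta_stats(state, gd)
  expect_equal(unname(st$u), c(1, 0))
  expect_equal(unname(st$v), c(2, 0))
  expect_equal(st$u0, 3)
  expect_equal(st$v0, 1)

  # all C = 0: everything pools into the background
  state$C <- matrix(0L, 2, 2)
  st0 <- theta_stats(state, gd)
  expect_equal(unname(st0$u), c(0, 0))
  expect_equal(st0$u0, sum(A))
  expect_equal(st0$v0, sum(D - A))

  # all C = 1: background empty
  state$C <- matrix(1L, 2, 2)
  st1 <- theta_stats(state, gd)
  expect_equal(st1$u0 + st1$v0, 0)
  # conservation: every covered read lands on exactly one side
  expect_equal(st$u0 + st$v0 + sum(st$u + st$v), sum(D))
})

test_that("theta draws follow the conjugate beta posteriors", {
  hp <- hyperparameters(v0 = c(1, 1), v1 = c(2.25, 2.65))
  stats <- list(u0 = 10, v0 = 990, u = c(0, 4500), v = c(0, 5500))
  set.seed(7)
  draws <- replicate(1e4, sample_theta(stats, hp))
  th0 <- unlist(draws["theta0", ])
  th2 <- vapply(draws["theta", ], `[`, numeric(1), 2)
  th1 <- vapply(draws["theta", ], `[`, numeric(1), 1)
  # Beta(11, 991): mean 11/1002
  se <- function(a, b, n) sqrt(a * b / ((a + b)^2 * (a + b + 1)) / n)
  expect_lt(abs(mean(th0) - 11 / 1002), 3 * se(11, 991, 1e4))
  # position with data: Beta(2.25+4500, 2.65+5500), mean ~0.45 within 0.01
  expect_lt(abs(mean(th2) - 0.45), 0.01)
  # position without data: the prior Beta(2.25, 2.65)
  expect_lt(abs(mean(th1) - 2.25 / 4.9), 3 * se(2.25, 2.65, 1e4))
})

test_that("corrected-genotype conditional matches the two-term ratio", {
  gd <- gibbs_data(worked_gd())
  # no cell assigned to clone 1 (the single cell's cluster maps to clone 2):
  # the conditional is exactly the prior |Omega - xi|
  state <- list(I = 2L, T = 1L, C = cbind(0L, 1L), theta0 = 0.01,
                theta = 0.5, xi = 0.2)
  pr <- genotype_update_probs(state, gd)
  expect_equal(unname(pr[1, 1]), 0.2)        # Omega=0: prior xi
  # xi = 0 pins C to Omega regardless of data
  state$xi <- 0
  pr0 <- genotype_update_probs(state, gd)
  expect_identical(unname(pr0[1, 1]), 0)
  expect_identical(unname(pr0[1, 2]), 1)

  # worked ratio: Omega=0, xi=0.1, one assigned cell with A=D=3
  A <- matrix(3, 1, 1); D <- matrix(3, 1, 1)
  cmd <- make_cmd(A, D, cbind(k1 = 0L, k2 = 0L))
  gd2 <- gibbs_data(cmd)
  state2 <- list(I = 1L, T = 1L, C = cbind(0L, 0L), theta0 = 0.01,
                 theta = 0.5, xi = 0.1)
  pr2 <- genotype_update_probs(state2, gd2)
  expect_equal(unname(pr2[1, 1]),
               0.1 * 0.125 / (0.1 * 0.125 + 0.9 * 1e-6), tolerance = 1e-10)
})

test_that("corrected-clustering conditional weighs prior times own likelihood", {
  # two singleton-style clusters assigned to different clones
  A <- matrix(c(2, 0), 1, 2); D <- matrix(c(2, 0), 1, 2)
  G <- matrix(0, 2, 2)
  cmd <- make_cmd(A, D, cbind(0, 1), cluster = c("q1", "q2"), G = G)
  gd <- gibbs_data(cmd, c = 0)   # uniform switch prior
  state <- list(I = c(1L, 2L), T = c(1L, 2L), C = gd$omega, theta0 = 0.01,
                theta = 0.5, xi = 0.1)
  pr <- cluster_membership_probs(state, gd)
  # cell 1: lik under q1 (clone1, theta0) = 1e-4; under q2 (clone2) = 0.25
  expect_equal(unname(pr[1, ]), c(1e-4, 0.25) / (1e-4 + 0.25),
               tolerance = 1e-12)
  # cell 2 has no covered positions: conditional equals the switch prior
  expect_equal(unname(pr[2, ]), c(0.5, 0.5))

  # all clusters on the same clone: conditional equals the prior
  state$I <- c(2L, 2L)
  expect_equal(unname(cluster_membership_probs(state, gd)[1, ]), c(0.5, 0.5))
})

test_that("xi draws follow the conjugate beta over genotype mismatches", {
  omega <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0), 4, 2)
  # C identical to omega: Beta(1, 9), mean 0.1
  set.seed(3)
  draws <- replicate(1e4, sample_xi(omega, omega, c(1, 1)))
  se <- sqrt(1 * 9 / (10^2 * 11) / 1e4)
  expect_lt(abs(mean(draws) - 0.1), 3 * se)
  # C complement of omega: Beta(9, 1)
  set.seed(4)
  draws2 <- replicate(1e4, sample_xi(1 - omega, omega, c(1, 1)))
  expect_lt(abs(mean(draws2) - 0.9), 3 * se)
  # parameter check by seed equality: 3 mismatches, 5 matches, kappa=(2,18)
  C <- omega; C[1:3, 1] <- 1 - C[1:3, 1]
  set.seed(5); d <- sample_xi(C, omega, c(2, 18))
  set.seed(5); expect_identical(d, rbeta(1, 5, 23))
})

test_that("conditionals are proper distributions and scale-invariant in log space", {
  set.seed(99)
  for (rep in 1:3) {
    cmd <- random_cmd(N = 3, M = 5, K = 3, Q = 2, seed = 100 + rep)
    gd <- gibbs_data(cmd)
    state <- list(I = sample.int(3, 2, replace = TRUE),
                  T = gd$cluster_index, C = gd$omega,
                  theta0 = 0.02, theta = runif(3, 0.3, 0.7), xi = 0.1)
    expect_equal(unname(rowSums(clone_assignment_probs(state, gd))),
                 rep(1, 2))
    expect_equal(unname(rowSums(cluster_membership_probs(state, gd))),
                 rep(1, 5))
    pr <- genotype_update_probs(state, gd)
    expect_true(all(pr >= 0 & pr <= 1))

    # multiplying every likelihood term by a constant leaves the
    # conditionals unchanged (log-space max subtraction)
    ll <- clonemap:::.loglik_mats(gd, state$theta0, state$theta)
    ll_scaled <- list(ll0 = ll$ll0 + 7, ll1 = ll$ll1 + 7)
    expect_equal(clone_assignment_probs(state, gd, ll),
                 clone_assignment_probs(state, gd, ll_scaled),
                 tolerance = 1e-9)
    expect_equal(cluster_membership_probs(state, gd, ll),
                 cluster_membership_probs(state, gd, ll_scaled),
                 tolerance = 1e-9)
  }
})
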