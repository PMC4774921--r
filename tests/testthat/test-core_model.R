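test_that("constructors enforce domain invariants", {
  expect_error(finger_profile("x", k = 0, mvc = 10), "positive")
  expect_error(finger_profile("x", k = 0.02, mvc = -1), "positive")
  expect_error(cost_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(cost_weights(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_error(norm_constants(data.frame()), "columns")
  w <- cost_weights(0.2, 0.4, 0.4)
  expect_s3_class(w, "cost_weights")
  expect_equal(w$nu + w$lam + w$mu, 1)
})

test_that("normalization constants are the stated population means", {
  one <- data.frame(participant_id = "P01", k_i = 1, mvc_i = 1,
                    k_j = 1, mvc_j = 1)
  b <- norm_constants(one)
  expect_equal(unclass(b)[c("b_nu", "b_lam", "b_mu")],
               list(b_nu = 2, b_lam = 2, b_mu = 2))

  two <- data.frame(participant_id = c("a", "b"),
                    k_i = sqrt(c(0.0003, 0.0006)),
                    k_j = sqrt(c(0.0001, 0.0002)),
                    mvc_i = c(10, 12), mvc_j = c(20, 25))
  expect_equal(norm_constants(two)$b_nu, 0.0006)

  # independent re-summation over a drawn population
  pairs <- toy_pairs(M = 25L, seed = 3L)
  b <- norm_constants(pairs)
  expect_equal(b$b_mu,
               sum(1 / pairs$mvc_i^2 + 1 / pairs$mvc_j^2) / nrow(pairs))
  expect_equal(b$b_nu, sum(pairs$k_i^2 + pairs$k_j^2) / nrow(pairs))
})

test_that("effective coefficient follows the tilded-weight formula", {
  consts <- structure(list(b_nu = 1, b_lam = 2, b_mu = 0.01),
                      class = "norm_constants")
  prof <- finger_profile("f", k = 0.02, mvc = 15)
  expect_equal(effective_coefficient(cost_weights(0, 1, 0), consts, prof),
               1 / 2)
  expect_equal(effective_coefficient(cost_weights(1, 0, 0), consts, prof),
               0.0004)
  # independent evaluation of the same algebra
  consts2 <- structure(list(b_nu = 0.0008, b_lam = 2, b_mu = 0.01),
                       class = "norm_constants")
  got <- effective_coefficient(cost_weights(0.2, 0.4, 0.4), consts2, prof)
  want <- 0.2 / 0.0008 * 0.02^2 + 0.4 / 2 + 0.4 / 0.01 / 15^2
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("optimal commands match the closed-form and examples", {
  # near-infinite error weight: exact attainment, symmetric split
  u <- optimal_command(1, 1, 1e12, 10)
  expect_equal(unname(u), c(5, 5), tolerance = 1e-10)
  # finite error weight undershoots
  u <- optimal_command(1, 1, 1, 10)
  expect_equal(unname(u), c(10 / 3, 10 / 3), tolerance = 1e-12)
  expect_lt(sum(u), 10)
  u <- optimal_command(2, 1, 1, 6)
  expect_equal(unname(u), c(1.2, 2.4), tolerance = 1e-12)
  expect_equal(u[["u_j"]], 2 * u[["u_i"]])
  expect_error(optimal_command(0, 1, 1, 5), "positive")
})

test_that("optimal commands agree with an independent quadratic minimizer", {
  set.seed(41)
  for (i in 1:200) {
    a_i <- exp(stats::runif(1, -6, 2))
    a_j <- exp(stats::runif(1, -6, 2))
    nt <- exp(stats::runif(1, -4, 4))
    g <- stats::runif(1, 0, 30)
    u <- optimal_command(a_i, a_j, nt, g)
    expect_equal(unname(u), solve_command_oracle(a_i, a_j, nt, g),
                 tolerance = 1e-8)
  }
})

test_that("optimal share is a g-free, scale-free ratio in (0, 1)", {
  expect_equal(optimal_share(1, 1), 0.5)
  expect_equal(optimal_share(1, 3), 0.75)
  set.seed(7)
  for (i in 1:50) {
    a_i <- exp(stats::rnorm(1)); a_j <- exp(stats::rnorm(1))
    s <- stats::runif(1, 0.1, 10)
    cst <- optimal_share(a_i, a_j)
    expect_gt(cst, 0); expect_lt(cst, 1)
    expect_equal(optimal_share(s * a_i, s * a_j), cst)
  }
  # identical profiles split evenly regardless of the weights
  pairs <- data.frame(participant_id = "P", k_i = 0.02, mvc_i = 15,
                      k_j = 0.02, mvc_j = 15)
  consts <- norm_constants(pairs)
  for (w in list(cost_weights(0.2, 0.4, 0.4), cost_weights(0, 0.1, 0.9)))
    expect_equal(pair_shares(w, consts, pairs), 0.5)
  # the command-level share equals c* at any target force
  pairs2 <- toy_pairs(M = 3L)
  consts2 <- norm_constants(pairs2)
  wts <- cost_weights(0.3, 0.3, 0.4)
  cst <- pair_shares(wts, consts2, pairs2)
  for (g in c(2, 10, 28)) {
    cmd <- pair_commands(wts, consts2, pairs2, g)
    expect_equal(cmd$u_i / (cmd$u_i + cmd$u_j), cst, tolerance = 1e-12)
  }
})

test_that("noise-only weights give the noise-ratio share", {
  pairs <- data.frame(participant_id = "P", k_i = 0.0238, mvc_i = 12.71,
                      k_j = 0.0162, mvc_j = 23.29)
  consts <- norm_constants(pairs)
  cst <- pair_shares(cost_weights(1, 0, 0), consts, pairs)
  expect_equal(cst, 0.0162^2 / (0.0238^2 + 0.0162^2), tolerance = 1e-12)
  expect_equal(cst, 0.3166, tolerance = 1e-4)
})

test_that("expanded cost equals the expectation form under the noise model", {
  expect_equal(sharing_cost(0, 0, 0, cost_weights(1 / 3, 1 / 3, 1 / 3),
                            norm_constants(toy_pairs(1)),
                            finger_profile("i", 0.02, 12),
                            finger_profile("j", 0.02, 23)), 0)
  consts <- structure(list(b_nu = 1, b_lam = 2, b_mu = 0.01),
                      class = "norm_constants")
  pi_ <- finger_profile("i", 0.02, 12)
  pj <- finger_profile("j", 0.015, 23)
  expect_equal(sharing_cost(0, 0, 5, cost_weights(1, 0, 0), consts, pi_, pj),
               25)
  # Monte-Carlo oracle for the expectation form
  set.seed(101)
  wts <- cost_weights(0.3, 0.5, 0.2)
  consts <- norm_constants(toy_pairs(4))
  tw <- forceshare:::tilde_weights(wts, consts)
  u_i <- 4.2; u_j <- 6.1; g <- 11
  n <- 1e6
  x_i <- stats::rnorm(n, u_i, pi_$k * u_i)
  x_j <- stats::rnorm(n, u_j, pj$k * u_j)
  draws <- tw$nu_t * (x_i + x_j - g)^2 +
    tw$lam_t * (u_i^2 + u_j^2) +
    tw$mu_t * ((u_i / pi_$mvc)^2 + (u_j / pj$mvc)^2)
  mc <- mean(draws)
  se <- stats::sd(draws) / sqrt(n)
  exact <- sharing_cost(u_i, u_j, g, wts, consts, pi_, pj)
  expect_lt(abs(mc - exact), 3 * se)
})
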