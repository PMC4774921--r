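test_that("stick-breaking reparametrization is an exact bijection", {
  w <- reparam_forward(0.2, 0.5)
  expect_equal(c(w$nu, w$lam, w$mu), c(0.2, 0.4, 0.4))
  expect_equal(reparam_inverse(cost_weights(0.2, 0.4, 0.4)),
               c(w = 0.2, z = 0.5))
  expect_error(reparam_inverse(cost_weights(1, 0, 0)), "undefined")

  grid <- (1:100 - 0.5) / 100
  for (wv in grid[seq(1, 100, by = 7)]) {
    wts <- lapply(grid, function(zv) reparam_forward(wv, zv))
    sums <- vapply(wts, function(x) x$nu + x$lam + x$mu, numeric(1))
    expect_true(all(abs(sums - 1) < 1e-12))
    back <- t(vapply(wts, reparam_inverse, numeric(2)))
    expect_equal(back[, "w"], rep(wv, 100), tolerance = 1e-12)
    expect_equal(back[, "z"], grid, tolerance = 1e-12)
  }
})

test_that("share log-likelihood matches closed forms and a naive oracle", {
  pairs <- toy_pairs(1)
  consts <- norm_constants(pairs)
  wts <- cost_weights(0.2, 0.5, 0.3)
  cst <- pair_shares(wts, consts, pairs)
  ds1 <- share_dataset(10, data.frame(participant_id = "P01", y = cst), pairs)
  expect_equal(log_likelihood(ds1, wts, 1, consts), -0.5 * log(2 * pi))
  expect_equal(log_likelihood(ds1, wts, 1, consts), -0.91894, tolerance = 1e-4)

  ds8 <- share_dataset(10, data.frame(participant_id = "P01",
                                      y = rep(cst, 8)), pairs)
  expect_equal(log_likelihood(ds8, wts, 1, consts), -4 * log(2 * pi))

  # naive per-point summation on a random small dataset
  pairs3 <- toy_pairs(3, seed = 6)
  consts3 <- norm_constants(pairs3)
  ds <- toy_share_dataset(pairs3, wts, N_lm = 7L, seed = 15)
  sig2 <- c(0.001, 0.004, 0.002)
  cstars <- pair_shares(wts, consts3, pairs3)
  naive <- 0
  for (i in seq_along(ds$y)) {
    m <- ds$pidx[i]
    naive <- naive + stats::dnorm(ds$y[i], cstars[m], sqrt(sig2[m]),
                                  log = TRUE)
  }
  expect_equal(log_likelihood(ds, wts, sig2, consts3), naive,
               tolerance = 1e-10)
  expect_error(log_likelihood(ds, wts, c(1, -1, 1), consts3), "positive")
})

test_that("variance Gibbs draw is the conjugate inverse gamma", {
  res <- c(0.1, -0.1, 0.1, -0.1)  # conditional InvGa(2, 0.02)
  set.seed(17)
  draws <- vapply(1:2e5, function(i) variance_gibbs_update(res), numeric(1))
  # analytic median via the gamma representation
  med <- 0.02 / stats::qgamma(0.5, 2)
  expect_equal(stats::median(draws), med, tolerance = 0.02)
  ks <- stats::ks.test(draws[seq(1, 2e5, by = 10)], pinvgamma,
                       shape = 2, scale = 0.02)
  expect_gt(ks$p.value, 0.01)

  # finite-variance case: mean within 3 SE of scale/(shape-1)
  res8 <- rep(c(0.1, -0.1), 4)  # InvGa(4, 0.04): mean 0.04/3, finite var
  set.seed(18)
  d8 <- vapply(1:2e5, function(i) variance_gibbs_update(res8), numeric(1))
  mu <- 0.04 / 3
  se <- sqrt(0.04^2 / (3^2 * 2) / 2e5)
  expect_lt(abs(mean(d8) - mu), 3 * se)

  # single-residual bookkeeping: InvGa(1/2, r^2/2)
  set.seed(19)
  d1 <- vapply(1:4e4, function(i) variance_gibbs_update(0.3), numeric(1))
  ks1 <- stats::ks.test(d1, pinvgamma, shape = 0.5, scale = 0.045)
  expect_gt(ks1$p.value, 0.01)

  expect_error(variance_gibbs_update(c(0, 0)), "degenerate")
  # flat prior lowers the shape by one
  set.seed(20)
  dflat <- vapply(1:4e4, function(i)
    variance_gibbs_update(res8, prior = "flat"), numeric(1))
  ksf <- stats::ks.test(dflat, pinvgamma, shape = 3, scale = 0.04)
  expect_gt(ksf$p.value, 0.01)
})

test_that("adaptive RWMH reaches its target acceptance on a flat target", {
  set.seed(23)
  st <- adapt_state()
  x <- 0.5
  acc <- logical(6e4)
  for (i in seq_along(acc)) {
    r <- rwmh_step(x, function(v) 0, st)
    x <- r$value; st <- r$state; acc[i] <- r$accepted
  }
  expect_lt(abs(mean(acc[2e4:6e4]) - 0.44), 0.03)
})

test_that("RWMH leaves a uniform target invariant", {
  set.seed(24)
  st <- adapt_state()
  x <- 0.5
  n <- 1e5
  draws <- numeric(n)
  for (i in seq_len(n)) {
    r <- rwmh_step(x, function(v) 0, st)
    x <- r$value; st <- r$state; draws[i] <- x
  }
  ks <- stats::ks.test(draws[seq(2e4, n, by = 25)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("vanishing proposal scale accepts almost everything", {
  set.seed(25)
  st <- adapt_state(log_sd = -20, batch_size = 1e6L)
  x <- 0.3
  acc <- vapply(1:500, function(i) {
    r <- rwmh_step(x, function(v) stats::dbeta(v, 2, 3, log = TRUE), st)
    x <<- r$value
    r$accepted
  }, logical(1))
  expect_gt(mean(acc), 0.99)
})

test_that("RWMH preserves a 3-bin piecewise-constant target", {
  probs <- c(0.2, 0.3, 0.5)
  logdens <- log(3 * probs)
  lt <- function(v) logdens[pmin(floor(v * 3) + 1, 3)]
  set.seed(26)
  st <- adapt_state()
  x <- 0.5
  n <- 2e5
  draws <- numeric(n)
  for (i in seq_len(n)) {
    r <- rwmh_step(x, lt, st)
    x <- r$value; st <- r$state; draws[i] <- x
  }
  freq <- tabulate(pmin(floor(draws[2e4:n] * 3) + 1, 3), 3) /
    length(draws[2e4:n])
  expect_lt(max(abs(freq - probs)), 0.03)
})

test_that("chains are exactly reproducible and respect the simplex", {
  pairs <- toy_pairs(4, seed = 2)
  ds <- toy_share_dataset(pairs, cost_weights(0.15, 0.55, 0.3),
                          N_lm = 15L, seed = 40)
  ch1 <- run_chain(ds, T = 1500, burn_in = 500, seed = 123)
  ch2 <- run_chain(ds, T = 1500, burn_in = 500, seed = 123)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$sig2, ch2$sig2)

  s <- ch1$samples
  expect_true(all(abs(s[, "nu"] + s[, "lam"] + s[, "mu"] - 1) < 1e-12))
  expect_true(all(s[, c("nu", "lam", "mu")] >= 0 &
                    s[, c("nu", "lam", "mu")] <= 1))
  expect_true(all(ch1$sig2 > 0))
  expect_true(all(ch1$accept >= 0 & ch1$accept <= 1, na.rm = TRUE))
})

test_that("per-level fits are independent of other levels", {
  pairs <- toy_pairs(4, seed = 2)
  sc <- scenario_spec(c(8, 16), list(cost_weights(0.1, 0.6, 0.3),
                                     cost_weights(0.1, 0.4, 0.5)),
                      N_lm = 12L, sigma_y = 0.05)
  dss <- simulate_share_data(pairs, sc, seed = 51)
  consts <- norm_constants(pairs)
  alone <- run_chain(dss[[1]], consts = consts, T = 800, burn_in = 300,
                     seed = 9)
  in_loop <- lapply(dss, run_chain, consts = consts, T = 800,
                    burn_in = 300, seed = 9)
  expect_identical(alone$samples, in_loop[[1]]$samples)
})

test_that("reduced models pin the right coordinates", {
  pairs <- toy_pairs(4, seed = 2)
  ds <- toy_share_dataset(pairs, cost_weights(0.1, 0.55, 0.35),
                          N_lm = 15L, seed = 44)
  no_nu <- run_chain(ds, model_spec(free = c("lam", "mu")),
                     T = 600, burn_in = 200, seed = 5)
  expect_true(all(no_nu$samples[, "nu"] == 0))
  expect_true(is.na(no_nu$accept[["w"]]) && !is.na(no_nu$accept[["z"]]))

  no_lam <- run_chain(ds, model_spec(free = c("nu", "mu")),
                      T = 600, burn_in = 200, seed = 5)
  expect_true(all(no_lam$samples[, "lam"] == 0))
  expect_equal(no_lam$samples[, "mu"], 1 - no_lam$samples[, "nu"])

  only_mu <- run_chain(ds, model_spec(free = "mu"),
                       T = 600, burn_in = 200, seed = 5)
  expect_true(all(only_mu$samples[, "mu"] == 1))
  expect_true(all(is.na(only_mu$accept)))
  expect_true(all(only_mu$sig2 > 0))
})

test_that("chain validation rejects bad settings and degenerate data", {
  pairs <- toy_pairs(2)
  ds <- toy_share_dataset(pairs, cost_weights(0.2, 0.4, 0.4),
                          N_lm = 10L, seed = 3)
  expect_error(run_chain(ds, T = 100, burn_in = 100, seed = 1),
               "T > burn_in")
  expect_error(run_chain(ds, T = 100, burn_in = 10, seed = 1,
                         init = list(w = 0, z = 0.5)), "initial w")
  const_y <- share_dataset(10, data.frame(
    participant_id = rep(c("P01", "P02"), each = 4),
    y = c(rep(0.4, 4), c(0.41, 0.42, 0.40, 0.39))), pairs)
  expect_error(run_chain(const_y, T = 100, burn_in = 10, seed = 1),
               "constant y")
  expect_error(share_dataset(10, data.frame(participant_id = "a", y = 1.2),
                             pairs), "\\(0, 1\\)")
  expect_error(share_dataset(10, data.frame(participant_id = "zz", y = 0.5),
                             pairs), "profiles")
})

test_that("the flat variance prior gives essentially the same fit", {
  pairs <- toy_pairs(6, seed = 4)
  ds <- toy_share_dataset(pairs, cost_weights(0.15, 0.5, 0.35),
                          N_lm = 25L, seed = 61)
  m0 <- posterior_summary(run_chain(ds, T = 3000, burn_in = 1000, seed = 2))
  m1 <- posterior_summary(run_chain(ds, T = 3000, burn_in = 1000, seed = 2,
                                    prior = "flat"))
  expect_lt(max(abs(m0$median[1:3] - m1$median[1:3])), 0.05)
})

test_that("posterior summaries are medians with equal-tailed intervals", {
  ch <- fake_chain(w = rep(0.3, 50), z = rep(0.6, 50))
  s <- posterior_summary(ch)
  nu_row <- s[s$parameter == "nu", ]
  expect_equal(nu_row$median, 0.3)
  expect_equal(nu_row$hi95 - nu_row$lo95, 0)

  set.seed(30)
  draws <- stats::rnorm(2e5, 0.5, 0.1)
  ch2 <- fake_chain(w = draws, z = rep(0.5, 2e5))
  s2 <- posterior_summary(ch2)
  nu2 <- s2[s2$parameter == "nu", ]
  expect_equal(c(nu2$lo95, nu2$hi95), c(0.304, 0.696), tolerance = 0.01)

  # medians stable under thinning by 10
  thin <- fake_chain(w = draws[seq(1, 2e5, by = 10)],
                     z = rep(0.5, 2e4))
  s3 <- posterior_summary(thin)
  expect_equal(s3$median[s3$parameter == "nu"], nu2$median,
               tolerance = 0.005)
})

test_that("MCMC medians match dense grid quadrature on a tiny instance", {
  pairs <- toy_pairs(2, seed = 12)
  ds <- toy_share_dataset(pairs, cost_weights(0.2, 0.5, 0.3), N_lm = 10L,
                          sigma_y = 0.04, seed = 55)
  consts <- norm_constants(pairs)
  oracle <- grid_wz_medians(ds, consts, n = 200L)
  ch <- run_chain(ds, consts = consts, T = 20000, burn_in = 5000, seed = 3)
  r <- retained(ch)
  expect_lt(abs(stats::median(r$samples[, "w"]) - oracle[["w"]]), 0.025)
  expect_lt(abs(stats::median(r$samples[, "z"]) - oracle[["z"]]), 0.025)
})
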