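# Shared fixtures built in code.

# small deterministic pair table with realistic k / MVC magnitudes
toy_pairs <- function(M = 2L, seed = 11L) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%02d", seq_len(M)),
             k_i = 0.0238 * exp(stats::rnorm(M, 0, 0.2)),
             mvc_i = 12.71 * exp(stats::rnorm(M, 0, 0.1)),
             k_j = 0.0162 * exp(stats::rnorm(M, 0, 0.2)),
             mvc_j = 23.29 * exp(stats::rnorm(M, 0, 0.1)))
}

# share dataset around known weights with additive Gaussian noise
toy_share_dataset <- function(pairs, weights, level_g = 10, N_lm = 20L,
                              sigma_y = 0.05, seed = 99L) {
  sc <- scenario_spec(level_g, weights, N_lm = N_lm, sigma_y = sigma_y)
  simulate_share_data(pairs, sc, seed = seed)[[1L]]
}

# hand-built chain object for summary/averaging edge cases
fake_chain <- function(w, z, loglik = NULL, sig2 = NULL, burn_in = 0L) {
  Tn <- length(w)
  nu <- w; lam <- (1 - w) * z; mu <- (1 - w) * (1 - z)
  if (is.null(loglik)) loglik <- rep(0, Tn)
  samples <- cbind(w = w, z = z, nu = nu, lam = lam, mu = mu,
                   loglik = loglik)
  if (is.null(sig2)) sig2 <- matrix(1, Tn, 1,
                                    dimnames = list(NULL, "sigma2"))
  structure(list(samples = samples, sig2 = sig2,
                 participant_id = "P01", level_g = 10,
                 spec = model_spec(), consts = NULL, T = Tn,
                 burn_in = burn_in, seed = 0L, prior = "invga00",
                 accept = c(w = 0.4, z = 0.4),
                 adapt = list(w = numeric(0), z = numeric(0))),
            class = "posterior_chain")
}

# independent minimizer of the sharing quadratic: solve the 2x2 normal
# equations of  nu_t*(u_i+u_j-g)^2 + a_i*u_i^2 + a_j*u_j^2
solve_command_oracle <- function(a_i, a_j, nu_tilde, g) {
  A <- matrix(c(nu_tilde + a_i, nu_tilde, nu_tilde, nu_tilde + a_j), 2, 2)
  drop(solve(A, rep(nu_tilde * g, 2)))
}

# dense-grid marginal medians of (w, z) under the sigma^2-integrated
# posterior: p(w, z | y) proportional to prod_m SS_m^(-N_m / 2)
grid_wz_medians <- function(ds, consts, n = 400L) {
  mid <- (seq_len(n) - 0.5) / n
  w <- rep(mid, times = n)
  z <- rep(mid, each = n)
  ps <- forceshare:::pair_stats(ds$pairs)
  logp <- 0
  for (m in seq_along(ds$participant_id)) {
    nu_t <- w / consts$b_nu
    lam_t <- (1 - w) * z / consts$b_lam
    mu_t <- (1 - w) * (1 - z) / consts$b_mu
    a_i <- nu_t * ps$k2i[m] + lam_t + mu_t * ps$im2i[m]
    a_j <- nu_t * ps$k2j[m] + lam_t + mu_t * ps$im2j[m]
    cst <- a_j / (a_i + a_j)
    ss <- ds$sum_y2[m] - 2 * cst * ds$sum_y[m] + ds$n_lm[m] * cst^2
    logp <- logp - ds$n_lm[m] / 2 * log(pmax(ss, 1e-300))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  marg_median <- function(pm) mid[which(cumsum(pm) >= 0.5)[1L]]
  c(w = marg_median(rowsum(p, rep(seq_len(n), times = n))[, 1]),
    z = marg_median(rowsum(p, rep(seq_len(n), each = n))[, 1]))
}

# inverse-gamma distribution function for KS checks
pinvgamma <- function(q, shape, scale) {
  stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE)
}
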