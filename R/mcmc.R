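# Per-force-level Bayesian fit of the cost weights and observation
# variances: adaptive random-walk Metropolis-within-Gibbs on the
# stick-breaking reparametrization (w, z) of the weight simplex, with exact
# inverse-gamma Gibbs draws for the Gaussian variances.

#' Stick-breaking reparametrization of the weight simplex
#'
#' `nu = w`, `lam = (1 - w) * z`, `mu = (1 - w) * (1 - z)`. Under the
#' uniform prior on the simplex, `w` and `z` are independent U(0, 1), which
#' removes the hard sum constraint from the sampler.
#'
#' @param w,z values in `(0, 1)` (closed endpoints are tolerated so reduced
#'   models can pin a coordinate at a simplex vertex).
#' @return [cost_weights()] for `reparam_forward`; named `c(w, z)` for
#'   `reparam_inverse`.
#' @export
reparam_forward <- function(w, z) {
  stopifnot(is.finite(w), is.finite(z), w >= 0, w <= 1, z >= 0, z <= 1)
  cost_weights(nu = w, lam = (1 - w) * z, mu = (1 - w) * (1 - z))
}

#' @rdname reparam_forward
#' @param weights a [cost_weights()] object with `nu < 1`.
#' @export
reparam_inverse <- function(weights) {
  if (weights$nu >= 1) stop("z is undefined at nu = 1")
  c(w = weights$nu, z = weights$lam / (1 - weights$nu))
}

#' Per-level share dataset for the designated finger pair
#'
#' @param level_g force level, Newtons.
#' @param data data frame with columns `participant_id` and `y`, the weaker
#'   finger's observed fraction of total force, strictly inside `(0, 1)`.
#' @param pairs pair table (see [as_pair_table()]) covering every
#'   participant present in `data`.
#' @return Object of class `"share_dataset"` with the observations sorted
#'   by participant and per-participant sufficient statistics attached.
#' @export
share_dataset <- function(level_g, data, pairs) {
  stopifnot(all(c("participant_id", "y") %in% names(data)))
  pairs <- check_pair_table(pairs)
  if (!is.finite(level_g) || level_g <= 0) stop("'level_g' must be positive")
  if (nrow(data) == 0L) stop("no share observations")
  if (any(!is.finite(data$y) | data$y <= 0 | data$y >= 1))
    stop("all shares y must lie strictly in (0, 1)")
  ids <- sort(unique(data$participant_id))
  missing <- setdiff(ids, pairs$participant_id)
  if (length(missing))
    stop("no finger profiles for participant(s): ",
         paste(missing, collapse = ", "))
  pairs <- pairs[match(ids, pairs$participant_id), ]
  data <- data[order(match(data$participant_id, ids)), ]
  pidx <- match(data$participant_id, ids)
  structure(list(level_g = level_g, y = data$y, pidx = pidx,
                 participant_id = ids, pairs = pairs,
                 n_lm   = as.vector(tabulate(pidx, length(ids))),
                 sum_y  = as.vector(rowsum(data$y, pidx)),
                 sum_y2 = as.vector(rowsum(data$y^2, pidx))),
            class = "share_dataset")
}

#' @export
print.share_dataset <- function(x, ...) {
  cat(sprintf("<share_dataset> level %g N: %d observations, %d participants\n",
              x$level_g, length(x$y), length(x$participant_id)))
  invisible(x)
}

# Per-participant residual sums of squares around shares cst, via the
# sufficient statistics (sum y, sum y^2, N) -- O(M) per evaluation.
dataset_ss <- function(data, cst) {
  ss <- data$sum_y2 - 2 * cst * data$sum_y + data$n_lm * cst^2
  pmax(ss, 0)
}

#' Gaussian log-likelihood of a share dataset
#'
#' Sum over participants and observations of the normal log-density of
#' `y_lm(n)` around the participant-specific optimal share `c*`, with
#' per-participant variances.
#'
#' @param data a [share_dataset()].
#' @param weights a [cost_weights()] object.
#' @param variances per-participant variances (vector of length M, in the
#'   order of `data$participant_id`), or a single pooled variance.
#' @param consts a [norm_constants()] object; defaults to constants computed
#'   from the dataset's own pair table.
#' @return Scalar log-likelihood in nats.
#' @export
log_likelihood <- function(data, weights, variances, consts = NULL) {
  stopifnot(inherits(data, "share_dataset"))
  if (is.null(consts)) consts <- norm_constants(data$pairs)
  M <- length(data$participant_id)
  if (length(variances) == 1L) variances <- rep(variances, M)
  if (length(variances) != M || any(!is.finite(variances) | variances <= 0))
    stop("'variances' must be ", M, " strictly positive values (or one)")
  cst <- cstar_from_stats(weights$nu, weights$lam, weights$mu, consts,
                          pair_stats(data$pairs))
  ss <- dataset_ss(data, cst)
  -sum(data$n_lm) / 2 * log(2 * pi) -
    0.5 * sum(data$n_lm * log(variances)) - 0.5 * sum(ss / variances)
}

#' One conjugate Gibbs draw of an observation variance
#'
#' Under the scale-invariant prior `p(sigma^2) ~ 1/sigma^2` the full
#' conditional of a participant's variance given residuals `r` is inverse
#' gamma with shape `N/2` and scale `sum(r^2)/2`; under the flat variant
#' `p(sigma^2) ~ 1` the shape is `N/2 - 1`.
#'
#' @param residuals numeric vector of residuals `y - c*` for one
#'   participant; must not be identically zero.
#' @param prior `"invga00"` (default) or `"flat"`.
#' @return One variance draw.
#' @export
variance_gibbs_update <- function(residuals, prior = c("invga00", "flat")) {
  prior <- match.arg(prior)
  n <- length(residuals)
  if (n < 1L) stop("need at least one residual")
  ss <- sum(residuals^2)
  if (ss <= 0)
    stop("all residuals are exactly zero: degenerate data, ",
         "conditional variance is improper")
  shape <- n / 2 + if (prior == "flat") -1 else 0
  if (shape <= 0)
    stop("flat variance prior needs more than 2 observations per group")
  ss / 2 / stats::rgamma(1L, shape = shape)
}

#' Adaptation state for the random-walk proposal
#'
#' Bookkeeping for diminishing adaptation of the proposal log-SD toward a
#' target acceptance rate: after every batch the log-SD moves up or down by
#' `min(0.01, b^(-1/2))` where `b` is the batch index.
#'
#' @param log_sd initial proposal log-SD on the logit scale.
#' @param target_accept target acceptance rate (0.44, the univariate
#'   optimum).
#' @param batch_size proposals per adaptation batch.
#' @return List of class `"adapt_state"`.
#' @export
adapt_state <- function(log_sd = 0, target_accept = 0.44, batch_size = 50L) {
  structure(list(log_sd = log_sd, target_accept = target_accept,
                 batch_size = as.integer(batch_size), batch = 0L,
                 in_batch = 0L, acc_in_batch = 0L, trace = numeric(0)),
            class = "adapt_state")
}

#' One adaptive random-walk Metropolis step on (0, 1)
#'
#' Proposes on the logit scale (so the support never truncates the
#' proposal) with the Jacobian correction in the acceptance ratio, and
#' updates the diminishing adaptation state.
#'
#' @param x current value in `(0, 1)`.
#' @param log_target function returning the log target density of a value
#'   in `(0, 1)` (up to a constant).
#' @param state an [adapt_state()].
#' @param lp_x optional cached `log_target(x)`.
#' @return List `value`, `accepted`, `state`, `lp` (log target at the
#'   returned value).
#' @export
rwmh_step <- function(x, log_target, state, lp_x = NULL) {
  if (is.null(lp_x)) lp_x <- log_target(x)
  if (!is.finite(lp_x)) stop("log target is not finite at the current point")
  xp <- stats::plogis(stats::qlogis(x) + exp(state$log_sd) * stats::rnorm(1L))
  accepted <- FALSE
  lp <- lp_x
  if (xp > 0 && xp < 1) {
    lp_xp <- log_target(xp)
    log_alpha <- (lp_xp + log(xp) + log1p(-xp)) -
      (lp_x + log(x) + log1p(-x))
    if (is.finite(log_alpha) && log(stats::runif(1L)) < log_alpha) {
      x <- xp
      lp <- lp_xp
      accepted <- TRUE
    }
  }
  state$in_batch <- state$in_batch + 1L
  state$acc_in_batch <- state$acc_in_batch + accepted
  if (state$in_batch == state$batch_size) {
    state$batch <- state$batch + 1L
    step <- min(0.01, 1 / sqrt(state$batch))
    rate <- state$acc_in_batch / state$batch_size
    state$log_sd <- state$log_sd +
      if (rate > state$target_accept) step else -step
    state$trace <- c(state$trace, state$log_sd)
    state$in_batch <- 0L
    state$acc_in_batch <- 0L
  }
  list(value = x, accepted = accepted, state = state, lp = lp)
}

#' Model specification: free weight terms and variance structure
#'
#' The full model frees all of `nu`, `lam`, `mu`; reduced models pin some
#' weights at zero by fixing the corresponding stick-breaking coordinate:
#' `nu = 0` fixes `w = 0`; `mu = 0` fixes `z = 1`; `lam = 0` fixes `z = 0`.
#' Single-term models sit at a simplex vertex and sample only variances.
#'
#' @param free character subset of `c("nu", "lam", "mu")` left free.
#' @param variance `"per_participant"` (a variance per participant and
#'   level) or `"pooled"` (one variance per level).
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(free = c("nu", "lam", "mu"),
                       variance = c("per_participant", "pooled")) {
  free <- match.arg(free, c("nu", "lam", "mu"), several.ok = TRUE)
  variance <- match.arg(variance)
  has <- c(nu = "nu" %in% free, lam = "lam" %in% free, mu = "mu" %in% free)
  fixed <- if (all(has)) c(w = NA_real_, z = NA_real_)
  else if (has[["lam"]] && has[["mu"]]) c(w = 0, z = NA_real_)
  else if (has[["nu"]] && has[["mu"]]) c(w = NA_real_, z = 0)
  else if (has[["nu"]] && has[["lam"]]) c(w = NA_real_, z = 1)
  else if (has[["mu"]]) c(w = 0, z = 0)
  else if (has[["lam"]]) c(w = 0, z = 1)
  else c(w = 1, z = 0)
  structure(list(free = names(has)[has], fixed = fixed, variance = variance,
                 n_free_weights = sum(is.na(fixed))),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> free: {%s}; variance: %s\n",
              paste(x$free, collapse = ", "), x$variance))
  invisible(x)
}

model_label <- function(spec) paste(spec$free, collapse = "+")

#' Run the Metropolis-within-Gibbs sampler for one force level
#'
#' Each cycle updates `w` by an adaptive random-walk Metropolis step, then
#' `z`, then sets `mu = (1 - w)(1 - z)` deterministically, then draws every
#' observation variance from its inverse-gamma full conditional. Levels are
#' always fitted independently of each other.
#'
#' @param data a [share_dataset()].
#' @param spec a [model_spec()].
#' @param consts [norm_constants()]; defaults to constants from the
#'   dataset's pair table.
#' @param T total number of cycles (default 90000).
#' @param burn_in cycles discarded from the front (default 40000).
#' @param seed integer seed; the chain is a pure function of
#'   (data, spec, seed).
#' @param prior variance prior, `"invga00"` or `"flat"`.
#' @param init list with starting `w` and `z` in `(0, 1)`.
#' @return Object of class `"posterior_chain"`: a `T x 6` sample matrix
#'   (`w`, `z`, `nu`, `lam`, `mu`, `loglik`), a variance sample matrix,
#'   acceptance rates, adaptation traces, and run metadata.
#' @export
run_chain <- function(data, spec = model_spec(), consts = NULL,
                      T = 90000L, burn_in = 40000L, seed = 1L,
                      prior = c("invga00", "flat"),
                      init = list(w = 0.5, z = 0.5)) {
  stopifnot(inherits(data, "share_dataset"), inherits(spec, "model_spec"))
  prior <- match.arg(prior)
  T <- as.integer(T); burn_in <- as.integer(burn_in)
  if (!(T > burn_in) || burn_in < 0)
    stop("need T > burn_in >= 0 (got T = ", T, ", burn_in = ", burn_in, ")")
  if (is.null(consts)) consts <- norm_constants(data$pairs)
  M <- length(data$participant_id)
  ps <- pair_stats(data$pairs)
  pooled <- spec$variance == "pooled"
  shape_shift <- if (prior == "flat") -1 else 0

  # degenerate-data validation: a constant-y participant has an improper
  # variance conditional whenever its share can be fitted exactly
  vary <- data$sum_y2 - data$sum_y^2 / data$n_lm
  if (!pooled && any(data$n_lm > 1L & vary <= 1e-300))
    stop("participant(s) with constant y: ",
         paste(data$participant_id[data$n_lm > 1L & vary <= 1e-300],
               collapse = ", "),
         " (degenerate data for per-participant variances)")
  if (pooled && sum(vary) <= 1e-300)
    stop("all shares are constant: degenerate data for a pooled variance")

  set.seed(seed)
  w <- if (is.na(spec$fixed[["w"]])) init$w else spec$fixed[["w"]]
  z <- if (is.na(spec$fixed[["z"]])) init$z else spec$fixed[["z"]]
  if (is.na(spec$fixed[["w"]]) && (w <= 0 || w >= 1))
    stop("initial w must be in (0, 1)")
  if (is.na(spec$fixed[["z"]]) && (z <= 0 || z >= 1))
    stop("initial z must be in (0, 1)")

  # variance init: per-participant sample variance of y (pooled: overall)
  if (pooled) {
    n_tot <- sum(data$n_lm)
    sig2 <- max(sum(vary) / max(n_tot - 1L, 1L), 1e-12)
  } else {
    sig2 <- pmax(vary / pmax(data$n_lm - 1L, 1L), 1e-12)
  }

  cond_lp <- function(wv, zv, s2) {
    cst <- cstar_from_stats(wv, (1 - wv) * zv, (1 - wv) * (1 - zv),
                            consts, ps)
    ss <- dataset_ss(data, cst)
    if (pooled) -0.5 * sum(ss) / s2 else -0.5 * sum(ss / s2)
  }
  if (!is.finite(cond_lp(w, z, sig2)))
    stop("log posterior is not finite at the initial state")

  st_w <- adapt_state()
  st_z <- adapt_state()
  acc_w <- 0L; acc_z <- 0L
  samples <- matrix(NA_real_, T, 6L,
                    dimnames = list(NULL,
                                    c("w", "z", "nu", "lam", "mu", "loglik")))
  sig2_samples <- matrix(NA_real_, T, if (pooled) 1L else M)
  colnames(sig2_samples) <- if (pooled) "sigma2" else
    paste0("sigma2_", data$participant_id)
  const_ll <- -sum(data$n_lm) / 2 * log(2 * pi)

  for (t in seq_len(T)) {
    if (is.na(spec$fixed[["w"]])) {
      res <- rwmh_step(w, function(x) cond_lp(x, z, sig2), st_w)
      w <- res$value; st_w <- res$state; acc_w <- acc_w + res$accepted
    }
    if (is.na(spec$fixed[["z"]])) {
      res <- rwmh_step(z, function(x) cond_lp(w, x, sig2), st_z)
      z <- res$value; st_z <- res$state; acc_z <- acc_z + res$accepted
    }
    nu <- w; lam <- (1 - w) * z; mu <- (1 - w) * (1 - z)
    cst <- cstar_from_stats(nu, lam, mu, consts, ps)
    ss <- dataset_ss(data, cst)
    if (pooled) {
      sig2 <- sum(ss) / 2 / stats::rgamma(1L, sum(data$n_lm) / 2 + shape_shift)
      ll <- const_ll - 0.5 * sum(data$n_lm) * log(sig2) -
        0.5 * sum(ss) / sig2
    } else {
      sig2 <- ss / 2 / stats::rgamma(M, data$n_lm / 2 + shape_shift)
      ll <- const_ll - 0.5 * sum(data$n_lm * log(sig2)) -
        0.5 * sum(ss / sig2)
    }
    samples[t, ] <- c(w, z, nu, lam, mu, ll)
    sig2_samples[t, ] <- sig2
  }

  n_w <- if (is.na(spec$fixed[["w"]])) T else 0L
  n_z <- if (is.na(spec$fixed[["z"]])) T else 0L
  structure(list(samples = samples, sig2 = sig2_samples,
                 participant_id = data$participant_id,
                 level_g = data$level_g, spec = spec, consts = consts,
                 T = T, burn_in = burn_in, seed = seed, prior = prior,
                 accept = c(w = if (n_w) acc_w / n_w else NA_real_,
                            z = if (n_z) acc_z / n_z else NA_real_),
                 adapt = list(w = st_w$trace, z = st_z$trace)),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "<posterior_chain> level %g N, model {%s}, %s variances\n  T = %d (burn-in %d), seed %d; acceptance w = %s, z = %s\n",
    x$level_g, paste(x$spec$free, collapse = ", "), x$spec$variance,
    x$T, x$burn_in, x$seed,
    formatC(x$accept[["w"]], digits = 3, format = "f"),
    formatC(x$accept[["z"]], digits = 3, format = "f")))
  invisible(x)
}

#' Retained (post burn-in) samples of a chain
#'
#' @param chain a [run_chain()] result.
#' @return List with the retained `samples` and `sig2` matrices.
#' @export
retained <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  keep <- (chain$burn_in + 1L):chain$T
  if (length(keep) < 1L) stop("no post burn-in samples")
  list(samples = chain$samples[keep, , drop = FALSE],
       sig2 = chain$sig2[keep, , drop = FALSE])
}

#' Posterior medians and equal-tailed 95% credible intervals
#'
#' @param chain a [run_chain()] result.
#' @param params parameters to summarize; variance columns are always
#'   appended.
#' @return Data frame `parameter`, `median`, `lo95`, `hi95`.
#' @export
posterior_summary <- function(chain, params = c("nu", "lam", "mu")) {
  r <- retained(chain)
  m <- cbind(r$samples[, params, drop = FALSE], r$sig2)
  q <- t(apply(m, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE))
  data.frame(parameter = colnames(m), median = q[, 1],
             lo95 = q[, 2], hi95 = q[, 3], row.names = NULL)
}
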