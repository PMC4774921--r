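# Quadratic force-sharing cost and its closed-form optimum.
#
# Two fingers, i and j, jointly hold a static force target g. Each finger's
# produced force is Gaussian around its motor command u with signal-dependent
# SD k*u. The cost weighs expected squared target error (nu), absolute effort
# (lam) and MVC-normalized effort (mu); the three weights live on the unit
# simplex and are divided by population normalization constants so that equal
# weights mean equal influence on the optimum.

#' A finger's noise and strength profile
#'
#' @param finger_id character label, e.g. `"left_little"`.
#' @param k coefficient of variation of force, a dimensionless fraction
#'   (`sd(force) = k * command`); e.g. `0.0238`, not a percentage.
#' @param mvc maximum voluntary contraction, in Newtons.
#' @return An object of class `"finger_profile"`.
#' @export
finger_profile <- function(finger_id, k, mvc) {
  stopifnot(is.character(finger_id), length(finger_id) == 1L)
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive fraction (sigma/u)")
  if (length(mvc) != 1L || !is.finite(mvc) || mvc <= 0)
    stop("'mvc' must be a single positive force in Newtons")
  structure(list(finger_id = finger_id, k = k, mvc = mvc),
            class = "finger_profile")
}

#' @export
print.finger_profile <- function(x, ...) {
  cat(sprintf("<finger_profile> %s: k = %.4f (%.2f%%), MVC = %.2f N\n",
              x$finger_id, x$k, 100 * x$k, x$mvc))
  invisible(x)
}

#' Simplex-constrained cost weights
#'
#' Weights of the squared-error (`nu`), absolute-effort (`lam`) and
#' normalized-effort (`mu`) terms. They must be in `[0, 1]` and sum to 1:
#' the cost is unit-less and only weight ratios matter, so the overall scale
#' is fixed by the simplex constraint.
#'
#' @param nu,lam,mu numeric scalars in `[0, 1]` summing to 1.
#' @return An object of class `"cost_weights"`.
#' @export
cost_weights <- function(nu, lam, mu) {
  v <- c(nu = nu, lam = lam, mu = mu)
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("each weight must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-8)
    stop("weights must sum to 1 (got ", format(sum(v)), ")")
  v <- pmin(pmax(v, 0), 1)
  structure(as.list(v), class = "cost_weights")
}

#' @export
print.cost_weights <- function(x, ...) {
  cat(sprintf("<cost_weights> nu = %.4f, lam = %.4f, mu = %.4f\n",
              x$nu, x$lam, x$mu))
  invisible(x)
}

#' Population normalization constants for the cost weights
#'
#' The raw weights are divided by constants so that equally weighted terms
#' have equal influence at the optimum: `b_nu` is the population mean of
#' `k_i^2 + k_j^2`, `b_lam` is the constant 2, and `b_mu` the mean of
#' `1/MVC_i^2 + 1/MVC_j^2`, all taken over the analyzed participants for the
#' designated finger pair.
#'
#' @param pairs a pair table: data frame with one row per participant and
#'   columns `k_i`, `mvc_i`, `k_j`, `mvc_j` (see [as_pair_table()]).
#' @return An object of class `"norm_constants"` with elements `b_nu`,
#'   `b_lam`, `b_mu`.
#' @export
norm_constants <- function(pairs) {
  pairs <- check_pair_table(pairs)
  if (nrow(pairs) == 0L) stop("need at least one participant")
  out <- list(b_nu  = mean(pairs$k_i^2 + pairs$k_j^2),
              b_lam = 2,
              b_mu  = mean(1 / pairs$mvc_i^2 + 1 / pairs$mvc_j^2))
  structure(out, class = "norm_constants")
}

#' @export
print.norm_constants <- function(x, ...) {
  cat(sprintf("<norm_constants> b_nu = %.3e, b_lam = %g, b_mu = %.3e\n",
              x$b_nu, x$b_lam, x$b_mu))
  invisible(x)
}

check_pair_table <- function(pairs) {
  need <- c("k_i", "mvc_i", "k_j", "mvc_j")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)))
    stop("'pairs' must be a data frame with columns ",
         paste(need, collapse = ", "))
  for (cl in need)
    if (any(!is.finite(pairs[[cl]]) | pairs[[cl]] <= 0))
      stop("column '", cl, "' must be strictly positive and finite")
  pairs
}

#' Build a participant-by-pair table from long finger profiles
#'
#' @param profiles long data frame with columns `participant_id`,
#'   `finger_id`, `k`, `mvc`.
#' @param finger_i,finger_j labels of the designated pair; finger i is by
#'   convention the weaker one whose share is modelled.
#' @return Data frame with columns `participant_id`, `k_i`, `mvc_i`, `k_j`,
#'   `mvc_j`, one row per participant having both fingers.
#' @export
as_pair_table <- function(profiles, finger_i = "left_little",
                          finger_j = "right_index") {
  stopifnot(all(c("participant_id", "finger_id", "k", "mvc") %in%
                  names(profiles)))
  pi <- profiles[profiles$finger_id == finger_i, ]
  pj <- profiles[profiles$finger_id == finger_j, ]
  m <- merge(pi[, c("participant_id", "k", "mvc")],
             pj[, c("participant_id", "k", "mvc")],
             by = "participant_id", suffixes = c("_i", "_j"))
  if (nrow(m) == 0L)
    stop("no participant has profiles for both '", finger_i, "' and '",
         finger_j, "'")
  m[order(m$participant_id),
    c("participant_id", "k_i", "mvc_i", "k_j", "mvc_j")]
}

tilde_weights <- function(weights, consts) {
  list(nu_t  = weights$nu / consts$b_nu,
       lam_t = weights$lam / consts$b_lam,
       mu_t  = weights$mu / consts$b_mu)
}

#' Effective quadratic coefficient of one finger
#'
#' The coefficient `a = nu_t*k^2 + lam_t + mu_t/MVC^2` multiplying the
#' squared command of a finger in the expanded cost, where the tilded
#' weights are the raw weights divided by their normalization constants.
#'
#' @param weights a [cost_weights()] object.
#' @param consts a [norm_constants()] object.
#' @param profile a [finger_profile()] (or any list with `k` and `mvc`).
#' @return Positive scalar.
#' @export
effective_coefficient <- function(weights, consts, profile) {
  if (weights$nu + weights$lam + weights$mu <= 0)
    stop("at least one cost weight must be positive")
  tw <- tilde_weights(weights, consts)
  tw$nu_t * profile$k^2 + tw$lam_t + tw$mu_t / profile$mvc^2
}

#' Optimal motor commands for a finger pair
#'
#' Minimizes the static sharing cost
#' `nu_t*(u_i + u_j - g)^2 + a_i*u_i^2 + a_j*u_j^2`. The closed-form
#' stationary point is `u_i* = g * a_j / (a_i + a_j + a_i*a_j/nu_t)` and
#' symmetrically for `u_j*`; the pair satisfies `u_j* = (a_i/a_j) * u_i*`.
#' With a finite error weight the total force undershoots `g` because the
#' effort terms penalize force production.
#'
#' @param a_i,a_j positive effective coefficients
#'   (see [effective_coefficient()]).
#' @param nu_tilde positive normalized error weight `nu / b_nu`.
#' @param g target total force, Newtons (non-negative).
#' @return Named numeric vector `c(u_i, u_j)` in Newtons.
#' @export
optimal_command <- function(a_i, a_j, nu_tilde, g) {
  if (any(a_i <= 0) || any(a_j <= 0) || any(nu_tilde <= 0))
    stop("'a_i', 'a_j' and 'nu_tilde' must be strictly positive")
  if (any(g < 0)) stop("'g' must be non-negative")
  den <- a_i + a_j + a_i * a_j / nu_tilde
  c(u_i = g * a_j / den, u_j = g * a_i / den)
}

#' Optimal force share of finger i
#'
#' The fraction of total force assigned to finger i at the optimum,
#' `c* = a_j / (a_i + a_j)`. It does not depend on the target force `g` nor
#' on a common rescaling of the raw weights.
#'
#' @inheritParams optimal_command
#' @return Scalar (vectorized) in `(0, 1)`.
#' @export
optimal_share <- function(a_i, a_j) {
  if (any(a_i <= 0) || any(a_j <= 0))
    stop("effective coefficients must be strictly positive")
  a_j / (a_i + a_j)
}

#' Static sharing cost of a command pair
#'
#' Evaluates the expanded quadratic form
#' `nu_t*(u_i + u_j - g)^2 + a_i*u_i^2 + a_j*u_j^2`, which equals the
#' expectation form `nu_t*E[(x_i + x_j - g)^2] + lam_t*(u_i^2 + u_j^2) +
#' mu_t*((u_i/MVC_i)^2 + (u_j/MVC_j)^2)` under independent signal-dependent
#' noise `x ~ N(u, (k*u)^2)`.
#'
#' @param u_i,u_j motor commands, Newtons.
#' @param g target total force, Newtons.
#' @param weights a [cost_weights()] object.
#' @param consts a [norm_constants()] object.
#' @param profile_i,profile_j [finger_profile()] objects for the pair.
#' @return Scalar cost (dimensionless up to the weight units).
#' @export
sharing_cost <- function(u_i, u_j, g, weights, consts, profile_i, profile_j) {
  tw <- tilde_weights(weights, consts)
  a_i <- effective_coefficient(weights, consts, profile_i)
  a_j <- effective_coefficient(weights, consts, profile_j)
  tw$nu_t * (u_i + u_j - g)^2 + a_i * u_i^2 + a_j * u_j^2
}

# Fast vectorized path used by the sampler: precompute per-participant
# squared noise and inverse-squared strength for the pair table.
pair_stats <- function(pairs) {
  list(k2i  = pairs$k_i^2,  k2j  = pairs$k_j^2,
       im2i = 1 / pairs$mvc_i^2, im2j = 1 / pairs$mvc_j^2,
       participant_id = pairs$participant_id)
}

cstar_from_stats <- function(nu, lam, mu, consts, ps) {
  nu_t  <- nu / consts$b_nu
  lam_t <- lam / consts$b_lam
  mu_t  <- mu / consts$b_mu
  a_i <- nu_t * ps$k2i + lam_t + mu_t * ps$im2i
  a_j <- nu_t * ps$k2j + lam_t + mu_t * ps$im2j
  a_j / (a_i + a_j)
}

#' Optimal shares for every participant in a pair table
#'
#' @param weights a [cost_weights()] object.
#' @param consts a [norm_constants()] object.
#' @param pairs pair table (see [as_pair_table()]).
#' @return Numeric vector of shares `c*` in `(0, 1)`, one per participant.
#' @export
pair_shares <- function(weights, consts, pairs) {
  pairs <- check_pair_table(pairs)
  if (weights$nu + weights$lam + weights$mu <= 0)
    stop("at least one cost weight must be positive")
  cstar_from_stats(weights$nu, weights$lam, weights$mu, consts,
                   pair_stats(pairs))
}

#' Optimal commands for every participant in a pair table
#'
#' @inheritParams pair_shares
#' @param g target total force, Newtons. Requires `nu > 0` (with no error
#'   weight the optimum is to produce no force at all).
#' @return Data frame `participant_id`, `u_i`, `u_j`, `share_i`.
#' @export
pair_commands <- function(weights, consts, pairs, g) {
  pairs <- check_pair_table(pairs)
  if (weights$nu <= 0)
    stop("'g'-level force predictions require a positive error weight nu")
  tw <- tilde_weights(weights, consts)
  ps <- pair_stats(pairs)
  a_i <- tw$nu_t * ps$k2i + tw$lam_t + tw$mu_t * ps$im2i
  a_j <- tw$nu_t * ps$k2j + tw$lam_t + tw$mu_t * ps$im2j
  den <- a_i + a_j + a_i * a_j / tw$nu_t
  data.frame(participant_id = pairs$participant_id,
             u_i = g * a_j / den, u_j = g * a_i / den,
             share_i = a_j / (a_i + a_j))
}
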