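# Seeded generators for every pipeline input: participant populations of
# finger profiles, unimanual recordings with signal-dependent noise, and
# per-level share datasets from known ground-truth weights.

# Population means/SDs of k (fraction) and MVC (N) per finger, matching the
# measured study population of 14 adults.
finger_param_table <- data.frame(
  finger_id = c("left_index", "right_index", "left_little", "right_little"),
  mean_k   = c(0.0128, 0.0162, 0.0238, 0.0179),
  sd_k     = c(0.0063, 0.0059, 0.0120, 0.0075),
  mean_mvc = c(20.43, 23.29, 12.71, 13.43),
  sd_mvc   = c(4.09, 5.18, 2.30, 2.87),
  stringsAsFactors = FALSE)

#' Reference population parameters per finger
#'
#' Mean and SD of the coefficient of variation `k` (as a fraction) and of
#' MVC (Newtons) for the four study fingers, as measured in the experiment
#' the generator emulates.
#'
#' @param fingers which fingers to return.
#' @return Data frame `finger_id`, `mean_k`, `sd_k`, `mean_mvc`, `sd_mvc`.
#' @export
default_finger_params <- function(fingers = c("left_little", "right_index")) {
  stopifnot(all(fingers %in% finger_param_table$finger_id))
  finger_param_table[match(fingers, finger_param_table$finger_id), ]
}

#' Population specification for profile sampling
#'
#' @param M number of participants (default 14, the study sample size).
#' @param fingers per-finger parameter data frame as returned by
#'   [default_finger_params()].
#' @param rho optional within-finger correlation between `k` and MVC
#'   (default 0).
#' @return Object of class `"population_spec"`.
#' @export
population_spec <- function(M = 14L, fingers = default_finger_params(),
                            rho = 0) {
  stopifnot(is.data.frame(fingers),
            all(c("finger_id", "mean_k", "sd_k", "mean_mvc", "sd_mvc") %in%
                  names(fingers)))
  if (!is.finite(M) || M < 1L) stop("'M' must be >= 1")
  if (any(fingers$mean_k <= 0) || any(fingers$mean_mvc <= 0) ||
      any(fingers$sd_k < 0) || any(fingers$sd_mvc < 0))
    stop("population means must be positive and SDs non-negative")
  if (abs(rho) >= 1) stop("'rho' must be in (-1, 1)")
  structure(list(M = as.integer(M), fingers = fingers, rho = rho),
            class = "population_spec")
}

# truncated-at-zero bivariate normal draws for one finger's (k, mvc)
rtrunc_profile <- function(n, mean_k, sd_k, mean_mvc, sd_mvc, rho) {
  k <- numeric(n); mvc <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    e1 <- stats::rnorm(m)
    e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(m)
    kk <- mean_k + sd_k * e1
    mm <- mean_mvc + sd_mvc * e2
    ok <- kk > 0 & mm > 0
    k[need[ok]] <- kk[ok]
    mvc[need[ok]] <- mm[ok]
    need <- need[!ok]
  }
  data.frame(k = k, mvc = mvc)
}

#' Sample a participant population of finger profiles
#'
#' Draws each finger's `(k, MVC)` from a (correlated, zero-truncated)
#' normal with the spec's means and SDs, independently across participants.
#'
#' @param spec a [population_spec()].
#' @param seed optional integer seed (the draw is a pure function of
#'   `(spec, seed)`).
#' @return Long profile data frame: `participant_id`, `finger_id`, `k`,
#'   `mvc`.
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%02d", seq_len(spec$M))
  out <- lapply(seq_len(nrow(spec$fingers)), function(r) {
    p <- spec$fingers[r, ]
    d <- rtrunc_profile(spec$M, p$mean_k, p$sd_k, p$mean_mvc, p$sd_mvc,
                        spec$rho)
    data.frame(participant_id = ids, finger_id = p$finger_id,
               k = d$k, mvc = d$mvc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one finger's unimanual session
#'
#' For each target level the produced force ramps linearly to its plateau
#' over the first `ramp` seconds, then holds; every sample carries i.i.d.
#' Gaussian signal-dependent noise with SD `k` times the momentary command.
#' Targets above the finger's MVC plateau at MVC (failed trials), so a
#' maintained-force criterion recovers the MVC.
#'
#' @param profile a [finger_profile()].
#' @param targets target levels in Newtons (default 2, 4, ... N up to just
#'   above the finger's MVC).
#' @param rate sampling rate, Hz.
#' @param duration trial length, seconds.
#' @param ramp ramp-up time, seconds.
#' @param seed optional integer seed.
#' @return List of [trial_recording()] objects, one per target.
#' @export
simulate_unimanual <- function(profile, targets = NULL, rate = 200,
                               duration = 7, ramp = 1.5, seed = NULL) {
  stopifnot(inherits(profile, "finger_profile"))
  if (is.null(targets))
    targets <- seq(2, 2 * ceiling(profile$mvc / 2) + 2, by = 2)
  if (length(targets) == 0L) stop("empty target list")
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate * duration)
  tt <- (seq_len(n) - 0.5) / rate
  lapply(targets, function(g) {
    plateau <- min(g, profile$mvc)
    u <- pmin(tt / ramp, 1) * plateau
    force <- stats::rnorm(n, mean = u, sd = profile$k * u)
    trial_recording(profile$finger_id, g, force, rate)
  })
}

#' Simulate a full unimanual session for a population
#'
#' @param profiles long profile data frame (`participant_id`, `finger_id`,
#'   `k`, `mvc`), e.g. from [sample_population()].
#' @param rate,duration,ramp as in [simulate_unimanual()].
#' @param seed optional integer seed.
#' @return Long trial table `participant_id`, `finger_id`, `target_g`, `t`,
#'   `force`, the schema [calibrate_profiles()] reads.
#' @export
simulate_session <- function(profiles, rate = 200, duration = 7, ramp = 1.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(profiles)), function(r) {
    pr <- finger_profile(profiles$finger_id[r], profiles$k[r],
                         profiles$mvc[r])
    recs <- simulate_unimanual(pr, rate = rate, duration = duration,
                               ramp = ramp)
    do.call(rbind, lapply(recs, function(rec)
      data.frame(participant_id = profiles$participant_id[r],
                 finger_id = rec$finger_id, target_g = rec$target_g,
                 t = (seq_along(rec$force) - 0.5) / rec$rate,
                 force = rec$force)))
  })
  do.call(rbind, rows)
}

#' Scenario specification for bimanual share data
#'
#' @param levels force levels, Newtons.
#' @param weights ground-truth [cost_weights()] per level: a single object
#'   (recycled) or a list of length `length(levels)`.
#' @param N_lm observations per participant per level.
#' @param sigma_y share-scale noise SD: a scalar, or one value per
#'   participant.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(levels, weights, N_lm = 50L, sigma_y = 0.05) {
  if (any(!is.finite(levels) | levels <= 0)) stop("levels must be positive")
  if (inherits(weights, "cost_weights"))
    weights <- rep(list(weights), length(levels))
  stopifnot(is.list(weights), length(weights) == length(levels),
            all(vapply(weights, inherits, logical(1), "cost_weights")))
  if (N_lm < 1L) stop("'N_lm' must be >= 1")
  if (any(sigma_y <= 0)) stop("'sigma_y' must be positive")
  structure(list(levels = levels, weights = weights,
                 N_lm = as.integer(N_lm), sigma_y = sigma_y),
            class = "scenario_spec")
}

#' The bundled default scenario
#'
#' Emulates the study design: 14 participants, seven force levels from 4 to
#' 28 N, a small constant error weight (`nu = 0.1`) and an absolute-effort
#' weight that falls linearly from 0.7 at the lowest level to 0.35 at the
#' highest while the normalized-effort weight rises correspondingly — the
#' qualitative sharing behaviour seen at large forces.
#'
#' @param levels force levels, Newtons.
#' @param N_lm observations per participant per level.
#' @param sigma_y share-scale noise SD.
#' @return A [scenario_spec()].
#' @export
default_scenario <- function(levels = seq(4, 28, by = 4), N_lm = 50L,
                             sigma_y = 0.05) {
  lam <- seq(0.7, 0.35, length.out = length(levels))
  wts <- lapply(seq_along(levels), function(i)
    cost_weights(nu = 0.1, lam = lam[i], mu = 0.9 - lam[i]))
  scenario_spec(levels, wts, N_lm = N_lm, sigma_y = sigma_y)
}

#' Simulate per-level share datasets from ground-truth weights
#'
#' For each level and participant the observed shares are the participant's
#' optimal share `c*` under the level's ground-truth weights plus additive
#' Gaussian noise on the share scale, truncated to `(0, 1)` by resampling.
#' A warning is raised if truncation touches more than 0.1% of draws.
#'
#' @param pairs pair table of the population (see [as_pair_table()]).
#' @param scenario a [scenario_spec()].
#' @param consts [norm_constants()] used for the ground-truth shares;
#'   defaults to constants computed from `pairs`.
#' @param seed optional integer seed.
#' @return Named list of [share_dataset()] objects, one per level, with the
#'   ground-truth shares attached as attribute `"truth"`.
#' @export
simulate_share_data <- function(pairs, scenario, consts = NULL,
                                seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  pairs <- check_pair_table(pairs)
  if (is.null(consts)) consts <- norm_constants(pairs)
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(pairs)
  sig <- rep_len(scenario$sigma_y, M)
  n_trunc <- 0L; n_draw <- 0L
  out <- lapply(seq_along(scenario$levels), function(li) {
    cst <- pair_shares(scenario$weights[[li]], consts, pairs)
    rows <- lapply(seq_len(M), function(m) {
      y <- cst[m] + sig[m] * stats::rnorm(scenario$N_lm)
      bad <- which(y <= 0 | y >= 1)
      n_draw <<- n_draw + scenario$N_lm
      n_trunc <<- n_trunc + length(bad)
      while (length(bad)) {
        y[bad] <- cst[m] + sig[m] * stats::rnorm(length(bad))
        bad <- bad[y[bad] <= 0 | y[bad] >= 1]
      }
      data.frame(participant_id = pairs$participant_id[m], y = y)
    })
    ds <- share_dataset(scenario$levels[li], do.call(rbind, rows), pairs)
    attr(ds, "truth") <- list(weights = scenario$weights[[li]],
                              cstar = cst, sigma_y = sig)
    ds
  })
  if (n_trunc > 0.001 * n_draw)
    warning(sprintf("share truncation affected %.2f%% of draws; ",
                    100 * n_trunc / n_draw),
            "the additive-Gaussian reading of the share noise is strained")
  names(out) <- paste0("level_", scenario$levels)
  out
}
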