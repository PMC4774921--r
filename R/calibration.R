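# Calibration of finger profiles from unimanual trials: coefficient of
# variation k by robust no-intercept regression of force SD on mean force,
# and MVC as the highest maintained target level.

#' One unimanual force recording
#'
#' @param finger_id finger label.
#' @param target_g target force level, Newtons.
#' @param force sampled force series, Newtons.
#' @param rate sampling rate in Hz (nominally 200).
#' @return An object of class `"trial_recording"`.
#' @export
trial_recording <- function(finger_id, target_g, force, rate = 200) {
  stopifnot(is.character(finger_id), length(finger_id) == 1L)
  if (!is.numeric(force) || length(force) == 0L || any(!is.finite(force)))
    stop("'force' must be a non-empty finite numeric series")
  if (!is.finite(rate) || rate <= 0) stop("'rate' must be positive (Hz)")
  if (!is.finite(target_g) || target_g < 0)
    stop("'target_g' must be a non-negative force")
  structure(list(finger_id = finger_id, target_g = target_g,
                 force = as.numeric(force), rate = rate,
                 duration = length(force) / rate),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s @ %g N: %d samples, %.1f s @ %g Hz\n",
              x$finger_id, x$target_g, length(x$force), x$duration, x$rate))
  invisible(x)
}

# Default analysis window: drop the first 1.5 s ramp-up and the last 0.5 s
# of the nominal 7 s hold, expressed as fractions of the recording.
default_window <- c(1.5, 6.5) / 7

window_index <- function(n, window) {
  if (length(window) != 2L || any(!is.finite(window)) ||
      window[1] < 0 || window[2] > 1 || window[1] >= window[2])
    stop("'window' must be a fraction pair within [0, 1] with start < end")
  i0 <- floor(n * window[1]) + 1L
  i1 <- ceiling(n * window[2])
  if (i1 - i0 + 1L < 1L) stop("window excludes all samples")
  i0:i1
}

#' Windowed mean and SD of a trial
#'
#' @param rec a [trial_recording()].
#' @param window fraction pair of the recording to retain; the default keeps
#'   the middle 5 s of a 7 s trial.
#' @return An object of class `"trial_summary"`: `target_g`, `mean_force`,
#'   `sd_force`, `n_samples`. SD uses the n-1 denominator.
#' @export
trial_summary <- function(rec, window = default_window) {
  stopifnot(inherits(rec, "trial_recording"))
  idx <- window_index(length(rec$force), window)
  if (length(idx) < 2L) stop("need at least 2 samples in the window")
  x <- rec$force[idx]
  structure(list(target_g = rec$target_g, mean_force = mean(x),
                 sd_force = stats::sd(x), n_samples = length(x)),
            class = "trial_summary")
}

summaries_frame <- function(summaries) {
  if (inherits(summaries, "trial_summary")) summaries <- list(summaries)
  if (is.data.frame(summaries)) return(summaries)
  do.call(rbind, lapply(summaries, function(s)
    data.frame(target_g = s$target_g, mean_force = s$mean_force,
               sd_force = s$sd_force, n_samples = s$n_samples)))
}

#' Coefficient of variation from per-level trial summaries
#'
#' Fits `sd_force = k * mean_force` (no intercept: the signal-dependent
#' noise model has none) by iteratively re-weighted least squares with
#' bisquare weights (tuning constant 4.685, convergence 1e-8, at most 100
#' iterations), so isolated outlying levels are down-weighted. When the
#' points are exactly collinear through the origin the ordinary
#' least-squares slope is returned directly.
#'
#' @param summaries list of [trial_summary()] objects (or an equivalent
#'   data frame) for one finger, at three or more distinct force levels.
#' @return Estimated `k`, a dimensionless fraction.
#' @export
estimate_cv <- function(summaries) {
  d <- summaries_frame(summaries)
  if (nrow(d) < 3L || length(unique(round(d$mean_force, 10))) < 3L)
    stop("need trial summaries at >= 3 distinct mean force levels")
  if (all(abs(d$mean_force) < 1e-12)) stop("all mean forces are zero")
  ols <- sum(d$mean_force * d$sd_force) / sum(d$mean_force^2)
  res <- d$sd_force - ols * d$mean_force
  # noiseless line through the origin: IRLS scale would degenerate
  if (max(abs(res)) <= 1e-10 * max(abs(d$sd_force), 1e-300)) return(ols)
  fit <- MASS::rlm(sd_force ~ mean_force - 1, data = d,
                   psi = MASS::psi.bisquare, c = 4.685,
                   acc = 1e-8, maxit = 100)
  unname(stats::coef(fit)[1])
}

#' Maximum voluntary contraction from unimanual trials
#'
#' A level counts as maintained when the windowed mean force reaches at
#' least `threshold` of the target; the MVC estimate is the highest
#' maintained target.
#'
#' @param recs list of [trial_recording()] objects for one finger.
#' @param threshold maintained-force criterion as a fraction of target.
#' @param window analysis window passed to [trial_summary()].
#' @return MVC estimate in Newtons.
#' @export
estimate_mvc <- function(recs, threshold = 0.95, window = default_window) {
  if (inherits(recs, "trial_recording")) recs <- list(recs)
  if (length(recs) == 0L) stop("need at least one trial")
  held <- vapply(recs, function(r) {
    s <- trial_summary(r, window)
    s$mean_force >= threshold * r$target_g
  }, logical(1))
  if (!any(held)) stop("no trial satisfies the maintained-force criterion")
  max(vapply(recs[held], function(r) r$target_g, numeric(1)))
}

#' Association between noise coefficient and strength across fingers
#'
#' Ordinary least-squares regression of `k` on `MVC` with intercept over all
#' fingers and participants, with the slope t-statistic on `n - 2` degrees
#' of freedom and the Pearson correlation.
#'
#' @param profiles data frame with columns `k` and `mvc` (one row per
#'   finger x participant).
#' @return List of class `"cv_mvc_assoc"`: `slope`, `t_stat`, `df`,
#'   `p_value`, `r`, `n`.
#' @export
cv_mvc_association <- function(profiles) {
  stopifnot(all(c("k", "mvc") %in% names(profiles)))
  d <- profiles[is.finite(profiles$k) & is.finite(profiles$mvc), ]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 (k, MVC) points")
  if (stats::sd(d$mvc) == 0) stop("MVC is constant; slope undefined")
  fit <- stats::lm(k ~ mvc, data = d)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["mvc", "Estimate"]),
                 t_stat = unname(cf["mvc", "t value"]),
                 df = n - 2L,
                 p_value = unname(cf["mvc", "Pr(>|t|)"]),
                 r = stats::cor(d$k, d$mvc),
                 n = n),
            class = "cv_mvc_assoc")
}

#' @export
print.cv_mvc_assoc <- function(x, ...) {
  cat(sprintf(
    "<cv_mvc_assoc> slope = %.3g, t(%d) = %.2f, p = %.4g, r = %.4f (n = %d)\n",
    x$slope, x$df, x$t_stat, x$p_value, x$r, x$n))
  invisible(x)
}

#' Calibrate finger profiles from a long trial table
#'
#' Groups a long-format trial table by participant and finger, summarizes
#' each target level over the analysis window, and estimates `k`
#' ([estimate_cv()]) and MVC ([estimate_mvc()]) per finger.
#'
#' @param trials data frame with columns `participant_id`, `finger_id`,
#'   `target_g`, `t`, `force` (one row per sample), as written by
#'   [simulate_session()] or read with [read_trials_csv()].
#' @param rate sampling rate in Hz.
#' @param window analysis window (fraction pair).
#' @param mvc_threshold maintained-force criterion for MVC.
#' @return Profile data frame: `participant_id`, `finger_id`, `k`, `mvc`.
#' @export
calibrate_profiles <- function(trials, rate = 200, window = default_window,
                               mvc_threshold = 0.95) {
  need <- c("participant_id", "finger_id", "target_g", "t", "force")
  stopifnot(all(need %in% names(trials)))
  keys <- unique(trials[, c("participant_id", "finger_id")])
  out <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- trials[trials$participant_id == keys$participant_id[r] &
                    trials$finger_id == keys$finger_id[r], ]
    recs <- lapply(split(sub, sub$target_g), function(tr) {
      tr <- tr[order(tr$t), ]
      trial_recording(keys$finger_id[r], tr$target_g[1], tr$force, rate)
    })
    mvc <- estimate_mvc(recs, mvc_threshold, window)
    held <- vapply(recs, function(rc) rc$target_g <= mvc, logical(1))
    sums <- lapply(recs[held], trial_summary, window = window)
    data.frame(participant_id = keys$participant_id[r],
               finger_id = keys$finger_id[r],
               k = estimate_cv(sums), mvc = mvc)
  })
  do.call(rbind, out)
}
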