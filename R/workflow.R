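# End-to-end orchestration: simulate (or read) inputs, calibrate profiles,
# fit the cost weights per force level, summarize, compare models, and
# write all artifacts with a reproducibility manifest.

#' Assemble and validate a pipeline configuration
#'
#' @param scenario a [scenario_spec()] for simulated share data, or `NULL`
#'   when reading observed data from `trials_csv`/`share_csv`.
#' @param population a [population_spec()] used when simulating.
#' @param trials_csv,share_csv input paths for observed data (ignored when
#'   `scenario` is given).
#' @param finger_i,finger_j the designated pair; finger i is the weaker
#'   finger whose share is modelled.
#' @param T,burn_in sampler settings per level.
#' @param seed master seed for every stochastic stage.
#' @param prior variance prior (`"invga00"` or `"flat"`).
#' @param variance variance structure.
#' @param compare_models fit and tabulate all seven weight subsets
#'   (otherwise only the full model is fitted).
#' @param calibrate_from_trials when simulating, re-estimate the finger
#'   profiles from simulated unimanual sessions (as the experiment does)
#'   instead of using the generator's true profiles.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(scenario = default_scenario(),
                       population = population_spec(),
                       trials_csv = NULL, share_csv = NULL,
                       finger_i = "left_little", finger_j = "right_index",
                       T = 9000L, burn_in = 4000L, seed = 1L,
                       prior = "invga00", variance = "per_participant",
                       compare_models = FALSE,
                       calibrate_from_trials = TRUE) {
  if (identical(finger_i, finger_j)) stop("the pair fingers must differ")
  if (!(T > burn_in) || burn_in < 0) stop("need T > burn_in >= 0")
  if (is.null(scenario)) {
    if (is.null(share_csv)) stop("need either a scenario or a share CSV")
    if (!file.exists(share_csv)) stop("share CSV not found: ", share_csv)
    if (!is.null(trials_csv) && !file.exists(trials_csv))
      stop("trials CSV not found: ", trials_csv)
  } else stopifnot(inherits(scenario, "scenario_spec"),
                   inherits(population, "population_spec"))
  structure(list(scenario = scenario, population = population,
                 trials_csv = trials_csv, share_csv = share_csv,
                 finger_i = finger_i, finger_j = finger_j,
                 T = as.integer(T), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), prior = prior,
                 variance = variance, compare_models = compare_models,
                 calibrate_from_trials = calibrate_from_trials),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `scenario`
#' may be given as a mapping with `levels`, `nu`, `lam` (per level), `N_lm`
#' and `sigma_y`.
#'
#' @param path YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    nu <- rep_len(sc$nu, length(sc$levels))
    lam <- rep_len(sc$lam, length(sc$levels))
    wts <- lapply(seq_along(sc$levels), function(i)
      cost_weights(nu[i], lam[i], 1 - nu[i] - lam[i]))
    y$scenario <- scenario_spec(sc$levels, wts,
                                N_lm = sc$N_lm %||% 50L,
                                sigma_y = sc$sigma_y %||% 0.05)
  }
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_msg <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(proc.time()[3] - t0)))
}

#' Run the complete pipeline
#'
#' Executes calibrate, fit-per-level, summarize and (optionally) compare,
#' writing every artifact plus a JSON manifest that suffices to reproduce
#' the run. With a scenario config, the population and all data are
#' simulated first under the master seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose log per-stage timing to stderr.
#' @return Invisibly, a list with `profiles`, `pairs`, `datasets`, `fits`
#'   (one chain per level), `report`, and `comparison` (or `NULL`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()[3]
  if (!is.null(config$scenario)) {
    profiles_true <- sample_population(config$population,
                                       seed = config$seed)
    if (config$calibrate_from_trials) {
      trials <- simulate_session(profiles_true, seed = config$seed + 1L)
      profiles <- calibrate_profiles(trials)
    } else profiles <- profiles_true
    pairs_true <- as_pair_table(profiles_true, config$finger_i,
                                config$finger_j)
    datasets <- simulate_share_data(pairs_true, config$scenario,
                                    seed = config$seed + 2L)
  } else {
    profiles <- if (!is.null(config$trials_csv))
      calibrate_profiles(read_trials_csv(config$trials_csv))
    else read_profiles_csv(file.path(dirname(config$share_csv),
                                     "profiles.csv"))
    datasets <- NULL
  }
  pairs <- as_pair_table(profiles, config$finger_i, config$finger_j)
  if (is.null(datasets)) datasets <- read_share_csv(config$share_csv, pairs)
  else datasets <- lapply(datasets, function(ds)
    share_dataset(ds$level_g,
                  data.frame(participant_id = ds$participant_id[ds$pidx],
                             y = ds$y), pairs))
  consts <- norm_constants(pairs)
  write_profiles_csv(profiles, file.path(out_dir, "profiles.csv"))
  write_share_csv(datasets, file.path(out_dir, "shares.csv"))
  stage_msg(verbose, "calibrate", t0)

  t0 <- proc.time()[3]
  full <- model_spec(variance = config$variance)
  fits <- lapply(seq_along(datasets), function(li)
    run_chain(datasets[[li]], full, consts, T = config$T,
              burn_in = config$burn_in,
              seed = chain_seed(config$seed, 0L, li),
              prior = config$prior))
  names(fits) <- names(datasets)
  dir.create(file.path(out_dir, "chains"), showWarnings = FALSE)
  for (nm in names(fits))
    write_chain(fits[[nm]], file.path(out_dir, "chains",
                                      paste0(nm, ".csv")))
  stage_msg(verbose, "fit", t0)

  t0 <- proc.time()[3]
  report <- report_weights(fits)
  utils::write.csv(report, file.path(out_dir, "weights_report.csv"),
                   row.names = FALSE, quote = FALSE)
  comparison <- NULL
  if (isTRUE(config$compare_models)) {
    comparison <- fit_all_models(datasets, variance = config$variance,
                                 consts = consts, T = config$T,
                                 burn_in = config$burn_in,
                                 seed = config$seed, prior = config$prior)
    utils::write.csv(as.data.frame(comparison),
                     file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(format_comparison(comparison),
               file.path(out_dir, "comparison.txt"))
  }
  stage_msg(verbose, "report", t0)

  manifest <- list(
    package = "forceshare",
    package_version = as.character(utils::packageVersion("forceshare")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, T = config$T, burn_in = config$burn_in,
    prior = config$prior, variance = config$variance,
    finger_i = config$finger_i, finger_j = config$finger_j,
    simulated = !is.null(config$scenario),
    levels = vapply(datasets, function(d) d$level_g, numeric(1)),
    config = config_fingerprint(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profiles = profiles, pairs = pairs, datasets = datasets,
                 consts = consts, fits = fits, report = report,
                 comparison = comparison))
}

# flatten the config into plain JSON-serializable values
config_fingerprint <- function(config) {
  fp <- config
  class(fp) <- NULL
  if (!is.null(fp$scenario)) {
    sc <- fp$scenario
    fp$scenario <- list(levels = sc$levels, N_lm = sc$N_lm,
                        sigma_y = sc$sigma_y,
                        weights = lapply(sc$weights, function(w)
                          c(nu = w$nu, lam = w$lam, mu = w$mu)))
  }
  if (!is.null(fp$population)) {
    fp$population <- list(M = fp$population$M, rho = fp$population$rho,
                          fingers = fp$population$fingers)
  }
  fp
}

#' Long-format per-level weight summaries
#'
#' One row per force level and parameter with the posterior median and
#' equal-tailed 95% interval. The three marginal medians at a level need
#' not sum to 1.
#'
#' @param fits named list of [run_chain()] results (one per level).
#' @return Data frame `level_g`, `parameter`, `median`, `lo95`, `hi95`.
#' @export
report_weights <- function(fits) {
  if (inherits(fits, "posterior_chain")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  out <- lapply(fits, function(ch) {
    s <- posterior_summary(ch)
    s <- s[s$parameter %in% c("nu", "lam", "mu"), ]
    cbind(level_g = ch$level_g, s)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot posterior weight trajectories across force levels
#'
#' Medians (solid) and 95% intervals (dashed) per parameter against the
#' force level, on the current graphics device.
#'
#' @param report a [report_weights()] table.
#' @export
plot_weight_report <- function(report) {
  pars <- c("nu", "lam", "mu")
  cols <- c(nu = "#D55E00", lam = "#0072B2", mu = "#009E73")
  graphics::plot(range(report$level_g), c(0, 1), type = "n",
                 xlab = "force level (N)", ylab = "posterior weight")
  for (p in pars) {
    d <- report[report$parameter == p, ]
    d <- d[order(d$level_g), ]
    graphics::lines(d$level_g, d$median, col = cols[[p]], lwd = 2)
    graphics::lines(d$level_g, d$lo95, col = cols[[p]], lty = 2)
    graphics::lines(d$level_g, d$hi95, col = cols[[p]], lty = 2)
  }
  graphics::legend("topright", legend = pars, col = cols[pars], lwd = 2,
                   bty = "n")
}

#' Plot fitted versus produced forces
#'
#' @param pred a [predict_forces()] table.
#' @param observed data frame with `participant_id`, `u_i`, `u_j` observed
#'   mean forces.
#' @export
plot_fitted_vs_produced <- function(pred, observed) {
  m <- merge(pred, observed, by = "participant_id",
             suffixes = c("_fit", "_obs"))
  lim <- range(m$u_i_fit, m$u_j_fit, m$u_i_obs, m$u_j_obs)
  graphics::plot(m$u_i_fit, m$u_i_obs, xlim = lim, ylim = lim, pch = 19,
                 col = "#D55E00", xlab = "fitted force (N)",
                 ylab = "produced force (N)")
  graphics::points(m$u_j_fit, m$u_j_obs, pch = 17, col = "#0072B2")
  graphics::abline(0, 1, lty = 3)
  graphics::legend("topleft", legend = c("finger i", "finger j"),
                   pch = c(19, 17), col = c("#D55E00", "#0072B2"),
                   bty = "n")
}
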