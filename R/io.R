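# Plain-CSV interfaces: long trial tables, finger profiles, per-level share
# observations, and chain output (samples CSV + JSON sidecar).

# write.csv via as.character truncates doubles to 15 significant digits;
# format with 17 so a write/read round trip is bit-exact
full_precision <- function(d) {
  for (cl in names(d))
    if (is.double(d[[cl]])) d[[cl]] <- sprintf("%.17g", d[[cl]])
  d
}

#' Read a long-format unimanual trial table
#'
#' Expects columns `participant_id`, `finger_id`, `target_g`, `t`, `force`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "finger_id", "target_g", "t", "force")
  if (!all(need %in% names(d)))
    stop("trials CSV must have columns ", paste(need, collapse = ", "))
  d
}

#' Read / write per-finger profile tables
#'
#' Columns `participant_id`, `finger_id`, `k`, `mvc`; `k` is stored as a
#' dimensionless fraction.
#'
#' @param path CSV file path.
#' @return `read_profiles_csv` returns the data frame;
#'   `write_profiles_csv` returns `path` invisibly.
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "finger_id", "k", "mvc")
  if (!all(need %in% names(d)))
    stop("profiles CSV must have columns ", paste(need, collapse = ", "))
  d
}

#' @rdname read_profiles_csv
#' @param profiles profile data frame.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(full_precision(profiles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write share observations
#'
#' Long CSV with columns `level_g`, `participant_id`, `y`.
#'
#' @param path CSV file path.
#' @param pairs pair table used to build the per-level [share_dataset()]s.
#' @return `read_share_csv` returns a named list of [share_dataset()]s.
#' @export
read_share_csv <- function(path, pairs) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level_g", "participant_id", "y")
  if (!all(need %in% names(d)))
    stop("share CSV must have columns ", paste(need, collapse = ", "))
  levels <- sort(unique(d$level_g))
  out <- lapply(levels, function(l)
    share_dataset(l, d[d$level_g == l, c("participant_id", "y")], pairs))
  names(out) <- paste0("level_", levels)
  out
}

#' @rdname read_share_csv
#' @param datasets named list of [share_dataset()]s.
#' @export
write_share_csv <- function(datasets, path) {
  rows <- lapply(datasets, function(ds)
    data.frame(level_g = ds$level_g,
               participant_id = ds$participant_id[ds$pidx], y = ds$y))
  utils::write.csv(full_precision(do.call(rbind, rows)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a posterior chain to CSV with a JSON sidecar
#'
#' The CSV holds one row per iteration (weight coordinates, weights,
#' log-likelihood, variances); the sidecar records seed, T, burn-in, prior,
#' model and acceptance rates.
#'
#' @param chain a [run_chain()] result.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  utils::write.csv(full_precision(cbind(as.data.frame(chain$samples),
                                        as.data.frame(chain$sig2))),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(level_g = chain$level_g, model = model_label(chain$spec),
               variance = chain$spec$variance, prior = chain$prior,
               T = chain$T, burn_in = chain$burn_in, seed = chain$seed,
               accept = as.list(chain$accept))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
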