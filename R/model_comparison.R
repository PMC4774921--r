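# Comparison of the seven weight-subset models (and both variance
# structures) by posterior-averaged log-likelihood, Bayes factors on that
# scale, and AIC with the maximum likelihood taken over MCMC samples.

#' Log-likelihood averaged over retained MCMC samples
#'
#' The arithmetic mean of the data log-likelihood evaluated at every post
#' burn-in sample — the fit measure used for the Bayes-factor comparison.
#' Note this is a posterior average of the log-likelihood, not a true
#' marginal likelihood.
#'
#' @param chain a [run_chain()] result (which stores the per-iteration
#'   log-likelihood).
#' @param data optional [share_dataset()]; when supplied the log-likelihood
#'   is recomputed at every retained sample instead of using the stored
#'   trace (slow; intended for verification).
#' @return Scalar nats.
#' @export
averaged_loglik <- function(chain, data = NULL) {
  r <- retained(chain)
  if (is.null(data)) return(mean(r$samples[, "loglik"]))
  ll <- vapply(seq_len(nrow(r$samples)), function(i) {
    wts <- cost_weights(r$samples[i, "nu"], r$samples[i, "lam"],
                        r$samples[i, "mu"])
    log_likelihood(data, wts, as.numeric(r$sig2[i, ]), chain$consts)
  }, numeric(1))
  mean(ll)
}

#' Maximum log-likelihood over retained MCMC samples
#'
#' @param chain a [run_chain()] result.
#' @return Scalar nats.
#' @export
max_loglik <- function(chain) {
  max(retained(chain)$samples[, "loglik"])
}

#' Log Bayes factor from two averaged log-likelihoods
#'
#' The comparison reports `B = exp(ll_a - ll_b)`; this returns the log,
#' `ll_a - ll_b`, in nats.
#'
#' @param ll_a,ll_b averaged log-likelihoods of models a and b.
#' @return Scalar nats; positive favours model a.
#' @export
log_bayes_factor <- function(ll_a, ll_b) {
  stopifnot(is.finite(ll_a), is.finite(ll_b))
  ll_a - ll_b
}

#' Akaike information criterion
#'
#' @param max_loglik maximum log-likelihood.
#' @param d number of free parameters (non-negative).
#' @return `-2 * max_loglik + 2 * d`; lower is better.
#' @export
aic <- function(max_loglik, d) {
  if (any(d < 0)) stop("'d' must be non-negative")
  -2 * max_loglik + 2 * d
}

all_free_sets <- function() {
  list(c("nu", "lam", "mu"), c("lam", "mu"), c("nu", "mu"), c("nu", "lam"),
       "mu", "lam", "nu")
}

#' Fit all weight-subset models across force levels
#'
#' Runs the sampler independently per force level for each of the seven
#' non-empty subsets of `{nu, lam, mu}`, sums the per-level averaged and
#' maximum log-likelihoods over levels, and tabulates AIC with
#' `d = levels * (free weight parameters + variance parameters)`
#' (M variance parameters per level for the per-participant structure, 1
#' for pooled).
#'
#' @param datasets list of [share_dataset()] objects, one per force level.
#' @param variance variance structure for every model.
#' @param consts [norm_constants()]; defaults to constants from the first
#'   dataset's pair table (participants are assumed shared across levels).
#' @param T,burn_in sampler settings per level.
#' @param seed base seed; each model x level chain gets a distinct seed
#'   derived from it.
#' @param prior variance prior.
#' @return Data frame of class `"comparison_table"`: `model`,
#'   `avg_loglik`, `max_loglik`, `d`, `aic`, sorted as given (full model
#'   first).
#' @export
fit_all_models <- function(datasets, variance = "per_participant",
                           consts = NULL, T = 9000L, burn_in = 4000L,
                           seed = 1L, prior = "invga00") {
  if (inherits(datasets, "share_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "share_dataset")))
  if (is.null(consts)) consts <- norm_constants(datasets[[1L]]$pairs)
  sets <- all_free_sets()
  rows <- lapply(seq_along(sets), function(si) {
    spec <- model_spec(free = sets[[si]], variance = variance)
    avg <- 0; mx <- 0; d <- 0
    for (li in seq_along(datasets)) {
      ch <- run_chain(datasets[[li]], spec, consts, T = T,
                      burn_in = burn_in,
                      seed = chain_seed(seed, si, li), prior = prior)
      avg <- avg + averaged_loglik(ch)
      mx <- mx + max_loglik(ch)
      d <- d + spec$n_free_weights +
        if (variance == "pooled") 1L
        else length(datasets[[li]]$participant_id)
    }
    data.frame(model = paste(sets[[si]], collapse = "+"),
               avg_loglik = avg, max_loglik = mx, d = d,
               aic = aic(mx, d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

# distinct, reproducible sub-seed per (model, level) below 2^31
chain_seed <- function(seed, model_idx, level_idx) {
  as.integer((as.numeric(seed) * 131L + model_idx * 17L + level_idx) %%
               2147483587)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Model comparison (averaged log-likelihood, AIC)\n")
  d <- as.data.frame(x)
  d$avg_loglik <- formatC(d$avg_loglik, digits = 2, format = "f")
  d$max_loglik <- formatC(d$max_loglik, digits = 2, format = "f")
  d$aic <- formatC(d$aic, digits = 2, format = "f")
  print(d, row.names = FALSE)
  invisible(x)
}

#' Format a comparison table as aligned text
#'
#' Models as columns, one row for the averaged log-likelihood and one for
#' AIC.
#'
#' @param tab a [fit_all_models()] result.
#' @return Character vector of lines.
#' @export
format_comparison <- function(tab) {
  stopifnot(inherits(tab, "comparison_table"))
  hdr <- c("Model", tab$model)
  ll <- c("Log-likelihood", formatC(tab$avg_loglik, digits = 2, format = "f"))
  ai <- c("AIC", formatC(tab$aic, digits = 2, format = "f"))
  wid <- pmax(nchar(hdr), nchar(ll), nchar(ai))
  pad <- function(v) paste(mapply(formatC, v, width = wid), collapse = "  ")
  c(pad(hdr), pad(ll), pad(ai))
}

#' Fitted forces at posterior-median weights
#'
#' Applies the closed-form optimal commands at the posterior medians of the
#' stick-breaking coordinates (`w`, `z`) mapped back to the simplex — the
#' marginal medians of `nu`, `lam`, `mu` themselves need not sum to 1 — for
#' pairing with observed mean forces.
#'
#' @param chain a [run_chain()] result (needs `nu > 0` at the median).
#' @param pairs pair table of the fitted participants.
#' @param g target total force (defaults to the chain's force level).
#' @return Data frame `participant_id`, `u_i`, `u_j`, `share_i`.
#' @export
predict_forces <- function(chain, pairs, g = chain$level_g) {
  r <- retained(chain)
  wts <- reparam_forward(stats::median(r$samples[, "w"]),
                         stats::median(r$samples[, "z"]))
  pair_commands(wts, chain$consts, pairs, g)
}
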