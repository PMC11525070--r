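#' Posterior of the deviance statistic
#'
#' Per retained draw, the deviance is -2 times the row sum of the pointwise
#' log-likelihood matrix. Summarised by mean, sd and the 2.5/97.5
#' percentiles.
#'
#' @param fit A `posterior_fit`.
#' @return List with `draws` (per-draw deviance), `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
deviance_posterior <- function(fit) {
  dev <- -2 * rowSums(fit$loglik)
  qs <- stats::quantile(dev, c(0.025, 0.975), names = FALSE)
  list(draws = dev, mean = mean(dev), sd = stats::sd(dev),
       q2.5 = qs[1], q97.5 = qs[2])
}

#' Watanabe-Akaike information criterion
#'
#' Computed from the stored pointwise log-likelihood matrix in the variance
#' form: `lppd = sum_i log mean_s exp(loglik[s, i])` (evaluated by
#' log-sum-exp to guard underflow), `p_waic = sum_i var_s loglik[s, i]`,
#' and `waic = -2 (lppd - p_waic)`. The pointwise unit is the tree x
#' interval observation.
#'
#' @param fit A `posterior_fit` with at least 2 retained draws.
#' @return Object of class `waic_result`: list with `lppd`, `p_waic`,
#'   `waic`, `mean_deviance`.
#' @export
compute_waic <- function(fit) {
  ll <- fit$loglik
  if (nrow(ll) < 2L) stop("WAIC needs at least 2 retained draws")
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  if (any(!is.finite(mx))) stop("non-finite pointwise log-likelihood")
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log-sum-exp
  p_i <- apply(ll, 2, stats::var)
  res <- list(lppd = sum(lppd_i), p_waic = sum(p_i),
              waic = -2 * (sum(lppd_i) - sum(p_i)),
              mean_deviance = mean(-2 * rowSums(ll)))
  class(res) <- "waic_result"
  res
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f  (lppd %.2f, penalty %.2f, mean deviance %.2f)\n",
              x$waic, x$lppd, x$p_waic, x$mean_deviance))
  invisible(x)
}

#' Rank candidate models by WAIC
#'
#' Ascending WAIC; `delta_waic` is relative to the best model (0.00 for the
#' best row). Exact ties are broken in favour of the model with fewer
#' active growth covariate blocks (parsimony), when specs are supplied.
#'
#' @param results Named list of [compute_waic()] results.
#' @param specs Optional named list of [model_spec()] objects matching
#'   `results`, used only for tie-breaking.
#' @return Data frame `model`, `mean_deviance`, `p_waic`, `waic`,
#'   `delta_waic`, sorted best-first.
#' @export
rank_models <- function(results, specs = NULL) {
  if (length(results) < 1L) stop("need at least one model result")
  tab <- data.frame(
    model = names(results),
    mean_deviance = vapply(results, function(r) r$mean_deviance, numeric(1)),
    p_waic = vapply(results, function(r) r$p_waic, numeric(1)),
    waic = vapply(results, function(r) r$waic, numeric(1)),
    stringsAsFactors = FALSE)
  blocks <- if (!is.null(specs))
    vapply(tab$model, function(m) n_growth_blocks(specs[[m]]), numeric(1))
  else rep(0, nrow(tab))
  tab <- tab[order(tab$waic, blocks), , drop = FALSE]
  tab$delta_waic <- tab$waic - tab$waic[1L]
  rownames(tab) <- NULL
  tab
}

#' Fit and rank the candidate model set
#'
#' Fits each candidate independently (fresh chains, no shared warm starts;
#' candidate `i` is seeded with `seed + i` when a seed is given) and ranks
#' by WAIC.
#'
#' @param observations A `survival_observations` data frame.
#' @param candidates Named list of [model_spec()]s
#'   (default [build_candidate_set()]).
#' @param priors,mcmc,seed Passed to [fit_mcmc()].
#' @return The [rank_models()] table, with the per-model WAIC results
#'   attached as attribute `"results"`.
#' @export
select_models <- function(observations, candidates = build_candidate_set(),
                          priors = default_priors(), mcmc = mcmc_config(),
                          seed = NULL) {
  results <- vector("list", length(candidates))
  names(results) <- names(candidates)
  for (i in seq_along(candidates)) {
    fit <- fit_mcmc(observations, candidates[[i]], priors, mcmc,
                    seed = if (is.null(seed)) NULL else seed + i)
    results[[i]] <- compute_waic(fit)
  }
  tab <- rank_models(results, candidates)
  attr(tab, "results") <- results
  tab
}
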