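#' MCMC configuration
#'
#' Desk-scale default: 3 chains of 50,000 iterations with a
#' 10,000-iteration burn-in, retaining every 40th draw (3,000 retained
#' draws in total) — the point where split-Rhat drops below 1.05 for the
#' full study-scale design under the package's random-walk sampler, at
#' about two minutes of runtime. The archival-scale protocol used for the
#' original field analysis — 150,000 post-burn-in iterations per chain
#' after a 10,000 burn-in, thinned by 3 — is `mcmc_config(chains = 3,
#' iterations = 160000, burn_in = 10000, thin = 3)`.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain, burn-in included.
#' @param burn_in Iterations discarded from the front of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iterations = 50000L, burn_in = 10000L,
                        thin = 40L) {
  stopifnot(chains >= 1L, iterations > burn_in, burn_in >= 0L, thin >= 1L)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Default priors
#'
#' Independent Normal(0, sd 10) priors on all fixed effects (logit scale)
#' and a half-Normal(sd 2) prior on the plot random-effect sd. Both are
#' weakly informative on the logit scale relative to the standardized
#' covariates.
#'
#' @param beta_sd Prior sd of fixed effects.
#' @param sigma_sd Scale of the half-Normal prior on `sigma_S`.
#' @return List with elements `beta_sd`, `sigma_sd`.
#' @export
default_priors <- function(beta_sd = 10, sigma_sd = 2) {
  stopifnot(beta_sd > 0, sigma_sd > 0)
  list(beta_sd = beta_sd, sigma_sd = sigma_sd)
}

#' Fit the Bayesian interval-survival model by MCMC
#'
#' Samples the posterior of all active fixed effects, the plot random
#' effects and their sd with an adaptive Metropolis-within-Gibbs sampler
#' (coordinate-wise random-walk proposals whose scales adapt during burn-in
#' only). The per-draw pointwise log-likelihood of every tree x interval
#' observation is retained for deviance and WAIC computation. A fixed
#' `seed` makes runs byte-identical.
#'
#' @param observations A `survival_observations` data frame.
#' @param spec A [model_spec()].
#' @param priors See [default_priors()].
#' @param mcmc An [mcmc_config()].
#' @param seed Optional integer seed.
#' @param include_random Include plot random effects (`TRUE` for the study
#'   model; `FALSE` gives the fixed-effects-only sub-model used for
#'   oracle checks).
#' @return Object of class `posterior_fit`: retained draws (array of
#'   draw x chain x parameter), pointwise log-likelihood matrix (all
#'   retained draws x observations), split-Rhat and effective sample size
#'   per parameter, and a config echo. A convergence warning (any
#'   split-Rhat > 1.05) is attached as attribute `convergence_warning` and
#'   also raised as an R warning.
#' @export
fit_mcmc <- function(observations, spec = model_spec("selected"),
                     priors = default_priors(), mcmc = mcmc_config(),
                     seed = NULL, include_random = TRUE) {
  for (q in sort(unique(observations$period)))
    if (sum(observations$period == q) < 1L)
      stop("no observations in period ", q)
  X <- build_design(observations, spec)
  p <- ncol(X)
  plot_levels <- if (include_random) sort(unique(observations$plot_id)) else character()
  n_plots <- length(plot_levels)
  plot_ix <- if (include_random)
    match(observations$plot_id, plot_levels) - 1L else integer(nrow(X))

  if (!is.null(seed)) set.seed(seed)
  prior_sd <- rep(priors$beta_sd, p)
  par_names <- c(colnames(X),
                 if (n_plots) paste0("eps[", plot_levels, "]"),
                 if (n_plots) "sigma_S")

  # proposal scales start near 2.4 / column scale so that the adaptive
  # burn-in only has to fine-tune them
  col_scale <- apply(X, 2, function(x) {
    s <- stats::sd(x[x != 0])
    if (!is.finite(s) || s == 0) max(abs(x), 1) else s
  })
  scale_init <- pmin(2.4 / col_scale, 2.4)
  mu_cols <- grep("^mu_", colnames(X))
  # plot-constant covariates, for the confounding-breaking shift moves
  pc_stubs <- c(avP = "soil_p_std", LI = "landform_std",
                ele = "elevation_std", dist = "distance_std")
  if (n_plots) {
    first_row <- match(plot_levels, observations$plot_id)
    pc_cols <- vapply(names(pc_stubs), function(s)
      match(paste0(s, "_", 1:3), colnames(X)), integer(3)) - 1L
    pc_vals <- vapply(unname(pc_stubs), function(cl)
      observations[[cl]][first_row], numeric(n_plots))
    if (is.null(dim(pc_vals))) pc_vals <- matrix(pc_vals, nrow = 1L)
  } else {
    pc_cols <- matrix(integer(), 3, 0)
    pc_vals <- matrix(numeric(), 0, 0)
  }
  # crude annualized survival estimate to centre the intercept inits
  mu_hat <- stats::qlogis(
    min(max(sum(observations$outcome * observations$delta_t) /
              sum(observations$delta_t), 0.5), 0.999))

  n_stored <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  draws <- array(NA_real_, c(n_stored, mcmc$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  loglik <- matrix(NA_real_, n_stored * mcmc$chains, nrow(X))
  for (ch in seq_len(mcmc$chains)) {
    beta0 <- stats::rnorm(p, 0, 0.1 / col_scale)
    beta0[mu_cols] <- mu_hat + stats::rnorm(length(mu_cols), 0, 0.5)
    eps0 <- if (n_plots) stats::rnorm(n_plots, 0, 0.1) else numeric()
    sigma0 <- stats::runif(1, 0.3, 1.5)
    res <- .run_chain(X, as.integer(observations$outcome),
                      as.numeric(observations$delta_t),
                      plot_ix, n_plots, beta0, eps0, sigma0,
                      prior_sd, priors$sigma_sd,
                      scale_init, mu_cols - 1L, pc_cols, pc_vals,
                      mcmc$iterations, mcmc$burn_in, mcmc$thin)
    draws[, ch, ] <- res$draws
    loglik[(ch - 1L) * n_stored + seq_len(n_stored), ] <- res$loglik
  }

  check <- c(colnames(X), if (n_plots) "sigma_S")
  diag <- chain_diagnostics(draws[, , check, drop = FALSE])
  fit <- structure(list(
    draws = draws, param_names = par_names, loglik = loglik,
    spec = spec, priors = priors, mcmc = mcmc, seed = seed,
    plot_levels = plot_levels, n_obs = nrow(X),
    diagnostics = diag,
    obs_meta = observations[c("period", "growth_prev", "elevation_std")]
  ), class = "posterior_fit")
  if (any(diag$rhat > 1.05, na.rm = TRUE)) {
    bad <- rownames(diag)[which(diag$rhat > 1.05)]
    msg <- paste0("split-Rhat > 1.05 for: ", paste(bad, collapse = ", "),
                  " — consider a longer chain")
    attr(fit, "convergence_warning") <- msg
    warning(msg)
  }
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior fit:", spec_label(x$spec), "\n")
  cat(d[2], "chains x", d[1], "retained draws;", x$n_obs, "observations;",
      length(x$plot_levels), "plots\n")
  cat("max split-Rhat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
      " min ESS:", round(min(x$diagnostics$ess, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Retained draws as a matrix
#'
#' @param fit A `posterior_fit`.
#' @param pars Optional parameter names to keep.
#' @return Matrix with chains stacked row-wise, one column per parameter.
#' @export
as_draws_matrix <- function(fit, pars = NULL) {
  d <- dim(fit$draws)
  m <- matrix(aperm(fit$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- fit$param_names
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

# split-Rhat and a Geyer initial-positive-sequence ESS per parameter
chain_diagnostics <- function(draws) {
  d <- dim(draws)
  out <- data.frame(rhat = rep(NA_real_, d[3]), ess = rep(NA_real_, d[3]),
                    row.names = dimnames(draws)[[3]])
  for (j in seq_len(d[3])) {
    x <- draws[, , j, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    out$rhat[j] <- split_rhat(x)
    out$ess[j] <- ess_ips(x)
  }
  out
}

split_rhat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mu <- colMeans(xs); v <- apply(xs, 2, stats::var)
  W <- mean(v)
  B <- nn * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_ips <- function(x) {
  n <- nrow(x); m <- ncol(x)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    v <- x[, ch] - mean(x[, ch])
    if (stats::sd(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    # Geyer: sum adjacent-pair autocorrelations while positive
    s <- 0; k <- 2L
    while (k + 1L <= length(ac)) {
      pair <- ac[k] + ac[k + 1L]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2L
    }
    rho_sum <- rho_sum + s / m
  }
  n * m / (1 + 2 * rho_sum)
}

#' Posterior growth-survival curve
#'
#' Mean annual survival (with 95% credible band) against previous growth at
#' a fixed elevation, for one survival period, with all other standardized
#' covariates at zero and the plot random effect excluded. The growth grid
#' is constrained to the central 95% of observed previous growth for that
#' period within the elevation class of `elevation_m` (classes: low
#' 640-970 m, medium 971-1130 m, high 1131-1417 m); points outside are
#' trimmed with a message.
#'
#' @param fit A `posterior_fit`.
#' @param period Survival period, 1, 2 or 3.
#' @param elevation_m Elevation in metres (default curves use 800, 1000 and
#'   1200 m, the class medians).
#' @param growth Optional growth grid (mm/yr); default 50 points across the
#'   allowed range.
#' @param config The [standardization_config()] used to build the
#'   observations.
#' @return Data frame with `growth`, `mean`, `lower`, `upper`,
#'   `period`, `elevation_m`.
#' @export
predict_survival_curve <- function(fit, period, elevation_m, growth = NULL,
                                   config = standardization_config()) {
  stopifnot(period %in% 1:3)
  ele_std <- standardize(elevation_m, config, "elevation")
  meta <- fit$obs_meta
  ele_raw <- unstandardize(meta$elevation_std, config, "elevation")
  cls <- elevation_class(elevation_m)
  in_cls <- elevation_class(ele_raw) == cls & meta$period == period
  if (!any(in_cls))
    stop("no observations in period ", period, ", elevation class ", cls)
  bounds <- stats::quantile(meta$growth_prev[in_cls], c(0.025, 0.975),
                            names = FALSE)
  if (is.null(growth)) {
    growth <- seq(bounds[1], bounds[2], length.out = 50L)
  } else {
    drop_n <- sum(growth < bounds[1] | growth > bounds[2])
    if (drop_n > 0) {
      message("trimmed ", drop_n, " growth grid point(s) outside the ",
              "central 95% of observed previous growth")
      growth <- growth[growth >= bounds[1] & growth <= bounds[2]]
    }
  }
  pars <- intersect(paste0(c("mu_", "G_", "G_x_ele_", "ele_"), period),
                    fit$param_names)
  dm <- as_draws_matrix(fit, pars)
  get <- function(stub) {
    nm <- paste0(stub, "_", period)
    if (nm %in% colnames(dm)) dm[, nm] else rep(0, nrow(dm))
  }
  eta0 <- get("mu") + get("ele") * ele_std
  slope <- get("G") + get("G_x_ele") * ele_std
  out <- data.frame(growth = growth, mean = NA_real_, lower = NA_real_,
                    upper = NA_real_, period = period,
                    elevation_m = elevation_m)
  for (i in seq_along(growth)) {
    s <- stats::plogis(eta0 + slope * growth[i])
    out$mean[i] <- mean(s)
    qs <- stats::quantile(s, c(0.025, 0.975), names = FALSE)
    out$lower[i] <- qs[1]; out$upper[i] <- qs[2]
  }
  out
}

elevation_class <- function(elevation_m) {
  cut(elevation_m, c(-Inf, 970, 1130, Inf),
      labels = c("low", "medium", "high"))
}
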