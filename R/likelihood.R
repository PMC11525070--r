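#' Logit-scale linear predictor of annual survival
#'
#' For each observation in period `eq`, the linear predictor is
#' `mu_eq + gamma_y,eq y + gamma_y2,eq y^2 + gamma_bas,eq bas +
#' gamma_bas_x_ele,eq bas*ele + gamma_G,eq G + gamma_G_x_ele,eq G*ele +
#' gamma_G1,eq G1 (+ gamma_G1_x_ele,eq G1*ele) + gamma_avP,eq avP +
#' gamma_LI,eq LI + gamma_ele,eq ele + gamma_dist,eq dist + eps_j`, with all
#' covariates on their standardized scales and `eps_j` the plot effect
#' (taken as 0 when the coefficient set carries none).
#'
#' @param observations A `survival_observations` data frame.
#' @param coef A [model_coefficients()] object. Coefficients present in
#'   `beta` are used; anything not named there contributes zero.
#' @return Numeric vector of logit-scale values, one per observation.
#' @examples
#' # at the standardized-zero point in period 1, the predictor is mu_1
#' @export
linear_predictor <- function(observations, coef) {
  if (!all(observations$period %in% 1:3))
    stop("period index must be 1, 2 or 3")
  spec <- model_spec("full")
  X <- build_design(observations, spec)
  beta <- coef$beta
  unknown <- setdiff(names(beta), colnames(X))
  if (length(unknown))
    stop("unknown coefficient names: ", paste(unknown, collapse = ", "))
  full <- stats::setNames(numeric(ncol(X)), colnames(X))
  full[names(beta)] <- beta
  eta <- drop(X %*% full)
  if (!is.null(coef$eps)) {
    e <- coef$eps[observations$plot_id]
    if (anyNA(e)) stop("plot ids missing from coefficient set's plot effects")
    eta <- eta + unname(e)
  }
  eta
}

#' Annual survival probability from a logit value
#'
#' @param logit_value Finite numeric vector on the logit scale.
#' @return Inverse-logit survival probabilities, strictly inside (0, 1).
#' @examples
#' annual_survival(0)      # 0.5
#' annual_survival(3.691)  # 0.9756
#' @export
annual_survival <- function(logit_value) {
  if (any(!is.finite(logit_value))) stop("logit value must be finite")
  stats::plogis(logit_value)
}

#' Interval survival from annual survival
#'
#' A tree alive at the interval start survives the whole interval with
#' probability `annual_s ^ delta_t`: annual survival is assumed constant
#' within the interval (interval-censored death times, no finer hazard
#' shape).
#'
#' @param annual_s Annual survival probabilities in (0, 1).
#' @param delta_t Interval length(s) in years (> 0).
#' @return Interval survival probabilities.
#' @examples
#' interval_survival(0.9756, 6)  # 0.8625
#' @export
interval_survival <- function(annual_s, delta_t) {
  if (any(annual_s <= 0 | annual_s >= 1)) stop("annual_s must be in (0, 1)")
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  annual_s^delta_t
}

#' Annualized Bernoulli log-likelihood of survival observations
#'
#' Each tree x interval observation contributes
#' `outcome * delta_t * log(s) + (1 - outcome) * log(1 - s^delta_t)` where
#' `s` is the annual survival implied by the linear predictor. For
#' `delta_t = 1` this is the ordinary Bernoulli log-likelihood. The deviance
#' is -2 times the total.
#'
#' @param observations A `survival_observations` data frame (`outcome` in
#'   \{0, 1\}).
#' @param coef A [model_coefficients()] object (plot effects included if
#'   present).
#' @return List with `pointwise` (per-observation log-likelihood), `total`
#'   and `deviance`.
#' @export
log_likelihood <- function(observations, coef) {
  if (!all(observations$outcome %in% 0:1)) stop("outcome must be 0 or 1")
  eta <- linear_predictor(observations, coef)
  pw <- pointwise_loglik(eta, observations$outcome, observations$delta_t)
  if (any(!is.finite(pw))) {
    i <- which(!is.finite(pw))[1L]
    stop("non-finite log-likelihood for observation ", i,
         " (tree ", observations$tree_id[i], ")")
  }
  list(pointwise = pw, total = sum(pw), deviance = -2 * sum(pw))
}

# stable pointwise term: alive -> dt*log(s) = -dt*log1p(exp(-eta));
# dead -> log(1 - s^dt) = log(-expm1(dt*log(s)))
pointwise_loglik <- function(eta, outcome, delta_t) {
  log_s <- stats::plogis(eta, log.p = TRUE)
  ifelse(outcome == 1L, delta_t * log_s, log(-expm1(delta_t * log_s)))
}
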