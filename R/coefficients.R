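#' Survival model specification
#'
#' A model specification records which growth covariate blocks are active.
#' The base covariates — diameter, diameter squared, neighbourhood basal
#' area, basal area x elevation, soil-available P, landform index,
#' elevation, epicentre distance and the plot random effect — are always
#' present. Growth enters through previous growth, lagged growth, and their
#' interactions with elevation; an interaction can only be active when its
#' main effect is.
#'
#' @param name One of `"base"`, `"selected"` (both growth mains plus the
#'   previous-growth x elevation interaction; the default inference model)
#'   or `"full"` (both mains and both interactions); ignored when the
#'   individual flags are given.
#' @param prev,lag,prev_x_ele,lag_x_ele Logical flags for the growth blocks.
#' @return Object of class `model_spec`.
#' @examples
#' model_spec("selected")
#' model_spec(prev = TRUE, lag = FALSE, prev_x_ele = TRUE)
#' @export
model_spec <- function(name = NULL, prev = FALSE, lag = FALSE,
                       prev_x_ele = FALSE, lag_x_ele = FALSE) {
  if (!is.null(name)) {
    flags <- switch(name,
      base     = c(FALSE, FALSE, FALSE, FALSE),
      selected = c(TRUE,  TRUE,  TRUE,  FALSE),
      full     = c(TRUE,  TRUE,  TRUE,  TRUE),
      stop("unknown model name: ", name))
    prev <- flags[1]; lag <- flags[2]
    prev_x_ele <- flags[3]; lag_x_ele <- flags[4]
  }
  if (prev_x_ele && !prev)
    stop("previous-growth x elevation interaction requires the main effect")
  if (lag_x_ele && !lag)
    stop("lagged-growth x elevation interaction requires the main effect")
  structure(list(prev = prev, lag = lag, prev_x_ele = prev_x_ele,
                 lag_x_ele = lag_x_ele),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Survival model spec:", spec_label(x), "\n")
  invisible(x)
}

spec_label <- function(spec) {
  parts <- c("base",
             if (spec$prev) "previous growth",
             if (spec$lag) "lagged growth",
             if (spec$prev_x_ele) "previous growth x elevation",
             if (spec$lag_x_ele) "lagged growth x elevation")
  paste(parts, collapse = " + ")
}

n_growth_blocks <- function(spec)
  sum(spec$prev, spec$lag, spec$prev_x_ele, spec$lag_x_ele)

# Coefficient registry: names grouped as the posterior summary table prints
# them. Suffix _q is the survival period (1 pre-earthquake, 2 = 0-5 y post,
# 3 = 5+ y post).
registry_names <- function(spec = model_spec("full")) {
  per <- function(stub) paste0(stub, "_", 1:3)
  tree <- c(rbind(per("y"), per("y2")))
  out <- c(per("mu"), tree, per("bas"), per("bas_x_ele"))
  if (spec$prev) out <- c(out, per("G"))
  if (spec$prev_x_ele) out <- c(out, per("G_x_ele"))
  if (spec$lag) out <- c(out, per("G1"))
  if (spec$lag_x_ele) out <- c(out, per("G1_x_ele"))
  c(out, per("avP"), per("LI"), per("ele"), per("dist"))
}

#' Model coefficients
#'
#' Container for a complete set of survival-model coefficient values: the
#' fixed effects `beta` (named as in the coefficient registry, e.g. `mu_1`,
#' `G_3`, `bas_x_ele_2`), the plot random-effect standard deviation
#' `sigma_s`, and optionally the per-plot effects `eps` (named by plot id).
#' Coefficients absent from a model specification are identically zero.
#'
#' @param beta Named numeric vector of fixed effects.
#' @param sigma_s Plot random-effect sd (>= 0).
#' @param eps Optional named numeric vector of plot effects.
#' @return Object of class `model_coefficients`.
#' @export
model_coefficients <- function(beta, sigma_s = 0, eps = NULL) {
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("beta must be a fully named numeric vector")
  if (sigma_s < 0) stop("sigma_s must be >= 0")
  structure(list(beta = beta, sigma_s = sigma_s, eps = eps),
            class = "model_coefficients")
}

#' Reference coefficient set for a montane beech forest
#'
#' Coefficient values estimated for mountain beech (*Nothofagus solandri*
#' var. *cliffortioides*) survival across an earthquake-disturbed elevation
#' gradient in New Zealand's Southern Alps, under the selected model
#' specification (both growth mains plus the previous-growth x elevation
#' interaction). Used as the default truth for the synthetic forest
#' simulator: high baseline annual survival (logit 3.69-3.90), a positive
#' effect of previous growth that is weakest 0-5 years after the earthquake
#' and strongest 5+ years after, a positive distance-from-epicentre effect
#' confined to the 0-5 year post-earthquake period, and a plot random
#' effect sd of 0.966.
#'
#' @return A [model_coefficients()] object (without plot effects).
#' @export
default_truth <- function() {
  beta <- c(
    mu_1 = 3.691, mu_2 = 3.896, mu_3 = 3.667,
    y_1 = 0.00485, y2_1 = -0.00002,
    y_2 = 0.00563, y2_2 = -0.00002,
    y_3 = 0.00201, y2_3 = -0.00001,
    bas_1 = -0.011, bas_2 = -0.002, bas_3 = 0.002,
    bas_x_ele_1 = -0.004, bas_x_ele_2 = 0.009, bas_x_ele_3 = -0.005,
    G_1 = 0.575, G_2 = 0.187, G_3 = 0.776,
    G_x_ele_1 = -0.054, G_x_ele_2 = 0.062, G_x_ele_3 = 0.123,
    G1_1 = 0.361, G1_2 = 0.261, G1_3 = 0.288,
    avP_1 = -0.047, avP_2 = -0.218, avP_3 = 0.072,
    LI_1 = -0.009, LI_2 = -0.092, LI_3 = -0.026,
    ele_1 = 0.242, ele_2 = -0.006, ele_3 = 0.023,
    dist_1 = -0.055, dist_2 = 1.036, dist_3 = -0.004
  )
  model_coefficients(beta, sigma_s = 0.966)
}

#' Design matrix for the survival model
#'
#' Expands survival observations into the fixed-effect design matrix of a
#' given model specification. Every coefficient is period-specific: column
#' `G_2`, say, is previous growth for rows in period 2 and zero elsewhere.
#'
#' @param observations A `survival_observations` data frame.
#' @param spec A [model_spec()].
#' @return Numeric matrix with one named column per active coefficient.
#' @export
build_design <- function(observations, spec = model_spec("selected")) {
  obs <- observations
  base_cols <- list(
    mu = rep(1, nrow(obs)),
    y = obs$diameter_std,
    y2 = obs$diameter_sq_std,
    bas = obs$local_ba_std,
    bas_x_ele = obs$local_ba_std * obs$elevation_std,
    avP = obs$soil_p_std,
    LI = obs$landform_std,
    ele = obs$elevation_std,
    dist = obs$distance_std
  )
  growth_cols <- list()
  if (spec$prev) growth_cols$G <- obs$growth_prev
  if (spec$prev_x_ele) growth_cols$G_x_ele <- obs$growth_prev * obs$elevation_std
  if (spec$lag) growth_cols$G1 <- obs$growth_lag
  if (spec$lag_x_ele) growth_cols$G1_x_ele <- obs$growth_lag * obs$elevation_std
  cols <- c(base_cols, growth_cols)
  names_out <- registry_names(spec)
  X <- matrix(0, nrow(obs), length(names_out),
              dimnames = list(NULL, names_out))
  for (stub in names(cols)) {
    for (q in 1:3) {
      nm <- paste0(stub, "_", q)
      if (nm %in% names_out) X[, nm] <- cols[[stub]] * (obs$period == q)
    }
  }
  X
}

#' The nine candidate survival models
#'
#' All combinations of the two growth covariates and their elevation
#' interactions, subject to an interaction requiring its main effect: the
#' base model (no growth covariates), each single growth main with and
#' without its interaction, both mains, both mains with either single
#' interaction, and the full model with both interactions.
#'
#' @return Named list of nine [model_spec()] objects, from simplest to
#'   fullest.
#' @export
build_candidate_set <- function() {
  list(
    base = model_spec("base"),
    `base+prev` = model_spec(prev = TRUE),
    `base+prev+prev_x_ele` = model_spec(prev = TRUE, prev_x_ele = TRUE),
    `base+lag` = model_spec(lag = TRUE),
    `base+lag+lag_x_ele` = model_spec(lag = TRUE, lag_x_ele = TRUE),
    `base+prev+lag` = model_spec(prev = TRUE, lag = TRUE),
    `base+prev+lag+prev_x_ele` = model_spec(prev = TRUE, lag = TRUE,
                                            prev_x_ele = TRUE),
    `base+prev+lag+lag_x_ele` = model_spec(prev = TRUE, lag = TRUE,
                                           lag_x_ele = TRUE),
    full = model_spec("full")
  )
}
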