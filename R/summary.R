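#' Posterior summary table
#'
#' One row per model parameter in the conventional reporting order: the
#' period intercepts, the plot random-effect sd, the tree-level
#' coefficients by period, then the plot-level coefficients by period.
#' Columns are the posterior mean, sd and the empirical 2.5% and 97.5%
#' percentiles.
#'
#' @param fit A `posterior_fit` with at least 100 retained draws.
#' @return Data frame with columns `parameter`, `description`, `mean`,
#'   `sd`, `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  m <- as_draws_matrix(fit)
  if (nrow(m) < 100L)
    stop("posterior summary needs at least 100 retained draws")
  reg <- registry_names(fit$spec)
  order_names <- c(reg[1:3],
                   if ("sigma_S" %in% colnames(m)) "sigma_S",
                   reg[-(1:3)])
  order_names <- order_names[order_names %in% colnames(m)]
  qs <- apply(m[, order_names, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  data.frame(
    parameter = order_names,
    description = vapply(order_names, describe_parameter, character(1)),
    mean = colMeans(m[, order_names, drop = FALSE]),
    sd = apply(m[, order_names, drop = FALSE], 2, stats::sd),
    q2.5 = qs[1, ], q97.5 = qs[2, ],
    row.names = NULL, stringsAsFactors = FALSE)
}

describe_parameter <- function(name) {
  if (name == "sigma_S") return("SD of plot-level random effect")
  stub <- sub("_[123]$", "", name)
  q <- sub(".*_", "", name)
  period <- c(`1` = "pre-earthquake", `2` = "0-5 years post-earthquake",
              `3` = "5+ years post-earthquake")[q]
  what <- switch(stub,
    mu = "mean survival (logit scale)",
    y = "linear effect of diameter",
    y2 = "quadratic effect of diameter",
    bas = "effect of basal area",
    bas_x_ele = "change of basal-area effect with elevation",
    G = "effect of previous growth",
    G_x_ele = "change of previous-growth effect with elevation",
    G1 = "effect of lagged growth",
    G1_x_ele = "change of lagged-growth effect with elevation",
    avP = "effect of soil-available P",
    LI = "effect of landform index",
    ele = "effect of elevation",
    dist = "effect of distance from epicentre",
    name)
  paste0(toupper(substring(period, 1, 1)), substring(period, 2), " ", what)
}
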