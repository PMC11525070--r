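#' Covariate standardization
#'
#' The survival model is parameterised on standardized covariate scales so
#' that a coefficient of zero corresponds to a "typical" tree on a "typical"
#' plot. Each covariate has an optional natural-log transform, a zero point
#' (subtracted on the transformed scale) and a divisor. Defaults:
#'
#' | covariate  | transform | zero point        | divisor | raw units   |
#' |------------|-----------|-------------------|---------|-------------|
#' | `basal_area` | identity | 50                | 1       | m2/ha       |
#' | `diameter`   | identity | 164               | 1       | mm          |
#' | `growth`     | identity | 0                 | 1       | mm/yr       |
#' | `soil_p`     | log      | 2.7 (= ln 14.88)  | 1       | ug/g        |
#' | `landform`   | identity | 20                | 1       | degrees     |
#' | `distance`   | log      | 2.9 (= ln 18.17)  | 1       | km          |
#' | `elevation`  | identity | 1000              | 100     | m           |
#'
#' The elevation divisor of 100 m means elevation coefficients are per
#' 100 m of elevation; with raw metres their printed magnitudes would imply
#' implausibly extreme logits across a 640-1417 m gradient.
#'
#' @param overrides Named list of per-covariate lists with any of `zero`,
#'   `transform` (`"identity"` or `"log"`), `divisor`.
#' @return Object of class `standardization_config`: a named list of
#'   per-covariate settings.
#' @examples
#' cfg <- standardization_config()
#' standardize(14.88, cfg, "soil_p")    # 0
#' standardize(1100, cfg, "elevation")  # 1
#' @export
standardization_config <- function(overrides = list()) {
  cfg <- list(
    basal_area = list(zero = 50,   transform = "identity", divisor = 1),
    diameter   = list(zero = 164,  transform = "identity", divisor = 1),
    growth     = list(zero = 0,    transform = "identity", divisor = 1),
    soil_p     = list(zero = 2.7,  transform = "log",      divisor = 1),
    landform   = list(zero = 20,   transform = "identity", divisor = 1),
    distance   = list(zero = 2.9,  transform = "log",      divisor = 1),
    elevation  = list(zero = 1000, transform = "identity", divisor = 100)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown covariate: ", nm)
    for (f in names(overrides[[nm]])) {
      if (!f %in% c("zero", "transform", "divisor"))
        stop("unknown standardization field: ", f)
      cfg[[nm]][[f]] <- overrides[[nm]][[f]]
    }
  }
  for (nm in names(cfg)) {
    if (!cfg[[nm]]$transform %in% c("identity", "log"))
      stop("transform must be 'identity' or 'log' for ", nm)
    if (cfg[[nm]]$divisor == 0) stop("divisor must be nonzero for ", nm)
  }
  structure(cfg, class = "standardization_config")
}

#' @rdname standardization_config
#' @param value Numeric vector on the covariate's measurement scale.
#' @param config A `standardization_config`.
#' @param covariate Covariate name (one of the table rows above).
#' @export
standardize <- function(value, config = standardization_config(), covariate) {
  cv <- config[[covariate]]
  if (is.null(cv)) stop("unknown covariate: ", covariate)
  if (cv$transform == "log") {
    if (any(value <= 0, na.rm = TRUE))
      stop("non-positive value under log transform for ", covariate)
    value <- log(value)
  }
  (value - cv$zero) / cv$divisor
}

#' @rdname standardization_config
#' @export
unstandardize <- function(value, config = standardization_config(), covariate) {
  cv <- config[[covariate]]
  if (is.null(cv)) stop("unknown covariate: ", covariate)
  out <- value * cv$divisor + cv$zero
  if (cv$transform == "log") out <- exp(out)
  out
}
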