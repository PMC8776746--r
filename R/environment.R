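# Standardisation of raw environmental measurements into oriented stress
# gradients: higher value = more stressful, mean 0, SD 1 across soil samples.

#' Standardize raw environmental measurements into stress gradients
#'
#' Converts a raw per-soil-sample environment table (temperature, rainfall,
#' pH, salinity) into four dimensionless stress gradients with a common
#' "higher = more stressful" orientation. Each variable is standardized to
#' mean 0 and SD 1 (sample SD, denominator n - 1) across soil samples.
#' Variables in `reverse_set` are negated *after* standardization, so that
#' stress increases with decreasing pH (acidity) and decreasing rainfall
#' (aridity). Variables in `log_set` are transformed with `log(x + 0.01)`
#' *before* standardization to accommodate exact zeroes (salinity).
#'
#' @param raw Data frame with a `sample_id` column and the raw variables
#'   named in `var_map`.
#' @param reverse_set Raw variables whose scale is reversed after
#'   standardization. Default `c("pH", "rainfall")`.
#' @param log_set Raw variables log-transformed (natural log of x + 0.01)
#'   before standardization. Default `"salinity"`; must be non-negative.
#' @param var_map Named character vector mapping raw variable names to
#'   output stress names.
#' @return A `stress_profile` data frame with columns `sample_id`,
#'   `acidity`, `aridity`, `heat`, `salinity`; each stress column has mean 0
#'   and SD 1 across samples.
#' @examples
#' raw <- data.frame(sample_id = c("a", "b", "c"),
#'                   temperature = c(20, 25, 30), rainfall = c(300, 500, 700),
#'                   pH = c(4, 6, 8), salinity = c(0, 0.5, 2))
#' standardize_environment(raw)
#' @export
standardize_environment <- function(raw,
                                    reverse_set = c("pH", "rainfall"),
                                    log_set = "salinity",
                                    var_map = c(pH = "acidity",
                                                rainfall = "aridity",
                                                temperature = "heat",
                                                salinity = "salinity")) {
  if (!is.data.frame(raw)) stopf("'raw' must be a data frame")
  if (!"sample_id" %in% names(raw)) stopf("'raw' needs a 'sample_id' column")
  if (nrow(raw) < 2L) stopf("need at least 2 samples to standardize")
  miss <- setdiff(names(var_map), names(raw))
  if (length(miss)) stopf("raw table lacks variable(s): %s",
                          paste(miss, collapse = ", "))

  out <- data.frame(sample_id = as.character(raw$sample_id),
                    stringsAsFactors = FALSE)
  for (v in names(var_map)) {
    x <- raw[[v]]
    if (!is.numeric(x)) stopf("raw variable '%s' is not numeric", v)
    if (anyNA(x)) stopf("raw variable '%s' has missing values", v)
    if (v %in% log_set) {
      if (any(x < 0)) stopf("raw variable '%s' must be non-negative for the log transform", v)
      x <- log(x + 0.01)
    }
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stopf("raw variable '%s' is constant (SD = 0)", v)
    z <- (x - mean(x)) / s
    if (v %in% reverse_set) z <- -z
    out[[var_map[[v]]]] <- z
  }
  out <- out[, c("sample_id", STRESS_NAMES)]
  class(out) <- c("stress_profile", "data.frame")
  out
}
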