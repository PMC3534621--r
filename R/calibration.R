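#' Fit the SGT-versus-log10(CFU/mL) calibration line
#'
#' Under exponential regrowth the time to a fixed OD threshold is affine in
#' the log of the starting live-cell concentration, with slope
#' `-td * log2(10)` hours per decade (td = doubling time). This fits that
#' line by ordinary least squares of SGT (hours) on log10(CFU/mL); the known
#' concentrations are the predictor, so inversion to concentration is
#' analytic.
#'
#' @param points Data frame with columns `sgt_hours` and `cfu_per_ml`
#'   (>= 3 rows, all concentrations positive, no censored SGTs).
#' @return An `sgt_calibration` model: `slope` (hours per log10 CFU/mL,
#'   expected negative), `intercept` (hours), `r_squared`, `residual_sd`
#'   (hours), `n_points`, `log_base` (10), and the fitted `sgt_range` /
#'   `log10_cfu_range` used to police extrapolation.
#' @export
fit_calibration <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("sgt_hours", "cfu_per_ml") %in% names(points)))
    validation_error("points must be a data.frame with sgt_hours and cfu_per_ml")
  sgt <- as.numeric(points$sgt_hours)
  cfu <- as.numeric(points$cfu_per_ml)
  if (anyNA(sgt) || any(!is.finite(sgt)))
    validation_error("censored or non-finite SGT values cannot be used for calibration")
  if (anyNA(cfu) || any(cfu <= 0))
    validation_error("all cfu_per_ml must be positive")
  if (length(sgt) < 3L)
    fit_error(sprintf("calibration needs >= 3 points, got %d", length(sgt)))
  x <- log10(cfu)
  if (stats::sd(x) == 0)
    fit_error("zero variance in log10(cfu_per_ml): cannot fit a line")
  fit <- stats::lm(sgt ~ x)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = s$r.squared,
    residual_sd = s$sigma,
    n_points = length(sgt),
    log_base = 10,
    sgt_range = range(sgt),
    log10_cfu_range = range(x)
  ), class = "sgt_calibration")
}

#' @export
print.sgt_calibration <- function(x, ...) {
  cat(sprintf(paste0("<sgt_calibration> SGT = %.4f %+.4f * log10(CFU/mL)\n",
                     "  n = %d, R^2 = %.5f, residual sd = %.4f h, ",
                     "fitted SGT range [%.2f, %.2f] h\n"),
              x$intercept, x$slope, x$n_points, x$r_squared, x$residual_sd,
              x$sgt_range[1L], x$sgt_range[2L]))
  invisible(x)
}

#' Estimate live-cell concentration from an SGT value
#'
#' Inverse prediction through the calibration line:
#' `cfu = 10^((sgt - intercept) / slope)`, with an interval obtained by
#' propagating the fit's residual standard deviation through the inverse map
#' (delta method on the log10 scale). Prediction outside the fitted SGT range
#' is refused unless extrapolation is explicitly allowed.
#'
#' @param model An `sgt_calibration` from [fit_calibration()].
#' @param sgt_hours Numeric vector of non-censored SGT values (hours).
#' @param allow_extrapolation Permit SGTs outside the fitted range.
#' @param level Confidence level for the interval (default 0.95).
#' @return Data frame: `sgt_hours`, `cfu_per_ml`, `lower`, `upper`.
#' @export
estimate_concentration <- function(model, sgt_hours, allow_extrapolation = FALSE,
                                   level = 0.95) {
  if (!inherits(model, "sgt_calibration"))
    validation_error("model must be an sgt_calibration")
  if (model$slope >= 0)
    fit_error("calibration slope is non-negative: SGT must decrease with inoculum")
  sgt_hours <- as.numeric(sgt_hours)
  if (anyNA(sgt_hours) || any(!is.finite(sgt_hours)))
    validation_error("censored or non-finite SGT values cannot be inverted")
  out_of_range <- sgt_hours < model$sgt_range[1L] | sgt_hours > model$sgt_range[2L]
  if (any(out_of_range) && !isTRUE(allow_extrapolation))
    range_error(sprintf(
      "SGT value(s) %s outside the fitted range [%.3f, %.3f] h; set allow_extrapolation = TRUE to override",
      paste(formatC(sgt_hours[out_of_range], digits = 4, format = "g"),
            collapse = ", "),
      model$sgt_range[1L], model$sgt_range[2L]))
  log10_n <- (sgt_hours - model$intercept) / model$slope
  sd_log10 <- model$residual_sd / abs(model$slope)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(sgt_hours = sgt_hours,
             cfu_per_ml = 10^log10_n,
             lower = 10^(log10_n - z * sd_log10),
             upper = 10^(log10_n + z * sd_log10))
}

#' Doubling time implied by a calibration slope
#'
#' The exponential-growth model forces `slope = -td * log2(10)`, so the
#' doubling time is recoverable from the calibration alone:
#' `td = -slope * log10(2)`.
#'
#' @param model An `sgt_calibration` with negative slope.
#' @return Doubling time in hours.
#' @export
doubling_time_from_slope <- function(model) {
  if (!inherits(model, "sgt_calibration"))
    validation_error("model must be an sgt_calibration")
  if (model$slope >= 0)
    fit_error("calibration slope is non-negative: no doubling time implied")
  -model$slope * log10(2)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model An `sgt_calibration`.
#' @param path Output (or input) path of the JSON document.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `sgt_calibration`.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "sgt_calibration"))
    validation_error("model must be an sgt_calibration")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("slope", "intercept", "r_squared", "residual_sd", "n_points",
              "sgt_range", "log10_cfu_range")
  if (!all(needed %in% names(obj)))
    parse_error(sprintf("%s is not a calibration model (missing fields)", path))
  obj$log_base <- 10
  structure(obj[c(needed[1:5], "log_base", "sgt_range", "log10_cfu_range")],
            class = "sgt_calibration")
}
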