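#' Start Growth Time of one well
#'
#' The Start Growth Time (SGT) is the time at which a culture's OD600 first
#' reaches a preset threshold set just above background (0.15 by default,
#' configurable up to 0.2). A crossing requires `consecutive` supra-threshold
#' readings in a row, which makes the call robust to single-read spikes; if
#' fewer than `consecutive` readings remain at the end of the series, the
#' remaining supra-threshold readings are accepted. The crossing time is
#' linearly interpolated between the last sub-threshold read and the first
#' read of the qualifying run, so SGT resolution is finer than the read
#' cadence. A culture that never reaches the threshold is censored: its SGT
#' is reported as the last observed time, a lower bound, and flagged.
#'
#' @param curve A [growth_curve()].
#' @param threshold OD600 threshold, > 0. Default 0.15.
#' @param consecutive Number of consecutive supra-threshold reads required
#'   (>= 1). Default 2.
#' @param smooth If `TRUE`, apply a moving median of window 3 before
#'   thresholding. Off by default.
#' @return An `sgt_result`: list with `well_id`, `sgt_hours`, `threshold`,
#'   `censored`, `interpolated`.
#' @export
compute_sgt <- function(curve, threshold = 0.15, consecutive = 2L,
                        smooth = FALSE) {
  if (!inherits(curve, "growth_curve"))
    validation_error("compute_sgt expects a growth_curve")
  if (!is_scalar_number(threshold) || threshold <= 0)
    usage_error("threshold must be a single positive number")
  consecutive <- as.integer(consecutive)
  if (is.na(consecutive) || consecutive < 1L)
    usage_error("consecutive must be a positive integer")
  if (length(curve$times) < 2L)
    validation_error(sprintf("well %s: need at least 2 readings", curve$well_id))

  ods <- if (isTRUE(smooth)) stats::runmed(curve$ods, 3L) else curve$ods
  t <- curve$times
  n <- length(ods)
  above <- ods >= threshold

  hit <- NA_integer_
  for (i in which(above)) {
    run_end <- min(n, i + consecutive - 1L)
    if (all(above[i:run_end])) { hit <- i; break }
  }

  if (is.na(hit)) {
    res <- list(well_id = curve$well_id, sgt_hours = t[n], threshold = threshold,
                censored = TRUE, interpolated = FALSE)
  } else if (hit == 1L) {
    res <- list(well_id = curve$well_id, sgt_hours = t[1L], threshold = threshold,
                censored = FALSE, interpolated = FALSE)
  } else {
    # od[hit-1] < threshold by construction of the first qualifying run
    frac <- (threshold - ods[hit - 1L]) / (ods[hit] - ods[hit - 1L])
    res <- list(well_id = curve$well_id,
                sgt_hours = t[hit - 1L] + frac * (t[hit] - t[hit - 1L]),
                threshold = threshold, censored = FALSE, interpolated = TRUE)
  }
  structure(res, class = "sgt_result")
}

#' @export
print.sgt_result <- function(x, ...) {
  cat(sprintf("<sgt_result> well %s: %s h (threshold %.3f)%s\n", x$well_id,
              formatC(x$sgt_hours, digits = 4, format = "fg"), x$threshold,
              if (x$censored) " [censored: lower bound]" else ""))
  invisible(x)
}

#' Tabulate per-well SGT results
#'
#' @param results List of `sgt_result` objects.
#' @param map Optional [plate_map()] used to attach `sample_id` and `role`.
#' @return Data frame with one row per well: `well_id`, `sample_id`, `role`,
#'   `sgt_hours`, `censored`, `interpolated`, `threshold`.
#' @export
sgt_table <- function(results, map = NULL) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(well_id = r$well_id, sgt_hours = r$sgt_hours,
               censored = r$censored, interpolated = r$interpolated,
               threshold = r$threshold, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (!is.null(map)) {
    map <- plate_map(map)
    idx <- match(df$well_id, map$well)
    df$sample_id <- map$sample_id[idx]
    df$role <- map$role[idx]
    df <- df[, c("well_id", "sample_id", "role", "sgt_hours",
                 "censored", "interpolated", "threshold")]
  }
  df
}

#' Aggregate SGT replicates
#'
#' Groups per-well SGT results by replicate group (the plate map's
#' `replicate_group` where given, otherwise `sample_id` x `role`) and reports
#' the sample mean and sample standard deviation (n - 1 denominator) of the
#' non-censored members. Censored wells are counted and excluded from the
#' mean with a warning; a group whose members are all censored is reported
#' censored. A single-replicate group gets `sd = NA`, never 0.
#'
#' @param results List of `sgt_result` objects.
#' @param map A [plate_map()] covering every well in `results`.
#' @return Data frame: `replicate_group`, `sample_id`, `role`, `mean_sgt`,
#'   `sd_sgt`, `n`, `n_censored`, `censored`.
#' @export
aggregate_replicates <- function(results, map) {
  map <- plate_map(map)
  tab <- sgt_table(results)
  idx <- match(tab$well_id, map$well)
  if (anyNA(idx))
    validation_error(sprintf("well(s) missing from plate map: %s",
                             paste(tab$well_id[is.na(idx)], collapse = ", ")))
  tab$sample_id <- map$sample_id[idx]
  tab$role <- map$role[idx]
  grp <- map$replicate_group[idx]
  grp[is.na(grp) | !nzchar(grp)] <-
    paste(tab$sample_id, tab$role, sep = ".")[is.na(grp) | !nzchar(grp)]
  tab$replicate_group <- grp
  tab <- tab[tab$role != "blank", , drop = FALSE]

  out <- do.call(rbind, lapply(split(tab, tab$replicate_group), function(g) {
    ok <- !g$censored
    n_cens <- sum(!ok)
    if (n_cens > 0L && any(ok))
      warning(sprintf("group %s: %d censored well(s) excluded from the mean",
                      g$replicate_group[1L], n_cens), call. = FALSE)
    data.frame(
      replicate_group = g$replicate_group[1L],
      sample_id = g$sample_id[1L], role = g$role[1L],
      mean_sgt = if (any(ok)) mean(g$sgt_hours[ok]) else NA_real_,
      sd_sgt = if (sum(ok) >= 2L) stats::sd(g$sgt_hours[ok]) else NA_real_,
      n = sum(ok), n_censored = n_cens, censored = !any(ok),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

as_aggregate <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1L, ])
  if (is.null(x$mean) && !is.null(x$mean_sgt)) x$mean <- x$mean_sgt
  if (is.null(x$sd) && !is.null(x$sd_sgt)) x$sd <- x$sd_sgt
  if (is.null(x$censored)) x$censored <- FALSE
  if (is.null(x$n)) x$n <- NA_integer_
  x
}

#' Delta-SGT of a treated sample against its normalizer
#'
#' Computes `delta_sgt = mean SGT(treated) - mean SGT(normalizer)`, the delay
#' attributable to cell death, with the standard deviation propagated in
#' quadrature (the qPCR delta-Ct convention). Censoring on either side is
#' propagated: the result is flagged and carries no numeric value.
#'
#' @param treated,normalizer Aggregated SGT summaries: a list or one-row data
#'   frame with `mean` (or `mean_sgt`), `sd` (or `sd_sgt`), `n`, `censored`.
#' @param sample_id Label attached to the result.
#' @return A `delta_sgt` object: `sample_id`, `value` (hours), `sd`,
#'   `n_treated`, `n_normalizer`, `censored`.
#' @export
delta_sgt <- function(treated, normalizer, sample_id) {
  treated <- as_aggregate(treated); normalizer <- as_aggregate(normalizer)
  censored <- isTRUE(treated$censored) || isTRUE(normalizer$censored)
  structure(list(
    sample_id = as.character(sample_id),
    value = if (censored) NA_real_ else treated$mean - normalizer$mean,
    sd = if (censored) NA_real_ else sqrt(treated$sd^2 + normalizer$sd^2),
    n_treated = treated$n, n_normalizer = normalizer$n,
    censored = censored
  ), class = "delta_sgt")
}

#' Delta-delta-SGT and fold change
#'
#' Relative survival of a sample against a reference ("calibrator") sample,
#' by the qPCR delta-delta-Ct recipe: `ddsgt = delta_sgt(sample) -
#' delta_sgt(calibrator)`, fold change `F = 2^-ddsgt`, log2 fold change
#' `-ddsgt`. Two unit conventions are offered. In `"paper"` mode (default)
#' the hour-valued ddsgt is exponentiated directly. In `"doublings"` mode
#' ddsgt is first divided by the culture's doubling time, so that `2^-ddsgt`
#' is a true cell-count ratio under exponential growth. The mode is always
#' recorded in the result.
#'
#' @param sample,calibrator `delta_sgt` objects.
#' @param mode `"paper"` or `"doublings"`.
#' @param doubling_time_hours Required (> 0) in doublings mode.
#' @return A `ddsgt_result`: `sample_id`, `calibrator_id`, `ddsgt` (hours or
#'   doublings per mode), `log2_fold = -ddsgt`, `fold = 2^-ddsgt`, `sd`
#'   (same scale as `ddsgt`), `sd_fold` (delta method), `mode`,
#'   `doubling_time_hours` (doublings mode only), `censored`.
#' @export
delta_delta_sgt <- function(sample, calibrator, mode = c("paper", "doublings"),
                            doubling_time_hours = NULL) {
  mode <- match.arg(mode)
  if (!inherits(sample, "delta_sgt") || !inherits(calibrator, "delta_sgt"))
    validation_error("delta_delta_sgt expects delta_sgt inputs")
  if (mode == "doublings" &&
      (is.null(doubling_time_hours) || !is_scalar_number(doubling_time_hours) ||
       doubling_time_hours <= 0))
    usage_error("doublings mode requires doubling_time_hours > 0")

  censored <- isTRUE(sample$censored) || isTRUE(calibrator$censored)
  if (censored) {
    dd <- NA_real_; sd_dd <- NA_real_
  } else {
    dd <- sample$value - calibrator$value
    sd_dd <- sqrt(sample$sd^2 + calibrator$sd^2)
    if (mode == "doublings") {
      dd <- dd / doubling_time_hours
      sd_dd <- sd_dd / doubling_time_hours
    }
  }
  fold <- 2^(-dd)
  structure(list(
    sample_id = sample$sample_id, calibrator_id = calibrator$sample_id,
    ddsgt = dd, log2_fold = -dd, fold = fold, sd = sd_dd,
    sd_fold = fold * log(2) * sd_dd, mode = mode,
    doubling_time_hours = if (mode == "doublings") doubling_time_hours else NULL,
    censored = censored
  ), class = "ddsgt_result")
}

#' @export
print.ddsgt_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<ddsgt> %s vs %s: censored\n", x$sample_id, x$calibrator_id))
  } else {
    cat(sprintf("<ddsgt> %s vs %s: log2 fold %.3f +/- %.3f (fold %.4g, %s mode)\n",
                x$sample_id, x$calibrator_id, x$log2_fold,
                x$sd, x$fold, x$mode))
  }
  invisible(x)
}

#' Doubling time from the log-linear phase of a growth curve
#'
#' Ordinary least-squares fit of `ln(OD)` on time over the reads whose OD
#' falls inside `window` (default threshold to 4x threshold, i.e. the early
#' exponential phase just above detection); doubling time is `ln(2) / slope`.
#'
#' @param curve A [growth_curve()].
#' @param window OD interval `c(lo, hi)` selecting the fit points.
#' @return Doubling time in hours.
#' @export
estimate_doubling_time <- function(curve, window = c(0.15, 0.6)) {
  if (!inherits(curve, "growth_curve"))
    validation_error("estimate_doubling_time expects a growth_curve")
  if (length(window) != 2L || window[1L] <= 0 || window[2L] <= window[1L])
    usage_error("window must be an increasing positive OD interval")
  sel <- curve$ods >= window[1L] & curve$ods <= window[2L]
  if (sum(sel) < 3L)
    estimation_error(sprintf(
      "well %s: need >= 3 readings with OD in [%g, %g] to estimate doubling time",
      curve$well_id, window[1L], window[2L]))
  slope <- stats::coef(stats::lm(log(curve$ods[sel]) ~ curve$times[sel]))[[2L]]
  if (!is.finite(slope) || slope <= 0)
    estimation_error(sprintf("well %s: no positive growth in the fit window",
                             curve$well_id))
  log(2) / slope
}
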