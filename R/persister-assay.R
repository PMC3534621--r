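#' Describe a relative-survival assay
#'
#' Captures the design of a paired-arm tolerance assay: every sample has
#' antibiotic-treated and untreated (normalizer) replicate wells, one sample
#' is the reference calibrator, and both arms share one post-treatment
#' dilution factor. Unequal dilutions between arms would bias every
#' delta-SGT by `log2(ratio) * td` and are therefore rejected by design.
#'
#' @param samples Character vector of sample ids.
#' @param calibrator_id Reference sample; must be one of `samples`.
#' @param dilution_factor Common post-treatment dilution (default 500).
#' @param threshold OD600 threshold for SGT detection (default 0.15).
#' @param mode Fold-change unit convention, `"paper"` or `"doublings"`
#'   (see [delta_delta_sgt()]).
#' @param doubling_time_hours Required when `mode = "doublings"`; if `NULL`
#'   there, it is estimated from the calibrator's normalizer curves.
#' @param consecutive Supra-threshold reads required for a crossing.
#' @param slope_warn_factor Warn when a sample's treated-arm apparent
#'   doubling time differs from its normalizer's by more than this factor —
#'   a symptom of altered awakening kinetics or antibiotic carryover that
#'   biases SGT-based survival estimates.
#' @return An `assay_design` object.
#' @export
assay_design <- function(samples, calibrator_id, dilution_factor = 500,
                         threshold = 0.15, mode = c("paper", "doublings"),
                         doubling_time_hours = NULL, consecutive = 2L,
                         slope_warn_factor = 1.5) {
  mode <- match.arg(mode)
  samples <- as.character(samples)
  if (!length(samples) || anyDuplicated(samples))
    validation_error("samples must be a non-empty set of unique ids")
  if (!calibrator_id %in% samples)
    validation_error(sprintf("calibrator '%s' is not among the samples", calibrator_id))
  if (!is_scalar_number(dilution_factor) || dilution_factor < 1)
    validation_error("dilution_factor must be >= 1")
  if (!is_scalar_number(threshold) || threshold <= 0)
    validation_error("threshold must be > 0")
  if (!is.null(doubling_time_hours) &&
      (!is_scalar_number(doubling_time_hours) || doubling_time_hours <= 0))
    validation_error("doubling_time_hours must be > 0")
  structure(list(samples = samples, calibrator_id = calibrator_id,
                 dilution_factor = dilution_factor, threshold = threshold,
                 mode = mode, doubling_time_hours = doubling_time_hours,
                 consecutive = as.integer(consecutive),
                 slope_warn_factor = slope_warn_factor),
            class = "assay_design")
}

# Apparent doubling time of each arm, for the awakening-kinetics warning.
arm_doubling <- function(curves, wells, threshold) {
  tds <- vapply(wells, function(w) {
    tryCatch(estimate_doubling_time(curves[[w]], c(threshold, 4 * threshold)),
             sgt_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(tds))) NA_real_ else mean(tds, na.rm = TRUE)
}

#' Quantify relative survival across an assay plate
#'
#' Runs the full SGT relative-survival pipeline: per-well SGT detection,
#' replicate aggregation, per-sample delta-SGT (treated minus normalizer),
#' and delta-delta-SGT against the calibrator, reporting
#' `log2_fold = -ddsgt` and `fold = 2^-ddsgt` with standard deviations
#' propagated in quadrature. The calibrator row has `log2_fold` 0 by
#' construction. Censoring propagates: a sample whose treated wells never
#' reach the threshold is flagged, never silently numeric.
#'
#' @param curves Named list of [growth_curve()] objects.
#' @param map A [plate_map()] assigning wells to samples and roles.
#' @param design An [assay_design()].
#' @return Data frame with one row per sample: `sample_id`, `n_treated`,
#'   `n_normalizer`, `delta_sgt`, `sd_delta`, `ddsgt`, `log2_fold`, `fold`,
#'   `sd`, `mode`, `censored`.
#' @export
quantify_survival <- function(curves, map, design) {
  stopifnot(inherits(design, "assay_design"))
  map <- plate_map(map)
  for (sid in design$samples) {
    for (role in c("treated", "normalizer")) {
      w <- map$well[map$sample_id == sid & map$role == role]
      if (!length(intersect(w, names(curves)))) {
        msg <- sprintf("sample '%s' has no %s wells with curves", sid, role)
        if (sid == design$calibrator_id) validation_error(paste("calibrator:", msg))
        validation_error(msg)
      }
    }
  }

  used <- map[map$sample_id %in% design$samples &
                map$role %in% c("treated", "normalizer") &
                map$well %in% names(curves), , drop = FALSE]
  results <- lapply(used$well, function(w)
    compute_sgt(curves[[w]], design$threshold, design$consecutive))
  agg <- aggregate_replicates(results, used)

  pick <- function(sid, role) {
    row <- agg[agg$sample_id == sid & agg$role == role, , drop = FALSE]
    if (nrow(row) != 1L)
      validation_error(sprintf(
        "sample '%s' %s wells split across replicate groups: use one group per arm",
        sid, role))
    row
  }
  deltas <- lapply(design$samples, function(sid)
    delta_sgt(pick(sid, "treated"), pick(sid, "normalizer"), sid))
  names(deltas) <- design$samples

  td <- design$doubling_time_hours
  if (design$mode == "doublings" && is.null(td)) {
    cal_norm <- used$well[used$sample_id == design$calibrator_id &
                            used$role == "normalizer"]
    td <- arm_doubling(curves, cal_norm, design$threshold)
    if (is.na(td))
      estimation_error("cannot estimate doubling time from calibrator normalizer wells; supply doubling_time_hours")
  }

  # awakening-kinetics / carryover surveillance
  for (sid in design$samples) {
    td_t <- arm_doubling(curves, used$well[used$sample_id == sid &
                                             used$role == "treated"],
                         design$threshold)
    td_n <- arm_doubling(curves, used$well[used$sample_id == sid &
                                             used$role == "normalizer"],
                         design$threshold)
    if (!is.na(td_t) && !is.na(td_n)) {
      ratio <- td_t / td_n
      if (ratio > design$slope_warn_factor || ratio < 1 / design$slope_warn_factor)
        warning(sprintf(
          "sample '%s': treated-arm apparent doubling time differs from normalizer by factor %.2f; awakening-kinetics bias possible",
          sid, ratio), call. = FALSE)
    }
  }

  cal <- deltas[[design$calibrator_id]]
  rows <- lapply(design$samples, function(sid) {
    dd <- delta_delta_sgt(deltas[[sid]], cal, design$mode,
                          doubling_time_hours = td)
    data.frame(sample_id = sid,
               n_treated = deltas[[sid]]$n_treated,
               n_normalizer = deltas[[sid]]$n_normalizer,
               delta_sgt = deltas[[sid]]$value, sd_delta = deltas[[sid]]$sd,
               ddsgt = dd$ddsgt, log2_fold = dd$log2_fold, fold = dd$fold,
               sd = dd$sd, mode = dd$mode, censored = dd$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare SGT-derived folds with ground-truth counts
#'
#' Pairs each sample's SGT log2 fold change with the log2 fold change from an
#' independent count table (CFU plating in the wet lab; simulator ground
#' truth here) and summarizes their discrepancy: per-sample differences, the
#' mean absolute difference, and a paired two-sided t-test p-value. The
#' p-value is reported, not thresholded.
#'
#' @param sgt_folds Data frame with `sample_id` and `log2_fold` (e.g. from
#'   [quantify_survival()]).
#' @param count_folds Data frame with `sample_id` and `log2_fold` from the
#'   reference counts (see [true_log2_fold()]).
#' @return List of class `sgt_count_comparison`: `per_sample` (sample_id,
#'   log2_fold_sgt, log2_fold_counts, difference), `mean_abs_difference`,
#'   `p_value`, `n`.
#' @export
compare_with_counts <- function(sgt_folds, count_folds) {
  for (nm in list(sgt_folds, count_folds))
    if (!is.data.frame(nm) || !all(c("sample_id", "log2_fold") %in% names(nm)))
      validation_error("both tables need sample_id and log2_fold columns")
  if (!setequal(sgt_folds$sample_id, count_folds$sample_id) ||
      anyDuplicated(sgt_folds$sample_id) || anyDuplicated(count_folds$sample_id))
    validation_error("sample_id sets must match one-to-one")
  idx <- match(sgt_folds$sample_id, count_folds$sample_id)
  per <- data.frame(sample_id = sgt_folds$sample_id,
                    log2_fold_sgt = sgt_folds$log2_fold,
                    log2_fold_counts = count_folds$log2_fold[idx],
                    stringsAsFactors = FALSE)
  per$difference <- per$log2_fold_sgt - per$log2_fold_counts
  p <- if (nrow(per) >= 2L && stats::sd(per$difference) > 0)
    stats::t.test(per$log2_fold_sgt, per$log2_fold_counts,
                  paired = TRUE)$p.value
  else NA_real_
  structure(list(per_sample = per,
                 mean_abs_difference = mean(abs(per$difference)),
                 p_value = p, n = nrow(per)),
            class = "sgt_count_comparison")
}

#' @export
print.sgt_count_comparison <- function(x, ...) {
  cat(sprintf("<sgt_count_comparison> %d samples, mean |log2 fold difference| = %.4f, paired p = %s\n",
              x$n, x$mean_abs_difference,
              if (is.na(x$p_value)) "NA" else formatC(x$p_value, digits = 3)))
  invisible(x)
}

#' Screening capacity of a plate
#'
#' How many compounds fit on one plate at a given replication level:
#' `floor((total_wells - control_wells) / replicates)` — e.g. triplicates of
#' 32 compounds in a 96-well plate, or 128 in a 384-well plate.
#'
#' @param total_wells Wells on the plate (96, 384, or any positive count).
#' @param replicates Replicate wells per compound (>= 1).
#' @param control_wells Wells reserved for controls (< total_wells).
#' @return Integer number of compounds.
#' @export
plate_capacity <- function(total_wells, replicates, control_wells = 0L) {
  if (!is_scalar_number(total_wells) || total_wells < 1)
    usage_error("total_wells must be a positive count")
  if (!is_scalar_number(replicates) || replicates < 1)
    usage_error("replicates must be >= 1")
  if (!is_scalar_number(control_wells) || control_wells < 0 ||
      control_wells >= total_wells)
    usage_error("control_wells must be >= 0 and smaller than total_wells")
  as.integer(floor((total_wells - control_wells) / replicates))
}
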