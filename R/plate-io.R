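#' Construct a growth curve
#'
#' A growth curve is one well's kinetic OD600 series. Times are always stored
#' in hours; readers convert from minutes or seconds on ingest.
#'
#' @param well_id Plate coordinate, e.g. `"A1"`.
#' @param times Numeric vector of read times in hours, strictly increasing.
#' @param ods Numeric vector of OD600 values, same length as `times`.
#' @param blank_corrected Logical flag; set by [apply_blank_correction()].
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(well_id, times, ods, blank_corrected = FALSE) {
  if (!is.character(well_id) || length(well_id) != 1L || !nzchar(well_id))
    validation_error("well_id must be a single non-empty string")
  times <- as.numeric(times)
  ods <- as.numeric(ods)
  if (length(times) != length(ods))
    validation_error(sprintf("well %s: times and ods differ in length", well_id))
  if (length(times) < 2L)
    validation_error(sprintf("well %s: a growth curve needs at least 2 readings", well_id))
  if (anyNA(times) || any(!is.finite(times)))
    validation_error(sprintf("well %s: non-finite times", well_id))
  if (anyNA(ods) || any(!is.finite(ods)))
    validation_error(sprintf("well %s: non-finite OD values", well_id))
  if (any(diff(times) <= 0))
    validation_error(sprintf("well %s: times must be strictly increasing", well_id))
  structure(
    list(well_id = well_id, times = times, ods = ods,
         blank_corrected = isTRUE(blank_corrected)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> well %s: %d reads, %.2f-%.2f h, OD %.3f-%.3f%s\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              min(x$ods), max(x$ods),
              if (x$blank_corrected) ", blank-corrected" else ""))
  invisible(x)
}

time_to_hours <- function(t, time_unit) {
  switch(time_unit,
         hours = t,
         minutes = t / 60,
         seconds = t / 3600,
         usage_error(sprintf("unknown time unit '%s' (use hours, minutes or seconds)",
                             time_unit)))
}

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, sep) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

# Convert a character column to numeric, naming the 1-based data line
# (header = line 1) of the first failure.
numeric_column <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    parse_error(sprintf("%s: cannot parse '%s' as number in column '%s' (line %d)",
                        path, x[bad[1L]], column, bad[1L] + 1L))
  out
}

#' Read a kinetic plate-reader table
#'
#' Reads kinetic OD600 exports in either a long layout (columns
#' `well,time,od`) or a wide layout (a time column followed by one column per
#' well). Delimiter is comma, or tab for `.tsv`/`.txt` extensions. Times are
#' converted to hours and each well's series sorted ascending; duplicate
#' `(well, time)` pairs are rejected.
#'
#' @param path Path to a delimited text file.
#' @param layout `"long"`, `"wide"`, or `"auto"` (long iff the header is
#'   exactly `well,time,od`).
#' @param time_unit Unit of the time column: `"hours"`, `"minutes"` or
#'   `"seconds"`.
#' @param sep Field delimiter; default inferred from the file extension.
#' @return A named list of [growth_curve()] objects, one per well.
#' @export
read_kinetic_table <- function(path, layout = c("auto", "long", "wide"),
                               time_unit = c("hours", "minutes", "seconds"),
                               sep = NULL) {
  layout <- match.arg(layout)
  if (length(time_unit) == 1L && !time_unit %in% c("hours", "minutes", "seconds"))
    usage_error(sprintf("unknown time unit '%s' (use hours, minutes or seconds)", time_unit))
  time_unit <- match.arg(time_unit)
  sep <- delim_for(path, sep)
  df <- read_delim_checked(path, sep)
  if (layout == "auto")
    layout <- if (identical(tolower(names(df)), c("well", "time", "od"))) "long" else "wide"

  if (layout == "long") {
    names(df) <- tolower(names(df))
    missing_cols <- setdiff(c("well", "time", "od"), names(df))
    if (length(missing_cols))
      parse_error(sprintf("%s: long layout requires columns well,time,od (missing: %s)",
                          path, paste(missing_cols, collapse = ", ")))
    time <- time_to_hours(numeric_column(df$time, "time", path), time_unit)
    od <- numeric_column(df$od, "od", path)
    well <- df$well
    curves <- lapply(split(seq_along(well), well), function(idx) {
      t_w <- time[idx]; od_w <- od[idx]
      o <- order(t_w)
      t_w <- t_w[o]; od_w <- od_w[o]
      if (anyDuplicated(t_w))
        validation_error(sprintf("well %s: duplicate time points", well[idx[1L]]))
      growth_curve(well[idx[1L]], t_w, od_w)
    })
  } else {
    if (ncol(df) < 2L)
      parse_error(sprintf("%s: wide layout needs a time column plus well columns", path))
    time <- time_to_hours(numeric_column(df[[1L]], names(df)[1L], path), time_unit)
    o <- order(time)
    time <- time[o]
    if (anyDuplicated(time))
      validation_error(sprintf("%s: duplicate time points in wide table", path))
    wells <- names(df)[-1L]
    if (anyDuplicated(wells))
      validation_error(sprintf("%s: duplicate well columns", path))
    curves <- lapply(wells, function(w) {
      growth_curve(w, time, numeric_column(df[[w]], w, path)[o])
    })
    names(curves) <- wells
  }
  curves[order(names(curves))]
}

#' Write growth curves as a long kinetic table
#'
#' Writes the long `well,time,od` CSV layout with enough digits that reading
#' the file back reproduces times and ODs exactly.
#'
#' @param curves Named list of [growth_curve()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_table <- function(curves, path) {
  stopifnot(length(curves) >= 1L)
  rows <- lapply(curves, function(cv)
    data.frame(well = cv$well_id,
               time = formatC(cv$times, digits = 17, format = "g"),
               od = formatC(cv$ods, digits = 17, format = "g"),
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

PLATE_ROLES <- c("treated", "normalizer", "blank", "calibration_point")

#' Construct / validate a plate map
#'
#' A plate map assigns wells to samples and experimental roles: `treated`
#' (antibiotic-exposed), `normalizer` (untreated aliquot of the same culture),
#' `blank` (medium only), or `calibration_point` (well with a known CFU/mL).
#'
#' @param df A data.frame with columns `well`, `sample_id`, `role`, and
#'   optionally `replicate_group`, `known_cfu_per_ml`, `compound`.
#' @return A validated `plate_map` data.frame with all six columns.
#' @export
plate_map <- function(df) {
  if (!is.data.frame(df)) validation_error("plate map must be a data.frame")
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(c("well", "sample_id", "role"), names(df))
  if (length(missing_cols))
    validation_error(sprintf("plate map missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  df$well <- as.character(df$well)
  df$sample_id <- as.character(df$sample_id)
  df$role <- tolower(trimws(as.character(df$role)))
  if (anyDuplicated(df$well))
    validation_error(sprintf("duplicate well(s) in plate map: %s",
                             paste(unique(df$well[duplicated(df$well)]), collapse = ", ")))
  bad_roles <- setdiff(unique(df$role), PLATE_ROLES)
  if (length(bad_roles))
    validation_error(sprintf("unknown role(s): %s (expected %s)",
                             paste(bad_roles, collapse = ", "),
                             paste(PLATE_ROLES, collapse = ", ")))
  if (!"replicate_group" %in% names(df)) df$replicate_group <- NA_character_
  df$replicate_group <- as.character(df$replicate_group)
  if (!"compound" %in% names(df)) df$compound <- NA_character_
  df$compound <- as.character(df$compound)
  if (!"known_cfu_per_ml" %in% names(df)) df$known_cfu_per_ml <- NA_real_
  df$known_cfu_per_ml <- suppressWarnings(as.numeric(df$known_cfu_per_ml))

  is_cal <- df$role == "calibration_point"
  has_cfu <- !is.na(df$known_cfu_per_ml)
  if (any(has_cfu & !is_cal))
    validation_error(sprintf("known_cfu_per_ml given for non-calibration well(s): %s",
                             paste(df$well[has_cfu & !is_cal], collapse = ", ")))
  if (any(is_cal & !has_cfu))
    validation_error(sprintf("calibration_point well(s) missing known_cfu_per_ml: %s",
                             paste(df$well[is_cal & !has_cfu], collapse = ", ")))
  if (any(has_cfu & df$known_cfu_per_ml <= 0))
    validation_error("known_cfu_per_ml must be positive")

  out <- df[, c("well", "sample_id", "role", "replicate_group",
                "known_cfu_per_ml", "compound")]
  rownames(out) <- NULL
  class(out) <- c("plate_map", "data.frame")
  out
}

#' Read a plate map CSV
#'
#' Expects header `well,sample_id,role` plus optional `replicate_group`,
#' `known_cfu_per_ml`, `compound`. Roles are matched case-insensitively.
#'
#' @param path Path to the plate-map CSV/TSV.
#' @param sep Field delimiter; default inferred from the file extension.
#' @return A `plate_map` data.frame (see [plate_map()]).
#' @export
read_plate_map <- function(path, sep = NULL) {
  df <- read_delim_checked(path, delim_for(path, sep))
  names(df) <- tolower(names(df))
  if ("known_cfu_per_ml" %in% names(df)) {
    nonempty <- !is.na(df$known_cfu_per_ml) & nzchar(trimws(df$known_cfu_per_ml))
    vals <- rep(NA_real_, nrow(df))
    if (any(nonempty))
      vals[nonempty] <- numeric_column(df$known_cfu_per_ml[nonempty],
                                       "known_cfu_per_ml", path)
    df$known_cfu_per_ml <- vals
  }
  plate_map(df)
}

#' Subtract the blank signal from sample wells
#'
#' If the plate map declares `blank` wells, the per-timepoint median OD across
#' blanks is subtracted from every non-blank well and the result flagged
#' `blank_corrected`; values are not clipped at zero. Without blank wells the
#' input is returned unchanged. Blank wells must share one time grid, and all
#' corrected wells must be on that grid. Correcting an already-corrected set
#' raises an error, so the operation cannot be applied twice.
#'
#' @param curves Named list of [growth_curve()] objects.
#' @param map A [plate_map()].
#' @return The curve list, blank-corrected where applicable.
#' @export
apply_blank_correction <- function(curves, map) {
  map <- plate_map(map)
  blank_wells <- intersect(map$well[map$role == "blank"], names(curves))
  if (!length(blank_wells)) return(curves)
  grid <- curves[[blank_wells[1L]]]$times
  for (w in blank_wells)
    if (!isTRUE(all.equal(curves[[w]]$times, grid)))
      validation_error(sprintf("blank well %s is not on the shared blank time grid", w))
  blank_median <- apply(do.call(rbind, lapply(curves[blank_wells], `[[`, "ods")),
                        2L, stats::median)
  lapply(curves, function(cv) {
    if (cv$well_id %in% blank_wells) return(cv)
    if (cv$blank_corrected)
      validation_error(sprintf("well %s is already blank-corrected", cv$well_id))
    if (!isTRUE(all.equal(cv$times, grid)))
      validation_error(sprintf("well %s is not on the blank wells' time grid", cv$well_id))
    growth_curve(cv$well_id, cv$times, cv$ods - blank_median, blank_corrected = TRUE)
  })
}
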