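#' Simulation parameters for a plate-reader growth experiment
#'
#' The generative model: cells at concentration `n0` sit through an optional
#' lag, then grow logistically with rate `ln(2) / doubling_time_hours`
#' towards carrying capacity `K`; optical density is
#' `od_background + od_per_cell * N(t)`, multiplied by mean-one lognormal
#' noise of the given CV and perturbed by additive Gaussian read noise; the
#' reader samples every `read_interval_hours`. Defaults place OD 2.0 at
#' 4e9 cells/mL, reads every 15 min for 24 h, and use 5% multiplicative plus
#' 0.005 additive OD noise. Inocula below 1000 cells/mL are Poisson-sampled,
#' reproducing the large relative error of very dilute inocula. A seed is
#' mandatory: there is no hidden global randomness.
#'
#' @param n0 Initial concentration, cells/mL (> 0).
#' @param doubling_time_hours Exponential-phase doubling time (> 0).
#' @param carrying_capacity Logistic ceiling, cells/mL (>= n0).
#' @param od_per_cell OD600 per cell/mL of culture.
#' @param od_background OD600 of sterile medium (>= 0).
#' @param noise_multiplicative_cv CV of mean-one lognormal OD noise (>= 0).
#' @param noise_additive_sd SD of additive Gaussian OD noise (>= 0).
#' @param lag_hours Lag before growth starts (>= 0).
#' @param read_interval_hours Read cadence (> 0), default 0.25 h (15 min).
#' @param duration_hours Total observation window (>= one interval).
#' @param seed Integer RNG seed (required).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n0 = 1e6, doubling_time_hours = 0.5,
                       carrying_capacity = 5e9, od_per_cell = 5e-10,
                       od_background = 0.04, noise_multiplicative_cv = 0.05,
                       noise_additive_sd = 0.005, lag_hours = 0,
                       read_interval_hours = 0.25, duration_hours = 24,
                       seed) {
  if (missing(seed) || is.null(seed))
    usage_error("sim_params: a seed is required")
  seed <- as.integer(seed)
  if (is.na(seed)) usage_error("sim_params: seed must be an integer")
  p <- list(n0 = n0, doubling_time_hours = doubling_time_hours,
            carrying_capacity = carrying_capacity, od_per_cell = od_per_cell,
            od_background = od_background,
            noise_multiplicative_cv = noise_multiplicative_cv,
            noise_additive_sd = noise_additive_sd, lag_hours = lag_hours,
            read_interval_hours = read_interval_hours,
            duration_hours = duration_hours, seed = seed)
  for (f in setdiff(names(p), "seed"))
    if (!is_scalar_number(p[[f]]))
      validation_error(sprintf("sim_params: %s must be a single finite number", f))
  if (p$n0 <= 0) validation_error("sim_params: n0 must be > 0")
  if (p$doubling_time_hours <= 0)
    validation_error("sim_params: doubling_time_hours must be > 0")
  if (p$n0 > p$carrying_capacity)
    validation_error("sim_params: n0 must not exceed carrying_capacity")
  if (p$od_per_cell <= 0) validation_error("sim_params: od_per_cell must be > 0")
  if (p$od_background < 0 || p$noise_multiplicative_cv < 0 ||
      p$noise_additive_sd < 0 || p$lag_hours < 0)
    validation_error("sim_params: background, noise and lag must be >= 0")
  if (p$read_interval_hours <= 0)
    validation_error("sim_params: read_interval_hours must be > 0")
  if (p$duration_hours < p$read_interval_hours)
    validation_error("sim_params: duration must cover at least one read interval")
  structure(p, class = "sim_params")
}

#' Antibiotic-kill parameters
#'
#' Describes the surviving (persister) subpopulation left by a bactericidal
#' treatment: the surviving count before regrowth is
#' `n0 * persister_fraction`, and regrowth is delayed by the persisters'
#' awakening lag.
#'
#' @param persister_fraction Surviving fraction in (0, 1].
#' @param awakening_delay_hours Regrowth lag of the survivors (>= 0).
#' @return A `kill_params` list.
#' @export
kill_params <- function(persister_fraction, awakening_delay_hours = 0) {
  if (!is_scalar_number(persister_fraction) ||
      persister_fraction <= 0 || persister_fraction > 1)
    validation_error("persister_fraction must be in (0, 1]")
  if (!is_scalar_number(awakening_delay_hours) || awakening_delay_hours < 0)
    validation_error("awakening_delay_hours must be >= 0")
  structure(list(persister_fraction = persister_fraction,
                 awakening_delay_hours = awakening_delay_hours),
            class = "kill_params")
}

# Poisson-sample a dilute inoculum: below 1000 cells/mL pipetting error is
# dominated by counting statistics.
realize_inoculum <- function(n0) {
  if (n0 < 1000) as.numeric(stats::rpois(1L, n0)) else n0
}

# Deterministic cell trajectory: constant n0 through the lag, then logistic.
cell_trajectory <- function(times, n0, td, K, lag) {
  if (n0 == 0) return(rep(0, length(times)))
  r <- log(2) / td
  tp <- pmax(times - lag, 0)
  e <- exp(r * tp)
  K * n0 * e / (K + n0 * (e - 1))
}

# Core generator; assumes the RNG state is already set by the caller.
simulate_well <- function(p, n0, lag, well_id) {
  times <- seq(0, p$duration_hours, by = p$read_interval_hours)
  cells <- cell_trajectory(times, n0, p$doubling_time_hours,
                           p$carrying_capacity, lag)
  od <- p$od_background + p$od_per_cell * cells
  if (p$noise_multiplicative_cv > 0) {
    sigma <- sqrt(log1p(p$noise_multiplicative_cv^2))
    od <- od * stats::rlnorm(length(od), meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  if (p$noise_additive_sd > 0)
    od <- od + stats::rnorm(length(od), sd = p$noise_additive_sd)
  list(curve = growth_curve(well_id, times, od),
       truth = data.frame(well = well_id, time = times, cells = cells,
                          stringsAsFactors = FALSE))
}

#' Simulate one well's growth curve
#'
#' Generates a kinetic OD600 series from the logistic-growth + noise model in
#' [sim_params()], together with the true cell-count trajectory. The same
#' parameters and seed always give bit-identical output.
#'
#' @param params A [sim_params()].
#' @param well_id Well label for the generated curve.
#' @return List with `curve` (a [growth_curve()]), `truth` (data frame
#'   `well,time,cells`), `realized_n0` (Poisson-sampled inoculum where
#'   applicable), and `params`.
#' @export
simulate_growth <- function(params, well_id = "A1") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n0 <- realize_inoculum(params$n0)
  w <- simulate_well(params, n0, params$lag_hours, well_id)
  list(curve = w$curve, truth = w$truth, realized_n0 = n0, params = params)
}

well_names <- function(n) {
  rows <- LETTERS[1:8]
  paste0(rep(rows, each = 12L), rep(1:12, times = 8L))[seq_len(n)]
}

#' Simulate a serial dilution series
#'
#' One plate row of wells inoculated at `n0 / fold^k`, `k = 0..steps-1`, each
#' with independent noise draws. Nominal and realized (Poisson-sampled where
#' dilute) inocula are recorded as ground truth — the realized value is what
#' CFU plating of the inoculum would measure.
#'
#' @param params A [sim_params()]; `params$n0` is the top concentration.
#' @param fold Dilution factor between steps (default 10).
#' @param steps Number of wells (>= 2).
#' @return List with `curves` (named list of growth curves), `truth` (data
#'   frame `well,nominal_n0,realized_n0`), and `params`.
#' @export
simulate_dilution_series <- function(params, fold = 10, steps = 8L) {
  stopifnot(inherits(params, "sim_params"))
  if (!is_scalar_number(fold) || fold <= 1)
    usage_error("fold must be > 1")
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 2L) usage_error("steps must be >= 2")
  nominal <- params$n0 / fold^(seq_len(steps) - 1L)
  if (nominal[steps] < 1)
    warning("lowest dilution is below 1 cell/mL: sub-single-cell regime",
            call. = FALSE)
  set.seed(params$seed)
  wells <- well_names(steps)
  curves <- vector("list", steps)
  realized <- numeric(steps)
  for (k in seq_len(steps)) {
    realized[k] <- realize_inoculum(nominal[k])
    curves[[k]] <- simulate_well(params, realized[k], params$lag_hours,
                                 wells[k])$curve
  }
  names(curves) <- wells
  list(curves = curves,
       truth = data.frame(well = wells, nominal_n0 = nominal,
                          realized_n0 = realized, stringsAsFactors = FALSE),
       params = params)
}

#' Simulate an antibiotic-kill / persister assay plate
#'
#' Emulates the paired-arm design of a tolerance assay: for each sample an
#' untreated aliquot is diluted (default 1:500) into fresh medium to serve as
#' the normalizer, while the antibiotic-treated culture — of which only the
#' persister fraction survives — is identically diluted and regrows after the
#' survivors' awakening delay. True surviving concentrations are recorded for
#' oracle comparisons. Dilute inocula are Poisson-sampled, so a treated well
#' whose expected survivor count is below one cell may come up sterile (and
#' will be censored downstream); this is recorded in the truth table.
#'
#' @param params A [sim_params()]; `params$n0` is the pre-dilution culture
#'   concentration of every arm.
#' @param kill A [kill_params()] giving the default persister fraction and
#'   awakening delay.
#' @param samples Data frame with `sample_id` and optionally per-sample
#'   `persister_fraction` and `awakening_delay_hours` overriding `kill`.
#' @param dilution_factor Post-treatment dilution applied to both arms.
#' @param replicates Wells per arm per sample (default 3).
#' @return List with `curves`, `map` (a [plate_map()] with treated and
#'   normalizer roles), `truth` (per-sample fractions and per-well realized
#'   inocula), and `params`.
#' @export
simulate_persister_assay <- function(params, kill, samples,
                                     dilution_factor = 500, replicates = 3L) {
  stopifnot(inherits(params, "sim_params"), inherits(kill, "kill_params"))
  if (!is.data.frame(samples) || !"sample_id" %in% names(samples))
    validation_error("samples must be a data.frame with a sample_id column")
  if (anyDuplicated(samples$sample_id))
    validation_error("duplicate sample_id in samples")
  if (!is_scalar_number(dilution_factor) || dilution_factor < 1)
    usage_error("dilution_factor must be >= 1")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    usage_error("replicates must be >= 1")

  frac <- if ("persister_fraction" %in% names(samples))
    samples$persister_fraction else rep(kill$persister_fraction, nrow(samples))
  delay <- if ("awakening_delay_hours" %in% names(samples))
    samples$awakening_delay_hours else rep(kill$awakening_delay_hours, nrow(samples))
  if (any(!is.finite(frac)) || any(frac <= 0) || any(frac > 1))
    validation_error("persister fractions must be in (0, 1]")

  set.seed(params$seed)
  n_wells <- 2L * replicates * nrow(samples)
  wells <- well_names(n_wells)
  curves <- list(); map_rows <- list(); well_rows <- list()
  wi <- 0L
  for (s in seq_len(nrow(samples))) {
    sid <- as.character(samples$sample_id[s])
    arms <- list(
      normalizer = list(conc = params$n0 / dilution_factor, lag = params$lag_hours),
      treated = list(conc = params$n0 * frac[s] / dilution_factor,
                     lag = params$lag_hours + delay[s]))
    for (role in names(arms)) {
      for (r in seq_len(replicates)) {
        wi <- wi + 1L
        w <- wells[wi]
        realized <- realize_inoculum(arms[[role]]$conc)
        curves[[w]] <- simulate_well(params, realized, arms[[role]]$lag, w)$curve
        map_rows[[wi]] <- data.frame(
          well = w, sample_id = sid, role = role,
          replicate_group = paste(sid, role, sep = "."),
          stringsAsFactors = FALSE)
        well_rows[[wi]] <- data.frame(
          well = w, sample_id = sid, role = role,
          nominal_n0 = arms[[role]]$conc, realized_n0 = realized,
          sterile = realized == 0, stringsAsFactors = FALSE)
      }
    }
  }
  truth_samples <- data.frame(
    sample_id = as.character(samples$sample_id),
    persister_fraction = frac, awakening_delay_hours = delay,
    true_surviving_per_ml = params$n0 * frac, stringsAsFactors = FALSE)
  list(curves = curves,
       map = plate_map(do.call(rbind, map_rows)),
       truth = truth_samples,
       truth_wells = do.call(rbind, well_rows),
       params = params)
}

#' True log2 fold changes from simulator ground truth
#'
#' Converts the simulator's per-sample surviving fractions into the log2
#' fold change each sample should report against a chosen calibrator:
#' `log2(f_sample / f_calibrator)`.
#'
#' @param truth The `truth` data frame from [simulate_persister_assay()].
#' @param calibrator_id Reference sample.
#' @return Data frame `sample_id,log2_fold`.
#' @export
true_log2_fold <- function(truth, calibrator_id) {
  if (!calibrator_id %in% truth$sample_id)
    validation_error(sprintf("calibrator '%s' not in truth table", calibrator_id))
  f_cal <- truth$persister_fraction[truth$sample_id == calibrator_id]
  data.frame(sample_id = truth$sample_id,
             log2_fold = log2(truth$persister_fraction / f_cal),
             stringsAsFactors = FALSE)
}
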