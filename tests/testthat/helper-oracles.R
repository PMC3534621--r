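# Closed-form oracles and fixture builders, independent of the package's
# interpolation / simulation code paths.

# Time for an exponential culture (n0 cells/mL, doubling time td) to reach
# the cell density at which OD hits `threshold`: sgt = td * log2(N_thr / n0).
oracle_sgt <- function(n0, td, threshold = 0.15, od_per_cell = 5e-10,
                       od_background = 0) {
  n_thr <- (threshold - od_background) / od_per_cell
  td * log2(n_thr / n0)
}

# Noiseless exponential growth curve built directly from the closed form.
exp_curve <- function(n0, td, dt = 0.01, duration = 12,
                      od_per_cell = 5e-10, od_background = 0,
                      well_id = "A1") {
  t <- seq(0, duration, by = dt)
  growth_curve(well_id, t, od_background + od_per_cell * n0 * 2^(t / td))
}

# Noiseless, exponential-regime simulation parameters on a fine grid.
noiseless_params <- function(n0, td = 0.5, dt = 0.001, duration = 12, seed = 1,
                             carrying_capacity = 1e15, ...) {
  sim_params(n0 = n0, doubling_time_hours = td,
             carrying_capacity = carrying_capacity,
             od_per_cell = 5e-10, od_background = 0,
             noise_multiplicative_cv = 0, noise_additive_sd = 0,
             read_interval_hours = dt, duration_hours = duration, seed = seed,
             ...)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
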