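test_that("threshold crossing is linearly interpolated and censoring flagged", {
  cv <- growth_curve("A1", c(1, 2), c(0.10, 0.20))
  r <- compute_sgt(cv, threshold = 0.15, consecutive = 1)
  expect_equal(r$sgt_hours, 1.5)
  expect_true(r$interpolated)
  expect_false(r$censored)

  flat <- growth_curve("A2", seq(0, 5, 0.25), rep(0.05, 21))
  rc <- compute_sgt(flat, 0.15)
  expect_true(rc$censored)
  expect_equal(rc$sgt_hours, 5)        # lower bound = last observed time

  hot <- growth_curve("A3", c(0, 1, 2), c(0.2, 0.3, 0.4))
  rh <- compute_sgt(hot, 0.15)
  expect_equal(rh$sgt_hours, 0)
  expect_false(rh$interpolated)

  expect_error(compute_sgt(cv, threshold = -1), class = "sgt_usage_error")
  expect_error(compute_sgt(growth_curve("A4", c(0, 1), c(0.1, 0.1))[
    c("well_id", "times")], 0.15), class = "sgt_validation_error")
})

test_that("consecutive supra-threshold reads reject single-read spikes", {
  spiky <- growth_curve("A1", 0:4, c(0.10, 0.20, 0.10, 0.20, 0.25))
  r2 <- compute_sgt(spiky, 0.15, consecutive = 2)
  expect_equal(r2$sgt_hours, 2.5)      # run starting at t = 3, from od 0.10
  r1 <- compute_sgt(spiky, 0.15, consecutive = 1)
  expect_equal(r1$sgt_hours, 0.5)      # the spike counts when consecutive = 1
})

test_that("compute_sgt matches the closed-form exponential oracle", {
  for (n0 in c(1e2, 1e4, 1e6)) {
    for (td in c(0.3, 0.5, 1.2)) {
      cv <- exp_curve(n0, td, dt = 0.01, duration = 40)
      got <- compute_sgt(cv, 0.15)
      expect_false(got$censored)
      expect_lt(abs(got$sgt_hours - oracle_sgt(n0, td)), 1e-3)
    }
  }
})

test_that("SGT decreases monotonically with inoculum and obeys dilution shifts", {
  n0s <- 10^seq(3, 7, by = 0.5)
  sgts <- vapply(n0s, function(n0)
    compute_sgt(exp_curve(n0, 0.5, dt = 0.005, duration = 15), 0.15)$sgt_hours,
    numeric(1))
  expect_true(all(diff(sgts) < 0))
  # 1:2 dilution adds one doubling time; 1:10 adds td*log2(10)
  s1 <- compute_sgt(exp_curve(1e6, 0.5, dt = 0.001), 0.15)$sgt_hours
  s2 <- compute_sgt(exp_curve(5e5, 0.5, dt = 0.001), 0.15)$sgt_hours
  s10 <- compute_sgt(exp_curve(1e5, 0.5, dt = 0.001), 0.15)$sgt_hours
  expect_equal(s2 - s1, 0.5, tolerance = 1e-6)
  expect_equal(s10 - s1, 0.5 * log2(10), tolerance = 1e-6)
})

test_that("delta_sgt subtracts means and propagates sd in quadrature", {
  d <- delta_sgt(list(mean = 10, sd = 0.2, n = 3),
                 list(mean = 4, sd = 0.1, n = 3), "s1")
  expect_equal(d$value, 6)
  expect_equal(d$sd, sqrt(0.04 + 0.01))
  expect_equal(d$sd, 0.2236068, tolerance = 1e-6)

  same <- delta_sgt(list(mean = 4, sd = 0.1, n = 3),
                    list(mean = 4, sd = 0.1, n = 3), "s0")
  expect_equal(same$value, 0)

  cen <- delta_sgt(list(mean = NA_real_, sd = NA_real_, n = 0, censored = TRUE),
                   list(mean = 4, sd = 0.1, n = 3), "sc")
  expect_true(cen$censored)
  expect_true(is.na(cen$value))
})

test_that("delta_delta_sgt fold calculus matches 2^-ddsgt in both modes", {
  mk <- function(v, sd = 0, id = "x") {
    d <- delta_sgt(list(mean = v, sd = sd, n = 3),
                   list(mean = 0, sd = 0, n = 3), id)
    d
  }
  r0 <- delta_delta_sgt(mk(5), mk(5, id = "cal"))
  expect_identical(r0$fold, 1)
  expect_identical(r0$log2_fold, 0)

  r3 <- delta_delta_sgt(mk(8), mk(5, id = "cal"))
  expect_equal(r3$ddsgt, 3)
  expect_equal(r3$fold, 0.125)
  expect_equal(r3$log2_fold, -3)

  rd <- delta_delta_sgt(mk(4), mk(5, id = "cal"), mode = "doublings",
                        doubling_time_hours = 0.5)
  expect_equal(rd$ddsgt, -2)
  expect_equal(rd$fold, 4)

  expect_error(delta_delta_sgt(mk(4), mk(5), mode = "doublings"),
               class = "sgt_usage_error")
})

test_that("fold antisymmetry: swapping sample and calibrator inverts the fold", {
  set.seed(7)
  for (i in 1:25) {
    a <- delta_sgt(list(mean = runif(1, 0, 12), sd = runif(1, 0, 0.5), n = 3),
                   list(mean = runif(1, 0, 6), sd = runif(1, 0, 0.5), n = 3), "a")
    b <- delta_sgt(list(mean = runif(1, 0, 12), sd = runif(1, 0, 0.5), n = 3),
                   list(mean = runif(1, 0, 6), sd = runif(1, 0, 0.5), n = 3), "b")
    ab <- delta_delta_sgt(a, b)
    ba <- delta_delta_sgt(b, a)
    expect_equal(ab$ddsgt, -ba$ddsgt)
    expect_equal(ab$fold * ba$fold, 1, tolerance = 1e-12)
    expect_equal(ab$sd, ba$sd)
  }
})

test_that("censoring propagates to flagged, non-numeric ddsgt output", {
  cen <- delta_sgt(list(mean = NA_real_, sd = NA_real_, n = 0, censored = TRUE),
                   list(mean = 4, sd = 0.1, n = 3), "sc")
  ok <- delta_sgt(list(mean = 6, sd = 0.1, n = 3),
                  list(mean = 4, sd = 0.1, n = 3), "cal")
  for (r in list(delta_delta_sgt(cen, ok), delta_delta_sgt(ok, cen))) {
    expect_true(r$censored)
    expect_true(is.na(r$ddsgt))
    expect_true(is.na(r$fold))
  }
})

test_that("replicate aggregation uses sample sd and handles censoring honestly", {
  t <- c(0, 1)
  mk_res <- function(well, sgt, censored = FALSE) {
    structure(list(well_id = well, sgt_hours = sgt, threshold = 0.15,
                   censored = censored, interpolated = TRUE),
              class = "sgt_result")
  }
  map <- plate_map(data.frame(
    well = c("A1", "A2", "A3", "B1", "C1", "C2", "D1", "D2"),
    sample_id = c("s1", "s1", "s1", "s2", "s3", "s3", "s4", "s4"),
    role = "treated"))
  res <- list(mk_res("A1", 4.0), mk_res("A2", 4.2), mk_res("A3", 4.4),
              mk_res("B1", 5.0),
              mk_res("C1", 4.0), mk_res("C2", 6.0, censored = TRUE),
              mk_res("D1", 6.0, censored = TRUE),
              mk_res("D2", 7.0, censored = TRUE))
  expect_warning(agg <- aggregate_replicates(res, map), "censored")
  s1 <- agg[agg$sample_id == "s1", ]
  expect_equal(s1$mean_sgt, 4.2)
  expect_equal(s1$sd_sgt, 0.2)
  expect_equal(s1$n, 3L)
  expect_true(is.na(agg$sd_sgt[agg$sample_id == "s2"]))  # single replicate
  s3 <- agg[agg$sample_id == "s3", ]
  expect_equal(s3$mean_sgt, 4.0)
  expect_equal(s3$n_censored, 1L)
  s4 <- agg[agg$sample_id == "s4", ]
  expect_true(s4$censored)
  expect_true(is.na(s4$mean_sgt))
})

test_that("doubling time is recovered from the log-linear window", {
  cv <- exp_curve(1e6, 0.5, dt = 0.05, duration = 8)
  expect_equal(estimate_doubling_time(cv), 0.5, tolerance = 1e-6)
  dense <- exp_curve(1e6, 0.5, dt = 0.01, duration = 8)
  expect_equal(estimate_doubling_time(dense), 0.5, tolerance = 1e-6)
  flat <- growth_curve("F1", seq(0, 5, 0.25), rep(0.05, 21))
  expect_error(estimate_doubling_time(flat), class = "sgt_estimation_error")
})
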