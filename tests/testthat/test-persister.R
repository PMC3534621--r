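test_that("noiseless survival quantification matches the simulator ground truth", {
  p <- noiseless_params(1e9, td = 0.5, dt = 0.01, duration = 16)
  sim <- simulate_persister_assay(
    p, kill_params(1e-3),
    data.frame(sample_id = c("cal", "hi", "lo"),
               persister_fraction = c(1e-3, 8e-3, 1e-3 / 8)),
    dilution_factor = 100, replicates = 2)
  design <- assay_design(c("cal", "hi", "lo"), "cal", dilution_factor = 100,
                         mode = "doublings", doubling_time_hours = 0.5)
  tab <- quantify_survival(sim$curves, sim$map, design)
  truth <- true_log2_fold(sim$truth, "cal")

  cal_row <- tab[tab$sample_id == "cal", ]
  expect_identical(cal_row$log2_fold, 0)   # calibrator: exactly 0 by construction
  expect_identical(cal_row$fold, 1)
  expect_equal(tab$log2_fold[tab$sample_id == "hi"],
               truth$log2_fold[truth$sample_id == "hi"], tolerance = 1e-4)
  expect_equal(tab$log2_fold[tab$sample_id == "lo"], -3, tolerance = 1e-4)
  expect_equal(tab$fold[tab$sample_id == "lo"], 0.125, tolerance = 1e-4)
  expect_false(any(tab$censored))
})

test_that("a sample identical to the calibrator reports log2 fold 0", {
  p <- noiseless_params(1e8, td = 0.5, dt = 0.01, duration = 16)
  sim <- simulate_persister_assay(
    p, kill_params(1e-3),
    data.frame(sample_id = c("cal", "twin"), persister_fraction = c(1e-3, 1e-3)),
    dilution_factor = 100, replicates = 2)
  design <- assay_design(c("cal", "twin"), "cal", dilution_factor = 100)
  tab <- quantify_survival(sim$curves, sim$map, design)
  expect_equal(tab$log2_fold[tab$sample_id == "twin"], 0, tolerance = 1e-9)
})

test_that("sterile treated wells censor the sample instead of faking a number", {
  p <- noiseless_params(5e6, td = 0.5, dt = 0.05, duration = 16, seed = 77)
  sim <- suppressWarnings(simulate_persister_assay(
    p, kill_params(1e-9),
    data.frame(sample_id = c("cal", "dead"),
               persister_fraction = c(0.5, 1e-9)),
    dilution_factor = 500, replicates = 2))
  expect_true(all(sim$truth_wells$sterile[sim$truth_wells$sample_id == "dead" &
                                            sim$truth_wells$role == "treated"]))
  design <- assay_design(c("cal", "dead"), "cal", threshold = 0.15)
  tab <- suppressWarnings(quantify_survival(sim$curves, sim$map, design))
  dead <- tab[tab$sample_id == "dead", ]
  expect_true(dead$censored)
  expect_true(is.na(dead$log2_fold))
  cal <- tab[tab$sample_id == "cal", ]
  expect_false(cal$censored)
})

test_that("missing calibrator wells are a design error", {
  p <- noiseless_params(1e8, dt = 0.05, duration = 16)
  sim <- simulate_persister_assay(p, kill_params(1e-3),
                                  data.frame(sample_id = "s1"),
                                  dilution_factor = 100, replicates = 1)
  design <- assay_design(c("s1", "ghost"), "ghost", dilution_factor = 100)
  expect_error(quantify_survival(sim$curves, sim$map, design),
               "calibrator", class = "sgt_validation_error")
})

test_that("diverging treated-arm growth rate triggers an awakening-kinetics warning", {
  t <- seq(0, 12, 0.1)
  curves <- list(
    A1 = growth_curve("A1", t, 5e-10 * 1e6 * 2^(t / 0.5)),
    A2 = growth_curve("A2", t, 5e-10 * 1e7 * 2^(t / 1.2)))
  map <- plate_map(data.frame(well = c("A1", "A2"), sample_id = "s1",
                              role = c("normalizer", "treated")))
  design <- assay_design("s1", "s1", slope_warn_factor = 1.5)
  expect_warning(quantify_survival(curves, map, design),
                 "awakening")
})

test_that("SGT folds and ground-truth counts agree within replicate noise", {
  sim <- simulate_persister_assay(
    sim_params(n0 = 1e9, seed = 555),
    kill_params(1e-3),
    data.frame(sample_id = c("cal", "s2", "s3"),
               persister_fraction = c(1e-3, 4e-3, 5e-4)),
    dilution_factor = 500, replicates = 3)
  design <- assay_design(c("cal", "s2", "s3"), "cal", mode = "doublings",
                         doubling_time_hours = 0.5)
  tab <- quantify_survival(sim$curves, sim$map, design)
  cmp <- compare_with_counts(tab[, c("sample_id", "log2_fold")],
                             true_log2_fold(sim$truth, "cal"))
  expect_lt(cmp$mean_abs_difference, 0.5)
  expect_equal(nrow(cmp$per_sample), 3L)
  expect_true(is.na(cmp$p_value) || (cmp$p_value >= 0 && cmp$p_value <= 1))
})

test_that("count comparison handles identical tables and rejects mismatches", {
  tab <- data.frame(sample_id = c("a", "b"), log2_fold = c(1, -2))
  same <- compare_with_counts(tab, tab)
  expect_identical(same$mean_abs_difference, 0)
  expect_true(is.na(same$p_value))     # no variance in the differences
  expect_error(compare_with_counts(tab, tab[1, ]),
               class = "sgt_validation_error")
})

test_that("more replicates shrink the propagated sd of the log2 fold", {
  sd_at <- function(reps, seed) {
    sim <- simulate_persister_assay(
      sim_params(n0 = 1e9, seed = seed), kill_params(1e-3),
      data.frame(sample_id = c("cal", "s"), persister_fraction = c(1e-3, 8e-3)),
      dilution_factor = 500, replicates = reps)
    design <- assay_design(c("cal", "s"), "cal", mode = "doublings",
                           doubling_time_hours = 0.5)
    tab <- quantify_survival(sim$curves, sim$map, design)
    tab$sd[tab$sample_id == "s"]
  }
  seeds <- 900 + 1:12
  expect_lt(mean(vapply(seeds, function(s) sd_at(10L, s), numeric(1))),
            mean(vapply(seeds, function(s) sd_at(3L, s), numeric(1))))
})

test_that("plate capacity follows the floor formula", {
  expect_identical(plate_capacity(96, 3), 32L)
  expect_identical(plate_capacity(384, 3), 128L)
  expect_identical(plate_capacity(96, 3, 6), 30L)
  expect_identical(plate_capacity(96, 5), 19L)
  expect_error(plate_capacity(96, 0), class = "sgt_usage_error")
  expect_error(plate_capacity(96, 3, 96), class = "sgt_usage_error")
})
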