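test_that("closed-form cohort RM matches the numeric-integration oracle", {
  u <- c(0, 0.1, 0.25, 0.5, 0.8, 1)
  expect_equal(closed_form_rm(u), rm_integration_oracle(u), tolerance = 1e-9)
  expect_identical(closed_form_rm(0), 0.5)
  expect_identical(closed_form_rm(1), 1.0)
  expect_equal(closed_form_rm(0.5), 0.875)
  expect_error(closed_form_rm(1.2), "must lie in")
  expect_error(closed_form_rm(-0.1), "must lie in")
})

test_that("configuration validation rejects non-physical settings", {
  expect_error(sim_config(t_s = -1), "t_s")
  expect_error(sim_config(t_g1 = Inf), "t_g1")
  expect_error(sim_config(dapi_cv = -0.1), "dapi_cv")
  expect_error(sim_config(debris_fraction = 1.5), "debris_fraction")
  expect_error(sim_config(slow_factor = 0.5), "slow_factor")
  expect_error(sim_config(chase_times = c(1, 2)), "chase_times")
  expect_error(sim_config(chase_times = c(0, 2, 1)), "chase_times")
  # arrest encoding is legal
  expect_s3_class(sim_config(slow_factor = Inf), "sim_config")
})

test_that("identical seed and config reproduce the time course bitwise", {
  cfg <- sim_config(n_cells = 2000L, chase_times = 0:3, seed = 99L)
  tc1 <- simulate_time_course(cfg)
  tc2 <- simulate_time_course(cfg)
  expect_identical(tc1, tc2)
})

test_that("event counts are conserved without division and grow with it", {
  cfg <- sim_config(n_cells = 5000L, chase_times = 0:4,
                    debris_fraction = 0.1, divide_labeled = FALSE,
                    noncycling_fraction = 0.3, seed = 5L)
  tc <- simulate_time_course(cfg)
  expected <- 5000L + round(5000 * 0.1 / 0.9)
  for (et in tc$entries) expect_equal(nrow(et), expected)

  cfg2 <- sim_config(n_cells = 5000L, chase_times = 0:6,
                     debris_fraction = 0, divide_labeled = TRUE,
                     daughter_cycling = 1, seed = 5L)
  counts <- vapply(simulate_time_course(cfg2)$entries, nrow, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])
})

test_that("noise-free DNA values lie exactly between 2C and 4C gain-scaled", {
  cfg <- ideal_config(n_cells = 20000, chase_times = c(0, 1, 3), seed = 3L)
  tc <- simulate_time_course(cfg)
  for (et in tc$entries) {
    expect_true(all(et$dapi >= 2 * cfg$dapi_gain - 1e-9))
    expect_true(all(et$dapi <= 4 * cfg$dapi_gain + 1e-9))
  }
})

test_that("ideal labeled cohort is uniform on (2C, 4C) at pulse end", {
  cfg <- ideal_config(n_cells = 1e5, chase_times = 0, seed = 21L)
  et <- simulate_time_course(cfg)$entries[[1]]
  lab <- et$dapi[et$label > 0]
  # scaled positions should be U(0, 1)
  f <- (lab / cfg$dapi_gain - 2) / 2
  expect_gt(stats::ks.test(f, "punif")$p.value, 1e-3)
  expect_equal(mean(f), 0.5, tolerance = 3 * 0.2887 / sqrt(length(f)))
})

test_that("undivided labeled nuclei sit at exactly 4C once the chase passes t_s", {
  cfg <- ideal_config(t_s = 2, chase_times = c(0, 2.5), n_cells = 5000,
                      seed = 8L)
  tc <- simulate_time_course(cfg)
  et <- tc$entries[[2]]
  lab <- et$dapi[et$label > 0]
  expect_gt(length(lab), 0)
  expect_true(all(abs(lab - 4 * cfg$dapi_gain) < 1e-9))
})

test_that("empirical cohort RM follows the closed form within Monte-Carlo error", {
  t_s <- 2.7
  times <- c(0, 0.675, 1.35, 2.025, 2.7)
  cfg <- ideal_config(t_s = t_s, chase_times = times, n_cells = 1e5,
                      seed = 42L)
  tc <- simulate_time_course(cfg)
  rms <- ideal_rm_trajectory(tc)
  n_lab <- sum(tc$entries[[1]]$label > 0)
  mc_se <- 0.2887 / sqrt(n_lab) / 2  # sd of U(0,1) / sqrt(n), DNA spans 2C
  for (i in seq_along(times)) {
    theory <- closed_form_rm(times[i] / t_s)
    expect_lt(abs(rms[i] - theory), 3 * max(mc_se, 1e-4) + 1e-12)
  }
})

test_that("residual labeling forms an arm 10-100x below the pulse cohort", {
  for (rate in c(0.01, 0.1)) {
    cfg <- sim_config(n_cells = 30000L, chase_times = c(0, 2),
                      residual_rate = rate, debris_fraction = 0,
                      seed = 31L)
    tc <- simulate_time_course(cfg)
    g <- auto_gates(tc$entries[[1]])
    et <- tc$entries[[2]]
    cohort <- et$label >= g$full_label_threshold
    arm <- et$label > g$label_threshold & !cohort
    expect_gt(sum(arm), 20)
    ratio <- stats::median(et$label[cohort]) / stats::median(et$label[arm])
    expect_gt(ratio, 10)
    expect_lt(ratio, 100)
  }
})

test_that("arrested cells freeze at their replicated fraction", {
  cfg <- ideal_config(chase_times = c(0, 5), n_cells = 20000, seed = 13L,
                      slow_fraction = 0.5, slow_factor = Inf)
  tc <- simulate_time_course(cfg)
  et <- tc$entries[[2]]
  lab <- et$dapi[et$label > 0]
  # roughly half the cohort should still sit strictly between 2C and 4C
  frac_mid <- mean(lab > 2 * cfg$dapi_gain + 1e-9 &
                   lab < 4 * cfg$dapi_gain - 1e-9)
  expect_gt(frac_mid, 0.4)
  expect_lt(frac_mid, 0.6)
})

test_that("a time course round-trips through CSV files and a manifest", {
  cfg <- sim_config(n_cells = 800L, n_replicates = 2L, chase_times = 0:2,
                    seed = 17L)
  tc <- simulate_time_course(cfg)
  dir <- withr::local_tempdir()
  mpath <- write_time_course(tc, dir, manifest_format = "yaml")
  tc2 <- load_manifest(mpath)
  expect_identical(length(tc2$entries), length(tc$entries))
  expect_equal(tc2$samples$time_h, tc$samples$time_h)
  for (i in seq_along(tc$entries)) {
    expect_equal(tc2$entries[[i]]$dapi, tc$entries[[i]]$dapi,
                 tolerance = 1e-6)
    expect_equal(tc2$entries[[i]]$label, tc$entries[[i]]$label,
                 tolerance = 1e-6)
  }
})
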