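test_that("automatic gates find 2C and 4C modes at the expected ratio", {
  cfg <- sim_config(n_cells = 20000L, chase_times = 0, seed = 2L)
  et <- simulate_time_course(cfg)$entries[[1]]
  g <- auto_gates(et)
  expect_gt(g$g2m_mode / g$g1_mode, 1.95)
  expect_lt(g$g2m_mode / g$g1_mode, 2.05)
  expect_lt(g$g1_box[2], g$g2m_box[1])
  expect_gte(g$full_label_threshold, g$label_threshold)
})

test_that("gating fails informatively on degenerate DNA distributions", {
  set.seed(4)
  # single G1 peak only
  et1 <- event_table(dapi = rnorm(5000, 200, 8),
                     label = rnorm(5000, 10, 1))
  expect_error(auto_gates(et1), "fewer than two")
  # two peaks at a non-2x ratio
  et2 <- event_table(dapi = c(rnorm(5000, 200, 8), rnorm(5000, 520, 20)),
                     label = rnorm(10000, 10, 1))
  expect_error(auto_gates(et2), "ratio")
})

test_that("noise-free peaks are captured completely by zero-width boxes", {
  cfg <- ideal_config(n_cells = 30000, chase_times = 0, seed = 6L)
  et <- simulate_time_course(cfg)$entries[[1]]
  g <- auto_gates(et)
  unl <- et$label <= g$label_threshold
  g1 <- unl & abs(et$dapi - 2 * cfg$dapi_gain) < 1e-9
  g2m <- unl & abs(et$dapi - 4 * cfg$dapi_gain) < 1e-9
  st <- gated_stats(et, g, is_t0 = TRUE)
  expect_identical(st$n_g1, sum(g1))
  expect_identical(st$n_g2m, sum(g2m))
})

test_that("population means of point-mass clusters are exact", {
  et <- event_table(dapi = c(2, 3, 4), label = c(0, 100, 0),
                    time_h = 0)
  st <- gated_stats(et, manual_gates(), is_t0 = TRUE)
  expect_identical(st$f_g1, 2)
  expect_identical(st$f_l, 3)
  expect_identical(st$f_g2m, 4)
})

test_that("returned 2C nuclei are excluded from the cohort after 0 h", {
  et <- event_table(dapi = c(2, 2, 4, 4, 2, 4),
                    label = c(0, 0, 0, 0, 100, 100), time_h = 2)
  st <- gated_stats(et, manual_gates(), is_t0 = FALSE)
  expect_identical(st$f_l, 4)          # the labeled 2C event is excluded
  expect_identical(st$n_labeled, 1L)
  st0 <- gated_stats(et, manual_gates(), is_t0 = TRUE)
  expect_identical(st0$f_l, 3)         # at 0 h both labeled events count
})

test_that("residually labeled events below the arm threshold are excluded", {
  g <- manual_gates(label_threshold = 5, full_label_threshold = 50)
  et <- event_table(dapi = c(2, 4, 3.5, 3.0),
                    label = c(0, 0, 49, 100), time_h = 1)
  st <- gated_stats(et, g, is_t0 = FALSE)
  expect_identical(st$f_l, 3.0)
  expect_identical(st$n_labeled, 1L)
})

test_that("gate assignment partitions events", {
  cfg <- sim_config(n_cells = 10000L, chase_times = c(0, 3), seed = 12L)
  tc <- simulate_time_course(cfg)
  g <- auto_gates(tc$entries[[1]])
  for (et in tc$entries) {
    is_t0 <- event_meta(et)$time_h == 0
    keep <- et$dapi >= g$debris_floor
    unl <- et$label <= g$label_threshold & keep
    in_g1 <- unl & et$dapi >= g$g1_box[1] & et$dapi <= g$g1_box[2]
    in_g2m <- unl & et$dapi >= g$g2m_box[1] & et$dapi <= g$g2m_box[2]
    lower <- if (is_t0) g$g1_box[1] else g$g1_box[2]
    coh <- keep & et$label > g$label_threshold &
      et$label >= g$full_label_threshold &
      et$dapi >= lower & et$dapi <= g$g2m_box[2]
    expect_identical(sum(in_g1 & in_g2m), 0L)
    expect_identical(sum(in_g1 & coh), 0L)
    expect_identical(sum(in_g2m & coh), 0L)
    st <- gated_stats(et, g, is_t0 = is_t0)
    expect_identical(st$n_g1 + st$n_g2m + st$n_labeled,
                     sum(in_g1) + sum(in_g2m) + sum(coh))
  }
})

test_that("all gate means scale linearly with DNA-stain gain and RM is invariant", {
  cfg <- sim_config(n_cells = 8000L, chase_times = c(0, 2), seed = 9L)
  tc <- simulate_time_course(cfg)
  g <- auto_gates(tc$entries[[1]])
  et <- tc$entries[[2]]
  st <- gated_stats(et, g, is_t0 = FALSE)
  for (c_gain in c(0.37, 5.1)) {
    et2 <- event_table(dapi = et$dapi * c_gain, label = et$label,
                       time_h = event_meta(et)$time_h)
    g2 <- g
    g2$g1_box <- g$g1_box * c_gain
    g2$g2m_box <- g$g2m_box * c_gain
    g2$debris_floor <- g$debris_floor * c_gain
    st2 <- gated_stats(et2, g2, is_t0 = FALSE)
    expect_equal(st2$f_g1, st$f_g1 * c_gain, tolerance = 1e-12)
    expect_equal(st2$f_g2m, st$f_g2m * c_gain, tolerance = 1e-12)
    expect_equal(st2$f_l, st$f_l * c_gain, tolerance = 1e-12)
    expect_equal(relative_movement(st2), relative_movement(st),
                 tolerance = 1e-12)
  }
})

test_that("gate sets survive JSON serialization", {
  cfg <- sim_config(n_cells = 5000L, chase_times = 0, seed = 2L)
  g <- auto_gates(simulate_time_course(cfg)$entries[[1]])
  path <- withr::local_tempfile(fileext = ".json")
  write_gates(g, path)
  g2 <- read_gates(path)
  expect_equal(g2$g1_box, g$g1_box)
  expect_equal(g2$full_label_threshold, g$full_label_threshold)
})
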