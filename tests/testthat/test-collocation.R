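test_that("cost is zero for identical sets and at the exact restoring shift", {
  m <- make_spiral_measurement()
  expect_equal(collocation_cost(m, m, axis_shift(0, 0)), 0, tolerance = 1e-12)

  pair <- noise_free_pair(0.37, -0.22, seed = 3)
  expect_lt(collocation_cost(pair$moving, pair$reference,
                             axis_shift(0.37, -0.22)), 1e-9)
})

test_that("cost errors are classed: pairing, zero variance", {
  m <- make_spiral_measurement()
  short <- electrode_measurement("A1", "m", c(1L, 2L, 4L), c(2, 2.1, 2.2),
                                 c(20, 60, 100))
  expect_error(collocation_cost(m, short, axis_shift(0, 0)),
               class = "cochloc_pairing_error")
  const <- electrode_measurement("A1", "m", m$electrode,
                                 rep(2, 12), m$adoi)
  expect_error(collocation_cost(m, const, axis_shift(0, 0)),
               class = "cochloc_undefined_correlation")
})

test_that("cost stays within [0, 4] over a probed shift grid", {
  pair <- noisy_pair(0.3, 0.1, seed = 9)
  for (sx in seq(-1.5, 1.5, by = 0.5)) {
    for (sy in seq(-1.5, 1.5, by = 0.5)) {
      cost <- collocation_cost(pair$moving, pair$reference,
                               axis_shift(sx, sy))
      expect_gte(cost, 0)
      expect_lte(cost, 4)
    }
  }
})

test_that("the true restoring shift beats every probed shift 0.2 mm away", {
  pair <- noise_free_pair(0.25, 0.15, seed = 4)
  c_true <- collocation_cost(pair$moving, pair$reference,
                             axis_shift(0.25, 0.15))
  set.seed(21)
  for (i in 1:25) {
    ang <- runif(1, 0, 2 * pi)
    d <- runif(1, 0.2, 1.5)
    probe <- axis_shift(0.25 + d * cos(ang), 0.15 + d * sin(ang))
    expect_gt(collocation_cost(pair$moving, pair$reference, probe), c_true)
  }
})

test_that("optimizer recovers the axis displacement on noise-free pairs", {
  m <- make_spiral_measurement()
  est0 <- optimize_shift(m, m)
  expect_lt(abs(est0$shift$shift_x), 1e-3)
  expect_lt(abs(est0$shift$shift_y), 1e-3)
  expect_lt(est0$cost, 1e-8)

  pair <- noise_free_pair(0.4, -0.3, seed = 2)
  est <- optimize_shift(pair$moving, pair$reference)
  expect_lt(abs(est$shift$shift_x - 0.4), 0.01)
  expect_lt(abs(est$shift$shift_y - (-0.3)), 0.01)
  expect_true(est$converged)
  # reported cost is recomputed at the returned shift
  expect_equal(est$cost,
               collocation_cost(pair$moving, pair$reference, est$shift),
               tolerance = 1e-12)
  # never worse than no alteration at all
  expect_lte(est$cost,
             collocation_cost(pair$moving, pair$reference, axis_shift(0, 0)))
})

test_that("swapping moving and reference sets negates the recovered shift", {
  pair <- noise_free_pair(0.3, 0.2, seed = 6)
  est <- optimize_shift(pair$moving, pair$reference)
  back <- optimize_shift(pair$reference, pair$moving)
  expect_lt(abs(back$shift$shift_x - (-est$shift$shift_x)), 0.01)
  expect_lt(abs(back$shift$shift_y - (-est$shift$shift_y)), 0.01)
  # and once collocated, the remaining shift is null
  shifted <- to_polar(apply_shift(to_cartesian(pair$moving), est$shift),
                      method_label = "auto_collocated")
  residual <- optimize_shift(pair$reference, shifted)
  expect_lt(abs(residual$shift$shift_x), 0.01)
  expect_lt(abs(residual$shift$shift_y), 0.01)
})

test_that("grid search finds the origin for identical sets and the true node otherwise", {
  m <- make_spiral_measurement()
  g <- grid_search_shift(m, m, search_bound = 1, grid_step = 0.1)
  expect_equal(c(g$shift$shift_x, g$shift$shift_y), c(0, 0))
  expect_equal(g$n_evaluations, 21L^2)

  pair <- noise_free_pair(0.4, -0.3, seed = 2)
  g2 <- grid_search_shift(pair$moving, pair$reference, search_bound = 1,
                          grid_step = 0.05)
  expect_lt(abs(g2$shift$shift_x - 0.4), 0.05 / 2 + 1e-9)
  expect_lt(abs(g2$shift$shift_y - (-0.3)), 0.05 / 2 + 1e-9)
})

test_that("the continuous optimum is at least as good as any grid node", {
  set.seed(13)
  for (i in 1:5) {
    pair <- noisy_pair(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4),
                       seed = 100 + i)
    g <- grid_search_shift(pair$moving, pair$reference, search_bound = 0.8,
                           grid_step = 0.1)
    o <- optimize_shift(pair$moving, pair$reference, search_bound = 0.8)
    expect_gte(g$cost, o$cost - 1e-10)
  }
})

test_that("collocation cancels a pure axis offset to numerical precision", {
  pair <- noise_free_pair(0.35, -0.18, seed = 8)
  pre_emd <- pair$moving$emd - pair$reference$emd
  pre_adoi <- pair$moving$adoi - pair$reference$adoi
  est <- optimize_shift(pair$moving, pair$reference, tolerance = 1e-8)
  shifted <- to_polar(apply_shift(to_cartesian(pair$moving), est$shift),
                      method_label = "auto")
  post_emd <- shifted$emd - pair$reference$emd
  post_adoi <- shifted$adoi - pair$reference$adoi
  expect_lt(max(abs(post_emd)), 1e-6 * max(abs(pre_emd)))
  expect_lt(max(abs(post_adoi)), 1e-6 * max(abs(pre_adoi)))
})

test_that("cohort collocation returns one shift per array plus shifted tables", {
  cfg <- spiral_cohort_config(n_arrays = 4, seed = 17)
  coh <- generate_cohort(cfg)
  auto <- coh$measurements[coh$measurements$method == "auto", ]
  manual <- coh$measurements[coh$measurements$method == "manual_rater1", ]
  col <- collocate_cohort(auto, manual)
  expect_equal(nrow(col$shifts), 4)
  expect_true(all(col$shifts$converged))
  expect_equal(nrow(col$collocated), nrow(auto))
  path <- withr::local_tempfile(fileext = ".json")
  write_shifts_json(col$shifts, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$shift_x_mm, col$shifts$shift_x_mm, tolerance = 1e-12)
})
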