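test_that("expected season totals follow the exponential link", {
  bci <- bci_defaults()
  modelI <- list(c1 = bci$c1, c2 = bci$c2)
  lam <- expected_season_total(1000, 0, 0, modelI)
  expect_equal(lam, exp(-0.12 + 1.5), tolerance = 1e-12)  # ~3.975
  # exponential additivity: adding ln 2 to u doubles the expectation
  expect_equal(expected_season_total(1000, log(2), 0, modelI), 2 * lam)
  expect_true(expected_season_total(250, -3, -2, modelI) > 0)
})

test_that("the seasonal curve has the Gaussian peak height and unit mass", {
  bci <- bci_defaults()
  lam <- 10
  peak <- 209.3
  at_peak <- expected_fruit_intensity(peak, lam, peak, bci$sigma_resid)
  expect_equal(at_peak, lam / (bci$sigma_resid * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(at_peak / lam, 0.020333, tolerance = 1e-4)
  # symmetry about the peak
  expect_equal(expected_fruit_intensity(peak + 11, lam, peak, 19.62),
               expected_fruit_intensity(peak - 11, lam, peak, 19.62))
  # daily midpoint sums recover the season total
  t_mid <- seq(0.5, 365, by = 1)
  daily <- expected_fruit_intensity(t_mid, lam, peak, bci$sigma_resid)
  expect_rel_equal(sum(daily), lam, 1e-3)
})

test_that("random-effect vectors have the nominal spread and reproduce", {
  set.seed(71)
  mI <- list(sd_u = 0.49, sd_v = 0.87)
  mII <- list(sd_w = 13.31, sd_z = 8.51)
  eff <- draw_random_effects(1e5, 1e5, mI, mII)
  expect_rel_equal(sd(eff$u), 0.49, 0.02)
  expect_rel_equal(sd(eff$v), 0.87, 0.02)
  expect_rel_equal(sd(eff$w), 13.31, 0.02)
  expect_rel_equal(sd(eff$z), 8.51, 0.02)
  zero <- draw_random_effects(10, 5, list(sd_u = 0, sd_v = 0.5), mII)
  expect_true(all(zero$u == 0))
  set.seed(9); a <- draw_random_effects(5, 5, mI, mII)
  set.seed(9); b <- draw_random_effects(5, 5, mI, mII)
  expect_identical(a, b)
})

test_that("simulated forests draw positions and diameters from the fits", {
  set.seed(72)
  w <- rectangle_window(0, 1000, 0, 1000)
  dbh_fit <- fit_dbh_distribution(synthetic_dbh_sample(500))
  flat <- density_surface(0, 0, 50, matrix(3e-4, 20, 20),
                          matrix(TRUE, 20, 20), w)
  counts <- replicate(200, nrow(simulate_forest(w, flat, dbh_fit)))
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 200))
  f <- simulate_forest(w, flat, dbh_fit)
  expect_true(all(f$dbh >= dbh_fit$min_ref * 0.9))
  expect_true(all(f$dbh <= dbh_fit$max_ref * 1.1))
  expect_true(all(points_in_window(w, f$x, f$y)))
  # zero intensity: empty forest
  zero <- density_surface(0, 0, 50, matrix(0, 20, 20),
                          matrix(TRUE, 20, 20), w)
  expect_equal(nrow(simulate_forest(w, zero, dbh_fit)), 0)
})

test_that("landscapes are deterministic given effects, and season-invariant without season effects", {
  set.seed(73)
  forest <- tibble::tibble(tree_id = paste0("t", 1:4),
                           x = runif(4, 0, 100), y = runif(4, 0, 100),
                           dbh = c(600, 800, 1000, 1400))
  mI <- list(c1 = -0.12, c2 = 1.5e-3, sd_u = 0.49, sd_v = 0)
  mII <- list(c3 = 209.3, sd_w = 13.31, sd_z = 0, sigma_resid = 19.62)
  land <- simulate_landscape(forest, mI, mII, s = 3)
  # no season effects: each tree's expected curve identical across seasons
  wide <- tidyr::pivot_wider(land$table, names_from = "season",
                             values_from = "expected")
  expect_equal(wide$`1`, wide$`2`)
  expect_equal(wide$`1`, wide$`3`)
  # rerun with the same effects is bit-identical
  land2 <- simulate_landscape(forest, mI, mII, s = 3,
                              effects = land$effects)
  expect_identical(land$table, land2$table)
})

test_that("realized totals are Poisson around the expected totals", {
  set.seed(74)
  forest <- tibble::tibble(tree_id = sprintf("t%03d", 1:80),
                           x = runif(80, 0, 500), y = runif(80, 0, 500),
                           dbh = runif(80, 500, 1500))
  bci <- bci_defaults()
  mI <- list(c1 = bci$c1, c2 = bci$c2, sd_u = bci$sd_u, sd_v = bci$sd_v)
  mII <- list(c3 = bci$c3, sd_w = bci$sd_w, sd_z = bci$sd_z,
              sigma_resid = bci$sigma_resid)
  land <- simulate_landscape(forest, mI, mII, s = 6, realize = TRUE)
  tot_expected <- sum(land$table$expected) * land$time_step
  tot_realized <- sum(land$table$realized)
  expect_lt(abs(tot_realized - tot_expected), 3 * sqrt(tot_expected))
  # seasonal peak lands near the intercept (late January)
  by_day <- land$table |>
    dplyr::group_by(day) |>
    dplyr::summarise(expected = sum(expected), .groups = "drop")
  peak_day <- by_day$day[which.max(by_day$expected)]
  expect_gt(peak_day, 209.3 - 3 * bci$sd_z)
  expect_lt(peak_day, 209.3 + 3 * bci$sd_z)
})
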