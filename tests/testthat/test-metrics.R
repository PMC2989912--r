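test_that("season metrics match hand-computed values", {
  met <- compute_season_metrics(fix_trap_records(), complete = FALSE)
  a <- met[met$tree_id == "a" & met$season_id == "s1", ]
  expect_equal(a$production, 3)
  expect_equal(a$peak, 210)          # mean of 200, 210, 220
  expect_equal(a$duration, 40)       # 4 * sd({200,210,220}) = 4 * 10
  b <- met[met$tree_id == "b" & met$season_id == "s1", ]
  expect_equal(b$production, 4)
  expect_equal(b$peak, 210)
  expect_equal(b$duration, 4 * sqrt(400 / 3))  # weighted, n-1 over 4 fruits
  c1 <- met[met$tree_id == "c", ]
  expect_equal(c1$production, 1)
  expect_equal(c1$peak, 150)
  expect_true(is.na(c1$duration))    # single fruit: duration undefined
})

test_that("completion adds zero-production tree-seasons", {
  met <- compute_season_metrics(fix_trap_records())
  expect_equal(nrow(met), 6)         # 3 trees x 2 seasons
  zero <- met[met$tree_id == "a" & met$season_id == "s2", ]
  expect_equal(zero$production, 0)
  expect_true(is.na(zero$peak))
})

test_that("metrics are equivariant under day shifts and scalings", {
  rec <- fix_trap_records()
  met <- compute_season_metrics(rec, complete = FALSE)
  shifted <- rec; shifted$day <- shifted$day + 30
  met_s <- compute_season_metrics(shifted, complete = FALSE)
  expect_equal(met_s$peak, met$peak + 30)
  expect_equal(met_s$duration, met$duration)
  expect_equal(met_s$production, met$production)
  scaled <- rec; scaled$day <- scaled$day * 1.5
  met_c <- compute_season_metrics(scaled, complete = FALSE)
  expect_equal(met_c$duration, met$duration * 1.5)
})

test_that("descriptive models recover generating variance components", {
  set.seed(51)
  n <- 200; s <- 60
  tree <- rnorm(n, 0, 15.49); season <- rnorm(s, 0, 5.04)
  grid <- tidyr::expand_grid(i = seq_len(n), j = seq_len(s))
  met <- tibble::tibble(
    tree_id = sprintf("t%03d", grid$i),
    season_id = sprintf("s%02d", grid$j),
    production = 5L,
    peak = 209.3 + tree[grid$i] + season[grid$j] + rnorm(nrow(grid), 0, 8),
    duration = NA_real_
  )
  fit <- fit_descriptive_lmm(met, "peak")
  expect_rel_equal(fit$intercept, 209.3, 0.05)
  expect_rel_equal(fit$sd_tree, 15.49, 0.15)
  expect_rel_equal(fit$sd_season, 5.04, 0.15)
  expect_rel_equal(fit$sd_resid, 8, 0.15)

  # permuting tree labels within season destroys the tree component
  perm <- met |>
    dplyr::group_by(season_id) |>
    dplyr::mutate(tree_id = sample(tree_id)) |>
    dplyr::ungroup()
  fit_p <- fit_descriptive_lmm(perm, "peak")
  expect_lt(fit_p$sd_tree, 0.25 * fit$sd_tree)
})

test_that("zero-variance data collapse to the grand value", {
  grid <- tidyr::expand_grid(i = 1:5, j = 1:5)
  met <- tibble::tibble(tree_id = paste0("t", grid$i),
                        season_id = paste0("s", grid$j),
                        production = 2L, peak = 123.4,
                        duration = NA_real_)
  fit <- suppressMessages(fit_descriptive_lmm(met, "peak"))
  expect_equal(fit$intercept, 123.4, tolerance = 1e-6)
  expect_lt(fit$sd_tree, 1e-6)
  expect_lt(fit$sd_season, 1e-6)
})
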