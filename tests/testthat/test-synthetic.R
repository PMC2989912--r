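test_that("synthetic censuses pass the reader validation untouched", {
  set.seed(81)
  dir <- withr::local_tempdir()
  w <- rectangle_window(0, 1200, 0, 900)
  cen <- generate_census(synthetic_truth(), w, cell = 50)
  path <- file.path(dir, "census.csv")
  write_tree_table(cen$trees, path)
  back <- read_tree_table(path, w, source = "simulated")
  expect_equal(nrow(back), nrow(cen$trees))
  expect_true(all(points_in_window(w, back$x, back$y)))
})

test_that("census counts track the generating intensity integral", {
  set.seed(82)
  w <- rectangle_window(0, 1200, 0, 900)
  truth <- synthetic_truth()
  counts <- purrr::map_dbl(1:25, function(i) {
    cen <- generate_census(truth, w, cell = 60)
    nrow(cen$trees) / surface_integral(cen$intensity)
  })
  # each count is Poisson(integral); the ratio should centre on 1
  expect_gt(mean(counts), 0.9)
  expect_lt(mean(counts), 1.1)
})

test_that("larger trees are detected more often in synthetic censuses", {
  set.seed(83)
  w <- rectangle_window(0, 2500, 0, 1500)
  cen <- generate_census(synthetic_truth(beta1 = 0.004), w, cell = 50)
  trees <- cen$trees
  expect_gt(mean(trees$dbh[trees$visible_aerial]),
            mean(trees$dbh[!trees$visible_aerial]))
})

test_that("trap data carry the designed overdispersion and phenology", {
  set.seed(84)
  truth <- synthetic_truth()
  # the study design: 6 trees, 22 seasons, trap-count scale
  trap <- generate_trap_data(truth, 6, 22, fruits_scale = 1)
  met <- compute_season_metrics(trap$phenology)
  totals <- met$production
  expect_gt(var(totals) / mean(totals), 1)  # lognormal mixing overdisperses
  # per-fruit days centre near the intercept
  days <- rep(trap$phenology$day, trap$phenology$count)
  expect_lt(abs(mean(days) - truth$c3),
            3 * sqrt(truth$sd_w^2 + truth$sd_z^2) / sqrt(6))
})

test_that("no random effects means one shared seasonal shape", {
  set.seed(85)
  truth <- synthetic_truth(sd_u = 0, sd_v = 0, sd_w = 0, sd_z = 0)
  trap <- generate_trap_data(truth, 5, 5, fruits_scale = 20)
  days <- rep(trap$phenology$day, trap$phenology$count)
  expect_lt(abs(mean(days) - truth$c3), 2)
  expect_lt(abs(sd(days) - truth$sigma_resid), 1.5)
})

test_that("truth parameter sets serialize and validate", {
  dir <- withr::local_tempdir()
  truth <- synthetic_truth(alpha = -8.5, sd_z = 4)
  p <- file.path(dir, "truth.json")
  write_truth(truth, p)
  back <- read_truth(p)
  expect_equal(unclass(back), unclass(truth))
  expect_error(synthetic_truth(sd_u = -1), "non-negative")
  expect_error(synthetic_truth(nope = 1), "unknown truth field")
})
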