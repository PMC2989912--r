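test_that("the production model reduces to plain Poisson regression when variances vanish", {
  set.seed(61)
  n <- 40; s <- 12
  dbh <- runif(n, 500, 1500)
  grid <- tidyr::expand_grid(i = seq_len(n), j = seq_len(s))
  mu <- exp(-0.12 + 1.5e-3 * dbh[grid$i])          # no random effects
  totals <- tibble::tibble(tree_id = sprintf("t%02d", grid$i),
                           season_id = sprintf("s%02d", grid$j),
                           production = rpois(nrow(grid), mu))
  fit <- suppressWarnings(
    fit_model_I(totals, tibble::tibble(tree_id = sprintf("t%02d", 1:n),
                                       dbh = dbh)))
  expect_lt(fit$sd_u, 0.05)
  expect_lt(fit$sd_v, 0.05)
  # fixed-effects oracle: ordinary Poisson GLM on the same data
  oracle <- glm(production ~ dbh, family = poisson(),
                data = dplyr::mutate(totals, dbh = dbh[grid$i]))
  expect_lt(abs(fit$c1 - unname(coef(oracle)[1])), 1e-3)
  expect_lt(abs(fit$c2 - unname(coef(oracle)[2])), 1e-3)
})

test_that("the production model validates its inputs", {
  totals <- tibble::tibble(tree_id = rep(paste0("t", 1:3), each = 3),
                           season_id = rep(paste0("s", 1:3), 3),
                           production = 0L)
  dbh <- tibble::tibble(tree_id = paste0("t", 1:3), dbh = c(500, 800, 1200))
  expect_error(fit_model_I(totals, dbh), "all totals are zero")
  bad <- totals; bad$production <- c(1.5, rep(1, 8))
  expect_error(fit_model_I(bad, dbh), "non-negative integers")
  neg <- totals; neg$production <- c(-1L, rep(1L, 8))
  expect_error(fit_model_I(neg, dbh), "non-negative integers")
})

test_that("the fruit-date model reduces to mean and SD without random effects", {
  set.seed(62)
  grid <- tidyr::expand_grid(i = 1:20, j = 1:10, k = 1:5)
  days <- rnorm(nrow(grid), 209.3, 19.62)
  fruit <- tibble::tibble(tree_id = paste0("t", grid$i),
                          season_id = paste0("s", grid$j),
                          day = days)
  fit <- suppressMessages(fit_model_II(fruit))
  expect_lt(fit$sd_w, 1.5)
  expect_lt(fit$sd_z, 1.5)
  # with variance components at ~0, REML collapses to the sample moments
  expect_equal(fit$c3, mean(days), tolerance = 0.05)
  expect_equal(fit$sigma_resid, sd(days), tolerance = 0.05)
})

test_that("weekly binning perturbs the residual SD less than the bin SD", {
  set.seed(63)
  truth <- synthetic_truth()
  trap <- generate_trap_data(truth, 40, 15, fruits_scale = 3)
  trap_w <- generate_trap_data(truth, 40, 15, fruits_scale = 3,
                               weekly = TRUE)
  m <- fit_model_II(trap$phenology)
  mw <- fit_model_II(trap_w$phenology)
  bin_sd <- sqrt(7^2 / 12)  # ~2.02 days
  expect_lt(abs(mw$sigma_resid - m$sigma_resid), bin_sd)
})

test_that("unidentifiable fruit-date designs error or warn", {
  one_cell <- tibble::tibble(tree_id = "t1", season_id = "s1",
                             day = c(100, 120, 140))
  expect_error(fit_model_II(one_cell), "unidentifiable")
  expect_error(fit_model_II(one_cell[1, ]), "at least 2 fruits")
  sparse <- tibble::tibble(tree_id = c("t1", "t2", "t1", "t2"),
                           season_id = c("s1", "s1", "s2", "s2"),
                           day = c(100, 150, 200, 250))
  expect_warning(fit_model_II(sparse), "not separately identified")
})

test_that("recovery bias shrinks as the design grows", {
  set.seed(64)
  truth <- synthetic_truth()
  err <- purrr::map_dbl(list(c(25, 8), c(100, 25)), function(sz) {
    trap <- generate_trap_data(truth, sz[1], sz[2], fruits_scale = 5)
    m2 <- fit_model_II(trap$phenology)
    mean(abs(c(m2$sd_w / truth$sd_w, m2$sd_z / truth$sd_z,
               m2$sigma_resid / truth$sigma_resid) - 1))
  })
  expect_lt(err[2], err[1])
})

test_that("bootstrap p-values are powerful against a real tree effect and bounded", {
  set.seed(65)
  truth <- synthetic_truth(sd_w = 15, sigma_resid = 5, sd_z = 3)
  trap <- generate_trap_data(truth, 12, 12, fruits_scale = 2)
  fit <- fit_model_II(trap$phenology)
  p <- bootstrap_variance_pvalue(fit, "tree", n_boot = 99)
  expect_gt(p, 0)
  expect_lte(p, 1)
  expect_lt(p, 0.05)   # sd_w = 15 on sigma = 5 is unmissable
})

test_that("bootstrap p-values are roughly uniform under a true null", {
  set.seed(66)
  # small but fast null calibration; the full 200 x 199 experiment runs in
  # the acceptance suite
  truth <- synthetic_truth(sd_w = 0, sd_z = 5, sigma_resid = 15)
  pvals <- purrr::map_dbl(1:20, function(i) {
    trap <- generate_trap_data(truth, 10, 10, fruits_scale = 1.2)
    fit <- fit_model_II(trap$phenology)
    as.numeric(bootstrap_variance_pvalue(fit, "tree", n_boot = 49))
  })
  expect_gt(mean(pvals), 0.25)         # not systematically anti-conservative
  expect_lte(mean(pvals < 0.05), 0.2)  # near-nominal rejection
})
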