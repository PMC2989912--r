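test_that("homogeneous MLE is n/|A| and matches numeric maximization", {
  w <- rectangle_window(0, 1000, 0, 500)  # 50 ha
  set.seed(31)
  pat <- point_pattern(runif_in_window(w, 100), w)
  fit <- fit_homogeneous_poisson(pat)
  expect_equal(fit$lambda_hat, 100 / 5e5)
  expect_equal(fit$lambda_hat, 2.0e-4)
  # doubling the window halves the estimate
  w2 <- rectangle_window(0, 2000, 0, 500)
  expect_equal(fit_homogeneous_poisson(point_pattern(pat$points,
                                                     w2))$lambda_hat,
               1.0e-4)
  # brute-force 1-D likelihood maximization oracle
  ll <- function(l) 100 * log(l) - l * 5e5
  opt <- optimize(ll, c(1e-6, 1e-2), maximum = TRUE, tol = 1e-14)
  expect_lt(abs(fit$lambda_hat - opt$maximum), 1e-10)
})

test_that("a constant covariate reduces to the homogeneous fit", {
  w <- rectangle_window(0, 1000, 0, 1000)
  set.seed(32)
  pat <- point_pattern(runif_in_window(w, 200), w)
  g <- seq(25, 975, by = 50)
  flat <- density_surface(0, 0, 50, matrix(3, 20, 20),
                          matrix(TRUE, 20, 20), w)
  expect_warning(fit <- fit_inhomogeneous_poisson(pat, flat), "constant")
  expect_equal(exp(fit$alpha), 200 / 1e6, tolerance = 1e-8)
  expect_equal(fit$beta, 0)
})

test_that("inhomogeneous fits recover the generating coefficients", {
  set.seed(33)
  truth <- synthetic_truth(alpha = -9, beta = 2)
  w <- rectangle_window(0, 1650, 0, 1000)
  cen <- generate_census(truth, w, cell = 25)
  pat <- point_pattern(cen$trees[, c("x", "y")], w)
  fit <- fit_inhomogeneous_poisson(pat, cen$covariate)
  expect_lt(abs(fit$alpha - truth$alpha), 3 * fit$se[1])
  expect_lt(abs(fit$beta - truth$beta), 3 * fit$se[2])
  # score identity: expected count equals the observed count at the MLE
  expect_rel_equal(fit$expected_count, npoints(pat), 1e-6)
})

test_that("thinning simulation has Poisson moments and correct ratios", {
  w <- rectangle_window(0, 1000, 0, 1000)
  set.seed(34)
  # constant-rate counts: mean lambda*A within Monte Carlo error
  lam <- 2e-4
  counts <- replicate(300, npoints(simulate_poisson(lam, w)))
  expect_lt(abs(mean(counts) - lam * 1e6),
            3 * sqrt(lam * 1e6 / 300))
  expect_rel_equal(var(counts), lam * 1e6, 0.35)  # Poisson variance = mean

  # two-level step intensity: empirical density ratio matches intensity ratio
  vals <- matrix(1e-4, 20, 20); vals[, 11:20] <- 4e-4
  step <- density_surface(0, 0, 50, vals, matrix(TRUE, 20, 20), w)
  pts <- purrr::map_dfr(1:60, function(i) simulate_poisson(step)$points)
  n_left <- sum(pts$x < 475); n_right <- sum(pts$x > 525)
  expect_gt(n_right / n_left, 4 * 0.8)
  expect_lt(n_right / n_left, 4 * 1.25)

  # zero intensity gives an empty pattern
  zero <- density_surface(0, 0, 50, matrix(0, 20, 20),
                          matrix(TRUE, 20, 20), w)
  expect_equal(npoints(simulate_poisson(zero)), 0)
})

test_that("bandwidth selection returns a full profile and a sane optimum", {
  set.seed(35)
  truth <- synthetic_truth(alpha = -9, beta = 2, sigma_kernel = 150)
  w <- rectangle_window(0, 1650, 0, 1000)
  cen <- generate_census(truth, w, cell = 50)
  pat <- point_pattern(cen$trees[, c("x", "y")], w)
  det <- cen$trees[cen$trees$visible_aerial, c("x", "y")]
  grid <- c(50, 100, 150, 250, 400)
  sel <- optimize_sigma(pat, det, sigma_grid = grid, cell = 50)
  expect_equal(nrow(sel$profile), length(grid))
  expect_true(all(is.finite(sel$profile$criterion)))
  expect_true(sel$sigma_star %in% grid)
  # single-element grid: that bandwidth is returned
  one <- optimize_sigma(pat, det, sigma_grid = 172, cell = 50)
  expect_equal(one$sigma_star, 172)
})

test_that("envelope diagnostics are ordered and reject clustering", {
  set.seed(36)
  w <- rectangle_window(0, 1000, 0, 1000)
  pat <- point_pattern(runif_in_window(w, 150), w)
  hom <- fit_homogeneous_poisson(pat)
  env <- gof_envelope(hom, pat, n_sim = 39, cell = 50)
  expect_true(all(env$lower <= env$mean + 1e-12))
  expect_true(all(env$mean <= env$upper + 1e-12))

  # a strongly clustered pattern is flagged against its homogeneous fit
  parents <- runif_in_window(w, 5)
  kids <- purrr::map_dfr(seq_len(5), function(i) {
    tibble::tibble(x = pmin(pmax(rnorm(30, parents$x[i], 20), 0), 1000),
                   y = pmin(pmax(rnorm(30, parents$y[i], 20), 0), 1000))
  })
  clus <- point_pattern(kids, w)
  env_c <- gof_envelope(fit_homogeneous_poisson(clus), clus, n_sim = 39,
                        cell = 50)
  expect_false(attr(env_c, "inside"))
})
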