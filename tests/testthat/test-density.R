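test_that("kernel surface matches the closed-form Gaussian peak", {
  w <- rectangle_window(0, 4000, 0, 4000)
  # point at a cell centre, far from edges, no edge correction
  pt <- data.frame(x = 2025, y = 2025)
  s <- kernel_density_surface(pt, w, sigma = 172, cell = 50,
                              edge_correct = FALSE)
  expect_lt(abs(eval_surface(s, 2025, 2025) - 1 / (2 * pi * 172^2)), 1e-9)
})

test_that("edge-corrected surfaces integrate to the total weight", {
  w <- rectangle_window(0, 2000, 0, 2000)
  set.seed(21)
  pts <- runif_in_window(w, 40)
  wts <- runif(40, 0.5, 3)
  s <- kernel_density_surface(pts, w, sigma = 150, weights = wts, cell = 25)
  expect_rel_equal(surface_integral(s), sum(wts), 1e-3)
})

test_that("kernel smoothing is linear and translation invariant", {
  w <- rectangle_window(0, 1000, 0, 1000)
  p1 <- data.frame(x = 300, y = 400)
  p2 <- data.frame(x = 700, y = 600)
  both <- rbind(p1, p2)
  s1 <- kernel_density_surface(p1, w, 100, cell = 50, edge_correct = FALSE)
  s2 <- kernel_density_surface(p2, w, 100, cell = 50, edge_correct = FALSE)
  s12 <- kernel_density_surface(both, w, 100, cell = 50,
                                edge_correct = FALSE)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-12)

  shift <- 5000
  w_t <- rectangle_window(shift, 1000 + shift, shift, 1000 + shift)
  s_t <- kernel_density_surface(both + shift, w_t, 100, cell = 50,
                                edge_correct = FALSE)
  expect_equal(s_t$values, s12$values, tolerance = 1e-12)
})

test_that("empty patterns yield a zero surface with a warning", {
  w <- rectangle_window(0, 500, 0, 500)
  expect_warning(
    s <- kernel_density_surface(data.frame(x = numeric(0),
                                           y = numeric(0)),
                                w, 100, cell = 50),
    "empty")
  expect_true(all(s$values == 0))
})

test_that("surfaces round-trip through ESRI ASCII grids", {
  w <- rectangle_window(0, 600, 0, 400)
  set.seed(22)
  s <- kernel_density_surface(runif_in_window(w, 15), w, 80, cell = 50)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(s, tmp)
  s2 <- read_esri_ascii(tmp)
  expect_equal(s2$values, unname(s$values), tolerance = 1e-8)
  expect_equal(s2$cell, s$cell)
  expect_equal(unname(s2$mask), unname(s$mask))
})

test_that("bilinear interpolation agrees with grid values at cell centres", {
  w <- rectangle_window(0, 400, 0, 400)
  set.seed(23)
  s <- kernel_density_surface(runif_in_window(w, 10), w, 60, cell = 40)
  g <- surface_grid(s)
  expect_equal(eval_surface(s, g$x[3], g$y[5]), s$values[5, 3])
  # halfway between two centres: the average
  mid <- (s$values[5, 3] + s$values[5, 4]) / 2
  expect_equal(eval_surface(s, (g$x[3] + g$x[4]) / 2, g$y[5]), mid)
})
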