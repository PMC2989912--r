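#' Gridded intensity surface
#'
#' A raster of intensity values (trees per m^2, or an arbitrary covariate) on
#' a regular grid of square cells covering the bounding box of a window.
#' `values[iy, ix]` is the value at the cell centre
#' `(x0 + (ix - 0.5) cell, y0 + (iy - 0.5) cell)`; rows index ascending y.
#' `mask` marks cells whose centre lies inside the window; masked-out cells
#' are excluded from integrals and fits.
#'
#' @param x0,y0 Lower-left corner of the grid (m).
#' @param cell Cell side (m).
#' @param values Numeric matrix `ny` x `nx`.
#' @param mask Logical matrix, same shape.
#' @param window The `spatial_window` the grid covers.
#' @return Object of class `density_surface`.
#' @export
density_surface <- function(x0, y0, cell, values, mask, window) {
  stopifnot(is.matrix(values), identical(dim(values), dim(mask)), cell > 0)
  if (any(values[mask] < 0, na.rm = TRUE)) {
    stop("intensity values must be non-negative", call. = FALSE)
  }
  structure(list(x0 = x0, y0 = y0, cell = cell, values = values,
                 mask = mask, window = window),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %d x %d cells of %g m; range [%.4g, %.4g]; integral %.4g\n",
              nrow(x$values), ncol(x$values), x$cell,
              min(x$values[x$mask]), max(x$values[x$mask]),
              surface_integral(x)))
  invisible(x)
}

#' Integral of a surface over its window
#' @param surface A `density_surface`.
#' @return Sum of masked cell values times cell area.
#' @export
surface_integral <- function(surface) {
  sum(surface$values[surface$mask]) * surface$cell^2
}

#' Cell-centre coordinates of a surface grid
#' @param surface A `density_surface`.
#' @return List with vectors `x` (length nx) and `y` (length ny).
#' @export
surface_grid <- function(surface) {
  list(x = surface$x0 + (seq_len(ncol(surface$values)) - 0.5) * surface$cell,
       y = surface$y0 + (seq_len(nrow(surface$values)) - 0.5) * surface$cell)
}

#' Kernel-smoothed intensity surface of a point pattern
#'
#' Places an isotropic Gaussian kernel of standard deviation `sigma` on each
#' point and sums:
#' \deqn{\hat\lambda(s) = \sum_k w_k (2\pi\sigma^2)^{-1}
#'       \exp(-\|s - s_k\|^2 / 2\sigma^2).}
#' With `edge_correct = TRUE` each point's kernel is renormalized by its mass
#' inside the window, so the surface integrates to the total weight.
#'
#' @param points Data frame with columns `x`, `y` (m), or a `point_pattern`.
#' @param window `spatial_window` (taken from the pattern if omitted).
#' @param sigma Kernel standard deviation (m), positive.
#' @param weights Optional positive per-point weights (default 1); use
#'   inverse detection probabilities to estimate total density from a
#'   partially detected survey.
#' @param cell Grid cell size (m).
#' @param edge_correct Renormalize kernels inside the window (default TRUE).
#' @return A `density_surface` in units of weight per m^2.
#' @export
kernel_density_surface <- function(points, window = NULL, sigma,
                                   weights = NULL, cell = 50,
                                   edge_correct = TRUE) {
  if (inherits(points, "point_pattern")) {
    if (is.null(window)) window <- points$window
    points <- points$points
  }
  stopifnot(!is.null(window), sigma > 0, cell > 0)
  bb <- window_bbox(window)
  nx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cell))
  ny <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cell))
  gx <- bb["xmin"] + (seq_len(nx) - 0.5) * cell
  gy <- bb["ymin"] + (seq_len(ny) - 0.5) * cell
  mask <- outer(gy, gx, function(yy, xx) points_in_window(window, xx, yy))
  npts <- nrow(points)
  if (npts == 0) {
    warning("empty point pattern: returning all-zero surface", call. = FALSE)
    return(density_surface(bb["xmin"], bb["ymin"], cell,
                           matrix(0, ny, nx), mask, window))
  }
  w <- if (is.null(weights)) rep(1, npts) else as.numeric(weights)
  stopifnot(length(w) == npts, all(w > 0))
  konst <- 1 / (2 * pi * sigma^2)
  Ex <- exp(-outer(points$x, gx, "-")^2 / (2 * sigma^2))  # npts x nx
  Ey <- exp(-outer(points$y, gy, "-")^2 / (2 * sigma^2))  # npts x ny
  if (edge_correct) {
    # mass of each point's kernel inside the window, by the same quadrature
    tmp <- Ey %*% (mask * 1)            # npts x nx
    mass <- konst * cell^2 * rowSums(tmp * Ex)
    mass <- pmax(mass, 1e-12)
    w <- w / mass
  }
  vals <- konst * t(Ey * w) %*% Ex       # ny x nx
  density_surface(bb["xmin"], bb["ymin"], cell, vals, mask, window)
}

#' Evaluate a Gaussian kernel sum exactly at arbitrary locations
#'
#' Used for leave-one-out bandwidth selection: the kernel sum over source
#' points is evaluated at target locations without gridding, optionally
#' excluding any source point closer than `loo_eps` to the target (its own
#' contribution).
#'
#' @param sources Data frame with `x`, `y` of kernel centres.
#' @param at Data frame with `x`, `y` of evaluation locations.
#' @param sigma Kernel SD (m).
#' @param weights Optional per-source weights.
#' @param leave_one_out Exclude coincident source points (default FALSE).
#' @param loo_eps Coincidence tolerance (m).
#' @return Numeric vector of kernel sums (weight per m^2).
#' @export
kernel_values_at <- function(sources, at, sigma, weights = NULL,
                             leave_one_out = FALSE, loo_eps = 1e-6) {
  npts <- nrow(sources)
  w <- if (is.null(weights)) rep(1, npts) else as.numeric(weights)
  konst <- 1 / (2 * pi * sigma^2)
  d2 <- outer(at$x, sources$x, "-")^2 + outer(at$y, sources$y, "-")^2
  K <- konst * exp(-d2 / (2 * sigma^2))
  if (leave_one_out) K[d2 < loo_eps^2] <- 0
  as.numeric(K %*% w)
}

#' Interpolate a surface at arbitrary locations
#'
#' Bilinear interpolation between cell centres; locations beyond the outer
#' cell centres are clamped to the edge value. Points exactly on a cell
#' boundary resolve to the lower-left cell.
#'
#' @param surface A `density_surface`.
#' @param x,y Coordinates (m).
#' @return Numeric vector of interpolated values.
#' @export
eval_surface <- function(surface, x, y) {
  g <- surface_grid(surface)
  nx <- length(g$x); ny <- length(g$y)
  fx <- (x - g$x[1]) / surface$cell
  fy <- (y - g$y[1]) / surface$cell
  ix <- pmin(pmax(floor(fx), 0), nx - 1)       # lower cell index, 0-based
  iy <- pmin(pmax(floor(fy), 0), ny - 1)
  ix1 <- pmin(ix + 1, nx - 1); iy1 <- pmin(iy + 1, ny - 1)
  tx <- pmin(pmax(fx - ix, 0), 1)
  ty <- pmin(pmax(fy - iy, 0), 1)
  v <- surface$values
  idx <- function(iyy, ixx) v[cbind(iyy + 1, ixx + 1)]
  (1 - tx) * (1 - ty) * idx(iy, ix) + tx * (1 - ty) * idx(iy, ix1) +
    (1 - tx) * ty * idx(iy1, ix) + tx * ty * idx(iy1, ix1)
}

#' Apply a function to the values of a surface
#' @param surface A `density_surface`.
#' @param f Vectorized function applied to the value matrix.
#' @return A new `density_surface` (mask and geometry preserved).
#' @export
transform_surface <- function(surface, f) {
  vals <- f(surface$values)
  density_surface(surface$x0, surface$y0, surface$cell, vals, surface$mask,
                  surface$window)
}

#' Write / read a surface as an ESRI ASCII grid
#'
#' Standard `.asc` raster interchange: a 6-line header then rows of values
#' from the top (north) row down. Masked-out cells are written as the NODATA
#' value.
#'
#' @param surface A `density_surface`.
#' @param path Output path.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_esri_ascii <- function(surface, path, nodata = -9999) {
  v <- surface$values
  v[!surface$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(surface$x0, digits = 12)),
    paste("yllcorner", format(surface$y0, digits = 12)),
    paste("cellsize", format(surface$cell, digits = 12)),
    paste("NODATA_value", nodata)
  ), con)
  for (iy in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[iy, ], digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_esri_ascii
#' @param window Optional `spatial_window` to attach; defaults to the grid
#'   rectangle.
#' @export
read_esri_ascii <- function(path, window = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- get("ncols"); nrows <- get("nrows")
  x0 <- get("xllcorner"); y0 <- get("yllcorner")
  cell <- get("cellsize"); nodata <- get("NODATA")
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  vals <- vals[rev(seq_len(nrows)), , drop = FALSE]  # back to ascending y
  mask <- vals != nodata
  vals[!mask] <- 0
  if (is.null(window)) {
    window <- rectangle_window(x0, x0 + ncols * cell, y0, y0 + nrows * cell)
  }
  density_surface(x0, y0, cell, vals, mask, window)
}
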