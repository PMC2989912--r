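#' Create a planar observation window
#'
#' An observation window is a simple (non-self-intersecting) polygon in
#' projected metric coordinates (x east, y north). All point patterns,
#' intensity surfaces and simulated forests refer to such a window.
#'
#' @param vertices A data frame with columns `x` and `y` (metres), listing the
#'   polygon boundary in order. The polygon is closed automatically; a
#'   repeated last vertex is dropped.
#' @return An object of class `spatial_window` with elements `vertices`
#'   (a tibble of the open ring) and `area` (m^2).
#' @examples
#' w <- spatial_window(data.frame(x = c(0, 1000, 1000, 0),
#'                                y = c(0, 0, 500, 500)))
#' window_area(w)
#' @export
spatial_window <- function(vertices) {
  vertices <- tibble::as_tibble(vertices)
  if (!all(c("x", "y") %in% names(vertices))) {
    stop("`vertices` must have columns `x` and `y`", call. = FALSE)
  }
  v <- dplyr::select(vertices, "x", "y")
  v$x <- as.numeric(v$x); v$y <- as.numeric(v$y)
  if (!all(is.finite(v$x)) || !all(is.finite(v$y))) {
    stop("window vertices must be finite", call. = FALSE)
  }
  n <- nrow(v)
  if (n >= 2 && v$x[1] == v$x[n] && v$y[1] == v$y[n]) {
    v <- v[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stop("a window polygon needs at least 3 distinct vertices",
                  call. = FALSE)
  if (.ring_self_intersects(v$x, v$y)) {
    stop("window boundary is self-intersecting", call. = FALSE)
  }
  area <- .shoelace_area(v$x, v$y)
  if (area < 0) {           # force counter-clockwise orientation
    v <- v[rev(seq_len(n)), , drop = FALSE]
    area <- -area
  }
  if (area <= 0) stop("window has zero area", call. = FALSE)
  structure(list(vertices = v, area = area), class = "spatial_window")
}

#' @rdname spatial_window
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @export
rectangle_window <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  spatial_window(data.frame(x = c(xmin, xmax, xmax, xmin),
                            y = c(ymin, ymin, ymax, ymax)))
}

#' @rdname spatial_window
#' @param window A `spatial_window`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "spatial_window"))
  window$area
}

#' @export
print.spatial_window <- function(x, ...) {
  bb <- window_bbox(x)
  cat(sprintf(
    "<spatial_window> %d vertices, area %.4g m^2, bbox [%.6g, %.6g] x [%.6g, %.6g]\n",
    nrow(x$vertices), x$area, bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"]))
  invisible(x)
}

#' Bounding box of a window
#' @param window A `spatial_window`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax`.
#' @export
window_bbox <- function(window) {
  v <- window$vertices
  c(xmin = min(v$x), xmax = max(v$x), ymin = min(v$y), ymax = max(v$y))
}

#' Test whether points fall inside a window
#'
#' Boundary points count as inside, so containment is deterministic for
#' points on polygon edges.
#'
#' @param window A `spatial_window`.
#' @param x,y Coordinate vectors (metres).
#' @return Logical vector.
#' @export
points_in_window <- function(window, x, y) {
  stopifnot(inherits(window, "spatial_window"), length(x) == length(y))
  if (length(x) == 0) return(logical(0))
  v <- window$vertices
  sp::point.in.polygon(x, y, v$x, v$y) > 0
}

#' Read a window polygon from WKT or GeoJSON
#'
#' Accepts a text file holding either a WKT `POLYGON ((x y, ...))` string or a
#' GeoJSON Polygon (bare geometry, Feature or FeatureCollection). Only the
#' exterior ring is used.
#'
#' @param path Path to the polygon file.
#' @return A `spatial_window`.
#' @export
read_window <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) {
    gj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
    geom <- gj
    if (!is.null(gj$type) && identical(gj$type, "FeatureCollection")) {
      geom <- gj$features$geometry
      ring <- geom$coordinates[[1]]
      if (is.list(ring)) ring <- ring[[1]]
      if (length(dim(ring)) == 3) ring <- ring[1, , ]
    } else {
      if (!is.null(gj$type) && identical(gj$type, "Feature")) geom <- gj$geometry
      ring <- geom$coordinates
      if (length(dim(ring)) == 3) ring <- ring[1, , ] else if (is.list(ring)) ring <- ring[[1]]
    }
    return(spatial_window(data.frame(x = ring[, 1], y = ring[, 2])))
  }
  if (grepl("POLYGON", txt, ignore.case = TRUE)) {
    inner <- sub(".*POLYGON\\s*\\(\\(", "", txt, ignore.case = TRUE)
    inner <- sub("\\).*", "", inner)
    pairs <- strsplit(trimws(strsplit(inner, ",")[[1]]), "\\s+")
    xy <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
    return(spatial_window(data.frame(x = xy[, 1], y = xy[, 2])))
  }
  stop("unrecognized polygon format (expected WKT POLYGON or GeoJSON): ", path,
       call. = FALSE)
}

#' Write a window polygon as WKT
#' @param window A `spatial_window`.
#' @param path Output file path.
#' @export
write_window <- function(window, path) {
  v <- window$vertices
  ring <- paste(sprintf("%.10g %.10g", c(v$x, v$x[1]), c(v$y, v$y[1])),
                collapse = ", ")
  writeLines(sprintf("POLYGON ((%s))", ring), path)
  invisible(path)
}

#' Draw uniform random points inside a window
#'
#' Rejection sampling from the bounding box; used by the homogeneous branch of
#' the point-process simulator.
#'
#' @param window A `spatial_window`.
#' @param n Number of points.
#' @return A tibble with columns `x`, `y`.
#' @export
runif_in_window <- function(window, n) {
  stopifnot(n >= 0)
  bb <- window_bbox(window)
  out_x <- numeric(0); out_y <- numeric(0)
  frac <- max(window$area / ((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])),
              1e-3)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / frac) + 10
    x <- stats::runif(m, bb["xmin"], bb["xmax"])
    y <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- points_in_window(window, x, y)
    out_x <- c(out_x, x[keep]); out_y <- c(out_y, y[keep])
  }
  tibble::tibble(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# signed polygon area (shoelace); positive for counter-clockwise rings
.shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# brute-force segment intersection check; windows have few vertices
.ring_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  crosses <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (crosses(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}
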