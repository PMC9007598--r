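#' Polyline and polygon primitives for isobole geometry
#'
#' Isoboles are represented as plain tibbles with numeric columns `x` and `y`
#' (ordered vertices of an open polyline). Polygons use the same layout with
#' the closing edge implied. All distance computations are intended to run in
#' normalized dose space (each axis divided by its maximum dose) so that
#' thresholds expressed in grid spacings are scale-free.
#'
#' @param points A data frame with numeric columns `x` and `y`.
#' @return `as_polyline()` returns a validated tibble with columns `x`, `y`.
#' @examples
#' as_polyline(data.frame(x = c(0, 1), y = c(1, 0)))
#' @export
as_polyline <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("x", "y") %in% names(points))) {
    stop("polyline needs numeric columns `x` and `y`", call. = FALSE)
  }
  pl <- tibble::as_tibble(points)[, c("x", "y")]
  if (nrow(pl) > 0 && nrow(pl) < 2) {
    stop("a non-empty polyline needs at least 2 points", call. = FALSE)
  }
  if (anyNA(pl$x) || anyNA(pl$y)) {
    stop("polyline coordinates must be finite", call. = FALSE)
  }
  pl
}

#' @rdname as_polyline
#' @return `as_polygon()` returns a validated tibble of polygon vertices
#'   (implicitly closed).
#' @export
as_polygon <- function(points) {
  pg <- as_polyline(points)
  # drop a repeated closing vertex if the caller supplied one
  n <- nrow(pg)
  if (n >= 2 && pg$x[1] == pg$x[n] && pg$y[1] == pg$y[n]) pg <- pg[-n, ]
  if (nrow(pg) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  pg
}

#' Extract level-set contours from a gridded surface
#'
#' Thin, validating wrapper around [grDevices::contourLines()], the standard
#' marching-squares routine with linear interpolation along cell edges.
#' Used both for effective isoboles of success-rate surfaces and for
#' confidence-level isoboles of aggregated surfaces.
#'
#' @param values Numeric matrix of surface values; rows correspond to `x`,
#'   columns to `y`.
#' @param x,y Strictly increasing coordinate vectors for the rows and columns
#'   of `values`.
#' @param level Scalar level at which to extract the contour.
#' @return A list of polylines (tibbles with columns `x`, `y`), one per
#'   connected contour component; empty list when all values lie strictly on
#'   one side of `level`.
#' @examples
#' z <- outer(seq(0, 1, length.out = 9), seq(0, 1, length.out = 9), `+`)
#' extract_contour(z, seq(0, 1, length.out = 9), seq(0, 1, length.out = 9), 1)
#' @export
extract_contour <- function(values, x, y, level) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (length(x) != nrow(values) || length(y) != ncol(values)) {
    stop("`values` must be a length(x) by length(y) matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("all lattice nodes must be evaluated (no missing values)", call. = FALSE)
  }
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  if (max(values) == min(values)) return(list()) # constant surface: no crossing
  cl <- grDevices::contourLines(x = x, y = y, z = values, levels = level)
  lapply(cl, function(cc) tibble::tibble(x = cc$x, y = cc$y))
}

#' Discrete Fréchet distance between two polylines
#'
#' Exact dynamic program over vertex pairs (the coupled-walk recurrence).
#' Used as the convergence metric between successive isobole estimates:
#' it bounds how far any point of one curve is from the other under
#' order-preserving traversal.
#'
#' Because the discrete metric couples vertices, a sparse polyline (e.g. a
#' two-vertex closed-form segment) should be densified with
#' [densify_polyline()] before comparison against a dense contour. The
#' metric is direction-sensitive; `orientation = "either"` takes the minimum
#' over the two traversal directions of `b`, useful when comparing contours
#' whose extraction order is arbitrary.
#'
#' @param a,b Polylines (data frames with columns `x`, `y`), non-empty.
#' @param orientation `"fixed"` (standard, direction-sensitive) or
#'   `"either"`.
#' @return Non-negative scalar distance, in the units of the inputs.
#' @examples
#' a <- data.frame(x = c(0, 1), y = c(0, 0))
#' b <- data.frame(x = c(0, 1), y = c(0.25, 0.25))
#' discrete_frechet(a, b) # 0.25
#' @export
discrete_frechet <- function(a, b, orientation = c("fixed", "either")) {
  orientation <- match.arg(orientation)
  if (orientation == "either") {
    b <- as_polyline(b)
    return(min(discrete_frechet(a, b),
               discrete_frechet(a, b[rev(seq_len(nrow(b))), ])))
  }
  a <- as_polyline(a); b <- as_polyline(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("polylines must be non-empty", call. = FALSE)
  n <- nrow(a); m <- nrow(b)
  d <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
  ca <- matrix(0, n, m)
  ca[1, ] <- cummax(d[1, ])
  if (n > 1) {
    ca[, 1] <- cummax(d[, 1])
    for (i in 2:n) {
      row_prev <- ca[i - 1, ]
      row_cur <- ca[i, ]
      for (j in 2:m) {
        row_cur[j] <- max(d[i, j], min(row_prev[j], row_prev[j - 1], row_cur[j - 1]))
      }
      ca[i, ] <- row_cur
    }
  }
  ca[n, m]
}

# classify one point against a simple polygon: "interior", "boundary", "exterior"
# even-odd rule with half-open edge convention; boundary detected explicitly
# within a small absolute tolerance scaled to the polygon extent.
classify_point <- function(px, py, poly, eps = NULL) {
  xs <- poly$x; ys <- poly$y
  n <- length(xs)
  if (is.null(eps)) eps <- 1e-9 * max(1, max(abs(xs)), max(abs(ys)))
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      if (abs(px - xi) <= eps && abs(py - yi) <= eps) return("boundary")
    } else {
      t <- ((px - xi) * dx + (py - yi) * dy) / L2
      t <- min(1, max(0, t))
      qx <- xi + t * dx; qy <- yi + t * dy
      if ((px - qx)^2 + (py - qy)^2 <= eps * eps) return("boundary")
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) "interior" else "exterior"
}

#' Point-in-polygon classification (ray casting)
#'
#' Even-odd (ray-casting) containment against a simple polygon. Points on the
#' polygon boundary count as inside: a dose combination lying exactly on an
#' effective isobole achieves the efficacy target, so only strictly interior
#' points of the failure polygon are classified as failing.
#'
#' @param points Data frame with columns `x`, `y`: the query points.
#' @param poly Polygon (data frame with columns `x`, `y`, implicitly closed,
#'   at least 3 vertices, simple).
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' point_in_polygon(data.frame(x = c(0.5, 2), y = c(0.5, 2)), sq)
#' @export
point_in_polygon <- function(points, poly) {
  poly <- as_polygon(poly)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  vapply(
    seq_len(nrow(points)),
    function(i) classify_point(points$x[i], points$y[i], poly) != "exterior",
    logical(1)
  )
}

#' Minimum distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to any segment of the
#' polyline (segments, not only vertices). This is the distance used by the
#' grid-refinement rule: a candidate node is simulated only if it lies within
#' one grid spacing of the current isobole estimate.
#'
#' @param points Data frame with columns `x`, `y`: the query points.
#' @param polyline Polyline (data frame with columns `x`, `y`), non-empty.
#' @return Numeric vector of distances, one per query point.
#' @examples
#' distance_to_polyline(data.frame(x = 0, y = 1), data.frame(x = c(0, 1), y = c(0, 0)))
#' @export
distance_to_polyline <- function(points, polyline) {
  polyline <- as_polyline(polyline)
  if (nrow(polyline) == 0) stop("polyline must be non-empty", call. = FALSE)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  px <- points$x; py <- points$y
  xs <- polyline$x; ys <- polyline$y
  n <- length(xs)
  if (n == 1) return(sqrt((px - xs)^2 + (py - ys)^2))
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    x1 <- xs[i]; y1 <- ys[i]; dx <- xs[i + 1] - x1; dy <- ys[i + 1] - y1
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      di <- sqrt((px - x1)^2 + (py - y1)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
      di <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
    }
    best <- pmin(best, di)
  }
  best
}

#' Signed-area (shoelace) of a polygon
#'
#' @param poly Polygon (data frame with columns `x`, `y`, implicitly closed).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# total arc length of a polyline (used to pick the main contour component)
polyline_length <- function(pl) {
  if (nrow(pl) < 2) return(0)
  sum(sqrt(diff(pl$x)^2 + diff(pl$y)^2))
}

#' Resample a polyline to evenly spaced vertices
#'
#' Linear interpolation along arc length. Used to densify sparse closed-form
#' isoboles before discrete Fréchet comparisons.
#'
#' @param polyline Polyline tibble with columns `x`, `y`.
#' @param n Number of output vertices (>= 2).
#' @return Polyline tibble with `n` vertices.
#' @export
densify_polyline <- function(polyline, n = 1025) {
  pl <- as_polyline(polyline)
  stopifnot(n >= 2, nrow(pl) >= 2)
  s <- c(0, cumsum(sqrt(diff(pl$x)^2 + diff(pl$y)^2)))
  if (s[length(s)] == 0) stop("degenerate polyline of zero length", call. = FALSE)
  sq <- seq(0, s[length(s)], length.out = n)
  tibble::tibble(
    x = stats::approx(s, pl$x, xout = sq, ties = "ordered")$y,
    y = stats::approx(s, pl$y, xout = sq, ties = "ordered")$y)
}
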