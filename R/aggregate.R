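#' Close an effective isobole into the failure polygon
#'
#' The effective isobole separates the dosing space into a non-efficacious
#' region (containing the origin) and an efficacious one. Augmenting the
#' ordered isobole vertices with the stretch of the dosing-space boundary
#' that runs through the origin yields a simple polygon enclosing the region
#' in which the efficacy target is not reached.
#'
#' Both isobole endpoints must lie on the boundary of the dosing rectangle
#' (the axes or the maximum-dose edges); an isobole ending strictly in the
#' interior violates the separation assumption and raises an error.
#'
#' @param iso Isobole polyline (tibble with columns `x`, `y`, dose units) or
#'   a `fastisoboles_result`.
#' @param bounds Length-2 dosing-space bounds (taken from the result if one
#'   is supplied).
#' @return Polygon tibble (columns `x`, `y`, implicitly closed).
#' @examples
#' isobole_to_polygon(data.frame(x = c(0, 1), y = c(1, 0)), bounds = c(1, 1))
#' @export
isobole_to_polygon <- function(iso, bounds = NULL) {
  if (inherits(iso, "fastisoboles_result")) {
    bounds <- iso$bounds
    iso <- iso$isobole
  }
  if (is.null(bounds)) stop("`bounds` must be supplied", call. = FALSE)
  iso <- as_polyline(iso)
  if (nrow(iso) < 2) stop("isobole must have at least 2 vertices", call. = FALSE)
  b1 <- bounds[1]; b2 <- bounds[2]
  tol <- 1e-6 * max(b1, b2)

  on_boundary <- function(px, py) {
    abs(px) <= tol || abs(px - b1) <= tol || abs(py) <= tol || abs(py - b2) <= tol
  }
  e1 <- c(iso$x[1], iso$y[1])
  e2 <- c(iso$x[nrow(iso)], iso$y[nrow(iso)])
  if (!on_boundary(e1[1], e1[2]) || !on_boundary(e2[1], e2[2])) {
    stop("isobole endpoints must terminate on the dosing-space boundary",
         call. = FALSE)
  }
  snap <- function(p) c(
    if (abs(p[1]) <= tol) 0 else if (abs(p[1] - b1) <= tol) b1 else p[1],
    if (abs(p[2]) <= tol) 0 else if (abs(p[2] - b2) <= tol) b2 else p[2])
  e1 <- snap(e1); e2 <- snap(e2)

  # boundary parameterized counterclockwise from the origin:
  # (0,0) -> (b1,0) -> (b1,b2) -> (0,b2) -> (0,0); perimeter length L
  L <- 2 * (b1 + b2)
  t_of <- function(p) {
    if (p[2] == 0) p[1]
    else if (p[1] == b1) b1 + p[2]
    else if (p[2] == b2) b1 + b2 + (b1 - p[1])
    else 2 * b1 + b2 + (b2 - p[2])
  }
  corners <- list(c(b1, 0), c(b1, b2), c(0, b2))
  corner_t <- vapply(corners, t_of, numeric(1))
  t1 <- t_of(e1); t2 <- t_of(e2)

  # walk the boundary from e2 back to e1 along the arc containing the origin
  # (t = 0); collect the corners passed, plus the origin itself.
  path <- list()
  add <- function(p) path[[length(path) + 1]] <<- p
  if (t2 <= t1) {
    # decreasing t from t2 through 0, wrapping to L, down to t1
    ct <- sort(corner_t[corner_t < t2], decreasing = TRUE)
    for (tt in ct) add(corners[[which(corner_t == tt)]])
    add(c(0, 0))
    ct <- sort(corner_t[corner_t > t1], decreasing = TRUE)
    for (tt in ct) add(corners[[which(corner_t == tt)]])
  } else {
    # increasing t from t2 through L (= origin), up to t1
    ct <- sort(corner_t[corner_t > t2])
    for (tt in ct) add(corners[[which(corner_t == tt)]])
    add(c(0, 0))
    ct <- sort(corner_t[corner_t < t1])
    for (tt in ct) add(corners[[which(corner_t == tt)]])
  }

  verts <- rbind(as.matrix(iso[, c("x", "y")]),
                 do.call(rbind, path))
  verts <- verts[c(TRUE, rowSums(abs(diff(verts))) > tol / 10), , drop = FALSE]
  n <- nrow(verts)
  if (n >= 2 && all(abs(verts[1, ] - verts[n, ]) <= tol / 10)) {
    verts <- verts[-n, , drop = FALSE]
  }
  as_polygon(tibble::tibble(x = verts[, 1], y = verts[, 2]))
}

#' Binary success field of one population on a lattice
#'
#' Encodes every lattice node with 0 where the efficacy target is not
#' reached (node strictly inside the failure polygon, or on its closure
#' segments along the dosing-space boundary) and 1 where it is achieved or
#' exceeded (node on the isobole itself, or outside the polygon). Nodes
#' exactly on the effective isobole achieve the target exactly, hence count
#' as success; nodes on the origin-side closure of the polygon (e.g. the
#' origin itself) are failures.
#'
#' @param poly Failure polygon from [isobole_to_polygon()].
#' @param x,y Lattice coordinate vectors.
#' @param isobole The isobole polyline (or list of contour components) whose
#'   closure `poly` is; nodes on it are coded success. When `NULL`, polygon
#'   boundary nodes on the dosing-space edge are treated as closure
#'   (failure) and all other boundary nodes as isobole (success).
#' @return Integer matrix (`length(x)` by `length(y)`) of 0/1.
#' @export
classify_binary <- function(poly, x, y, isobole = NULL) {
  poly <- as_polygon(poly)
  g <- expand.grid(x = x, y = y)
  px <- g$x; py <- g$y
  xs <- poly$x; ys <- poly$y
  n <- length(xs)
  eps <- 1e-9 * max(1, max(abs(xs)), max(abs(ys)))
  inside <- rep(FALSE, length(px))
  bnd <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      bnd <- bnd | (abs(px - xi) <= eps & abs(py - yi) <= eps)
    } else {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
      bnd <- bnd | ((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2 <= eps * eps)
    }
    cross <- (yi > py) != (yj > py)
    if (any(cross)) {
      xint <- xi + (py - yi) / (yj - yi) * dx
      flip <- cross & (px < xint)
      flip[is.na(flip)] <- FALSE
      inside <- xor(inside, flip)
    }
    j <- i
  }

  # boundary nodes: success on the isobole, failure on the closure segments
  on_iso <- rep(FALSE, length(px))
  if (any(bnd)) {
    if (!is.null(isobole)) {
      if (is.data.frame(isobole)) isobole <- list(isobole)
      di <- rep(Inf, sum(bnd))
      bpts <- data.frame(x = px[bnd], y = py[bnd])
      for (cp in isobole) {
        if (nrow(cp) >= 2) di <- pmin(di, distance_to_polyline(bpts, cp))
      }
      on_iso[bnd] <- di <= eps
    } else {
      bx <- max(xs); by <- max(ys)
      on_edge <- abs(px[bnd]) <= eps | abs(py[bnd]) <= eps |
        abs(px[bnd] - bx) <= eps | abs(py[bnd] - by) <= eps
      on_iso[bnd] <- !on_edge
    }
  }
  success <- ifelse(bnd, on_iso, !inside)
  matrix(as.integer(success), nrow = length(x), ncol = length(y))
}

#' Aggregate an ensemble of effective isoboles into a confidence surface
#'
#' For each population the failure polygon is built and the lattice encoded
#' 0/1; averaging the binary fields over populations gives, at every dose
#' combination, the fraction of populations achieving the efficacy target —
#' the confidence level. The aggregation lattice is a fresh uniform grid,
#' by default at twice the isobole-search resolution. Populations whose
#' isobole search classified the whole space contribute a constant field
#' (all 1 for "entire space efficacious", all 0 otherwise).
#'
#' @param isoboles List of `fastisoboles_result` objects or isobole polyline
#'   tibbles, one per population.
#' @param bounds Dosing-space bounds; must match across results.
#' @param resolution Nodes per axis of the aggregation lattice; default
#'   `2^(j_final + 1) + 1`, i.e. twice the final search resolution.
#' @param target_rate Efficacy level being aggregated (taken from the
#'   results when available).
#' @return An object of class `confidence_surface`: axes `x`, `y`, matrix
#'   `values` of confidence levels (multiples of `1/n_pop`), `n_pop`,
#'   `target_rate`.
#' @export
aggregate_isoboles <- function(isoboles, bounds = NULL, resolution = NULL,
                               target_rate = NULL) {
  stopifnot(length(isoboles) >= 1)
  is_res <- vapply(isoboles, inherits, logical(1), "fastisoboles_result")
  if (any(is_res)) {
    bset <- unique(lapply(isoboles[is_res], `[[`, "bounds"))
    if (length(bset) > 1) stop("mixed dosing bounds among isoboles", call. = FALSE)
    if (is.null(bounds)) bounds <- bset[[1]]
    if (max(abs(bset[[1]] - bounds)) > 0) {
      stop("mixed dosing bounds among isoboles", call. = FALSE)
    }
    if (is.null(target_rate)) target_rate <- isoboles[[which(is_res)[1]]]$target_rate
    if (is.null(resolution)) {
      j_final <- max(vapply(isoboles[is_res], function(r) r$grid$level, integer(1)))
      resolution <- 2^(j_final + 1) + 1
    }
  }
  if (is.null(bounds)) stop("`bounds` must be supplied", call. = FALSE)
  if (is.null(resolution)) resolution <- 129
  if (is.null(target_rate)) target_rate <- NA_real_

  x <- seq(0, bounds[1], length.out = resolution)
  y <- seq(0, bounds[2], length.out = resolution)
  acc <- matrix(0, resolution, resolution)
  for (iso in isoboles) {
    if (inherits(iso, "fastisoboles_result") && !is.null(iso$classification)) {
      field <- matrix(
        as.integer(iso$classification == "entire space efficacious"),
        resolution, resolution)
    } else {
      comps <- if (inherits(iso, "fastisoboles_result")) iso$components else iso
      main <- if (inherits(iso, "fastisoboles_result")) iso$isobole else iso
      poly <- isobole_to_polygon(main, bounds = bounds)
      field <- classify_binary(poly, x, y, isobole = comps)
    }
    acc <- acc + field
  }
  structure(
    list(x = x, y = y, values = acc / length(isoboles),
         n_pop = length(isoboles), target_rate = target_rate,
         bounds = as.numeric(bounds)),
    class = "confidence_surface")
}

#' @export
print.confidence_surface <- function(x, ...) {
  cat(sprintf("<confidence_surface> %d x %d lattice on [0,%g] x [0,%g], %d populations\n",
              length(x$x), length(x$y), x$bounds[1], x$bounds[2], x$n_pop))
  cat(sprintf("  target rate %.3g; confidence range [%.3g, %.3g]\n",
              x$target_rate, min(x$values), max(x$values)))
  invisible(x)
}

#' Extract a confidence-level isobole from a confidence surface
#'
#' Contour of the confidence-level response surface at probability `level`
#' via linear interpolation: the minimum dose combinations achieving the
#' efficacy target with at least that confidence.
#'
#' @param surface A [aggregate_isoboles()] result.
#' @param level Confidence level in (0, 1), e.g. `0.95`.
#' @return Polyline tibble (longest contour component; all components in
#'   attribute `components`). Empty tibble with attribute `flag =
#'   "level outside surface range"` when the surface never crosses `level`.
#' @export
confidence_isobole <- function(surface, level) {
  stopifnot(inherits(surface, "confidence_surface"), level > 0, level < 1)
  comps <- extract_contour(surface$values, surface$x, surface$y, level)
  if (length(comps) == 0) {
    out <- tibble::tibble(x = numeric(), y = numeric())
    attr(out, "flag") <- "level outside surface range"
    return(out)
  }
  main <- main_component(comps)
  attr(main, "components") <- comps
  main
}
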