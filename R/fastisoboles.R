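#' Initialize the dyadic dose grid
#'
#' Level-1 grid over the rectangular dosing space: the 3x3 lattice
#' `{0, max/2, max}` per axis, all nine nodes marked for evaluation. Each
#' later refinement doubles the resolution, so the level-`j` lattice has
#' `2^j + 1` doses per drug.
#'
#' @param bounds Length-2 positive vector `(amt1_max, amt2_max)`.
#' @return An object of class `dose_grid`: axes `x`, `y`, the filled value
#'   matrix (`NA` until evaluated), logical `evaluated` matrix, integer
#'   `iter` matrix (iteration of first evaluation), and `pending`, a tibble
#'   of nodes awaiting evaluation.
#' @export
init_grid <- function(bounds) {
  if (length(bounds) != 2 || any(bounds <= 0)) {
    stop("bounds must be two positive dose limits", call. = FALSE)
  }
  x <- seq(0, bounds[1], length.out = 3)
  y <- seq(0, bounds[2], length.out = 3)
  pending <- tidyr::expand_grid(ix = 1:3, iy = 1:3)
  pending <- dplyr::mutate(pending, amt1 = x[.data$ix], amt2 = y[.data$iy])
  structure(
    list(bounds = as.numeric(bounds), level = 1L, x = x, y = y,
         value = matrix(NA_real_, 3, 3),
         evaluated = matrix(FALSE, 3, 3),
         iter = matrix(NA_integer_, 3, 3),
         pending = pending),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> level %d (%d x %d), %d evaluated, %d pending\n",
              x$level, length(x$x), length(x$y), sum(x$evaluated), nrow(x$pending)))
  invisible(x)
}

# bilinear upsampling of an n x m lattice to (2n-1) x (2m-1); midpoint values
# are edge/cell averages, so unevaluated fine nodes inherit the coarse
# interpolant (they are far from the isobole, hence on a known side of it).
upsample_bilinear <- function(z) {
  n <- nrow(z); m <- ncol(z)
  out <- matrix(NA_real_, 2 * n - 1, 2 * m - 1)
  out[seq(1, 2 * n - 1, by = 2), seq(1, 2 * m - 1, by = 2)] <- z
  if (n > 1) {
    out[seq(2, 2 * n - 2, by = 2), seq(1, 2 * m - 1, by = 2)] <-
      (z[-n, ] + z[-1, ]) / 2
  }
  if (m > 1) {
    out[seq(1, 2 * n - 1, by = 2), seq(2, 2 * m - 2, by = 2)] <-
      (z[, -m] + z[, -1]) / 2
  }
  if (n > 1 && m > 1) {
    out[seq(2, 2 * n - 2, by = 2), seq(2, 2 * m - 2, by = 2)] <-
      (z[-n, -m] + z[-1, -m] + z[-n, -1] + z[-1, -1]) / 4
  }
  out
}

upsample_logical <- function(e) {
  n <- nrow(e); m <- ncol(e)
  out <- matrix(FALSE, 2 * n - 1, 2 * m - 1)
  out[seq(1, 2 * n - 1, by = 2), seq(1, 2 * m - 1, by = 2)] <- e
  out
}

upsample_integer <- function(it) {
  n <- nrow(it); m <- ncol(it)
  out <- matrix(NA_integer_, 2 * n - 1, 2 * m - 1)
  out[seq(1, 2 * n - 1, by = 2), seq(1, 2 * m - 1, by = 2)] <- it
  out
}

#' Refine the dose grid towards the current isobole estimate
#'
#' Doubles the grid resolution and marks for evaluation exactly those
#' not-yet-evaluated nodes of the refined lattice whose distance to the
#' current isobole estimate, in normalized dose units, is smaller than the
#' pre-refinement grid spacing `2^-level`. Distances are taken to the
#' polyline segments of every contour component. With an empty isobole
#' estimate, all unevaluated nodes of the refined lattice are selected
#' (full-lattice fallback for one iteration).
#'
#' @param grid A [init_grid()] dose grid with no pending nodes.
#' @param current_isobole A polyline tibble (dose units), a list of such
#'   components, or `NULL`/empty for the fallback.
#' @return The grid at level `level + 1` with `pending` set to the selected
#'   nodes.
#' @export
refine <- function(grid, current_isobole) {
  stopifnot(inherits(grid, "dose_grid"))
  if (nrow(grid$pending) > 0) {
    stop("grid has pending nodes; evaluate them before refining", call. = FALSE)
  }
  j <- grid$level
  spacing <- 2^-j
  b <- grid$bounds
  nx <- 2^(j + 1) + 1
  x <- seq(0, b[1], length.out = nx)
  y <- seq(0, b[2], length.out = nx)

  value <- upsample_bilinear(grid$value)
  evaluated <- upsample_logical(grid$evaluated)
  iter <- upsample_integer(grid$iter)

  idx <- which(!evaluated, arr.ind = TRUE)
  cand <- tibble::tibble(ix = idx[, 1], iy = idx[, 2],
                         amt1 = x[idx[, 1]], amt2 = y[idx[, 2]])

  comps <- normalize_components(current_isobole, b)
  if (length(comps) == 0) {
    sel <- rep(TRUE, nrow(cand))
  } else {
    pts <- tibble::tibble(x = cand$amt1 / b[1], y = cand$amt2 / b[2])
    d <- rep(Inf, nrow(pts))
    for (cp in comps) d <- pmin(d, distance_to_polyline(pts, cp))
    sel <- d < spacing
  }

  structure(
    list(bounds = b, level = j + 1L, x = x, y = y,
         value = value, evaluated = evaluated, iter = iter,
         pending = cand[sel, ]),
    class = "dose_grid"
  )
}

# coerce an isobole argument (tibble, list of tibbles, NULL) to a list of
# normalized polylines
normalize_components <- function(iso, bounds) {
  if (is.null(iso)) return(list())
  if (is.data.frame(iso)) iso <- list(iso)
  iso <- Filter(function(cp) !is.null(cp) && nrow(cp) >= 2, iso)
  lapply(iso, function(cp) tibble::tibble(x = cp$x / bounds[1], y = cp$y / bounds[2]))
}

# evaluate all pending nodes of a grid with the objective (row-major order)
evaluate_pending <- function(grid, objective, iteration) {
  pd <- dplyr::arrange(grid$pending, .data$iy, .data$ix)
  if (nrow(pd) == 0) return(grid)
  for (r in seq_len(nrow(pd))) {
    v <- objective(pd$amt1[r], pd$amt2[r])
    if (!is.finite(v) || v < -1e-9 || v > 1 + 1e-9) {
      stop(sprintf("objective returned %s at (%g, %g); success rates must be in [0,1]",
                   format(v), pd$amt1[r], pd$amt2[r]), call. = FALSE)
    }
    grid$value[pd$ix[r], pd$iy[r]] <- min(1, max(0, v))
    grid$evaluated[pd$ix[r], pd$iy[r]] <- TRUE
    grid$iter[pd$ix[r], pd$iy[r]] <- iteration
  }
  grid$pending <- grid$pending[0, ]
  grid
}

grid_contour <- function(grid, level_value) {
  extract_contour(grid$value, grid$x, grid$y, level_value)
}

main_component <- function(comps) {
  if (length(comps) == 0) return(NULL)
  lens <- vapply(comps, polyline_length, numeric(1))
  comps[[which.max(lens)]]
}

classify_degenerate <- function(grid, target_rate) {
  if (all(grid$value >= target_rate, na.rm = TRUE)) {
    "entire space efficacious"
  } else {
    "entire space non-efficacious"
  }
}

#' Locate the effective isobole by adaptive dyadic grid refinement
#'
#' The two-dimensional generalization of bisection: starting from the nine
#' nodes of the level-1 lattice, the success-rate objective is evaluated,
#' the isobole at `target_rate` is estimated by linear-interpolation contour
#' extraction, the grid resolution is doubled, and new nodes are evaluated
#' only within one (pre-refinement) grid spacing of the current isobole
#' estimate. Iteration stops when the discrete Fréchet distance between
#' successive isobole estimates (normalized units) falls below `tol`, or
#' after `max_iter` iterations; after `j` iterations the lattice has
#' `2^j + 1` doses per drug.
#'
#' If the level-1 nodes all fall on one side of the target, one full-lattice
#' refinement to level 2 (25 nodes total) is performed before declaring the
#' space unbracketed, so steep sub-cell isoboles are not overlooked.
#'
#' @param objective Function `(amt1, amt2) -> success rate`, deterministic
#'   (freeze the population sample before calling).
#' @param target_rate Efficacy target in (0, 1).
#' @param bounds Length-2 dosing-space bounds `(amt1_max, amt2_max)`.
#' @param max_iter Maximum number of iterations (final level), >= 1.
#' @param tol Convergence tolerance on the Fréchet step, normalized units.
#' @param population_id Optional provenance tag stored in the result.
#' @return An object of class `fastisoboles_result`: `isobole` (polyline
#'   tibble, dose units; the longest contour component), `components` (all
#'   components), `iterations` (per-iteration log), `cache` (long-format
#'   table of evaluated nodes), `n_evaluations`, `converged`,
#'   `classification` (`NULL`, or the degenerate outcome when no isobole
#'   exists), plus the final `grid`.
#' @export
run_fastisoboles <- function(objective, target_rate, bounds, max_iter = 6,
                             tol = 2^-7, population_id = NA_integer_) {
  stopifnot(max_iter >= 1, target_rate > 0, target_rate < 1)
  grid <- init_grid(bounds)
  grid <- evaluate_pending(grid, objective, 1L)
  logs <- list(tibble::tibble(iteration = 1L, level = 1L,
                              n_new_evaluations = 9L,
                              n_evaluations_cum = 9L,
                              frechet_step = NA_real_))
  comps <- grid_contour(grid, target_rate)
  it <- 1L

  if (length(comps) == 0 && max_iter >= 2) {
    # bracket-check fallback: one full refinement at level 2 (25 nodes)
    grid <- refine(grid, NULL)
    grid <- evaluate_pending(grid, objective, 2L)
    it <- 2L
    logs[[2]] <- tibble::tibble(iteration = 2L, level = 2L,
                                n_new_evaluations = 16L,
                                n_evaluations_cum = 25L,
                                frechet_step = NA_real_)
    comps <- grid_contour(grid, target_rate)
  }

  if (length(comps) == 0) {
    return(new_fastisoboles_result(
      grid, comps, dplyr::bind_rows(logs), converged = FALSE,
      classification = classify_degenerate(grid, target_rate),
      target_rate = target_rate, tol = tol, population_id = population_id))
  }

  main_prev <- main_component(comps)
  converged <- FALSE
  while (it < max_iter) {
    grid <- refine(grid, comps)
    n_new <- nrow(grid$pending)
    it <- it + 1L
    grid <- evaluate_pending(grid, objective, it)
    comps <- grid_contour(grid, target_rate)
    if (length(comps) == 0) {
      return(new_fastisoboles_result(
        grid, comps, dplyr::bind_rows(logs), converged = FALSE,
        classification = classify_degenerate(grid, target_rate),
        target_rate = target_rate, tol = tol, population_id = population_id))
    }
    main_cur <- main_component(comps)
    step <- discrete_frechet(
      tibble::tibble(x = main_prev$x / bounds[1], y = main_prev$y / bounds[2]),
      tibble::tibble(x = main_cur$x / bounds[1], y = main_cur$y / bounds[2]))
    logs[[length(logs) + 1]] <- tibble::tibble(
      iteration = it, level = grid$level,
      n_new_evaluations = as.integer(n_new),
      n_evaluations_cum = sum(grid$evaluated),
      frechet_step = step)
    main_prev <- main_cur
    if (step < tol) { converged <- TRUE; break }
  }

  new_fastisoboles_result(grid, comps, dplyr::bind_rows(logs),
                          converged = converged, classification = NULL,
                          target_rate = target_rate, tol = tol,
                          population_id = population_id)
}

new_fastisoboles_result <- function(grid, comps, iterations, converged,
                                    classification, target_rate, tol,
                                    population_id, method = "fastisoboles") {
  idx <- which(grid$evaluated, arr.ind = TRUE)
  cache <- tibble::tibble(
    amt1 = grid$x[idx[, 1]], amt2 = grid$y[idx[, 2]],
    success_rate = grid$value[idx],
    iteration_first_evaluated = grid$iter[idx])
  cache <- dplyr::arrange(cache, .data$iteration_first_evaluated, .data$amt2, .data$amt1)
  main <- main_component(comps)
  structure(
    list(isobole = if (is.null(main)) tibble::tibble(x = numeric(), y = numeric()) else main,
         components = comps,
         iterations = iterations,
         cache = cache,
         n_evaluations = sum(grid$evaluated),
         converged = converged,
         classification = classification,
         target_rate = target_rate,
         bounds = grid$bounds,
         tol = tol,
         population_id = population_id,
         method = method,
         grid = grid),
    class = "fastisoboles_result")
}

#' @export
print.fastisoboles_result <- function(x, ...) {
  cat(sprintf("<fastisoboles_result> target %.3g on [0,%g] x [0,%g]\n",
              x$target_rate, x$bounds[1], x$bounds[2]))
  if (!is.null(x$classification)) {
    cat("  no isobole:", x$classification, "\n")
  } else {
    cat(sprintf("  isobole with %d vertices (%d components)\n",
                nrow(x$isobole), length(x$components)))
  }
  cat(sprintf("  %d evaluations over %d iterations; converged: %s\n",
              x$n_evaluations, max(x$iterations$iteration), x$converged))
  invisible(x)
}

#' Brute-force surface evaluation on the full dyadic lattice
#'
#' Evaluates the objective at every node of the level-`level` lattice
#' (`(2^level + 1)^2` evaluations) and extracts the isobole from the full
#' surface. Serves as the reference against which the adaptive search's
#' savings and accuracy are measured.
#'
#' @inheritParams run_fastisoboles
#' @param level Dyadic lattice level.
#' @return A `fastisoboles_result` with `method = "brute_force"`; its `grid`
#'   carries the fully evaluated surface.
#' @export
run_brute_force <- function(objective, target_rate, bounds, level = 6,
                            population_id = NA_integer_) {
  n <- 2^level + 1
  x <- seq(0, bounds[1], length.out = n)
  y <- seq(0, bounds[2], length.out = n)
  z <- eval_objective_grid(objective, x, y)
  z[] <- pmin(1, pmax(0, z)) # in-place: pmin/pmax would drop the dim
  grid <- structure(
    list(bounds = as.numeric(bounds), level = as.integer(level), x = x, y = y,
         value = z, evaluated = matrix(TRUE, n, n),
         iter = matrix(1L, n, n), pending = tibble::tibble()),
    class = "dose_grid")
  comps <- extract_contour(z, x, y, target_rate)
  logs <- tibble::tibble(iteration = 1L, level = as.integer(level),
                         n_new_evaluations = n * n,
                         n_evaluations_cum = n * n,
                         frechet_step = NA_real_)
  classification <- if (length(comps) == 0) classify_degenerate(grid, target_rate) else NULL
  new_fastisoboles_result(grid, comps, logs,
                          converged = length(comps) > 0,
                          classification = classification,
                          target_rate = target_rate, tol = NA_real_,
                          population_id = population_id,
                          method = "brute_force")
}
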