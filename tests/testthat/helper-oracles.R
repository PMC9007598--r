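# Independent oracles used across the suite. These deliberately use
# different formulations than the package internals.

# Discrete Fréchet by plain exhaustive recursion over all monotone couplings
# (no dynamic-programming table); feasible for short polylines only.
frechet_exhaustive <- function(a, b) {
  d <- function(i, j) sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d(1, 1))
    if (i == 1) return(max(rec(1, j - 1), d(1, j)))
    if (j == 1) return(max(rec(i - 1, 1), d(i, 1)))
    max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d(i, j))
  }
  rec(nrow(a), nrow(b))
}

# Winding-number containment (nonzero rule); for simple polygons it agrees
# with the even-odd rule away from the boundary.
winding_inside <- function(px, py, poly) {
  xs <- c(poly$x, poly$x[1]); ys <- c(poly$y, poly$y[1])
  wn <- 0L
  for (i in seq_len(length(xs) - 1)) {
    cr <- (xs[i + 1] - xs[i]) * (py - ys[i]) - (px - xs[i]) * (ys[i + 1] - ys[i])
    if (ys[i] <= py) {
      if (ys[i + 1] > py && cr > 0) wn <- wn + 1L
    } else {
      if (ys[i + 1] <= py && cr < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# star-shaped (hence simple) random polygon around a centre
random_simple_polygon <- function(n = 12, centre = c(0.5, 0.5)) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.1, 0.45)
  tibble::tibble(x = centre[1] + rad * cos(ang),
                 y = centre[2] + rad * sin(ang))
}

random_polyline <- function(n = 5) {
  tibble::tibble(x = stats::runif(n), y = stats::runif(n))
}

# dense-sampling oracle for point-to-polyline distance
distance_dense <- function(px, py, pl, per_segment = 1e4) {
  best <- Inf
  for (i in seq_len(nrow(pl) - 1)) {
    t <- seq(0, 1, length.out = per_segment)
    qx <- pl$x[i] + t * (pl$x[i + 1] - pl$x[i])
    qy <- pl$y[i] + t * (pl$y[i + 1] - pl$y[i])
    best <- min(best, min(sqrt((px - qx)^2 + (py - qy)^2)))
  }
  best
}

# shoelace signed area from first principles
shoelace <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# a small frozen malaria population for reuse across tests
small_malaria_setup <- function(n_pop = 1, n_subj = 50, seed = 7) {
  pd <- malaria_default_population()
  ens <- sample_ensemble(pd$uncertainty, pd$iiv, n_pop = n_pop,
                         n_subj = n_subj, seed = seed)
  model <- malaria_model()
  target <- efficacy_target(0.95)
  objectives <- lapply(ens$individuals, function(ind)
    population_objective(model, ind, target))
  list(ensemble = ens, model = model, target = target, objectives = objectives)
}
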