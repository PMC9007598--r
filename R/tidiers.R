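#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' the object's main tabular content, `glance()` a one-row summary.
#'
#' @param x A `fastisoboles_result`, `confidence_surface`,
#'   `population_ensemble` or `monotonicity_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name isocomb-tidiers
NULL

#' @rdname isocomb-tidiers
#' @export
tidy.fastisoboles_result <- function(x, ...) {
  if (nrow(x$isobole) == 0) {
    return(tibble::tibble(piece = integer(), x = numeric(), y = numeric()))
  }
  dplyr::bind_rows(purrr::imap(x$components, function(p, i)
    dplyr::mutate(p, piece = as.integer(i), .before = 1)))
}

#' @rdname isocomb-tidiers
#' @export
glance.fastisoboles_result <- function(x, ...) {
  fs <- x$iterations$frechet_step
  tibble::tibble(
    target_rate = x$target_rate,
    n_iterations = max(x$iterations$iteration),
    n_evaluations = x$n_evaluations,
    converged = x$converged,
    classification = x$classification %||% "isobole",
    final_frechet_step = if (all(is.na(fs))) NA_real_ else fs[max(which(!is.na(fs)))],
    final_resolution = 2^max(x$iterations$level) + 1)
}

#' @rdname isocomb-tidiers
#' @export
tidy.confidence_surface <- function(x, ...) tidy_surface(x)

#' @rdname isocomb-tidiers
#' @export
glance.confidence_surface <- function(x, ...) {
  tibble::tibble(
    n_pop = x$n_pop, target_rate = x$target_rate,
    resolution = length(x$x),
    mean_confidence = mean(x$values),
    min_confidence = min(x$values),
    max_confidence = max(x$values))
}

#' @rdname isocomb-tidiers
#' @export
tidy.population_ensemble <- function(x, ...) {
  dplyr::bind_rows(x$individuals)
}

#' @rdname isocomb-tidiers
#' @export
glance.population_ensemble <- function(x, ...) {
  tibble::tibble(n_pop = x$n_pop,
                 n_subj = paste(unique(x$n_subj), collapse = "/"),
                 seed = x$seed,
                 n_parameters = ncol(x$populations) - 1L)
}

#' @rdname isocomb-tidiers
#' @export
tidy.monotonicity_report <- function(x, ...) x$violations

#' @rdname isocomb-tidiers
#' @export
glance.monotonicity_report <- function(x, ...) {
  tibble::tibble(ok = x$ok, n_violations = nrow(x$violations), tol = x$tol,
                 max_drop = if (nrow(x$violations)) max(x$violations$drop) else 0)
}
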