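#' Parameter-uncertainty distribution
#'
#' Describes the sampling distribution of the population-parameter estimates
#' (typically the asymptotic maximum-likelihood covariance). Positive
#' parameters are handled on the log scale, so `mean` holds log point
#' estimates for those entries and `covariance` is the covariance on the
#' transformed scale; this matches standard nonlinear mixed-effects practice.
#'
#' @param mean Named numeric vector of point estimates on the sampling scale.
#' @param covariance Symmetric positive-semidefinite covariance matrix
#'   (use `0` or a zero matrix for a degenerate, uncertainty-free
#'   distribution).
#' @param parameter_names Optional labels; default `names(mean)`.
#' @param log_scale Logical vector (recycled): which parameters are sampled
#'   on the log scale and exponentiated on output. Default all `TRUE`.
#' @return An object of class `uncertainty_dist`.
#' @export
uncertainty_distribution <- function(mean, covariance,
                                     parameter_names = names(mean),
                                     log_scale = TRUE) {
  p <- length(mean)
  if (is.null(parameter_names) || length(parameter_names) != p) {
    stop("`mean` must be named (or supply `parameter_names`)", call. = FALSE)
  }
  if (length(covariance) == 1) covariance <- diag(rep(as.numeric(covariance), p), p)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(p, p))) {
    stop("covariance dimensions inconsistent with `mean`", call. = FALSE)
  }
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop("covariance must be symmetric (within 1e-10)", call. = FALSE)
  }
  log_scale <- rep_len(log_scale, p)
  structure(
    list(mean = stats::setNames(as.numeric(mean), parameter_names),
         covariance = covariance,
         parameter_names = parameter_names,
         log_scale = log_scale),
    class = "uncertainty_dist"
  )
}

#' Inter-individual variability specification
#'
#' Log-normal IIV with diagonal covariance by default; an optional
#' correlation matrix couples the random effects. Variances are on the log
#' scale (the usual omega-squared parameterization). A variance may instead
#' be drawn per population: if the uncertainty distribution contains a
#' parameter named `omega2_<p>`, that realization overrides the fixed entry
#' for `<p>`.
#'
#' @param variances Named numeric vector of log-scale IIV variances
#'   (entries >= 0); names must match model parameter names.
#' @param correlation Optional correlation matrix for the random effects
#'   (dimnames matching `names(variances)`); default independent.
#' @return An object of class `iiv_spec`.
#' @export
iiv_spec <- function(variances, correlation = NULL) {
  if (is.null(names(variances))) stop("`variances` must be named", call. = FALSE)
  if (any(variances < 0)) stop("IIV variances must be >= 0", call. = FALSE)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    k <- length(variances)
    if (!all(dim(correlation) == c(k, k))) {
      stop("correlation dimensions inconsistent with `variances`", call. = FALSE)
    }
  }
  structure(list(variances = variances, correlation = correlation),
            class = "iiv_spec")
}

check_psd <- function(covariance) {
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  tol <- -1e-8 * max(1, abs(ev[1]))
  if (any(ev < tol)) {
    bad <- ev[which.min(ev)]
    stop(sprintf("covariance is not positive semi-definite: eigenvalue %.6g < 0", bad),
         call. = FALSE)
  }
  invisible(ev)
}

draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Sample a hierarchical population ensemble
#'
#' Two-step Monte-Carlo sampling: population parameters are drawn
#' multivariate-normal from the uncertainty distribution on the transformed
#' (log) scale and back-transformed; for each population, subject-level
#' parameters are drawn log-normal around the population values with the
#' population's IIV variances. The whole ensemble is sampled up-front under a
#' seed chain (master seed -> per-population seeds -> per-subject seeds), so
#' every draw is reproducible from `(seed, population_id, subject_id)` and
#' independent of the order in which doses are later evaluated.
#'
#' @param u An [uncertainty_distribution()].
#' @param iiv An [iiv_spec()].
#' @param n_pop Number of population realizations (>= 1).
#' @param n_subj Subjects per population (>= 1); optionally a vector of
#'   length `n_pop` for population-specific sizes.
#' @param seed Master RNG seed (integer).
#' @return An object of class `population_ensemble`: `$populations` is a
#'   tibble (one row per population, columns = parameters), `$individuals` a
#'   list of per-population tibbles (one row per subject).
#' @export
sample_ensemble <- function(u, iiv, n_pop, n_subj, seed) {
  stopifnot(inherits(u, "uncertainty_dist"), inherits(iiv, "iiv_spec"),
            n_pop >= 1, all(n_subj >= 1))
  check_psd(u$covariance)
  n_subj <- rep_len(as.integer(n_subj), n_pop)
  iiv_names <- names(iiv$variances)
  unknown <- setdiff(iiv_names, u$parameter_names)
  if (length(unknown)) {
    stop("IIV parameters not in the uncertainty distribution: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  set.seed(seed)
  pop_seeds <- draw_seeds(n_pop)

  k <- length(iiv_names)
  omega_corr <- if (is.null(iiv$correlation)) diag(k) else iiv$correlation

  pops <- vector("list", n_pop)
  indivs <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    set.seed(pop_seeds[i])
    z <- MASS::mvrnorm(1, mu = u$mean, Sigma = u$covariance)
    theta <- ifelse(u$log_scale, exp(z), z)
    names(theta) <- u$parameter_names

    # per-population IIV variances: overridden by omega2_<p> draws if present
    om2 <- iiv$variances
    for (p in iiv_names) {
      op <- paste0("omega2_", p)
      if (op %in% u$parameter_names) om2[p] <- theta[[op]]
    }
    om2 <- pmax(om2, 0)

    subj_seeds <- draw_seeds(n_subj[i])
    sd_vec <- sqrt(om2)
    Sigma_eta <- diag(sd_vec, k) %*% omega_corr %*% diag(sd_vec, k)
    subj <- matrix(NA_real_, n_subj[i], length(theta),
                   dimnames = list(NULL, u$parameter_names))
    for (j in seq_len(n_subj[i])) {
      set.seed(subj_seeds[j])
      eta <- MASS::mvrnorm(1, mu = rep(0, k), Sigma = Sigma_eta)
      v <- theta
      v[iiv_names] <- theta[iiv_names] * exp(eta)
      subj[j, ] <- v
    }
    pops[[i]] <- tibble::tibble(population_id = i, !!!as.list(theta))
    indivs[[i]] <- dplyr::bind_cols(
      tibble::tibble(population_id = i, subject_id = seq_len(n_subj[i])),
      tibble::as_tibble(subj)
    )
  }

  structure(
    list(populations = dplyr::bind_rows(pops),
         individuals = indivs,
         n_pop = n_pop, n_subj = n_subj, seed = seed,
         uncertainty = u, iiv = iiv),
    class = "population_ensemble"
  )
}

#' @export
print.population_ensemble <- function(x, ...) {
  cat(sprintf("<population_ensemble> %d populations x %s subjects (seed %d)\n",
              x$n_pop, paste(unique(x$n_subj), collapse = "/"), x$seed))
  print(utils::head(x$populations, 3))
  invisible(x)
}

#' Efficacy target
#'
#' The prespecified population-level success-rate threshold together with
#' the per-individual success predicate (for the PK/PD testbeds: endpoint
#' value below a threshold at an evaluation time).
#'
#' @param target_rate Fraction in (0, 1), e.g. `0.95` for a 95% success rate.
#' @param predicate Name of the per-individual success rule (informational).
#' @param threshold,time Predicate parameters (endpoint threshold and
#'   evaluation time), passed through to the model.
#' @return An object of class `efficacy_target`.
#' @export
efficacy_target <- function(target_rate = 0.95, predicate = "endpoint_below",
                            threshold = 10, time = 28) {
  stopifnot(target_rate > 0, target_rate < 1)
  structure(list(target_rate = target_rate, predicate = predicate,
                 threshold = threshold, time = time),
            class = "efficacy_target")
}

#' Population success rate at one dose combination
#'
#' Fraction of a population's simulated subjects whose endpoint satisfies the
#' per-individual success predicate. Deterministic given the frozen
#' individual-parameter sample (common random numbers across doses).
#'
#' @param model A dose-response model (e.g. [malaria_model()]).
#' @param individuals Tibble of subject parameters (one row per subject), as
#'   found in `ensemble$individuals[[i]]`.
#' @param dose_pair Numeric length-2 vector `(amt1, amt2)`, doses >= 0.
#' @param target An [efficacy_target()].
#' @return Success rate in `[0, 1]` (a multiple of `1/n_subj`).
#' @export
success_rate <- function(model, individuals, dose_pair, target = efficacy_target()) {
  stopifnot(all(dose_pair >= 0))
  obj <- population_objective(model, individuals, target)
  obj(dose_pair[1], dose_pair[2])
}

#' One-dimensional effective-dose search by bisection
#'
#' Finds the effective dose (the dose at which a monotone dose to
#' success-rate function reaches the target rate) by binary search. Two
#' evaluations validate the bracket; each iteration adds exactly one
#' evaluation, so `n_iter` iterations cost `n_iter + 2` evaluations and the
#' final bracket has width `(hi - lo) / 2^n_iter`. The returned dose is the
#' midpoint of the final bracket.
#'
#' @param objective Function of one dose returning a success rate; must be
#'   non-decreasing.
#' @param target_rate Target success rate.
#' @param lo,hi Bracket bounds; requires `objective(lo) < target_rate <=
#'   objective(hi)`.
#' @param n_iter Number of halvings (>= 1).
#' @return Effective-dose estimate (midpoint of the final bracket), with
#'   attributes `bracket` and `n_evaluations`.
#' @export
effective_dose_bisection <- function(objective, target_rate, lo, hi, n_iter = 20) {
  stopifnot(n_iter >= 1, hi > lo)
  n_eval <- 0L
  f <- function(d) { n_eval <<- n_eval + 1L; objective(d) }
  flo <- f(lo); fhi <- f(hi)
  if (flo >= target_rate) {
    stop("invalid bracket: already efficacious at the lower bound (always efficacious)",
         call. = FALSE)
  }
  if (fhi < target_rate) {
    stop("invalid bracket: target not reached at the upper bound (never efficacious within bounds)",
         call. = FALSE)
  }
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target_rate) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), n_evaluations = n_eval)
}

#' Confidence levels from a sample of effective doses
#'
#' The confidence level of reaching the efficacy target at dose `d` is the
#' fraction of population realizations whose effective dose is at most `d`:
#' the empirical cumulative distribution function of effective doses
#' (right-continuous, non-decreasing).
#'
#' @param eds Numeric vector of effective doses (one per population),
#'   non-empty.
#' @param query_doses Doses at which to evaluate the confidence level.
#' @return Tibble with columns `dose` and `confidence`.
#' @export
confidence_from_effective_doses <- function(eds, query_doses) {
  if (length(eds) == 0) stop("`eds` must be non-empty", call. = FALSE)
  Fhat <- stats::ecdf(as.numeric(eds))
  tibble::tibble(dose = as.numeric(query_doses),
                 confidence = Fhat(as.numeric(query_doses)))
}

#' Monotonicity pre-check of a success-rate surface
#'
#' The isobole search assumes the success-rate surface is non-decreasing in
#' each dose. This brute-force probe evaluates the objective on a small
#' lattice and flags every pair of neighbouring nodes where the success rate
#' drops by more than `tol` when either dose increases.
#'
#' @param objective Function `(amt1, amt2) -> success rate`.
#' @param x,y Probe lattice coordinates (each of length >= 3).
#' @param tol Drop tolerance; decreases up to `tol` are ignored.
#' @return An object of class `monotonicity_report`: list with `ok` (logical)
#'   and `violations` (tibble of offending node pairs with the observed
#'   drop).
#' @export
check_monotonicity <- function(objective, x, y, tol = 0) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  z <- eval_objective_grid(objective, x, y)
  viol <- list()
  nx <- length(x); ny <- length(y)
  for (i in seq_len(nx - 1)) {
    drop <- z[i, ] - z[i + 1, ]
    bad <- which(drop > tol)
    if (length(bad)) {
      viol[[length(viol) + 1]] <- tibble::tibble(
        axis = "amt1", x_from = x[i], x_to = x[i + 1], other = y[bad],
        drop = drop[bad])
    }
  }
  for (j in seq_len(ny - 1)) {
    drop <- z[, j] - z[, j + 1]
    bad <- which(drop > tol)
    if (length(bad)) {
      viol[[length(viol) + 1]] <- tibble::tibble(
        axis = "amt2", x_from = y[j], x_to = y[j + 1], other = x[bad],
        drop = drop[bad])
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(axis = character(), x_from = numeric(), x_to = numeric(),
                   other = numeric(), drop = numeric())
  structure(list(ok = nrow(violations) == 0, violations = violations,
                 tol = tol, surface = z, x = x, y = y),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, ...) {
  if (x$ok) {
    cat("monotonicity check: clean (tol =", x$tol, ")\n")
  } else {
    cat("monotonicity check:", nrow(x$violations), "violations (tol =", x$tol, ")\n")
    print(x$violations)
  }
  invisible(x)
}

# evaluate a scalar objective on a lattice; objective may be vectorized or not
eval_objective_grid <- function(objective, x, y) {
  g <- expand.grid(x = x, y = y)
  v <- tryCatch(objective(g$x, g$y), error = function(e) NULL)
  if (is.null(v) || length(v) != nrow(g)) {
    v <- mapply(function(a, b) objective(a, b), g$x, g$y)
  }
  matrix(v, nrow = length(x), ncol = length(y))
}

#' Rank population parameters by influence on the effective isobole
#'
#' Correlates each population parameter's draw with a scalar summary of the
#' corresponding effective isobole's location: the area of the failure
#' polygon in normalized dose space (0 for an all-efficacious population, 1
#' for all-non-efficacious). Spearman rank correlation is used so monotone
#' nonlinear dependencies are picked up.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param isoboles List of per-population isobole results (from
#'   [run_fastisoboles()]) or polyline tibbles, one per population, in the
#'   same order as the ensemble.
#' @param bounds Length-2 dosing-space bounds `(amt1_max, amt2_max)`
#'   (needed when raw polylines are supplied).
#' @return Tibble with columns `parameter`, `rho`, sorted by `abs(rho)`
#'   descending; the isobole summary used is attached as attribute
#'   `summary_values`.
#' @export
rank_parameter_influence <- function(ensemble, isoboles, bounds = NULL) {
  stopifnot(inherits(ensemble, "population_ensemble"))
  if (length(isoboles) != ensemble$n_pop) {
    stop("need exactly one isobole per population", call. = FALSE)
  }
  if (ensemble$n_pop < 3) {
    stop("parameter influence requires at least 3 populations", call. = FALSE)
  }
  area <- vapply(isoboles, failure_area, numeric(1), bounds = bounds)
  pars <- dplyr::select(ensemble$populations, -"population_id")
  rho <- vapply(pars, function(v) {
    if (stats::sd(v) == 0 || stats::sd(area) == 0) return(0)
    suppressWarnings(stats::cor(v, area, method = "spearman"))
  }, numeric(1))
  out <- tibble::tibble(parameter = names(rho), rho = unname(rho))
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$rho)))
  attr(out, "summary_values") <- area
  out
}

# normalized failure-polygon area for one isobole result or raw polyline
failure_area <- function(iso, bounds = NULL) {
  if (inherits(iso, "fastisoboles_result")) {
    if (!is.null(iso$classification)) {
      return(switch(iso$classification,
                    "entire space efficacious" = 0,
                    "entire space non-efficacious" = 1,
                    stop("unknown classification", call. = FALSE)))
    }
    bounds <- iso$bounds
    pl <- iso$isobole
  } else {
    if (is.null(bounds)) stop("`bounds` required for raw polylines", call. = FALSE)
    pl <- iso
  }
  norm <- tibble::tibble(x = pl$x / bounds[1], y = pl$y / bounds[2])
  poly <- isobole_to_polygon(norm, bounds = c(1, 1))
  polygon_area(poly)
}
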