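#' Run configuration for the isobole pipeline
#'
#' A validated list of everything one end-to-end run needs: the model, the
#' uncertainty/IIV specification, the efficacy target, dosing bounds,
#' ensemble sizes, iteration limits and the master seed. Unknown keys are
#' errors (fail-fast); every run writes the fully resolved configuration
#' next to its outputs.
#'
#' Defaults mirror the malaria study conditions: target success rate 0.95,
#' 800 mg maximum feasible dose per drug, 750 populations of 1500 subjects,
#' six fastIsoboles iterations, convergence tolerance `2^-7` (one cell at
#' the practical maximum resolution), confidence levels 0.50 and 0.95.
#'
#' @param ... Configuration entries overriding the defaults; see
#'   `default_config()` in the source for the full key set.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  validate_config(utils::modifyList(default_config(), list(...)))
}

default_config <- function() {
  list(
    model = list(type = "malaria"),
    target_rate = 0.95,
    bounds = c(800, 800),
    n_pop = 750,
    n_subj = 1500,
    max_iter = 6,
    tol = 2^-7,
    resolution = NULL,
    seed = 1,
    confidence_levels = c(0.50, 0.95),
    n_quad = 401
  )
}

validate_config <- function(config) {
  known <- names(default_config())
  bad <- setdiff(names(config), known)
  problems <- character(0)
  if (length(bad)) problems <- c(problems, paste("unknown keys:", paste(bad, collapse = ", ")))
  need <- setdiff(known, c("resolution"))
  miss <- need[!need %in% names(config) | vapply(config[intersect(need, names(config))], is.null, logical(1))[match(need, intersect(need, names(config)))]]
  miss <- setdiff(need, names(config))
  if (length(miss)) problems <- c(problems, paste("missing keys:", paste(miss, collapse = ", ")))
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  if (!length(miss)) {
    chk(is.list(config$model) && !is.null(config$model$type), "model: needs a `type`")
    if (is.list(config$model) && !is.null(config$model$type)) {
      chk(config$model$type %in% c("malaria", "additive", "bliss", "probit_additive",
                                   "nonmonotone_bump"),
          "model$type: unknown model type")
    }
    chk(config$target_rate > 0 && config$target_rate < 1, "target_rate: must be in (0,1)")
    chk(length(config$bounds) == 2 && all(config$bounds > 0), "bounds: two positive doses")
    chk(config$n_pop >= 1, "n_pop: must be >= 1")
    chk(all(config$n_subj >= 1), "n_subj: must be >= 1")
    chk(config$max_iter >= 1, "max_iter: must be >= 1")
    chk(config$tol > 0, "tol: must be > 0")
    chk(is.numeric(config$seed) && length(config$seed) == 1, "seed: one integer")
    chk(all(config$confidence_levels > 0 & config$confidence_levels < 1),
        "confidence_levels: in (0,1)")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  config$bounds <- as.numeric(config$bounds)
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_config <- function(path) {
  validate_config(utils::modifyList(default_config(), yaml::read_yaml(path)))
}

write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$resolution <- cfg$resolution %||% "default"
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# build the model, target, ensemble and one frozen objective per population
build_run <- function(config) {
  target <- efficacy_target(target_rate = config$target_rate)
  if (config$model$type == "malaria") {
    params <- malaria_default_params()
    if (!is.null(config$model$params)) {
      params[names(config$model$params)] <- unlist(config$model$params)
    }
    model <- malaria_model(params = params)
    target <- efficacy_target(target_rate = config$target_rate,
                              threshold = model$endpoint$threshold,
                              time = model$endpoint$time)
    popdef <- malaria_default_population()
    ens <- sample_ensemble(popdef$uncertainty, popdef$iiv,
                           n_pop = config$n_pop, n_subj = config$n_subj,
                           seed = config$seed)
    objectives <- lapply(ens$individuals, function(ind)
      population_objective(model, ind, target, n_quad = config$n_quad))
  } else {
    surf <- do.call(analytic_surface,
                    c(list(family = config$model$type, bounds = config$bounds),
                      config$model$params %||% list()))
    ens <- NULL
    objectives <- rep(list(surf$f), config$n_pop)
  }
  list(target = target, ensemble = ens, objectives = objectives)
}

#' Per-population effective-isobole runs
#'
#' Samples the population ensemble, runs the adaptive isobole search for each
#' population, and writes one isobole polyline file per population, a
#' combined per-iteration evaluation log, and a summary table to `out_dir`
#' (plus the resolved configuration). Outputs are deterministic given the
#' seed: rerunning the same configuration yields byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param brute_force If `TRUE`, evaluate the full final-level lattice
#'   instead of the adaptive search (reference mode).
#' @return Invisibly, a list with `results` (per-population
#'   `fastisoboles_result`s), `ensemble`, and `summary` tibble.
#' @export
run_isoboles <- function(config, out_dir, brute_force = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rn <- build_run(config)
  results <- vector("list", config$n_pop)
  logs <- vector("list", config$n_pop)
  for (i in seq_len(config$n_pop)) {
    res <- if (brute_force) {
      run_brute_force(rn$objectives[[i]], config$target_rate, config$bounds,
                      level = config$max_iter, population_id = i)
    } else {
      run_fastisoboles(rn$objectives[[i]], config$target_rate, config$bounds,
                       max_iter = config$max_iter, tol = config$tol,
                       population_id = i)
    }
    results[[i]] <- res
    logs[[i]] <- dplyr::mutate(res$iterations, population_id = i, .before = 1)
    prov <- list(population_id = i, target_rate = config$target_rate,
                 bounds = config$bounds, seed = config$seed,
                 n_evaluations = res$n_evaluations,
                 level = res$grid$level,
                 converged = res$converged,
                 classification = res$classification %||% "isobole")
    write_polyline(res$components, file.path(out_dir, sprintf("isobole_pop_%04d.csv", i)),
                   provenance = prov)
  }
  summary <- tibble::tibble(
    population_id = seq_len(config$n_pop),
    n_evaluations = vapply(results, `[[`, numeric(1), "n_evaluations"),
    converged = vapply(results, `[[`, logical(1), "converged"),
    classification = vapply(results, function(r) r$classification %||% "isobole",
                            character(1)),
    final_frechet_step = vapply(results, function(r) {
      fs <- r$iterations$frechet_step
      if (all(is.na(fs))) NA_real_ else fs[max(which(!is.na(fs)))]
    }, numeric(1)))
  write_delim_prov(dplyr::bind_rows(logs), file.path(out_dir, "evaluation_log.csv"),
                   provenance = list(seed = config$seed))
  write_delim_prov(summary, file.path(out_dir, "summary.csv"),
                   provenance = list(seed = config$seed))
  write_config(config, file.path(out_dir, "config_resolved.yaml"))
  if (!is.null(rn$ensemble)) {
    write_ensemble(rn$ensemble, file.path(out_dir, "ensemble.csv"))
  }
  invisible(list(results = results, ensemble = rn$ensemble, summary = summary,
                 target = rn$target, objectives = rn$objectives))
}

# reconstruct lightweight isobole results from a directory of polyline files
read_isobole_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^isobole_pop_\\d+\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no isobole files found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    pieces <- read_polyline(f)
    prov <- attr(pieces, "provenance")
    bounds <- as.numeric(strsplit(prov$bounds, " +")[[1]])
    cls <- prov$classification
    main <- if (length(pieces)) main_component(pieces) else
      tibble::tibble(x = numeric(), y = numeric())
    structure(
      list(isobole = main, components = pieces,
           classification = if (identical(cls, "isobole")) NULL else cls,
           bounds = bounds,
           target_rate = as.numeric(prov$target_rate),
           grid = list(level = as.integer(prov$level %||% 6L)),
           n_evaluations = as.numeric(prov$n_evaluations %||% NA),
           converged = as.logical(prov$converged %||% NA)),
      class = "fastisoboles_result")
  })
}

#' Aggregate isobole runs into a confidence surface and write outputs
#'
#' @param isoboles Either the `results` list from [run_isoboles()] or a
#'   directory containing `isobole_pop_*.csv` files.
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `surface` (`confidence_surface`) and
#'   `confidence_isoboles` (named list of polylines per requested level).
#' @export
run_aggregate <- function(isoboles, config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(isoboles)) isoboles <- read_isobole_dir(isoboles)
  surface <- aggregate_isoboles(isoboles, bounds = config$bounds,
                                resolution = config$resolution,
                                target_rate = config$target_rate)
  write_surface(surface, file.path(out_dir, "confidence_surface.csv"),
                provenance = list(seed = config$seed,
                                  n_subj = paste(config$n_subj, collapse = " ")))
  iso_out <- list()
  for (lev in config$confidence_levels) {
    ci <- confidence_isobole(surface, lev)
    iso_out[[sprintf("%g", lev)]] <- ci
    comps <- attr(ci, "components") %||% list(ci)
    write_polyline(comps,
                   file.path(out_dir, sprintf("confidence_isobole_%03d.csv",
                                              round(100 * lev))),
                   provenance = list(confidence_level = lev,
                                     target_rate = config$target_rate,
                                     seed = config$seed,
                                     n_pop = surface$n_pop,
                                     bounds = config$bounds))
  }
  invisible(list(surface = surface, confidence_isoboles = iso_out))
}

#' End-to-end pipeline: ensemble, per-population isoboles, aggregation
#'
#' Composes [run_isoboles()] and [run_aggregate()] and writes a
#' machine-readable run manifest including the savings ratio relative to the
#' full-grid equivalent `(2^j + 1)^2 * n_pop` evaluations.
#'
#' @inheritParams run_isoboles
#' @return Invisibly, a list with `isoboles`, `aggregate` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, brute_force = FALSE) {
  config <- validate_config(config)
  iso <- run_isoboles(config, out_dir, brute_force = brute_force)
  agg <- run_aggregate(iso$results, config, out_dir)
  total <- sum(iso$summary$n_evaluations)
  full <- (2^config$max_iter + 1)^2 * config$n_pop
  manifest <- list(
    seed = config$seed, n_pop = config$n_pop,
    n_subj = paste(config$n_subj, collapse = " "),
    target_rate = config$target_rate,
    max_iter = config$max_iter,
    bounds = config$bounds,
    total_evaluations = total,
    full_grid_equivalent = full,
    savings_ratio = full / total,
    n_converged = sum(iso$summary$converged),
    surface_resolution = length(agg$surface$x))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(isoboles = iso, aggregate = agg, manifest = manifest))
}

#' Brute-force confidence surface (reference path)
#'
#' Evaluates every population's success rate at every node of a uniform
#' lattice and counts, per node, the fraction of populations meeting the
#' efficacy target. This is the direct population-counting construction the
#' adaptive pipeline approximates, used as the reference in accuracy checks.
#'
#' @param objectives List of frozen per-population objectives.
#' @param target_rate Efficacy target.
#' @param bounds Dosing-space bounds.
#' @param resolution Nodes per axis.
#' @return A `confidence_surface`.
#' @export
brute_force_confidence <- function(objectives, target_rate, bounds, resolution) {
  x <- seq(0, bounds[1], length.out = resolution)
  y <- seq(0, bounds[2], length.out = resolution)
  acc <- matrix(0, resolution, resolution)
  for (obj in objectives) {
    z <- eval_objective_grid(obj, x, y)
    acc <- acc + (z >= target_rate)
  }
  structure(
    list(x = x, y = y, values = acc / length(objectives),
         n_pop = length(objectives), target_rate = target_rate,
         bounds = as.numeric(bounds)),
    class = "confidence_surface")
}

#' Monotonicity pre-check for a configured run
#'
#' Probes a few populations' success-rate surfaces on a small lattice before
#' committing to the full ensemble, as the isobole search assumes monotone
#' surfaces.
#'
#' @param config A [run_config()].
#' @param n_pop_probe Number of probe populations.
#' @param probe_resolution Probe lattice nodes per axis (>= 3).
#' @param tol Allowed success-rate drop.
#' @return List of `monotonicity_report`s, one per probe population.
#' @export
check_monotonicity_run <- function(config, n_pop_probe = 3,
                                   probe_resolution = 9, tol = 0) {
  config <- validate_config(config)
  config$n_pop <- n_pop_probe
  rn <- build_run(config)
  x <- seq(0, config$bounds[1], length.out = probe_resolution)
  y <- seq(0, config$bounds[2], length.out = probe_resolution)
  lapply(rn$objectives, check_monotonicity, x = x, y = y, tol = tol)
}
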