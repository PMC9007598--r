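#' Delimited-text serialization of isoboles, surfaces and caches
#'
#' All outputs are plain comma-delimited text with a header row, preceded by
#' `#`-prefixed provenance comment lines (key: value). Numbers are written
#' with 17 significant digits so files round-trip through the readers
#' bit-exactly, and nothing time- or host-dependent is written, so identical
#' runs produce byte-identical files. Multiple contour components within one
#' polyline file are separated by `NaN,NaN` rows.
#'
#' @param polyline Tibble with columns `x`, `y` and optionally `piece`, or a
#'   list of polyline tibbles (one per component).
#' @param path Output file path.
#' @param provenance Named list written as `# key: value` comment lines.
#' @return The path, invisibly.
#' @name isocomb-io
NULL

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

write_delim_prov <- function(df, path, provenance = NULL) {
  lines <- character(0)
  if (length(provenance)) {
    lines <- sprintf("# %s: %s", names(provenance),
                     vapply(provenance, function(v) paste(format(v, digits = 15), collapse = " "),
                            character(1)))
  }
  lines <- c(lines, paste(names(df), collapse = ","))
  if (nrow(df)) {
    cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

read_delim_prov <- function(path) {
  lines <- readLines(path)
  is_com <- startsWith(lines, "#")
  prov <- list()
  if (any(is_com)) {
    kv <- sub("^# ", "", lines[is_com])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ?", "", kv)
    prov <- stats::setNames(as.list(vals), keys)
  }
  body <- lines[!is_com]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  attr(df, "provenance") <- prov
  tibble::as_tibble(df)
}

#' @rdname isocomb-io
#' @export
write_polyline <- function(polyline, path, provenance = NULL) {
  if (is.data.frame(polyline)) {
    pieces <- if ("piece" %in% names(polyline)) {
      lapply(split(polyline, polyline$piece), function(p) p[, c("x", "y")])
    } else list(polyline[, c("x", "y")])
  } else {
    pieces <- lapply(polyline, function(p) p[, c("x", "y")])
  }
  sep_row <- tibble::tibble(x = NaN, y = NaN)
  body <- dplyr::bind_rows(
    purrr::imap(pieces, function(p, i) {
      p <- tibble::as_tibble(p)
      if (as.integer(i) > 1 || (is.character(i) && i != names(pieces)[1])) {
        dplyr::bind_rows(sep_row, p)
      } else p
    })
  )
  # ensure a single leading piece has no separator
  write_delim_prov(body, path, provenance)
}

#' @rdname isocomb-io
#' @export
read_polyline <- function(path) {
  df <- read_delim_prov(path)
  prov <- attr(df, "provenance")
  brk <- is.nan(df$x) & is.nan(df$y)
  piece <- cumsum(brk) + 1L
  df <- df[!brk, ]
  df$piece <- piece[!brk]
  pieces <- lapply(split(seq_len(nrow(df)), df$piece), function(ii)
    tibble::tibble(x = df$x[ii], y = df$y[ii]))
  names(pieces) <- NULL
  attr(pieces, "provenance") <- prov
  pieces
}

#' @rdname isocomb-io
#' @param surface A `confidence_surface`.
#' @export
write_surface <- function(surface, path, provenance = NULL) {
  stopifnot(inherits(surface, "confidence_surface"))
  long <- tidy_surface(surface)
  prov <- c(list(n_pop = surface$n_pop, target_rate = surface$target_rate,
                 resolution = length(surface$x),
                 bounds = surface$bounds), provenance)
  write_delim_prov(long, path, prov)
}

#' @rdname isocomb-io
#' @export
read_surface <- function(path) {
  df <- read_delim_prov(path)
  prov <- attr(df, "provenance")
  x <- sort(unique(df$amt1)); y <- sort(unique(df$amt2))
  values <- matrix(NA_real_, length(x), length(y))
  values[cbind(match(df$amt1, x), match(df$amt2, y))] <- df$confidence
  structure(
    list(x = x, y = y, values = values,
         n_pop = as.integer(prov$n_pop %||% NA),
         target_rate = as.numeric(prov$target_rate %||% NA),
         bounds = c(max(x), max(y))),
    class = "confidence_surface")
}

tidy_surface <- function(surface) {
  tibble::tibble(
    amt1 = rep(surface$x, times = length(surface$y)),
    amt2 = rep(surface$y, each = length(surface$x)),
    confidence = as.vector(surface$values))
}

#' @rdname isocomb-io
#' @param result A `fastisoboles_result` whose evaluation cache to write.
#' @export
write_cache <- function(result, path, provenance = NULL) {
  stopifnot(inherits(result, "fastisoboles_result"))
  prov <- c(list(target_rate = result$target_rate, bounds = result$bounds,
                 n_evaluations = result$n_evaluations,
                 converged = result$converged,
                 method = result$method), provenance)
  write_delim_prov(result$cache, path, prov)
}

#' @rdname isocomb-io
#' @param ensemble A `population_ensemble` to export (one row per subject).
#' @export
write_ensemble <- function(ensemble, path, provenance = NULL) {
  stopifnot(inherits(ensemble, "population_ensemble"))
  long <- dplyr::bind_rows(ensemble$individuals)
  prov <- c(list(n_pop = ensemble$n_pop,
                 n_subj = paste(unique(ensemble$n_subj), collapse = " "),
                 seed = ensemble$seed), provenance)
  write_delim_prov(long, path, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
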