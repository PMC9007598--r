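#' Analytic dose-response fixture surfaces
#'
#' Closed-form success-rate surfaces with exactly known isoboles, used as
#' oracles for the isobole-search and aggregation algorithms. Families:
#'
#' * `additive` — `f = (w1*d1/b1 + w2*d2/b2) / (w1 + w2)`; every isobole is a
#'   straight segment.
#' * `bliss` — per-drug Hill effects combined by Bliss independence
#'   `e1 + e2 - e1*e2`; the isobole is obtained by analytic inversion of the
#'   second drug's Hill function along rays of constant `d1`.
#' * `probit_additive` — `f = pnorm(a1*d1 + a2*d2 - c)`; straight isoboles.
#' * `nonmonotone_bump` — additive surface minus a Gaussian dip, giving a
#'   locally decreasing response; used to exercise the monotonicity
#'   pre-check. No single contour exists, so `exact_isobole()` errors.
#'
#' @param family One of `"additive"`, `"bliss"`, `"probit_additive"`,
#'   `"nonmonotone_bump"`.
#' @param bounds Length-2 dosing-space bounds `(amt1_max, amt2_max)`.
#' @param ... Family parameters overriding the defaults (see Details in the
#'   source; all have sensible defaults on the unit square).
#' @return An object of class `analytic_surface` with elements `f(d1, d2)`
#'   (vectorized), `exact_isobole(level)` returning a polyline tibble, and
#'   `bounds`.
#' @examples
#' s <- analytic_surface("additive", bounds = c(1, 1))
#' s$f(0.5, 0.5)
#' head(s$exact_isobole(0.5))
#' @export
analytic_surface <- function(family = c("additive", "bliss", "probit_additive",
                                        "nonmonotone_bump"),
                             bounds = c(1, 1), ...) {
  family <- match.arg(family)
  stopifnot(length(bounds) == 2, all(bounds > 0))
  pars <- list(...)
  b1 <- bounds[1]; b2 <- bounds[2]
  get_par <- function(name, default) if (!is.null(pars[[name]])) pars[[name]] else default

  if (family == "additive") {
    w1 <- get_par("w1", 1); w2 <- get_par("w2", 1)
    f <- function(d1, d2) (w1 * d1 / b1 + w2 * d2 / b2) / (w1 + w2)
    iso <- function(level) {
      stopifnot(level > 0, level < 1)
      # line w1*u + w2*v = level*(w1+w2) on the unit square, mapped to bounds
      s <- level * (w1 + w2)
      pts <- list()
      # intersection with the four box edges in (u, v) in [0,1]^2
      cand <- list(c(s / w1, 0), c(0, s / w2),
                   c((s - w2) / w1, 1), c(1, (s - w1) / w2))
      keep <- Filter(function(p) all(is.finite(p)) && all(p >= 0 - 1e-12) && all(p <= 1 + 1e-12), cand)
      keep <- unique(lapply(keep, function(p) pmin(pmax(p, 0), 1)))
      if (length(keep) < 2) stop("level outside surface range", call. = FALSE)
      u <- vapply(keep, `[`, numeric(1), 1); v <- vapply(keep, `[`, numeric(1), 2)
      o <- order(u)
      densify_polyline(tibble::tibble(x = u[o] * b1, y = v[o] * b2), n = 1025)
    }
  } else if (family == "bliss") {
    ed50_1 <- get_par("ed50_1", 0.3 * b1); ed50_2 <- get_par("ed50_2", 0.3 * b2)
    h1 <- get_par("h1", 2); h2 <- get_par("h2", 2)
    emax1 <- get_par("emax1", 1); emax2 <- get_par("emax2", 1)
    hill <- function(d, ed50, h, emax) emax * d^h / (ed50^h + d^h)
    f <- function(d1, d2) {
      e1 <- hill(d1, ed50_1, h1, emax1); e2 <- hill(d2, ed50_2, h2, emax2)
      e1 + e2 - e1 * e2
    }
    iso <- function(level, n = 513) {
      stopifnot(level > 0, level < 1)
      d1 <- seq(0, b1, length.out = n)
      e1 <- hill(d1, ed50_1, h1, emax1)
      e2 <- (level - e1) / (1 - e1)          # required Bliss complement
      g <- e2 / emax2                        # Hill fraction for drug 2
      ok <- g > 0 & g < 1
      d2 <- rep(NA_real_, n)
      d2[ok] <- ed50_2 * (g[ok] / (1 - g[ok]))^(1 / h2)
      keep <- ok & d2 <= b2
      if (!any(keep)) stop("level outside surface range on this box", call. = FALSE)
      tibble::tibble(x = d1[keep], y = d2[keep])
    }
  } else if (family == "probit_additive") {
    a1 <- get_par("a1", 3 / b1); a2 <- get_par("a2", 3 / b2); cc <- get_par("c", 2)
    f <- function(d1, d2) stats::pnorm(a1 * d1 + a2 * d2 - cc)
    iso <- function(level) {
      stopifnot(level > 0, level < 1)
      s <- cc + stats::qnorm(level)          # a1*d1 + a2*d2 = s
      cand <- list(c(s / a1, 0), c(0, s / a2),
                   c((s - a2 * b2) / a1, b2), c(b1, (s - a1 * b1) / a2))
      keep <- Filter(function(p) all(is.finite(p)) && p[1] >= -1e-9 && p[1] <= b1 + 1e-9 &&
                       p[2] >= -1e-9 && p[2] <= b2 + 1e-9, cand)
      keep <- unique(lapply(keep, function(p) pmin(pmax(p, 0), c(b1, b2))))
      if (length(keep) < 2) stop("level outside surface range on this box", call. = FALSE)
      u <- vapply(keep, `[`, numeric(1), 1); v <- vapply(keep, `[`, numeric(1), 2)
      o <- order(u)
      densify_polyline(tibble::tibble(x = u[o], y = v[o]), n = 1025)
    }
  } else { # nonmonotone_bump
    amp <- get_par("amp", 0.3)
    m1 <- get_par("m1", 0.6 * b1); m2 <- get_par("m2", 0.6 * b2)
    sig <- get_par("sigma", 0.12 * max(b1, b2))
    f <- function(d1, d2) {
      base <- (d1 / b1 + d2 / b2) / 2
      dip <- amp * exp(-((d1 - m1)^2 + (d2 - m2)^2) / (2 * sig^2))
      pmin(1, pmax(0, base - dip))
    }
    iso <- function(level) {
      stop("no single-contour isobole exists for the nonmonotone-bump family",
           call. = FALSE)
    }
  }

  structure(list(family = family, bounds = bounds, f = f, exact_isobole = iso,
                 params = pars),
            class = "analytic_surface")
}

#' @export
print.analytic_surface <- function(x, ...) {
  cat(sprintf("<analytic_surface> family '%s' on [0,%g] x [0,%g]\n",
              x$family, x$bounds[1], x$bounds[2]))
  invisible(x)
}
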