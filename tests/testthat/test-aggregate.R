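test_that("isobole closure through the origin yields the failure polygon", {
  # straight anti-diagonal: triangle with the origin, area 1/2
  tri <- isobole_to_polygon(tibble::tibble(x = c(0, 1), y = c(1, 0)),
                            bounds = c(1, 1))
  expect_equal(nrow(tri), 3)
  expect_equal(polygon_area(tri), 0.5)

  # L-shaped isobole: area equals the shoelace formula on vertices + origin
  iso_l <- tibble::tibble(x = c(0, 0.2, 0.8), y = c(0.8, 0.2, 0))
  poly_l <- isobole_to_polygon(iso_l, bounds = c(1, 1))
  expect_equal(polygon_area(poly_l),
               shoelace(c(iso_l$x, 0), c(iso_l$y, 0)), tolerance = 1e-12)

  # isobole hugging the axes: vanishing failure area
  eps <- 1e-3
  tiny <- isobole_to_polygon(tibble::tibble(x = c(0, eps), y = c(eps, 0)),
                             bounds = c(1, 1))
  expect_lt(polygon_area(tiny), 1e-5)

  # endpoints on the max edges: the closure walks the boundary corners
  iso_hi <- tibble::tibble(x = c(0.3, 1), y = c(1, 0.3))
  poly_hi <- isobole_to_polygon(iso_hi, bounds = c(1, 1))
  # failure region = unit square minus the corner triangle of legs 0.7
  expect_equal(polygon_area(poly_hi), 1 - 0.5 * 0.7^2, tolerance = 1e-12)
  expect_true(point_in_polygon(data.frame(x = 0.05, y = 0.05), poly_hi))
  expect_false(point_in_polygon(data.frame(x = 0.95, y = 0.95), poly_hi))

  # interior endpoints violate the separation assumption
  expect_error(isobole_to_polygon(tibble::tibble(x = c(0.4, 0.6), y = c(0.5, 0.4)),
                                  bounds = c(1, 1)),
               "boundary")
})

test_that("binary classification encodes failure strictly inside the polygon", {
  iso <- tibble::tibble(x = c(0, 1), y = c(1, 0))
  tri <- isobole_to_polygon(iso, bounds = c(1, 1))
  ax <- seq(0, 1, length.out = 65)
  bin <- classify_binary(tri, ax, ax, isobole = iso)
  expect_identical(bin[1, 1], 0L)                      # origin fails
  expect_identical(bin[65, 65], 1L)                    # max-dose corner succeeds
  # closed-form oracle: success iff d1 + d2 >= 1 (isobole nodes count success)
  oracle <- outer(ax, ax, function(a, b) as.integer(a + b >= 1 - 1e-12))
  expect_identical(bin, oracle)
})

test_that("aggregation averages binary fields into confidence levels", {
  iso_small <- tibble::tibble(x = c(0, 0.4), y = c(0.4, 0))
  iso_big <- tibble::tibble(x = c(0, 0.8), y = c(0.8, 0))

  same <- aggregate_isoboles(list(iso_small, iso_small, iso_small),
                             bounds = c(1, 1), resolution = 33,
                             target_rate = 0.95)
  expect_true(all(same$values %in% c(0, 1)))

  nested <- aggregate_isoboles(list(iso_small, iso_big), bounds = c(1, 1),
                               resolution = 33, target_rate = 0.95)
  expect_true(all(nested$values %in% c(0, 0.5, 1)))
  # concentric bands along the diagonal: 0 near origin, 0.5 between, 1 outside
  dg <- diag(nested$values)
  expect_identical(dg[1], 0)
  expect_identical(dg[10], 0.5)   # d1 + d2 = 0.5625: outside small, inside big
  expect_identical(dg[33], 1)

  # conservation: surface mean equals the mean of per-population field means
  ax <- seq(0, 1, length.out = 33)
  f1 <- classify_binary(isobole_to_polygon(iso_small, c(1, 1)), ax, ax,
                        isobole = iso_small)
  f2 <- classify_binary(isobole_to_polygon(iso_big, c(1, 1)), ax, ax,
                        isobole = iso_big)
  expect_identical(mean(nested$values), mean(c(mean(f1), mean(f2))))

  expect_error(aggregate_isoboles(list()), "length")
})

test_that("degenerate classifications contribute constant fields", {
  stub <- function(classification) {
    structure(list(isobole = tibble::tibble(x = numeric(), y = numeric()),
                   components = list(), classification = classification,
                   bounds = c(1, 1), target_rate = 0.95,
                   grid = list(level = 3L)),
              class = "fastisoboles_result")
  }
  surf <- aggregate_isoboles(list(stub("entire space efficacious"),
                                  stub("entire space non-efficacious")),
                             resolution = 9)
  expect_true(all(surf$values == 0.5))
})

test_that("confidence isoboles recover the aggregated contours", {
  iso <- tibble::tibble(x = c(0, 0.5), y = c(0.5, 0))
  surf1 <- aggregate_isoboles(rep(list(iso), 4), bounds = c(1, 1),
                              resolution = 65, target_rate = 0.95)
  cell <- 1 / 64
  for (lev in c(0.25, 0.5, 0.75)) {
    ci <- confidence_isobole(surf1, lev)
    expect_lt(discrete_frechet(ci, densify_polyline(iso, 257),
                               orientation = "either"),
              sqrt(2) * cell + 1e-9)
  }

  # nested step surface: the 0.75 level sits on the outer isobole's step
  iso_out <- tibble::tibble(x = c(0, 0.8), y = c(0.8, 0))
  surf2 <- aggregate_isoboles(list(iso, iso, iso, iso_out), bounds = c(1, 1),
                              resolution = 65, target_rate = 0.95)
  ci75 <- confidence_isobole(surf2, 0.9) # needs all 4: outer isobole
  expect_lt(discrete_frechet(ci75, densify_polyline(iso_out, 257),
                             orientation = "either"),
            sqrt(2) * cell + 1e-9)

  # level above the surface maximum: empty result, flagged
  stub0 <- structure(list(isobole = tibble::tibble(x = numeric(), y = numeric()),
                          components = list(),
                          classification = "entire space non-efficacious",
                          bounds = c(1, 1), target_rate = 0.95,
                          grid = list(level = 3L)),
                     class = "fastisoboles_result")
  surf_half <- aggregate_isoboles(list(iso, stub0), bounds = c(1, 1),
                                  resolution = 17, target_rate = 0.95)
  expect_equal(max(surf_half$values), 0.5)
  empty <- confidence_isobole(surf_half, 0.75)
  expect_equal(nrow(empty), 0)
  expect_identical(attr(empty, "flag"), "level outside surface range")
})

test_that("confidence surfaces from monotone fixtures are monotone", {
  set.seed(21)
  intercepts <- stats::runif(8, 0.3, 0.9)
  isoboles <- lapply(intercepts, function(a)
    tibble::tibble(x = c(0, a), y = c(a, 0)))
  surf <- aggregate_isoboles(isoboles, bounds = c(1, 1), resolution = 33,
                             target_rate = 0.95)
  expect_true(all(diff(surf$values) >= 0))      # along drug 1
  expect_true(all(apply(surf$values, 1, diff) >= 0)) # along drug 2

  # higher confidence requires at-least-as-high doses along every ray
  ci50 <- confidence_isobole(surf, 0.5)
  ci95 <- confidence_isobole(surf, 0.95)
  r50 <- sqrt(ci50$x^2 + ci50$y^2)
  r95 <- sqrt(ci95$x^2 + ci95$y^2)
  ang50 <- atan2(ci50$y, ci50$x); ang95 <- atan2(ci95$y, ci95$x)
  for (i in seq_along(ang95)) {
    near <- which(abs(ang50 - ang95[i]) < 0.05)
    if (length(near)) expect_gte(r95[i], max(r50[near]) - 1 / 32)
  }
})
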