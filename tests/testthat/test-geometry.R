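test_that("contour extraction places crossings by linear interpolation", {
  # rows = x: surface rises from 0 at x=0 to 1 at x=1, constant in y
  z <- matrix(c(0, 1, 0, 1), 2, 2)
  cl <- extract_contour(z, c(0, 1), c(0, 1), 0.5)
  expect_length(cl, 1)
  expect_true(all(abs(cl[[1]]$x - 0.5) < 1e-12))
  expect_equal(range(cl[[1]]$y), c(0, 1))

  # level above the global maximum: no contour
  expect_length(extract_contour(z, c(0, 1), c(0, 1), 2), 0)

  # structural errors
  expect_error(extract_contour(1:4, c(0, 1), c(0, 1), 0.5), "matrix")
  zz <- z; zz[1, 1] <- NA
  expect_error(extract_contour(zz, c(0, 1), c(0, 1), 0.5), "evaluated")
  expect_error(extract_contour(z, c(1, 0), c(0, 1), 0.5), "increasing")
})

test_that("contour of an additive surface tracks the closed-form isobole", {
  ax <- seq(0, 1, length.out = 33)
  z <- outer(ax, ax, `+`)
  cl <- extract_contour(z, ax, ax, 1.0)
  expect_length(cl, 1)
  truth <- densify_polyline(tibble::tibble(x = c(1, 0), y = c(0, 1)), 1025)
  expect_lt(discrete_frechet(cl[[1]], truth, orientation = "either"), 1 / 32)
})

test_that("contour extraction commutes with transposition", {
  set.seed(11)
  ax <- seq(0, 1, length.out = 17)
  ay <- seq(0, 2, length.out = 21)
  z <- outer(ax, ay, function(u, v) u + 0.4 * v) # monotone, single contour
  a <- extract_contour(z, ax, ay, 0.7)
  b <- extract_contour(t(z), ay, ax, 0.7)
  expect_length(a, length(b))
  swapped <- tibble::tibble(x = b[[1]]$y, y = b[[1]]$x)
  expect_lt(discrete_frechet(a[[1]], swapped, orientation = "either"), 1e-9)
})

test_that("discrete Fréchet matches the exhaustive coupling oracle", {
  a <- tibble::tibble(x = c(0, 1), y = c(0, 0))
  expect_identical(discrete_frechet(a, a), 0)
  b <- tibble::tibble(x = c(0, 1), y = c(0.25, 0.25))
  expect_equal(discrete_frechet(a, b), 0.25)
  expect_error(discrete_frechet(a, tibble::tibble(x = numeric(), y = numeric())),
               "non-empty")

  set.seed(42)
  for (rep in 1:10) {
    p <- random_polyline(5); q <- random_polyline(5)
    expect_equal(discrete_frechet(p, q), frechet_exhaustive(p, q),
                 tolerance = 1e-12)
  }
})

test_that("discrete Fréchet behaves as a metric on vertex sequences", {
  set.seed(99)
  for (rep in 1:20) {
    p <- random_polyline(6); q <- random_polyline(6); r <- random_polyline(6)
    dpq <- discrete_frechet(p, q)
    expect_equal(dpq, discrete_frechet(q, p), tolerance = 1e-12)
    expect_gte(dpq, 0)
    expect_lte(dpq, discrete_frechet(p, r) + discrete_frechet(r, q) + 1e-12)
  }
})

test_that("point-in-polygon uses even-odd containment with boundary inside", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_true(point_in_polygon(data.frame(x = 0.5, y = 0.5), sq))
  expect_false(point_in_polygon(data.frame(x = 2, y = 2), sq))
  # boundary points count as inside
  expect_true(all(point_in_polygon(data.frame(x = c(0, 0.5, 1), y = c(0, 0, 0.5)), sq)))
  expect_error(point_in_polygon(data.frame(x = 0, y = 0),
                                tibble::tibble(x = c(0, 1), y = c(0, 1))),
               "3")
})

test_that("point-in-polygon agrees with a winding-number oracle", {
  set.seed(5)
  poly <- random_simple_polygon(12)
  pts <- tibble::tibble(x = stats::runif(1000), y = stats::runif(1000))
  ours <- point_in_polygon(pts, poly)
  oracle <- vapply(seq_len(nrow(pts)),
                   function(i) winding_inside(pts$x[i], pts$y[i], poly),
                   logical(1))
  # random points are almost surely non-boundary; the rules must agree
  expect_identical(ours, oracle)
  # independent third opinion
  prc <- pracma::inpolygon(pts$x, pts$y, poly$x, poly$y, boundary = TRUE)
  expect_identical(ours, prc)
})

test_that("distance to a polyline is the segment distance, not vertex distance", {
  seg <- tibble::tibble(x = c(0, 1), y = c(0, 0))
  expect_equal(distance_to_polyline(data.frame(x = 0.5, y = 0), seg), 0)
  expect_equal(distance_to_polyline(data.frame(x = 0, y = 1), seg), 1)
  # midpoint of a long segment: far from both vertices, on the segment
  expect_equal(distance_to_polyline(data.frame(x = 0.5, y = 0.2), seg), 0.2)

  set.seed(31)
  for (rep in 1:5) {
    pl <- random_polyline(4)
    p <- stats::runif(2)
    expect_equal(distance_to_polyline(data.frame(x = p[1], y = p[2]), pl),
                 distance_dense(p[1], p[2], pl),
                 tolerance = 1e-3)
  }
})

test_that("polygon area matches the shoelace formula and densify preserves shape", {
  set.seed(8)
  poly <- random_simple_polygon(9)
  expect_equal(polygon_area(poly), shoelace(poly$x, poly$y), tolerance = 1e-12)

  pl <- tibble::tibble(x = c(0, 0.5, 1), y = c(1, 0.2, 0))
  dense <- densify_polyline(pl, 257)
  expect_equal(nrow(dense), 257)
  expect_equal(dense[1, ], pl[1, ], ignore_attr = TRUE)
  expect_equal(dense[257, ], pl[3, ], ignore_attr = TRUE)
  # every resampled vertex lies exactly on the original polyline
  expect_lt(max(distance_to_polyline(dense, pl)), 1e-12)
})
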