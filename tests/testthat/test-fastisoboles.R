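test_that("grid initialization marks the nine level-1 nodes", {
  g <- init_grid(c(1000, 1000))
  expect_identical(g$level, 1L)
  expect_equal(nrow(g$pending), 9)
  expect_equal(sort(unique(g$pending$amt1)), c(0, 500, 1000))
  expect_equal(sort(unique(g$pending$amt2)), c(0, 500, 1000))

  g2 <- init_grid(c(800, 400))
  expect_equal(g2$x, c(0, 400, 800))
  expect_equal(g2$y, c(0, 200, 400))
  # level-1 spacing is half the maximum dose per axis
  expect_equal(diff(g2$x)[1], 400)
  expect_equal(diff(g2$y)[1], 200)

  expect_error(init_grid(c(-1, 1)), "positive")
})

test_that("refinement selects exactly the uncached nodes near the isobole", {
  s <- analytic_surface("additive", bounds = c(1, 1))
  g <- init_grid(c(1, 1))
  g <- isocomb:::evaluate_pending(g, s$f, 1L)
  anti <- tibble::tibble(x = c(0, 1), y = c(1, 0))
  expect_error(refine(init_grid(c(1, 1)), anti), "pending")

  g2 <- refine(g, anti)
  expect_identical(g2$level, 2L)
  expect_equal(length(g2$x), 5)
  # oracle: every unevaluated 5x5 node within 0.5 of the anti-diagonal
  all_nodes <- tidyr::expand_grid(ix = 1:5, iy = 1:5)
  all_nodes$amt1 <- g2$x[all_nodes$ix]; all_nodes$amt2 <- g2$y[all_nodes$iy]
  uncached <- !(all_nodes$amt1 %in% g$x & all_nodes$amt2 %in% g$y &
                  all_nodes$amt1 %in% c(0, 0.5, 1) & all_nodes$amt2 %in% c(0, 0.5, 1))
  d <- abs(all_nodes$amt1 + all_nodes$amt2 - 1) / sqrt(2)
  want <- all_nodes[uncached & d < 0.5, c("amt1", "amt2")]
  got <- g2$pending[, c("amt1", "amt2")]
  expect_equal(dplyr::arrange(got, amt1, amt2),
               dplyr::arrange(want, amt1, amt2), ignore_attr = TRUE)
  # far corners are never selected
  expect_false(any(got$amt1 == 0 & got$amt2 == 0))
  expect_false(any(got$amt1 == 1 & got$amt2 == 1))

  # empty isobole estimate: full-lattice fallback
  g3 <- refine(g, NULL)
  expect_equal(nrow(g3$pending), 25 - 9)
})

test_that("after j iterations the lattice has 2^j + 1 doses per drug", {
  s <- analytic_surface("additive", bounds = c(1, 1))
  for (j in 1:7) {
    r <- run_fastisoboles(s$f, 0.5, c(1, 1), max_iter = j, tol = 1e-12)
    expect_equal(length(r$grid$x), 2^j + 1)
    expect_equal(max(r$iterations$level), j)
    expect_lte(r$n_evaluations, (2^j + 1)^2)
    expect_equal(r$n_evaluations, nrow(r$cache))
  }
})

test_that("evaluated nodes form a subset of the full lattice with exact values", {
  s <- analytic_surface("bliss", bounds = c(1, 1))
  r <- run_fastisoboles(s$f, 0.9, c(1, 1), max_iter = 5)
  full <- run_brute_force(s$f, 0.9, c(1, 1), level = 5)
  ax <- full$grid$x
  # every cached node is a node of the final full lattice
  expect_true(all(r$cache$amt1 %in% ax))
  expect_true(all(r$cache$amt2 %in% ax))
  # and carries exactly the brute-force value there
  ij <- cbind(match(r$cache$amt1, ax), match(r$cache$amt2, ax))
  expect_identical(r$cache$success_rate, full$grid$value[ij])
})

test_that("adaptive isoboles match full-lattice contours (oracle equivalence)", {
  for (fam in c("additive", "bliss", "probit_additive")) {
    lev <- switch(fam, additive = 0.5, bliss = 0.9, probit_additive = 0.95)
    s <- analytic_surface(fam, bounds = c(1, 1))
    for (j in c(4, 6)) {
      fast <- run_fastisoboles(s$f, lev, c(1, 1), max_iter = j, tol = 1e-12)
      full <- run_brute_force(s$f, lev, c(1, 1), level = j)
      expect_lt(discrete_frechet(fast$isobole, full$isobole,
                                 orientation = "either"),
                2 * 2^-j)
    }
  }
})

test_that("the adaptive search saves most of the full-lattice evaluations", {
  fixtures <- list(
    list(f = analytic_surface("additive", bounds = c(1, 1))$f, lev = 0.5, b = c(1, 1)),
    list(f = analytic_surface("bliss", bounds = c(1, 1))$f, lev = 0.9, b = c(1, 1)),
    list(f = analytic_surface("probit_additive", bounds = c(1, 1))$f, lev = 0.95, b = c(1, 1)))
  for (fx in fixtures) {
    r <- run_fastisoboles(fx$f, fx$lev, fx$b, max_iter = 6)
    expect_lte(r$n_evaluations, 0.35 * 65^2)
  }
})

test_that("unbracketed targets are classified, not chased", {
  r0 <- run_fastisoboles(function(a, b) 0, 0.95, c(1, 1), max_iter = 6)
  expect_false(r0$converged)
  expect_identical(r0$classification, "entire space non-efficacious")
  expect_lte(r0$n_evaluations, 25)
  expect_equal(nrow(r0$isobole), 0)

  r1 <- run_fastisoboles(function(a, b) 1, 0.95, c(1, 1), max_iter = 6)
  expect_identical(r1$classification, "entire space efficacious")
  expect_lte(r1$n_evaluations, 25)
})

test_that("per-iteration evaluation counts scale with the curve, not the area", {
  # horizontal isobole: the refinement band holds ~2x more nodes per level
  f <- function(a, b) b
  r <- run_fastisoboles(f, 0.5, c(1, 1), max_iter = 7, tol = 1e-12)
  nn <- r$iterations$n_new_evaluations[r$iterations$iteration >= 3]
  ratios <- nn[-1] / nn[-length(nn)]
  expect_true(all(ratios < 3)) # doubling, nowhere near the 4x of a full scan
  expect_lt(r$n_evaluations, 0.2 * (2^7 + 1)^2)
})

test_that("Fréchet steps between successive estimates eventually shrink", {
  s <- analytic_surface("additive", bounds = c(1, 1))
  r <- run_fastisoboles(s$f, 0.5, c(1, 1), max_iter = 6, tol = 1e-12)
  steps <- r$iterations$frechet_step[-1]
  tail3 <- utils::tail(steps, 3)
  expect_true(all(diff(tail3) <= 1e-12))
})
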