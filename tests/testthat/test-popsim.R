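test_that("degenerate uncertainty and IIV reproduce the point estimate", {
  u <- uncertainty_distribution(mean = log(c(CL = 5, EC50 = 2)), covariance = 0)
  ens <- sample_ensemble(u, iiv_spec(c(CL = 0, EC50 = 0)),
                         n_pop = 3, n_subj = 4, seed = 1)
  expect_equal(unique(ens$populations$CL), 5)
  expect_equal(unique(ens$populations$EC50), 2)
  ind <- dplyr::bind_rows(ens$individuals)
  expect_true(all(abs(ind$CL - 5) < 1e-12))
  expect_true(all(abs(ind$EC50 - 2) < 1e-12))
})

test_that("population draws follow the uncertainty distribution (CLT bound)", {
  u <- uncertainty_distribution(mean = c(p = 0), covariance = matrix(1, 1, 1))
  ens <- sample_ensemble(u, iiv_spec(c(p = 0)), n_pop = 500, n_subj = 1, seed = 123)
  expect_lt(abs(mean(log(ens$populations$p))), 3 / sqrt(500))
})

test_that("ensembles are bit-identical under the same seed and hierarchical", {
  pd <- malaria_default_population()
  a <- sample_ensemble(pd$uncertainty, pd$iiv, n_pop = 4, n_subj = 6, seed = 77)
  b <- sample_ensemble(pd$uncertainty, pd$iiv, n_pop = 4, n_subj = 6, seed = 77)
  expect_identical(a$populations, b$populations)
  expect_identical(a$individuals, b$individuals)
  # population k's draws do not depend on how many populations follow it
  c2 <- sample_ensemble(pd$uncertainty, pd$iiv, n_pop = 2, n_subj = 6, seed = 77)
  expect_identical(a$populations[1:2, ], c2$populations)
  expect_identical(a$individuals[[2]], c2$individuals[[2]])
})

test_that("non-PSD covariance is rejected naming the eigenvalue", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2) # eigenvalues 3, -1
  u <- uncertainty_distribution(mean = c(a = 0, b = 0), covariance = bad)
  expect_error(sample_ensemble(u, iiv_spec(c(a = 0)), 2, 2, 1),
               "eigenvalue -1")
})

test_that("bisection costs n_iter + 2 evaluations and halves the bracket", {
  n_calls <- 0L
  f <- function(d) { n_calls <<- n_calls + 1L; d }
  ed <- effective_dose_bisection(f, 0.5, 0, 1, n_iter = 20)
  expect_lt(abs(ed - 0.5), 2^-20)
  expect_identical(n_calls, 22L)
  expect_identical(attr(ed, "n_evaluations"), 22L)

  n_calls <- 0L
  effective_dose_bisection(f, 0.5, 0, 1, n_iter = 5)
  expect_identical(n_calls, 7L) # five iterations, seven evaluations

  # step objective: estimate within the final bracket width of the step
  step <- function(d) as.numeric(d >= 0.7123)
  ed2 <- effective_dose_bisection(step, 0.5, 0, 1, n_iter = 12)
  expect_lt(abs(ed2 - 0.7123), 1 / 2^12)

  expect_error(effective_dose_bisection(function(d) 1, 0.5, 0, 1),
               "always efficacious")
  expect_error(effective_dose_bisection(function(d) 0, 0.5, 0, 1),
               "never efficacious")
})

test_that("confidence levels are the empirical CDF of effective doses", {
  out <- confidence_from_effective_doses(rep(3, 10), c(2.9, 3, 3.1))
  expect_equal(out$confidence, c(0, 1, 1))
  expect_equal(confidence_from_effective_doses(1:4, 2.5)$confidence, 0.5)
  expect_error(confidence_from_effective_doses(numeric(), 1), "non-empty")

  # Kolmogorov-Smirnov 95% band around the true log-normal CDF
  set.seed(2024)
  n <- 400
  eds <- stats::rlnorm(n, meanlog = 5, sdlog = 0.4)
  q <- seq(50, 500, length.out = 200)
  emp <- confidence_from_effective_doses(eds, q)$confidence
  truth <- stats::plnorm(q, 5, 0.4)
  expect_lt(max(abs(emp - truth)), 1.358 / sqrt(n))
})

test_that("monotonicity check flags constructed non-monotone surfaces only", {
  ax <- seq(0, 1, length.out = 9)
  add <- analytic_surface("additive")
  expect_true(check_monotonicity(add$f, ax, ax)$ok)

  bump <- analytic_surface("nonmonotone_bump", amp = 0.3)
  rep_bad <- check_monotonicity(bump$f, ax, ax)
  expect_false(rep_bad$ok)
  # violations cluster near the dip centre (0.6, 0.6)
  expect_true(all(abs(rep_bad$violations$x_from - 0.6) < 0.45))

  # a tolerance above the bump height silences the report
  expect_true(check_monotonicity(bump$f, ax, ax, tol = 0.5)$ok)
})

test_that("parameter influence ranking recovers constructed dependencies", {
  u <- uncertainty_distribution(mean = c(EC50 = log(1), V = log(10)),
                                covariance = diag(c(0.04, 0.04)))
  ens <- sample_ensemble(u, iiv_spec(c(EC50 = 0)), n_pop = 200, n_subj = 1,
                         seed = 9)

  # effective dose proportional to the EC50 draw: isobole intercepts a_i
  iso_dep <- lapply(ens$populations$EC50, function(e) {
    a <- min(0.5 * e, 1)
    tibble::tibble(x = c(0, a), y = c(a, 0))
  })
  rk <- rank_parameter_influence(ens, iso_dep, bounds = c(1, 1))
  expect_identical(rk$parameter[1], "EC50")
  expect_gt(abs(rk$rho[rk$parameter == "EC50"]), 0.9)
  # V does not enter the isobole at all: null correlation at n=200
  expect_lt(abs(rk$rho[rk$parameter == "V"]), 0.2)

  # constant isoboles: all correlations zero
  iso_const <- rep(list(tibble::tibble(x = c(0, 0.5), y = c(0.5, 0))), 200)
  rk0 <- rank_parameter_influence(ens, iso_const, bounds = c(1, 1))
  expect_true(all(rk0$rho == 0))

  ens3 <- sample_ensemble(u, iiv_spec(c(EC50 = 0)), n_pop = 2, n_subj = 1, seed = 1)
  expect_error(rank_parameter_influence(ens3, iso_const[1:2], bounds = c(1, 1)),
               "3 populations")
})
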