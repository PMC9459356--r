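test_that("spline basis reduces to {x} with no internal knots and matches FD derivatives", {
  knots <- c(log(0.1), log(5))
  x <- seq(-3, 3, by = 0.25)
  sb <- spline_basis(x, knots)
  expect_equal(ncol(sb$basis), 1L)
  expect_equal(sb$basis[, 1], x)
  expect_equal(sb$deriv[, 1], rep(1, length(x)))

  # analytic vs central finite-difference derivatives on random points
  set.seed(9)
  knots <- sort(rnorm(5))
  xs <- runif(100, -4, 4)
  for (cure in c(FALSE, TRUE)) {
    sb <- spline_basis(xs, knots, cure_constrained = cure)
    eps <- 1e-6
    fd <- (spline_basis(xs + eps, knots, cure)$basis -
             spline_basis(xs - eps, knots, cure)$basis) / (2 * eps)
    expect_equal(sb$deriv, fd, tolerance = 1e-6)
  }

  # cure constraint: derivative identically zero beyond the final knot
  xr <- seq(max(knots), max(knots) + 5, by = 0.1)
  sbc <- spline_basis(xr, knots, cure_constrained = TRUE)
  expect_true(all(sbc$deriv == 0))
  expect_error(spline_basis(c(1, NA), knots), "finite")
  expect_error(spline_basis(1, c(2, 1)), "ascending")
})

test_that("0-knot NRS recovers a Weibull excess hazard", {
  lam_pop <- 0.02
  ph <- pop_hazard(const_lifetable(lam_pop, ages = 50:130), 60)
  set.seed(15)
  n <- 10000
  t_e <- rweibull(n, shape = 1.4, scale = 2)
  t_p <- as.numeric(sample_population_time(ph, n))
  cens <- 25
  obs <- pmin(t_e, t_p, cens)
  d <- surv_data(obs, as.integer(pmin(t_e, t_p) <= cens))
  f <- fit_nrs(d, n_internal = 0, pop = ph)
  # log L_E = g0 + g1 log t  =>  Weibull with shape g1
  shape_hat <- f$gamma[2]
  se_shape <- sqrt(f$vcov[2, 2])
  expect_lt(abs(shape_hat - 1.4), 3 * se_shape)
  # the fitted 2-knot model can only improve the log-likelihood
  f2 <- fit_nrs(d, n_internal = 2, pop = ph)
  expect_gte(f2$loglik, f$loglik - 1e-6)
})

test_that("NRS likelihood matches an independent quadrature evaluator", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(300, a = 0.8, b = 1.8, ph = ph, seed = 18)
  f <- fit_nrs(d, n_internal = 2, pop = ph)
  lam_e <- function(t) hazard(f, t, type = "excess")
  ll_or <- sum(vapply(seq_len(nrow(d)), function(i) {
    ti <- d$time[i]
    He <- stats::integrate(lam_e, 1e-9, ti, rel.tol = 1e-9,
                           subdivisions = 800L)$value
    Hp <- population_cum_hazard(ph, ti)
    d$event[i] * log(population_hazard(ph, ti) + lam_e(ti)) - He - Hp
  }, numeric(1)))
  expect_equal(f$loglik, ll_or, tolerance = 1e-5)
})

test_that("the cure model's excess hazard vanishes beyond the final knot", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(1000, a = 0.8, b = 1.8, ph = ph, seed = 23)
  f <- fit_fcm(d, n_internal = 2, pop = ph)
  t_last <- exp(max(f$knots))
  expect_identical(hazard(f, 2 * t_last, type = "excess"), 0)
  # overall extrapolated hazard equals the population hazard exactly
  tt <- c(1.5 * t_last, 3 * t_last)
  expect_equal(hazard(f, tt), population_hazard(ph, tt))
  expect_true(f$cure_fraction > 0 && f$cure_fraction <= 1)
  # hazard is continuous at the last knot
  eps <- 1e-9
  expect_lt(abs(hazard(f, t_last + eps) - hazard(f, t_last - eps)), 1e-6)
})

test_that("the cure model recovers a genuine cure fraction", {
  lam_pop <- 0.02
  ph <- pop_hazard(const_lifetable(lam_pop, ages = 50:130), 60)
  set.seed(29)
  n <- 10000
  cured <- rbinom(n, 1, 0.3)
  t_e <- ifelse(cured == 1, Inf, rweibull(n, shape = 1.4, scale = 1.5))
  t_p <- as.numeric(sample_population_time(ph, n))
  cens <- 15
  obs <- pmin(t_e, t_p, cens)
  d <- surv_data(obs, as.integer(pmin(t_e, t_p) <= cens))
  f <- fit_fcm(d, n_internal = 2, pop = ph)
  expect_lt(abs(f$cure_fraction - 0.3), 0.05)
})

test_that("0-knot NRS extrapolation equals the Weibull closed form", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(500, a = 0.8, b = 1.8, ph = ph, seed = 33)
  f <- fit_nrs(d, n_internal = 0, pop = ph)
  b <- f$gamma[2]
  a <- exp(-f$gamma[1] / b)
  grid <- seq(0.5, 19, by = 0.5)
  h_closed <- (b / a) * (grid / a)^(b - 1) + population_hazard(ph, grid)
  ex <- extrapolate(f, grid, bands = FALSE)
  expect_equal(ex$hazard, h_closed, tolerance = 1e-8)
  # beyond the population table the error comes from the popmort layer
  expect_error(hazard(f, 60), "life-table range")
})

test_that("fitted overall hazard is positive at every event time", {
  # negative excursions of the fitted excess hazard are permitted between
  # knots, but the overall hazard must stay positive wherever an event
  # contributes a log-hazard term; the hard population floor is applied by
  # cap_hazard_at_population() when curves are exported to the economic
  # model
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(2000, a = 0.8, b = 1.8, ph = ph, seed = 51)
  fn <- fit_nrs(d, 2, pop = ph)
  fc <- fit_fcm(d, 2, pop = ph)
  grid <- sort(d$time[d$event == 1])
  expect_true(all(hazard(fn, grid) > 0))
  expect_true(all(hazard(fc, grid) > 0))
})
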