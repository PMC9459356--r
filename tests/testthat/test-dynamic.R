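test_that("model specification enforces its domain", {
  expect_error(dsm_spec("damped_trend", phi = 1.2), "\\(0, 1\\)")
  expect_error(dsm_spec("local_trend", phi = 0.9), "damped_trend")
  expect_error(dsm_spec("local_trend", relative = TRUE), "pop")
  expect_error(dsm_spec("local_trend", sigma_level = -1), ">= 0")
})

test_that("with zero innovations the local trend is exactly log-log linear", {
  d <- make_exp_data(800, 0.5, cens = 5, seed = 41)
  ic <- discretize(d, default_edges(d, width = 1 / 4))
  spec <- dsm_spec("local_trend", sigma_level = 0, sigma_trend = 0)
  f <- fit_dsm(ic, spec, engine = "laplace", seed = 3, n_draws = 200)
  eta_hat <- colMeans(f$eta)
  r2 <- stats::cor(eta_hat, ic$log_mid)^2
  expect_equal(r2, 1, tolerance = 1e-9)
  # every single draw is affine in log time too
  for (i in c(1, 50, 200)) {
    expect_equal(stats::cor(f$eta[i, ], ic$log_mid)^2, 1,
                 tolerance = 1e-9)
  }
})

test_that("the damped point forecast matches the series-summation oracle", {
  x0 <- log(5)
  xg <- log(seq(5.5, 40, by = 0.5))
  phi <- 0.8
  delta0 <- -0.6
  eta0 <- -1
  fc <- dsm_point_forecast(eta0, delta0, phi, x0, xg)
  # oracle: eta_k = eta0 + delta0 * sum_{i<=k} phi^(x_{i-1}-x_0) * (x_i - x_{i-1})
  xs <- c(x0, xg)
  oracle <- eta0 + delta0 * cumsum(phi^(utils::head(xs, -1) - x0) * diff(xs))
  expect_equal(fc, oracle, tolerance = 1e-12)
  # converging increments for the damped forecast
  expect_lt(abs(fc[length(fc)] - fc[length(fc) - 1]),
            abs(fc[2] - fc[1]))
  expect_true(all(is.finite(fc)))
  # undamped local trend is unbounded monotone when delta != 0
  fc1 <- dsm_point_forecast(eta0, delta0, 1, x0, xg)
  expect_true(all(diff(fc1) < 0))
  expect_equal(fc1[length(fc1)], eta0 + delta0 * (max(xg) - x0),
               tolerance = 1e-12)
})

test_that("nested structures coincide in their limits", {
  d <- make_exp_data(500, 0.5, cens = 4, seed = 43)
  ic <- discretize(d, default_edges(d, width = 1 / 2))
  # damped with phi ~ 1 matches the local trend's state prior
  m_lt <- dsm_model(ic, dsm_spec("local_trend", sigma_level = 0.2,
                                 sigma_trend = 0.1))
  m_dp <- dsm_model(ic, dsm_spec("damped_trend", phi = 1 - 1e-12,
                                 sigma_level = 0.2, sigma_trend = 0.1))
  th <- c(rnorm(2 * nrow(ic)))
  expect_equal(m_lt$logpost(th), m_dp$logpost(th), tolerance = 1e-6)
  # local level == local trend with delta fixed at 0, up to a constant
  # (the trend block's normalization does not involve the states)
  m_ll <- dsm_model(ic, dsm_spec("local_level", sigma_level = 0.2))
  aug <- function(th) c(th, numeric(nrow(ic)))
  th1 <- rnorm(nrow(ic)); th2 <- rnorm(nrow(ic))
  expect_equal(m_lt$logpost(aug(th1)) - m_ll$logpost(th1),
               m_lt$logpost(aug(th2)) - m_ll$logpost(th2),
               tolerance = 1e-8)
})

test_that("constant-hazard recovery: posterior matches truth and the MLE", {
  d <- make_exp_data(2000, 0.4, cens = 6, seed = 45)
  ic <- discretize(d)
  f <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace", seed = 46)
  h_draws <- exp(f$eta)
  pm <- colMeans(h_draws)
  psd <- apply(h_draws, 2, sd)
  expect_true(all(abs(pm - 0.4) < 3 * psd))
  mle <- sum(d$event) / sum(d$time)
  expect_lt(abs(mean(pm) - mle) / mle, 0.05)
  # identical seed, identical draws
  f2 <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace", seed = 46)
  expect_identical(f$eta, f2$eta)
})

test_that("MCMC engine is reproducible and reports split R-hat", {
  skip_if_not_installed("rjags")
  d <- make_exp_data(600, 0.4, cens = 5, seed = 47)
  ic <- discretize(d, default_edges(d, width = 1 / 2))
  f <- suppressWarnings(
    fit_dsm(ic, dsm_spec("local_level"), engine = "mcmc",
            chains = 2, iter = 400, warmup = 400, seed = 48))
  expect_equal(f$n_draws, 800L)
  expect_true(all(is.finite(f$diagnostics$rhat$rhat)))
  expect_gt(nrow(f$diagnostics$rhat), nrow(ic))
  f2 <- suppressWarnings(
    fit_dsm(ic, dsm_spec("local_level"), engine = "mcmc",
            chains = 2, iter = 400, warmup = 400, seed = 48))
  expect_identical(f$eta, f2$eta)
  pm <- colMeans(exp(f$eta))
  expect_lt(abs(mean(pm) - 0.4), 0.05)
})

test_that("the trend posterior tracks a Weibull log-log slope", {
  set.seed(49)
  tt <- rweibull(3000, shape = 1.5, scale = 2)
  cens <- runif(3000, 4, 5)
  d <- surv_data(pmin(tt, cens), as.integer(tt <= cens))
  ic <- discretize(d)
  f <- fit_dsm(ic, dsm_spec("local_trend"), engine = "laplace", seed = 50)
  tp <- trend_path(f)
  # d log h / d log t = shape - 1 = 0.5
  interior <- tp$time > 0.3 & tp$time < 4
  covered <- mean(tp$lower[interior] <= 0.5 & tp$upper[interior] >= 0.5)
  expect_gt(covered, 0.6)
  # no trend state in the local level
  fl <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace", seed = 50)
  expect_error(trend_path(fl), "no trend state")
})

test_that("trend intervals cover zero on constant-hazard data", {
  hits <- 0L
  for (s in 1:20) {
    d <- make_exp_data(500, 0.5, cens = 4, seed = 600 + s)
    ic <- discretize(d, default_edges(d, width = 1 / 4))
    f <- fit_dsm(ic, dsm_spec("local_trend"), engine = "laplace",
                 seed = 700 + s, n_draws = 300)
    tp <- trend_path(f)
    if (all(tp$lower <= 0 & tp$upper >= 0)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("damping shrinks the terminal trend on unimodal-hazard data", {
  set.seed(52)
  tt <- rllogis_(1500, 0.8, 1.8)
  cens <- runif(1500, 5, 6)
  d <- surv_data(pmin(tt, cens), as.integer(tt <= cens))
  ic <- discretize(d)
  f_lt <- fit_dsm(ic, dsm_spec("local_trend"), engine = "laplace", seed = 53)
  f_dp <- fit_dsm(ic, dsm_spec("damped_trend"), engine = "laplace", seed = 53)
  J <- nrow(ic)
  expect_lte(abs(mean(f_dp$delta[, J])), abs(mean(f_lt$delta[, J])))
})

test_that("extrapolation respects the DRSM floor and the structure's long-run shape", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(800, a = 0.8, b = 1.8, ph = ph, seed = 55)
  ic <- discretize(d)
  grid <- seq(6.5, 20, by = 0.25)

  # DRSM local level: overall = population + (approximately constant) excess
  f_ll <- fit_dsm(ic, dsm_spec("local_level", relative = TRUE, pop = ph),
                  engine = "laplace", seed = 56)
  ex <- extrapolate(f_ll, grid)
  popg <- population_hazard(ph, grid)
  expect_true(all(ex$hazard_draws >=
                    matrix(popg, nrow(ex$hazard_draws),
                           ncol(ex$hazard_draws), byrow = TRUE)))
  expect_true(all(ex$curve$lower <= ex$curve$hazard &
                    ex$curve$hazard <= ex$curve$upper))
  med_excess <- apply(ex$hazard_draws, 2, median) - popg
  expect_lt(diff(range(med_excess)) / median(med_excess), 0.5)

  # grids must be ascending, beyond the data, inside the life table
  expect_error(extrapolate(f_ll, c(1, 2)), "beyond the last")
  expect_error(extrapolate(f_ll, c(10, 60)), "life-table range")
})

test_that("a DSM can extrapolate below the population hazard; the DRSM cannot", {
  ph <- pop_hazard(std_lt, 63)
  # sharply declining hazard: h(t) = 0.8 exp(-0.6 t)
  set.seed(57)
  n <- 1500
  u <- runif(n)
  Hmax <- 0.8 / 0.6
  t0 <- rep(Inf, n)                    # survivors of the bounded hazard
  hit <- -log(u) < Hmax
  t0[hit] <- -log1p(0.6 * log(u[hit]) / 0.8) / 0.6
  cens <- runif(n, 5, 6)
  d <- surv_data(pmin(t0, cens), as.integer(t0 <= cens))
  ic <- discretize(d)
  grid <- seq(6.5, 30, by = 0.5)
  f_dsm <- fit_dsm(ic, dsm_spec("local_trend"), engine = "laplace", seed = 58)
  f_drsm <- suppressWarnings(
    fit_dsm(ic, dsm_spec("local_trend", relative = TRUE, pop = ph),
            engine = "laplace", seed = 58))
  ex_dsm <- extrapolate(f_dsm, grid)
  ex_drsm <- extrapolate(f_drsm, grid)
  popg <- population_hazard(ph, grid)
  expect_true(any(ex_dsm$curve$hazard < popg))
  expect_true(all(ex_drsm$curve$hazard >= popg))
})

test_that("the information score is finite, reproducible, and honest about trend", {
  scores <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    d <- make_exp_data(400, 0.5, cens = 4, seed = 800 + s)
    ic <- discretize(d, default_edges(d, width = 1 / 3))
    f_ll <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace",
                    seed = 900 + s, n_draws = 200)
    f_lt <- fit_dsm(ic, dsm_spec("local_trend"), engine = "laplace",
                    seed = 900 + s, n_draws = 200)
    scores[s, ] <- c(information_criterion(f_ll), information_criterion(f_lt))
  }
  expect_true(all(is.finite(scores)))
  # an unnecessary trend state does not improve the score beyond noise
  expect_gte(median(scores[, 2] - scores[, 1]), -2)
  # determinism
  d <- make_exp_data(400, 0.5, cens = 4, seed = 801)
  ic <- discretize(d, default_edges(d, width = 1 / 3))
  f_a <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace", seed = 901)
  f_b <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace", seed = 901)
  expect_identical(information_criterion(f_a), information_criterion(f_b))
})

test_that("posterior intervals cover the generating states", {
  # data generated from the local-level model's own generative process
  cover <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    J <- 16
    mids <- (seq_len(J) - 0.5) / 4
    x <- log(mids)
    eta_true <- numeric(J)
    eta_true[1] <- log(0.5)
    for (j in 2:J) {
      eta_true[j] <- eta_true[j - 1] + rnorm(1, 0, 0.25 * sqrt(x[j] - x[j - 1]))
    }
    e_j <- rep(3000 / J * 2, J)   # fixed exposure per interval
    d_j <- rpois(J, e_j * exp(eta_true))
    ic <- structure(
      data.frame(start = mids - 1 / 8, end = mids + 1 / 8, mid = mids,
                 log_mid = x, deaths = d_j, exposure = e_j,
                 n_risk = rep(3000, J)),
      class = c("interval_counts", "data.frame"))
    f <- fit_dsm(ic, dsm_spec("local_level"), engine = "laplace",
                 seed = 1100 + s, n_draws = 400)
    lo <- apply(f$eta, 2, quantile, 0.025)
    hi <- apply(f$eta, 2, quantile, 0.975)
    cover[s] <- mean(lo <= eta_true & eta_true <= hi)
  }
  expect_gte(mean(cover), 0.85)
})

test_that("weak excess identification triggers a warning", {
  ph <- pop_hazard(std_lt, 63)
  # nearly population-level mortality only
  set.seed(59)
  t_p <- as.numeric(sample_population_time(ph, 4000))
  cens <- runif(4000, 5, 6)
  d <- surv_data(pmin(t_p, cens), as.integer(t_p <= cens))
  ic <- discretize(d, default_edges(d, width = 1))
  expect_warning(dsm_model(ic, dsm_spec("local_level", relative = TRUE,
                                        pop = ph)),
                 "weakly identified")
})
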