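test_that("log-logistic closed forms and limit behaviour are correct", {
  f <- structure(list(family = "loglogistic", relative = FALSE, pop = NULL,
                      pars = c(scale = 1, shape = 2)),
                 class = "param_fit")
  # h(1) = (b/a)(t/a)^{b-1} / (1 + (t/a)^b) = 2 * 1 / 2 = 1
  expect_equal(hazard(f, 1), 1)
  expect_equal(cum_hazard(f, 1), log(2))
  expect_equal(hazard(f, 0), 0)      # b > 1: hazard starts at zero
  f$pars <- c(scale = 1, shape = 0.5)
  expect_equal(hazard(f, 0), Inf)    # b < 1: unbounded at 0+
  # unimodality for b > 1
  f$pars <- c(scale = 1, shape = 2)
  h <- hazard(f, seq(0.05, 10, by = 0.05))
  expect_equal(sum(diff(sign(diff(h))) != 0), 1)
})

test_that("relative fit with zero population hazard equals the standard fit", {
  ph0 <- pop_hazard(const_lifetable(0, ages = 50:130), 60)
  d <- make_exp_data(400, 0.5, cens = 4, seed = 21)
  f_std <- fit_parametric(d, "weibull")
  f_rel <- fit_parametric(d, "weibull", relative = TRUE, pop = ph0)
  expect_equal(f_rel$pars, f_std$pars, tolerance = 1e-4)
  expect_equal(f_rel$loglik, f_std$loglik, tolerance = 1e-6)
})

test_that("exponential MLE is the closed-form events over person-time", {
  d <- make_exp_data(300, 0.7, cens = 3, seed = 2)
  f <- fit_parametric(d, "exponential")
  expect_identical(f$pars[["rate"]], sum(d$event) / sum(d$time))
  expect_equal(f$aic, -2 * f$loglik + 2)
  expect_error(fit_parametric(surv_data(c(1, 2), c(0, 0)), "exponential"),
               "no events")
})

test_that("relative log-logistic fit recovers the generating parameters", {
  ph <- pop_hazard(const_lifetable(0.02, ages = 50:130), 60)
  d <- make_rel_ll_data(20000, a = 0.8, b = 1.8, ph = ph,
                        cens_lo = 25, cens_hi = 26, seed = 31)
  f <- fit_parametric(d, "loglogistic", relative = TRUE, pop = ph)
  expect_true(f$converged)
  expect_lt(abs(f$pars[["scale"]] - 0.8), 3 * f$se[["scale"]])
  expect_lt(abs(f$pars[["shape"]] - 1.8), 3 * f$se[["shape"]])
})

test_that("reported log-likelihood matches an independent quadrature evaluator", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(200, a = 0.8, b = 1.8, ph = ph, seed = 12)
  f <- fit_parametric(d, "loglogistic", relative = TRUE, pop = ph)
  a <- f$pars[["scale"]]; b <- f$pars[["shape"]]
  ll_or <- sum(vapply(seq_len(nrow(d)), function(i) {
    ti <- d$time[i]
    He <- stats::integrate(function(u) ll_hazard_(u, a, b), 0, ti,
                           rel.tol = 1e-10)$value
    Hp <- stats::integrate(function(u) population_hazard(ph, u), 0, ti,
                           rel.tol = 1e-10, subdivisions = 400L)$value
    d$event[i] * log(population_hazard(ph, ti) + ll_hazard_(ti, a, b)) -
      He - Hp
  }, numeric(1)))
  expect_equal(f$loglik, ll_or, tolerance = 1e-6)
})

test_that("relative fits agree with an independent excess-hazard fitter", {
  skip_if_not_installed("flexsurv")
  ph <- pop_hazard(const_lifetable(0.02, ages = 50:130), 60)
  d <- make_rel_ll_data(3000, a = 0.8, b = 1.8, ph = ph, seed = 44)
  f <- fit_parametric(d, "loglogistic", relative = TRUE, pop = ph)
  df <- data.frame(time = d$time, event = d$event,
                   bh = population_hazard(ph, d$time))
  g <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = df,
                             dist = "llogis", bhazard = df$bh)
  expect_equal(unname(f$pars[["scale"]]),
               unname(g$res["scale", "est"]), tolerance = 1e-3)
  expect_equal(unname(f$pars[["shape"]]),
               unname(g$res["shape", "est"]), tolerance = 1e-3)
})

test_that("the correctly specified family wins AIC on most replicates", {
  ph0 <- pop_hazard(const_lifetable(0, ages = 50:130), 60)
  fams <- c("exponential", "weibull", "gompertz", "lognormal", "loglogistic")
  wins <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    tt <- rllogis_(1000, 1, 2.2)
    cens <- runif(1000, 4, 6)
    d <- surv_data(pmin(tt, cens), as.integer(tt <= cens))
    aics <- vapply(fams, function(fm) {
      tryCatch(fit_parametric(d, fm)$aic, error = function(e) Inf)
    }, numeric(1))
    if (names(which.min(aics)) == "loglogistic") wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("inverse evidence ratios follow exp(-0.5 * delta AIC)", {
  expect_equal(inverse_evidence_ratio(c(100, 100)), c(1, 1))
  expect_equal(inverse_evidence_ratio(c(100, 102)), c(1, exp(-1)))
  expect_error(inverse_evidence_ratio(numeric(0)), "at least one")
  # invariance to a constant shift
  x <- c(210.3, 215.9, 212.4)
  expect_equal(inverse_evidence_ratio(x), inverse_evidence_ratio(x + 57.3))
  # best model scores exactly 1
  set.seed(61)
  aics <- runif(6, 100, 140)
  ier <- inverse_evidence_ratio(aics)
  expect_identical(ier[which.min(aics)], 1)
  expect_true(all(ier > 0 & ier <= 1))
})

test_that("a fixed hazard ratio rescales curves pointwise", {
  grid <- seq(0.1, 10, by = 0.1)
  curve <- hazard_curve(grid, rep(0.5, length(grid)))
  expect_equal(apply_hazard_ratio(curve, 1)$hazard, curve$hazard)
  hr <- apply_hazard_ratio(curve, 0.59)
  expect_equal(hr$hazard, rep(0.295, length(grid)))
  # exponential survival under the scaled hazard
  s <- curve_survival(hr)
  expect_equal(s$surv, exp(-0.295 * grid), tolerance = 1e-12)
  # hr < 1 implies improved survival everywhere
  expect_true(all(s$surv >= curve_survival(curve)$surv))
  expect_error(apply_hazard_ratio(curve, 0), "positive")
})

test_that("relative-model overall hazard never falls below the population floor", {
  ph <- pop_hazard(std_lt, 63)
  d <- make_rel_ll_data(800, a = 0.8, b = 1.8, ph = ph, seed = 77)
  grid <- seq(0.05, 20, by = 0.05)
  for (fam in c("loglogistic", "weibull", "lognormal")) {
    f <- fit_parametric(d, fam, relative = TRUE, pop = ph)
    expect_true(all(hazard(f, grid) >= population_hazard(ph, grid)))
  }
})
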