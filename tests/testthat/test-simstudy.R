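test_that("the DGM applies the minimum-of-three-times rule", {
  dgm <- dgm_spec(n = 2000, seed = 3)
  d <- simulate_replicate(dgm, 1)
  expect_equal(nrow(d), 2000L)
  # censored observations lie in the censoring window
  expect_true(all(d$time[d$event == 0] >= 5 & d$time[d$event == 0] <= 6))
  # no observation beyond the window's end
  expect_true(all(d$time <= 6))
  # reproducibility of a replicate
  d2 <- simulate_replicate(dgm, 1)
  expect_identical(d$time, d2$time)
  # different replicates use different substreams
  expect_false(identical(simulate_replicate(dgm, 2)$time, d$time))
  # the life table must cover the censoring window
  expect_error(dgm_spec(lt = life_table(64:66, c(0.01, 0.01, 0.01)),
                        start_age = 64), "life table too short")
})

test_that("closed-form truth adds the log-logistic and population hazards", {
  grid <- seq(0.25, 19.75, by = 0.25)
  dgm <- dgm_spec(seed = 5)
  tc <- dgm_truth(dgm, grid)
  popg <- population_hazard(dgm$pop, grid)
  expect_true(all(tc$hazard >= popg))
  expect_equal(tc$hazard - popg, ll_hazard_(grid, 0.8, 1.8), tolerance = 1e-12)
  # zero population hazard: truth is exactly the log-logistic hazard
  dgm0 <- dgm_spec(lt = const_lifetable(0, ages = 50:130), start_age = 60,
                   seed = 5)
  expect_equal(dgm_truth(dgm0, grid)$hazard, ll_hazard_(grid, 0.8, 1.8),
               tolerance = 1e-12)
})

test_that("Monte-Carlo truth converges to the closed form", {
  dgm <- dgm_spec(seed = 6)
  grid <- sim_grid()
  sel <- grid <= 10
  cf <- dgm_truth(dgm, grid)$hazard
  err <- vapply(c(1e4, 1e5, 1e6), function(N) {
    mc <- suppressWarnings(dgm_truth(dgm, grid, mode = "monte_carlo", N = N))
    max(abs(mc$hazard[sel] / cf[sel] - 1), na.rm = TRUE)
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1])
  expect_warning(dgm_truth(dgm, grid, mode = "monte_carlo", N = 1e4), "noisy")
})

test_that("observed times follow the implied overall survival", {
  dgm <- dgm_spec(n = 1e5, seed = 7)
  d <- simulate_replicate(dgm, 1)
  s_cens <- function(t) ifelse(t < 5, 1, pmax(6 - t, 0))
  for (t0 in c(0.5, 1, 3, 5.5)) {
    s_true <- (1 / (1 + (t0 / 0.8)^1.8)) *
      population_survival(dgm$pop, t0) * s_cens(t0)
    s_hat <- mean(d$time > t0)
    se <- sqrt(s_true * (1 - s_true) / 1e5)
    expect_lt(abs(s_hat - s_true), 3 * se)
  }
})

test_that("study plumbing: shapes, reproducibility, roster validation", {
  dgm <- dgm_spec(n = 120, replicates = 1, seed = 8)
  grid <- c(0.5, 2, 8)
  st <- run_sim_study(dgm, roster = "loglogistic_rsm", grid = grid,
                      replicates = 1)
  expect_equal(dim(st$estimates), c(1L, 1L, 3L))
  expect_true(all(st$estimates <= 0))  # capped at 1 before logging
  st2 <- run_sim_study(dgm, roster = "loglogistic_rsm", grid = grid,
                       replicates = 1)
  expect_identical(st$estimates, st2$estimates)
  expect_error(run_sim_study(dgm, roster = "logistic"), "valid models")
})

test_that("performance measures match their analytic oracle", {
  grid <- seq(0.5, 10, by = 0.5)
  truth <- log(ll_hazard_(grid, 0.8, 1.8) + 0.02)
  R <- 200
  # perfect estimator: zero bias and MSE
  est <- array(rep(truth, each = R), dim = c(R, 1, length(grid)),
               dimnames = list(NULL, "perfect", NULL))
  perf <- sim_performance(est, truth = truth, grid = grid)
  expect_equal(perf$summary$bias, 0)
  expect_equal(perf$summary$mse, 0)
  expect_true(all(perf$by_time$bias == 0 & perf$by_time$mse == 0))

  # estimator = truth + N(0, sigma^2): MSE -> sigma^2, bias -> 0
  sigma <- 0.4
  set.seed(17)
  noise <- matrix(rnorm(R * length(grid), 0, sigma), R, length(grid))
  est2 <- array(NA_real_, dim = c(R, 1, length(grid)),
                dimnames = list(NULL, "noisy", NULL))
  est2[, 1, ] <- rep(truth, each = R) + noise
  perf2 <- sim_performance(est2, truth = truth, grid = grid)
  # MC standard errors of the time-averaged quantities
  per_rep_mse <- rowMeans(noise^2)
  per_rep_bias <- rowMeans(noise)
  expect_lt(abs(perf2$summary$mse - sigma^2),
            3 * sd(per_rep_mse) / sqrt(R))
  expect_lt(abs(perf2$summary$bias - 0),
            3 * sd(per_rep_bias) / sqrt(R))
  # variance decomposition pointwise
  pt <- perf2$by_time
  expect_true(all(pt$mse >= pt$bias^2 - 1e-12))

  # degenerate single-replicate input
  est3 <- est2[1, , , drop = FALSE]
  expect_error(sim_performance(est3, truth = truth, grid = grid),
               "at least 2")
})

test_that("a small study ranks the correctly specified model first", {
  dgm <- dgm_spec(n = 300, replicates = 4, seed = 19)
  st <- suppressWarnings(
    run_sim_study(dgm, roster = c("loglogistic_rsm", "nrs", "fcm"),
                  replicates = 4))
  perf <- sim_performance(st)
  ov <- perf$summary[perf$summary$region == "overall", ]
  expect_equal(ov$model[which.min(ov$mse)], "loglogistic_rsm")
  expect_true(all(st$failures <= 1))
})
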