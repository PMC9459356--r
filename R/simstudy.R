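# Simulation study: additive relative-survival log-logistic data-generating
# mechanism, truth computation, five competing relative-survival models, and
# bias / MSE of the log hazard with Monte-Carlo confidence intervals.

#' Specify the simulation data-generating mechanism
#'
#' Each simulated subject gets three latent times — a disease (excess) time
#' from a log-logistic distribution, a general-population survival time
#' sampled from the life table under uniform deaths within year, and a
#' uniform censoring time — and the observed record is their minimum, with
#' event status set accordingly. The implied true overall hazard is the
#' log-logistic hazard plus the background hazard.
#'
#' @param a,b Log-logistic scale and shape of the excess distribution
#'   (`a, b > 0`).
#' @param lt A [life_table()]; defaults to the package's Gompertz-Makeham
#'   synthetic table.
#' @param start_age Cohort starting age in years (default 63).
#' @param cens_lo,cens_hi Censoring window in years (default uniform on
#'   `[5, 6]`).
#' @param n Subjects per replicate (default 300).
#' @param replicates Number of replicates (default 200).
#' @param seed Master seed; each replicate uses a derived substream.
#' @return A `dgm_spec` object.
#' @export
dgm_spec <- function(a = 0.8, b = 1.8, lt = synthetic_life_table(),
                     start_age = 63, cens_lo = 5, cens_hi = 6,
                     n = 300L, replicates = 200L, seed = 1L) {
  stopifnot(a > 0, b > 0, cens_lo >= 0, cens_hi > cens_lo,
            n >= 1, replicates >= 1)
  if (max(lt$age) + 1 < start_age + cens_hi) {
    stop("life table too short: must cover age start_age + cens_hi",
         call. = FALSE)
  }
  structure(list(a = a, b = b, lt = lt, start_age = start_age,
                 cens_lo = cens_lo, cens_hi = cens_hi, n = as.integer(n),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 pop = pop_hazard(lt, start_age)),
            class = "dgm_spec")
}

# replicate substreams derived from the master seed; kept below 2^31
substream_seed <- function(master, r, salt = 0L) {
  as.integer((as.numeric(master) * 10007 + 131 * as.numeric(r) + salt) %%
               2147483647)
}

rloglogistic <- function(n, a, b) {
  u <- stats::runif(n)
  a * (u / (1 - u))^(1 / b)
}

#' Simulate one replicate dataset from the DGM
#'
#' @param dgm A [dgm_spec()].
#' @param r Replicate index (determines the random substream).
#' @return A [surv_data()] dataset of `dgm$n` subjects.
#' @export
simulate_replicate <- function(dgm, r = 1L) {
  stopifnot(inherits(dgm, "dgm_spec"))
  set.seed(substream_seed(dgm$seed, r))
  n <- dgm$n
  t_ll <- rloglogistic(n, dgm$a, dgm$b)
  t_pop <- as.numeric(sample_population_time(dgm$pop, n))
  t_c <- stats::runif(n, dgm$cens_lo, dgm$cens_hi)
  obs <- pmin(t_ll, t_pop, t_c)
  event <- as.integer(pmin(t_ll, t_pop) <= t_c)
  surv_data(time = obs, event = event)
}

loglogistic_hazard <- function(t, a, b) {
  (b / a) * (t / a)^(b - 1) / (1 + (t / a)^b)
}

#' True overall hazard of the DGM
#'
#' Closed form: log-logistic excess hazard plus the uniform-deaths
#' background hazard. The Monte-Carlo mode estimates the same quantity from
#' `N` simulated uncensored event times (minimum of the disease and
#' population times) via interval occurrence/exposure rates around each
#' grid point, and exists as a self-consistency check of the sampler.
#'
#' @param dgm A [dgm_spec()].
#' @param grid Ascending positive times (years).
#' @param mode `"closed_form"` (default) or `"monte_carlo"`.
#' @param N Number of simulations in Monte-Carlo mode.
#' @param seed Seed for Monte-Carlo mode (default: derived from the DGM
#'   master seed).
#' @return A data frame `time`, `hazard` of class `hazard_curve`.
#' @export
dgm_truth <- function(dgm, grid, mode = c("closed_form", "monte_carlo"),
                      N = 1e6, seed = NULL) {
  stopifnot(inherits(dgm, "dgm_spec"))
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  if (mode == "closed_form") {
    h <- loglogistic_hazard(grid, dgm$a, dgm$b) +
      population_hazard(dgm$pop, grid)
    return(hazard_curve(grid, h))
  }
  if (N < 1e5) {
    warning("Monte-Carlo truth with N < 1e5 will be noisy", call. = FALSE)
  }
  if (is.null(seed)) seed <- substream_seed(dgm$seed, 0L, salt = 777L)
  set.seed(seed)
  t_ev <- pmin(rloglogistic(N, dgm$a, dgm$b),
               as.numeric(sample_population_time(dgm$pop, N)))
  # fine occurrence/exposure table, then an adaptive symmetric kernel
  # around each grid point: the bandwidth grows until at least
  # `min_deaths` deaths contribute, trading a little smoothing bias for
  # controlled Poisson noise in the sparse tail
  fine <- 1 / 48
  edges <- seq(0, max(grid) + 1, by = fine)
  st <- sort(t_ev)
  cs <- cumsum(st)
  tot <- cs[N]
  time_above <- function(v) {
    k <- findInterval(v, st)            # count of times <= v
    (tot - if (k > 0) cs[k] else 0) - v * (N - k)
  }
  Tab <- vapply(edges, time_above, numeric(1))
  exposure <- Tab[-length(Tab)] - Tab[-1]
  deaths <- tabulate(findInterval(t_ev, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  mids <- edges[-1] - fine / 2
  min_deaths <- 6000
  epan <- function(u) pmax(0, 0.75 * (1 - u^2))
  # local log-linear Poisson (local-likelihood) hazard estimate at each
  # grid point; the linear term removes the first-order smoothing bias of
  # a plain kernel occurrence/exposure ratio
  h <- vapply(grid, function(t0) {
    for (bw in c(fine, 0.1, 0.2, 0.3, 0.5, 0.75, 1, 1.5, 2, 3)) {
      w <- epan((mids - t0) / bw)
      if (sum(w * deaths) >= min_deaths || bw == 3) break
    }
    sel <- w > 0 & exposure > 0
    if (!any(sel) || sum(w[sel] * deaths[sel]) == 0) return(NA_real_)
    ws <- w[sel]; ds <- deaths[sel]; es <- exposure[sel]
    dt <- log(mids[sel] / t0)   # log-time: linear there over wide ranges
    alpha <- log(sum(ws * ds) / sum(ws * es))
    beta <- 0
    for (it in 1:4) {
      mu <- es * exp(alpha + beta * dt)
      g <- c(sum(ws * (ds - mu)), sum(ws * dt * (ds - mu)))
      I11 <- sum(ws * mu); I12 <- sum(ws * dt * mu); I22 <- sum(ws * dt^2 * mu)
      det <- I11 * I22 - I12^2
      if (!is.finite(det) || det <= 0) break
      alpha <- alpha + (I22 * g[1] - I12 * g[2]) / det
      beta <- beta + (I11 * g[2] - I12 * g[1]) / det
    }
    exp(alpha)
  }, numeric(1))
  hazard_curve(grid, h)
}

#' Default evaluation grid for the simulation study
#'
#' Monthly interval midpoints out to the horizon.
#'
#' @param horizon Horizon in years (default 20).
#' @return Numeric vector of times.
#' @export
sim_grid <- function(horizon = 20) {
  (seq_len(round(horizon * 12)) - 0.5) / 12
}

sim_model_roster <- c("loglogistic_rsm", "nrs", "fcm",
                      "drsm_trend", "drsm_damped")

# evaluate a fitted dynamic model's posterior-median overall hazard on an
# arbitrary grid: interpolation at the interval midpoints within sample,
# forecast medians beyond.
dsm_hazard_on_grid <- function(fit, grid, seed) {
  mids <- fit$counts_data$mid
  fh <- fitted_hazard(fit, type = "overall")
  inside <- grid <= mids[length(mids)]
  h <- numeric(length(grid))
  if (any(inside)) {
    h[inside] <- stats::approx(fh$time, fh$median, xout = grid[inside],
                               rule = 2)$y
  }
  if (any(!inside)) {
    ex <- extrapolate(fit, grid[!inside], seed = seed)
    h[!inside] <- ex$curve$hazard
  }
  h
}

fit_one_sim_model <- function(model, data, dgm, grid, engine, n_internal,
                              rep_seed) {
  pop <- dgm$pop
  h <- switch(
    model,
    loglogistic_rsm = {
      f <- fit_parametric(data, "loglogistic", relative = TRUE, pop = pop)
      hazard(f, grid)
    },
    nrs = {
      f <- fit_nrs(data, n_internal = n_internal, pop = pop)
      hazard(f, grid)
    },
    fcm = {
      f <- fit_fcm(data, n_internal = n_internal, pop = pop)
      hazard(f, grid)
    },
    drsm_trend = ,
    drsm_damped = {
      counts <- discretize(data)
      structure_ <- if (model == "drsm_trend") "local_trend" else "damped_trend"
      spec <- dsm_spec(structure_, relative = TRUE, pop = pop)
      f <- fit_dsm(counts, spec, engine = engine, seed = rep_seed,
                   n_draws = 400L)
      dsm_hazard_on_grid(f, grid, seed = rep_seed + 1L)
    },
    stop("unknown model '", model, "'; valid models: ",
         paste(sim_model_roster, collapse = ", "), call. = FALSE)
  )
  h
}

#' Run the simulation study
#'
#' For each replicate: simulate a dataset from the DGM, fit every model in
#' the roster, evaluate each fitted overall hazard on the grid, cap it at 1
#' and take logs (the estimand is the log hazard). Failed fits are recorded
#' and excluded from summaries; a model failing on more than 20% of
#' replicates triggers a prominent warning.
#'
#' @param dgm A [dgm_spec()].
#' @param roster Character vector of models, a subset of
#'   `c("loglogistic_rsm", "nrs", "fcm", "drsm_trend", "drsm_damped")`.
#' @param grid Evaluation times (default [sim_grid()]).
#' @param replicates Number of replicates (default `dgm$replicates`).
#' @param engine Engine for the dynamic models (`"laplace"`, the fast
#'   default for study use, or `"mcmc"`).
#' @param n_internal Internal knots for the spline models (default 2).
#' @param hazard_cap Cap applied to hazard estimates before logging
#'   (default 1).
#' @param verbose Print per-replicate progress?
#' @return A `sim_study` object: `estimates` (replicate x model x grid array
#'   of capped log hazards), `truth` (closed-form log truth, uncapped),
#'   `grid`, `failures`, `dgm`.
#' @export
run_sim_study <- function(dgm, roster = sim_model_roster, grid = sim_grid(),
                          replicates = dgm$replicates, engine = "laplace",
                          n_internal = 2L, hazard_cap = 1, verbose = FALSE) {
  stopifnot(inherits(dgm, "dgm_spec"))
  bad <- setdiff(roster, sim_model_roster)
  if (length(bad)) {
    stop("unknown model(s) ", paste(bad, collapse = ", "),
         "; valid models: ", paste(sim_model_roster, collapse = ", "),
         call. = FALSE)
  }
  grid <- as.numeric(grid)
  est <- array(NA_real_, dim = c(replicates, length(roster), length(grid)),
               dimnames = list(NULL, roster, NULL))
  failures <- stats::setNames(integer(length(roster)), roster)
  for (r in seq_len(replicates)) {
    data <- simulate_replicate(dgm, r)
    rep_seed <- substream_seed(dgm$seed, r, salt = 13L)
    for (m in roster) {
      h <- tryCatch(
        suppressWarnings(
          fit_one_sim_model(m, data, dgm, grid, engine, n_internal, rep_seed)),
        error = function(e) NULL)
      if (is.null(h) || anyNA(h)) {
        failures[m] <- failures[m] + 1L
      } else {
        est[r, m, ] <- log(pmin(h, hazard_cap))
      }
    }
    if (verbose) message("replicate ", r, "/", replicates, " done")
  }
  frac <- failures / replicates
  if (any(frac > 0.2)) {
    warning("model(s) failing on > 20% of replicates: ",
            paste(names(frac)[frac > 0.2], collapse = ", "), call. = FALSE)
  }
  truth <- log(dgm_truth(dgm, grid)$hazard)
  out <- list(estimates = est, truth = truth, grid = grid, roster = roster,
              failures = failures, dgm = dgm,
              insample_max = dgm$cens_hi)
  class(out) <- "sim_study"
  out
}

#' Bias and MSE of the log hazard
#'
#' Pointwise and time-averaged performance of each model's capped log-hazard
#' estimates against the true log hazard: `bias(t)` is the across-replicate
#' mean error and `MSE(t)` the mean squared error. Time-averaged summaries
#' average each replicate over the grid first; their 95% confidence
#' intervals use the normal approximation from the across-replicate
#' standard deviation of those per-replicate averages. Sub-averages are
#' reported for the within-sample (`t <= insample_max`) and extrapolation
#' regions.
#'
#' @param x A `sim_study` object, or a replicate x model x grid array of log
#'   hazard estimates.
#' @param truth True log hazard on the grid (taken from `x` if a
#'   `sim_study`).
#' @param grid Evaluation times (taken from `x` if a `sim_study`).
#' @param insample_max End of the within-sample region (years), or `NULL`
#'   for no split.
#' @return A list with `by_time` (long data frame: model, time, bias, mse)
#'   and `summary` (one row per model x region with means and 95% CIs).
#' @export
sim_performance <- function(x, truth = NULL, grid = NULL, insample_max = NULL) {
  if (inherits(x, "sim_study")) {
    truth <- x$truth
    grid <- x$grid
    if (is.null(insample_max)) insample_max <- x$insample_max
    est <- x$estimates
  } else {
    est <- x
    if (is.null(truth) || is.null(grid)) {
      stop("supply `truth` and `grid` with a raw estimate array", call. = FALSE)
    }
  }
  models <- dimnames(est)[[2]]
  if (is.null(models)) models <- paste0("model", seq_len(dim(est)[2]))
  regions <- list(overall = rep(TRUE, length(grid)))
  if (!is.null(insample_max)) {
    regions$insample <- grid <= insample_max
    regions$extrapolation <- grid > insample_max
  }
  by_time <- list()
  summ <- list()
  for (mi in seq_along(models)) {
    em <- est[, mi, , drop = FALSE]
    dim(em) <- dim(est)[c(1, 3)]
    ok <- stats::complete.cases(em)
    if (sum(ok) < 2L) {
      stop("need at least 2 successful replicates for model ", models[mi],
           call. = FALSE)
    }
    em <- em[ok, , drop = FALSE]
    err <- sweep(em, 2, truth)
    by_time[[mi]] <- data.frame(model = models[mi], time = grid,
                                bias = colMeans(err),
                                mse = colMeans(err^2))
    for (rg in names(regions)) {
      sel <- regions[[rg]]
      if (!any(sel)) next
      per_rep_bias <- rowMeans(err[, sel, drop = FALSE])
      per_rep_mse <- rowMeans(err[, sel, drop = FALSE]^2)
      ci <- function(v) {
        m <- mean(v)
        half <- 1.96 * stats::sd(v) / sqrt(length(v))
        c(m, m - half, m + half)
      }
      cb <- ci(per_rep_bias)
      cm <- ci(per_rep_mse)
      summ[[length(summ) + 1L]] <-
        data.frame(model = models[mi], region = rg, n_replicates = sum(ok),
                   mse = cm[1], mse_lo = cm[2], mse_hi = cm[3],
                   bias = cb[1], bias_lo = cb[2], bias_hi = cb[3])
    }
  }
  list(by_time = do.call(rbind, by_time), summary = do.call(rbind, summ))
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulation study:", dim(x$estimates)[1], "replicates x",
      length(x$roster), "models x", length(x$grid), "grid points\n")
  if (any(x$failures > 0)) {
    cat("  failures:", paste(names(x$failures), x$failures, sep = "=",
                             collapse = ", "), "\n")
  }
  invisible(x)
}
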