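# Shared fixtures: all test data are generated in code under fixed seeds.

# default synthetic life table / background curve for an adult cohort
std_lt <- synthetic_life_table()
std_pop <- pop_hazard(std_lt, 63)

# life table with a constant hazard `rate` at every age
const_lifetable <- function(rate, ages = 50:130) {
  life_table(age = ages, qx = rep(1 - exp(-rate), length(ages)))
}

# right-censored exponential data
make_exp_data <- function(n, rate, cens = Inf, seed = 1) {
  set.seed(seed)
  t0 <- stats::rexp(n, rate)
  surv_data(pmin(t0, cens), as.integer(t0 <= cens))
}

rllogis_ <- function(n, a, b) {
  u <- stats::runif(n)
  a * (u / (1 - u))^(1 / b)
}

# additive relative-survival data: log-logistic excess + life-table
# population deaths + uniform censoring
make_rel_ll_data <- function(n, a, b, ph, cens_lo = 5, cens_hi = 6, seed = 1) {
  set.seed(seed)
  t_ll <- rllogis_(n, a, b)
  t_pop <- as.numeric(sample_population_time(ph, n))
  t_c <- stats::runif(n, cens_lo, cens_hi)
  surv_data(pmin(t_ll, t_pop, t_c), as.integer(pmin(t_ll, t_pop) <= t_c))
}

# independent product-limit oracle (censorings after deaths at tied times)
brute_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    ti <- ev_times[i]
    n_risk <- sum(time >= ti)
    d <- sum(time == ti & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ev_times, surv = out)
}

ll_hazard_ <- function(t, a, b) (b / a) * (t / a)^(b - 1) / (1 + (t / a)^b)
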