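# Three-state partitioned-survival cost-effectiveness model: state occupancy
# (stable, progressed, dead) is read directly off the OS and PFS curves;
# QALYs and costs are discounted integrals of occupancy; PSA propagates
# utility/cost distributions.

#' Cap a hazard curve at the general-population hazard
#'
#' Pointwise floor on the modelled hazard: `h'(t) = max(h(t), p(t))`, so the
#' modelled mortality never falls below that of the age-matched general
#' population. Survival from the capped curve (via [curve_survival()]) is
#' never above the uncapped survival.
#'
#' @param curve A [hazard_curve()].
#' @param pop A [pop_hazard()] covering the curve's time range.
#' @return A [hazard_curve()] on the same grid.
#' @export
cap_hazard_at_population <- function(curve, pop) {
  stopifnot(inherits(curve, "hazard_curve"), inherits(pop, "pop_hazard"))
  p <- population_hazard(pop, curve$time)
  out <- curve
  if (any(curve$hazard < p)) {
    message("hazard cap applied on ", sum(curve$hazard < p), " of ",
            nrow(curve), " grid points")
  }
  out$hazard <- pmax(curve$hazard, p)
  if (!is.null(out$lower)) out$lower <- pmax(out$lower, p)
  if (!is.null(out$upper)) out$upper <- pmax(out$upper, p)
  out
}

as_surv_fun <- function(s) {
  if (is.function(s)) return(s)
  if (inherits(s, "hazard_curve")) {
    cs <- curve_survival(s)
    return(function(t) {
      stats::approx(c(0, cs$time), c(1, cs$surv), xout = t, rule = 2)$y
    })
  }
  if (is.data.frame(s) && all(c("time", "surv") %in% names(s))) {
    return(function(t) {
      stats::approx(c(0, s$time), c(1, s$surv), xout = t, rule = 2)$y
    })
  }
  stop("survival input must be a function, hazard_curve, or data frame ",
       "with columns time and surv", call. = FALSE)
}

#' Partitioned-survival state occupancy
#'
#' The three-state partition: stable = PFS survival, progressed = OS
#' survival minus PFS survival (floored at zero), dead = 1 - OS survival.
#' Occupancies sum to one at every grid point by construction (when the
#' independently fitted curves cross, PFS is truncated at OS and a warning
#' is raised).
#'
#' @param os,pfs Overall and progression-free survival: functions of time,
#'   [hazard_curve()]s, or data frames with `time`/`surv` columns.
#' @param grid Evaluation times (years), ascending from at least 0.
#' @return Data frame `time`, `stable`, `progressed`, `dead`.
#' @export
partition_survival <- function(os, pfs, grid) {
  f_os <- as_surv_fun(os)
  f_pfs <- as_surv_fun(pfs)
  s_os <- f_os(grid)
  s_pfs <- f_pfs(grid)
  if (any(s_pfs > s_os + 1e-12)) {
    warning("PFS survival exceeds OS survival at ",
            sum(s_pfs > s_os + 1e-12),
            " grid point(s); progressed occupancy floored at 0", call. = FALSE)
  }
  stable <- pmin(s_pfs, s_os)
  data.frame(time = grid, stable = stable,
             progressed = s_os - stable, dead = 1 - s_os)
}

#' Assemble cost-effectiveness model inputs
#'
#' @param arms Named list of exactly two arms (the first is the
#'   intervention, the second the comparator); each arm is a list with
#'   elements `os` and `pfs` (survival inputs accepted by
#'   [partition_survival()]), annual state cost rates `cost_stable` and
#'   `cost_progressed`, and optional `cost_oneoff` at model entry.
#' @param u_stable,u_progressed Utility (mean, sd) pairs for the two alive
#'   states; defaults 0.750 (SD 0.236) and 0.592 (SD 0.315).
#' @param discount Annual discount rate for both costs and QALYs (default
#'   0.035).
#' @param horizon Time horizon in years (default 20).
#' @param cycle Cycle length in years (default one week, 1/52).
#' @param psa_n PSA iterations (default 2000).
#' @param cost_cv Coefficient of variation for Gamma-distributed costs in
#'   the PSA (default 0.2).
#' @param seed PSA seed.
#' @return An `econ_inputs` object.
#' @export
econ_inputs <- function(arms,
                        u_stable = c(mean = 0.750, sd = 0.236),
                        u_progressed = c(mean = 0.592, sd = 0.315),
                        discount = 0.035, horizon = 20, cycle = 1 / 52,
                        psa_n = 2000L, cost_cv = 0.2, seed = 1L) {
  if (length(arms) != 2L || is.null(names(arms))) {
    stop("`arms` must be a named list of exactly two arms", call. = FALSE)
  }
  for (u in list(u_stable, u_progressed)) {
    if (u[["mean"]] < 0 || u[["mean"]] > 1) {
      stop("utility means must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(horizon > 0, cycle > 0, psa_n >= 1)
  for (nm in names(arms)) {
    need <- c("os", "pfs")
    miss <- setdiff(need, names(arms[[nm]]))
    if (length(miss)) {
      stop("arm '", nm, "' is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    arms[[nm]]$cost_stable <- arms[[nm]]$cost_stable %||% 0
    arms[[nm]]$cost_progressed <- arms[[nm]]$cost_progressed %||% 0
    arms[[nm]]$cost_oneoff <- arms[[nm]]$cost_oneoff %||% 0
  }
  structure(list(arms = arms, u_stable = u_stable,
                 u_progressed = u_progressed, discount = discount,
                 horizon = horizon, cycle = cycle, psa_n = as.integer(psa_n),
                 cost_cv = cost_cv, seed = as.integer(seed)),
            class = "econ_inputs")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# discounted trapezoid integral of a grid function
disc_trapz <- function(t, f, rate) {
  g <- f * exp(-rate * t)
  sum(diff(t) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
}

eval_arm <- function(arm, inputs, u_s, u_p, c_s, c_p, c_one) {
  grid <- seq(0, inputs$horizon, by = inputs$cycle)
  occ <- partition_survival(arm$os, arm$pfs, grid)
  qaly <- disc_trapz(grid, occ$stable * u_s + occ$progressed * u_p,
                     inputs$discount)
  cost <- disc_trapz(grid, occ$stable * c_s + occ$progressed * c_p,
                     inputs$discount) + c_one
  c(qaly = qaly, cost = cost)
}

beta_mom <- function(mean, sd) {
  v <- sd^2
  if (v <= 0) return(NULL)
  vmax <- mean * (1 - mean)
  if (v >= vmax) v <- 0.99 * vmax
  k <- vmax / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

gamma_mom <- function(mean, sd) {
  if (sd <= 0 || mean <= 0) return(NULL)
  c(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Evaluate the partitioned-survival cost-effectiveness model
#'
#' Deterministic mode evaluates QALYs and costs at the mean inputs.
#' PSA mode draws utilities from Beta and costs from Gamma distributions
#' (method of moments on the supplied means and SDs) and reports means over
#' iterations. The ICER is incremental cost over incremental QALYs of the
#' first arm versus the second; dominance and undefined (zero incremental
#' QALY) cases are labelled.
#'
#' @param inputs An [econ_inputs()] object.
#' @param method `"deterministic"` or `"psa"`.
#' @return A `ce_result` object.
#' @export
evaluate_ce <- function(inputs, method = c("deterministic", "psa")) {
  stopifnot(inherits(inputs, "econ_inputs"))
  method <- match.arg(method)
  nm <- names(inputs$arms)
  arm_eval <- function(u_s, u_p, cs, cp) {
    vapply(seq_along(inputs$arms), function(i) {
      a <- inputs$arms[[i]]
      eval_arm(a, inputs, u_s, u_p, cs[i], cp[i], a$cost_oneoff)
    }, numeric(2))
  }
  cs0 <- vapply(inputs$arms, function(a) a$cost_stable, numeric(1))
  cp0 <- vapply(inputs$arms, function(a) a$cost_progressed, numeric(1))
  if (method == "deterministic") {
    res <- arm_eval(inputs$u_stable[["mean"]], inputs$u_progressed[["mean"]],
                    cs0, cp0)
    draws <- NULL
  } else {
    bs <- beta_mom(inputs$u_stable[["mean"]], inputs$u_stable[["sd"]])
    bp <- beta_mom(inputs$u_progressed[["mean"]], inputs$u_progressed[["sd"]])
    set.seed(inputs$seed)
    acc <- matrix(0, 2, 2)
    draws <- matrix(NA_real_, inputs$psa_n, 2,
                    dimnames = list(NULL, c("inc_qaly", "inc_cost")))
    for (it in seq_len(inputs$psa_n)) {
      u_s <- if (is.null(bs)) inputs$u_stable[["mean"]] else
        stats::rbeta(1, bs[1], bs[2])
      u_p <- if (is.null(bp)) inputs$u_progressed[["mean"]] else
        stats::rbeta(1, bp[1], bp[2])
      cs <- vapply(cs0, function(m) {
        g <- gamma_mom(m, inputs$cost_cv * m)
        if (is.null(g)) m else stats::rgamma(1, g[1], g[2])
      }, numeric(1))
      cp <- vapply(cp0, function(m) {
        g <- gamma_mom(m, inputs$cost_cv * m)
        if (is.null(g)) m else stats::rgamma(1, g[1], g[2])
      }, numeric(1))
      r <- arm_eval(u_s, u_p, cs, cp)
      acc <- acc + r
      draws[it, ] <- c(r["qaly", 1] - r["qaly", 2], r["cost", 1] - r["cost", 2])
    }
    res <- acc / inputs$psa_n
  }
  dimnames(res) <- list(c("qaly", "cost"), nm)
  inc_qaly <- res["qaly", 1] - res["qaly", 2]
  inc_cost <- res["cost", 1] - res["cost", 2]
  if (abs(inc_qaly) < 1e-12) {
    icer <- NA_real_
    label <- "undefined (zero incremental QALYs)"
  } else {
    icer <- inc_cost / inc_qaly
    label <- if (inc_qaly > 0 && inc_cost <= 0) "dominant"
    else if (inc_qaly < 0 && inc_cost >= 0) "dominated"
    else "icer"
  }
  out <- list(per_arm = res, inc_qaly = inc_qaly, inc_cost = inc_cost,
              icer = icer, label = label, method = method,
              psa_draws = draws, inputs = inputs)
  class(out) <- "ce_result"
  out
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Partitioned-survival cost-effectiveness result (", x$method, ")\n",
      sep = "")
  print(round(t(x$per_arm), 4))
  cat("incremental QALYs:", format(x$inc_qaly, digits = 4),
      " incremental cost:", format(x$inc_cost, digits = 6), "\n")
  if (x$label == "icer") {
    cat("ICER:", format(x$icer, big.mark = ",", digits = 6), "per QALY\n")
  } else {
    cat("ICER:", x$label, "\n")
  }
  invisible(x)
}

#' @export
fit_summary.ce_result <- function(fit) {
  list(method = fit$method,
       per_arm = apply(fit$per_arm, 2, as.list),
       inc_qaly = fit$inc_qaly, inc_cost = fit$inc_cost,
       icer = if (is.na(fit$icer)) NULL else fit$icer, label = fit$label)
}
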