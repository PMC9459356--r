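# Spline-based excess hazard models: the log cumulative excess hazard is a
# restricted cubic (natural) spline in log time. Two variants:
#  * NRS  — natural spline, linear beyond the boundary knots, so the log
#    cumulative excess hazard continues log-linearly in the extrapolation.
#  * FCM  — the spline is additionally constrained to zero slope beyond the
#    final knot, so the cumulative excess hazard plateaus: the excess hazard
#    is exactly zero in the tail and exp(-plateau) is a cure fraction.

#' Restricted cubic spline basis on log time
#'
#' Returns the natural-spline basis (without intercept) and its analytic
#' derivative. Column 1 is the linear term; columns `2..m+1` are the usual
#' truncated-power natural-spline terms for each internal knot, constructed
#' so the spline is linear beyond both boundary knots. With
#' `cure_constrained = TRUE` the linear term is removed and each remaining
#' column `v_j` is replaced by `v_j - s_j * x` (with `s_j` the column's
#' slope beyond the final knot), which forces the spline's derivative to be
#' identically zero beyond the final knot.
#'
#' @param x Evaluation points (log time); must be finite.
#' @param knots Strictly ascending knots on log time; first and last are the
#'   boundary knots (at least 2 knots).
#' @param cure_constrained Constrain to zero slope beyond the final knot?
#' @return List with matrices `basis` and `deriv` (`length(x)` rows).
#' @export
spline_basis <- function(x, knots, cure_constrained = FALSE) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  knots <- as.numeric(knots)
  if (length(knots) < 2L || is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be >= 2 and strictly ascending", call. = FALSE)
  }
  kmin <- knots[1L]
  kmax <- knots[length(knots)]
  internal <- knots[-c(1L, length(knots))]
  pp3 <- function(u) pmax(u, 0)^3
  pp2 <- function(u) pmax(u, 0)^2
  cols <- list(x)
  dcols <- list(rep(1, length(x)))
  slopes <- 1  # slope of each column beyond kmax
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    v <- pp3(x - kj) - lam * pp3(x - kmin) - (1 - lam) * pp3(x - kmax)
    dv <- 3 * (pp2(x - kj) - lam * pp2(x - kmin) - (1 - lam) * pp2(x - kmax))
    sj <- 3 * (kj^2 - lam * kmin^2 - (1 - lam) * kmax^2)
    cols <- c(cols, list(v))
    dcols <- c(dcols, list(dv))
    slopes <- c(slopes, sj)
  }
  B <- do.call(cbind, cols)
  dB <- do.call(cbind, dcols)
  if (cure_constrained) {
    if (ncol(B) == 1L) {
      # no internal knots: only the (removed) linear term remains
      B <- matrix(0, length(x), 0)
      dB <- matrix(0, length(x), 0)
    } else {
      B <- B[, -1L, drop = FALSE] - outer(x, slopes[-1L])
      dB <- dB[, -1L, drop = FALSE] -
        matrix(slopes[-1L], length(x), ncol(dB) - 1L, byrow = TRUE)
      dB[x >= kmax, ] <- 0  # constraint holds exactly, not just to rounding
    }
  }
  list(basis = B, deriv = dB)
}

#' Default spline knots from event times
#'
#' Boundary knots at the minimum and maximum log event time; internal knots
#' at equally spaced centiles of the log event times (for the default of 2
#' internal knots: the 33rd and 67th centiles).
#'
#' @param data A [surv_data()] dataset.
#' @param n_internal Number of internal knots (`>= 0`).
#' @return Ascending knots on log time.
#' @export
default_knots <- function(data, n_internal = 2L) {
  ev <- log(data$time[data$event == 1L])
  if (length(ev) < 2L) stop("need at least 2 events to place knots", call. = FALSE)
  probs <- if (n_internal > 0) seq_len(n_internal) / (n_internal + 1) else numeric(0)
  unique(c(min(ev), stats::quantile(ev, probs, names = FALSE, type = 7), max(ev)))
}

spline_loglik_factory <- function(data, knots, cure, pop) {
  t <- data$time
  d <- data$event
  x <- log(t)
  sb <- spline_basis(x, knots, cure_constrained = cure)
  p_t <- population_hazard(pop, t)
  P_t <- population_cum_hazard(pop, t)
  ev <- d == 1L
  function(gamma) {
    s <- gamma[1] + if (ncol(sb$basis)) drop(sb$basis %*% gamma[-1]) else 0
    sp <- if (ncol(sb$deriv)) drop(sb$deriv %*% gamma[-1]) else rep(0, length(t))
    HE <- exp(s)
    lamE <- HE * sp / t
    htot <- p_t + lamE
    if (any(!is.finite(HE)) || any(htot[ev] <= 0)) return(1e10)
    ll <- sum(log(htot[ev])) - sum(HE) - sum(P_t)
    if (!is.finite(ll)) 1e10 else -ll
  }
}

fit_spline_excess <- function(data, n_internal, pop, cure, knots, restarts) {
  stopifnot(inherits(data, "surv_data"))
  if (!inherits(pop, "pop_hazard")) {
    stop("spline excess-hazard models need a `pop` background curve", call. = FALSE)
  }
  if (sum(data$event) < 1L) stop("cannot fit: no events in the data", call. = FALSE)
  if (is.null(knots)) knots <- default_knots(data, n_internal)
  negll <- spline_loglik_factory(data, knots, cure, pop)
  npar <- if (cure) length(knots) - 1L else length(knots)
  D <- sum(data$event)
  # starting values: least-squares fit of the log Nelson-Aalen excess
  # cumulative hazard on the spline basis at the event times
  g0 <- tryCatch({
    km <- kaplan_meier(data)
    keep <- km$n_event > 0 & km$surv > 0
    tev <- km$time[keep]
    He <- pmax(-log(km$surv[keep]) - population_cum_hazard(pop, tev), 1e-4)
    sb <- spline_basis(log(tev), knots, cure_constrained = cure)
    X <- cbind(1, sb$basis)
    as.numeric(stats::lm.fit(X, log(He))$coefficients)
  }, error = function(e) NULL)
  if (is.null(g0) || anyNA(g0) || length(g0) != npar) {
    rate0 <- max(D - sum(population_cum_hazard(pop, data$time)), 0.1 * D) /
      sum(data$time)
    g0 <- numeric(npar)
    g0[1] <- log(max(rate0, 1e-3))
    if (!cure) g0[2] <- 1
  }
  best <- NULL
  for (r in 0:restarts) {
    th <- if (r == 0) g0 else g0 + stats::rnorm(npar, 0, 0.3)
    opt <- tryCatch(
      stats::optim(th, negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    ok <- !is.null(opt) && is.finite(opt$value) && opt$value < 1e9
    if (ok && (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) {
    stop("spline excess-hazard fit failed after ", restarts, " restarts",
         call. = FALSE)
  }
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc)) vc <- matrix(NA_real_, npar, npar)
  vc <- (vc + t(vc)) / 2
  ll <- -best$value
  fit <- list(model = if (cure) "fcm" else "nrs", knots = knots,
              gamma = best$par, vcov = vc, cure = cure, pop = pop,
              loglik = ll, k = npar, aic = -2 * ll + 2 * npar,
              converged = best$convergence == 0,
              n = nrow(data), events = D)
  if (cure) {
    # plateau of the log cumulative excess hazard = value at the final knot
    s_end <- spline_eval(fit, knots[length(knots)])$s
    fit$cure_fraction <- exp(-exp(s_end))
  }
  class(fit) <- "spline_fit"
  if (!fit$converged) {
    warning("optimizer did not report convergence for the ",
            fit$model, " fit", call. = FALSE)
  }
  fit
}

spline_eval <- function(fit, x) {
  sb <- spline_basis(x, fit$knots, cure_constrained = fit$cure)
  s <- fit$gamma[1] + if (ncol(sb$basis)) drop(sb$basis %*% fit$gamma[-1]) else 0
  sp <- if (ncol(sb$deriv)) drop(sb$deriv %*% fit$gamma[-1]) else rep(0, length(x))
  list(s = s, sp = sp)
}

#' Fit the Nelson-type spline relative survival model (NRS)
#'
#' Models the log cumulative excess hazard as a natural cubic spline in log
#' time: `log L_E(t) = s(log t; gamma)`, with excess hazard
#' `L_E(t) * s'(log t) / t`, added to the general-population hazard. Beyond
#' the boundary knots the spline is linear, so extrapolations continue the
#' fitted log-log-linear trend in the cumulative excess hazard.
#'
#' @param data A [surv_data()] dataset.
#' @param n_internal Number of internal knots (default 2).
#' @param pop A [pop_hazard()] background curve.
#' @param knots Optional explicit knots on log time (overrides
#'   `n_internal`).
#' @param restarts Jittered optimizer restarts on failure.
#' @return A `spline_fit` object.
#' @export
fit_nrs <- function(data, n_internal = 2L, pop, knots = NULL, restarts = 5L) {
  fit_spline_excess(data, n_internal, pop, cure = FALSE, knots = knots,
                    restarts = restarts)
}

#' Fit the flexible mixture cure model (FCM)
#'
#' As [fit_nrs()], but the spline is constrained to zero slope beyond the
#' final knot, so the cumulative excess hazard plateaus and the excess
#' hazard is exactly zero in the extrapolated tail. The implied cure
#' fraction `exp(-L_E(Inf))` is reported as `cure_fraction`.
#'
#' @inheritParams fit_nrs
#' @return A `spline_fit` object with an extra `cure_fraction` element.
#' @export
fit_fcm <- function(data, n_internal = 2L, pop, knots = NULL, restarts = 5L) {
  fit_spline_excess(data, n_internal, pop, cure = TRUE, knots = knots,
                    restarts = restarts)
}

#' @rdname drsurv-generics
#' @export
hazard.spline_fit <- function(object, t, type = c("overall", "excess"), ...) {
  type <- match.arg(type)
  se <- spline_eval(object, log(t))
  lamE <- exp(se$s) * se$sp / t
  if (type == "overall") population_hazard(object$pop, t) + lamE else lamE
}

#' @rdname drsurv-generics
#' @export
cum_hazard.spline_fit <- function(object, t, type = c("overall", "excess"), ...) {
  type <- match.arg(type)
  HE <- exp(spline_eval(object, log(t))$s)
  if (type == "overall") population_cum_hazard(object$pop, t) + HE else HE
}

#' @rdname drsurv-generics
#' @export
survival_prob.spline_fit <- function(object, t, ...) {
  exp(-cum_hazard(object, t, type = "overall"))
}

#' @rdname drsurv-generics
#' @export
extrapolate.spline_fit <- function(object, times, bands = TRUE, level = 0.95,
                                   ...) {
  h <- hazard(object, times)
  lo <- hi <- NULL
  if (bands && !anyNA(object$vcov)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    grad <- vapply(seq_along(object$gamma), function(i) {
      eps <- 1e-5 * max(1, abs(object$gamma[i]))
      fp <- fm <- object
      fp$gamma[i] <- fp$gamma[i] + eps
      fm$gamma[i] <- fm$gamma[i] - eps
      (hazard(fp, times) - hazard(fm, times)) / (2 * eps)
    }, numeric(length(times)))
    v <- rowSums((grad %*% object$vcov) * grad)
    se <- sqrt(pmax(v, 0))
    pfloor <- population_hazard(object$pop, times)
    lo <- pmax(h - z * se, pfloor)
    hi <- pmax(h + z * se, pfloor)
  }
  hazard_curve(times, h, lower = lo, upper = hi)
}

#' @export
logLik.spline_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(toupper(x$model), "spline excess-hazard fit:",
      length(x$knots) - 2L, "internal knots\n")
  cat("gamma:", format(x$gamma, digits = 4), "\n")
  if (!is.null(x$cure_fraction)) {
    cat("cure fraction:", format(x$cure_fraction, digits = 4), "\n")
  }
  cat("loglik:", format(x$loglik, digits = 6), " AIC:",
      format(x$aic, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
fit_summary.spline_fit <- function(fit) {
  out <- list(model = fit$model, knots = as.list(fit$knots),
              gamma = as.list(fit$gamma),
              loglik = fit$loglik, aic = fit$aic, converged = fit$converged,
              n = fit$n, events = fit$events)
  if (!is.null(fit$cure_fraction)) out$cure_fraction <- fit$cure_fraction
  out
}
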