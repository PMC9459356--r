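#' Hazard curve container
#'
#' An evaluable hazard-over-time object: point estimates on a time grid with
#' optional central 95% uncertainty bands. Hazard curves are the common
#' currency between model fitting, extrapolation, simulation scoring and the
#' economic model.
#'
#' @param time Ascending positive times (years).
#' @param hazard Hazard per year at each time (`>= 0` for exported curves).
#' @param lower,upper Optional pointwise 95% band.
#' @return An object of class `hazard_curve` (a data frame).
#' @export
hazard_curve <- function(time, hazard, lower = NULL, upper = NULL) {
  time <- as.numeric(time)
  hazard <- as.numeric(hazard)
  if (length(time) != length(hazard)) {
    stop("`time` and `hazard` lengths differ", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly ascending", call. = FALSE)
  }
  out <- data.frame(time = time, hazard = hazard)
  if (!is.null(lower)) out$lower <- as.numeric(lower)
  if (!is.null(upper)) out$upper <- as.numeric(upper)
  class(out) <- c("hazard_curve", "data.frame")
  out
}

#' Evaluate a hazard curve at arbitrary times
#'
#' Linear interpolation inside the grid; constant extension at the ends.
#'
#' @param curve A [hazard_curve()].
#' @param t Times (years).
#' @return Hazard values.
#' @export
eval_hazard <- function(curve, t) {
  stopifnot(inherits(curve, "hazard_curve"))
  stats::approx(curve$time, curve$hazard, xout = t, rule = 2)$y
}

#' Survival function implied by a hazard curve
#'
#' Integrates the hazard by the trapezoid rule on the curve's own grid
#' (treating the hazard as linear between grid points, and constant at its
#' first value between 0 and the first grid point) and exponentiates.
#'
#' @param curve A [hazard_curve()].
#' @return Data frame with columns `time` and `surv`.
#' @export
curve_survival <- function(curve) {
  stopifnot(inherits(curve, "hazard_curve"))
  t <- curve$time
  h <- curve$hazard
  inc <- c(t[1] * h[1], diff(t) * (utils::head(h, -1) + utils::tail(h, -1)) / 2)
  data.frame(time = t, surv = exp(-cumsum(inc)))
}

#' Apply a fixed hazard ratio to a hazard curve
#'
#' Scales the hazard pointwise: `h'(t) = hr * h(t)`. The implied survival
#' is the original survival raised to the power `hr` (recomputed from the
#' scaled cumulative hazard by [curve_survival()]).
#'
#' @param curve A [hazard_curve()].
#' @param hr Hazard ratio (`> 0`).
#' @return A [hazard_curve()].
#' @export
apply_hazard_ratio <- function(curve, hr) {
  stopifnot(inherits(curve, "hazard_curve"))
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be positive", call. = FALSE)
  out <- curve
  out$hazard <- curve$hazard * hr
  if (!is.null(curve$lower)) out$lower <- curve$lower * hr
  if (!is.null(curve$upper)) out$upper <- curve$upper * hr
  out
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("Hazard curve on", nrow(x), "time points,",
      format(min(x$time), digits = 3), "-", format(max(x$time), digits = 3),
      "years", if (!is.null(x$lower)) "(with 95% bands)" else "", "\n")
  invisible(x)
}
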