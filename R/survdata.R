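#' Construct a subject-level survival dataset
#'
#' Holds right-censored time-to-event records: a positive follow-up time and
#' a binary event indicator per subject, with optional treatment-arm label
#' and age at entry. All times are stored internally in years; `units`
#' converts on ingest (`days`/365.25, `weeks`*7/365.25, `months`/12).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators in `{0, 1}` (1 = death observed).
#' @param arm Optional arm labels (character or factor).
#' @param age Optional ages at entry (years).
#' @param units Unit of `time`: one of `"years"`, `"days"`, `"weeks"`,
#'   `"months"`.
#' @return An object of class `surv_data` (a data frame).
#' @export
surv_data <- function(time, event, arm = NULL, age = NULL,
                      units = c("years", "days", "weeks", "months")) {
  units <- match.arg(units)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) == 0L) stop("empty dataset", call. = FALSE)
  if (length(event) != length(time)) {
    stop("`time` and `event` lengths differ", call. = FALSE)
  }
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    stop("times must be positive and finite; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event must be 0/1; offending row(s): ",
         paste(utils::head(which(!event %in% c(0, 1)), 5), collapse = ", "),
         call. = FALSE)
  }
  fac <- switch(units, years = 1, days = 1 / 365.25,
                weeks = 7 / 365.25, months = 1 / 12)
  out <- data.frame(time = time * fac, event = as.integer(event))
  if (!is.null(arm)) out$arm <- as.character(arm)
  if (!is.null(age)) out$age <- as.numeric(age)
  class(out) <- c("surv_data", "data.frame")
  out
}

#' Read subject-level survival data from CSV
#'
#' Expected schema: columns `time`, `event`, optional `arm` and `age`.
#'
#' @param path CSV path.
#' @param units Time unit of the `time` column (see [surv_data()]).
#' @return A `surv_data` object (times in years).
#' @export
read_ipd <- function(path, units = "years") {
  if (!file.exists(path)) stop("IPD file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time", "event"), names(raw))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(raw$time))
  if (anyNA(tm)) {
    stop("non-numeric time at row(s): ",
         paste(utils::head(which(is.na(tm)), 5), collapse = ", "), call. = FALSE)
  }
  surv_data(time = tm, event = raw$event,
            arm = if ("arm" %in% names(raw)) raw$arm else NULL,
            age = if ("age" %in% names(raw)) raw$age else NULL,
            units = units)
}

#' Write subject-level survival data to CSV
#'
#' Times are written in years at full double precision so that
#' write-then-read round-trips exactly.
#'
#' @param data A `surv_data` object.
#' @param path Output CSV path.
#' @export
write_ipd <- function(data, path) {
  stopifnot(inherits(data, "surv_data"))
  df <- data
  class(df) <- "data.frame"
  df$time <- format(df$time, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a dataset by arm
#'
#' @param data A `surv_data` object with an `arm` column.
#' @param arm Arm label to keep.
#' @return A `surv_data` object.
#' @export
subset_arm <- function(data, arm) {
  stopifnot(inherits(data, "surv_data"))
  if (is.null(data$arm)) stop("dataset has no arm column", call. = FALSE)
  out <- data[data$arm == arm, , drop = FALSE]
  if (nrow(out) == 0L) stop("no rows for arm '", arm, "'", call. = FALSE)
  class(out) <- c("surv_data", "data.frame")
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function with Greenwood standard
#' errors, computed via [survival::survfit()]. Ties between deaths and
#' censorings at the same time follow the standard convention (censorings
#' occur after deaths).
#'
#' @param data A `surv_data` object.
#' @return An object of class `km_estimate`: data frame with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `se` (Greenwood SE of S).
#' @export
kaplan_meier <- function(data) {
  stopifnot(inherits(data, "surv_data"))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "log")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, se = sf$std.err * sf$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km A `km_estimate`.
#' @param t Times (years).
#' @return Step-function values of the survival estimate; `S(0) = 1`.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' Default interval edges for discretization
#'
#' Equal-width intervals (one month by default) from zero to the smallest
#' whole multiple of the width covering all observed follow-up.
#'
#' @param data A `surv_data` object.
#' @param width Interval width in years (default one month, 1/12).
#' @return Numeric vector of ascending edges starting at 0.
#' @export
default_edges <- function(data, width = 1 / 12) {
  stopifnot(inherits(data, "surv_data"), width > 0)
  seq(0, ceiling(max(data$time) / width + 1e-9) * width, by = width)
}

#' Discretize follow-up into interval deaths and exposure
#'
#' Converts subject-level records into per-interval death counts `d_j` and
#' person-years of exposure `e_j` — the observation layer for the dynamic
#' (state-space) models. A death at exactly an interval edge is counted in
#' the interval ending at that edge. Total deaths and total person-time are
#' conserved exactly.
#'
#' @param data A `surv_data` object.
#' @param edges Ascending interval edges starting at 0 and covering the
#'   maximum observed time; defaults to [default_edges()].
#' @return An object of class `interval_counts`: data frame with columns
#'   `start`, `end`, `mid`, `log_mid`, `deaths`, `exposure`, `n_risk`.
#' @export
discretize <- function(data, edges = default_edges(data)) {
  stopifnot(inherits(data, "surv_data"))
  edges <- as.numeric(edges)
  if (edges[1] != 0 || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must ascend strictly from 0", call. = FALSE)
  }
  J <- length(edges) - 1L
  tmax <- max(data$time)
  if (tmax > edges[J + 1L] + 1e-12) {
    stop("observed time ", format(tmax), " beyond the last edge ",
         format(edges[J + 1L]), call. = FALSE)
  }
  lo <- edges[-(J + 1L)]
  hi <- edges[-1L]
  # exposure: person-time of each subject inside each interval
  exposure <- vapply(seq_len(J), function(j) {
    sum(pmax(0, pmin(data$time, hi[j]) - lo[j]))
  }, numeric(1))
  # deaths: interval with lo < t <= hi
  dj <- findInterval(data$time, edges, left.open = TRUE, rightmost.closed = TRUE)
  deaths <- tabulate(dj[data$event == 1L], nbins = J)
  n_risk <- vapply(seq_len(J), function(j) sum(data$time > lo[j] - 1e-12),
                   numeric(1))
  # drop trailing intervals with no exposure at all
  keep <- max(which(exposure > 0))
  out <- data.frame(start = lo, end = hi, mid = (lo + hi) / 2,
                    log_mid = log((lo + hi) / 2),
                    deaths = deaths, exposure = exposure,
                    n_risk = n_risk)[seq_len(keep), ]
  attr(out, "edges") <- edges[seq_len(keep + 1L)]
  class(out) <- c("interval_counts", "data.frame")
  out
}

#' Kernel-smoothed hazard estimate
#'
#' Smooths the crude interval mortality rates with an Epanechnikov kernel:
#' `h(t) = sum_j K((t - t_j)/b) d_j / sum_j K((t - t_j)/b) e_j`, a
#' nonnegative kernel-weighted occurrence/exposure rate. Used for the
#' "observed hazard" overlay on model fits.
#'
#' @param data A `surv_data` object.
#' @param bandwidth Kernel bandwidth in years (`> 0`).
#' @param width Width of the underlying fine discretization (default
#'   `bandwidth / 4`).
#' @param times Evaluation grid; defaults to the fine-interval midpoints.
#' @return A [hazard_curve()].
#' @export
smoothed_hazard <- function(data, bandwidth, width = bandwidth / 4,
                            times = NULL) {
  stopifnot(inherits(data, "surv_data"))
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  ic <- discretize(data, default_edges(data, width = width))
  if (is.null(times)) times <- ic$mid
  epan <- function(u) pmax(0, 0.75 * (1 - u^2))
  h <- vapply(times, function(t0) {
    w <- epan((t0 - ic$mid) / bandwidth)
    num <- sum(w * ic$deaths)
    den <- sum(w * ic$exposure)
    if (den <= 0) 0 else num / den
  }, numeric(1))
  hazard_curve(time = times, hazard = h)
}

#' @export
print.surv_data <- function(x, ...) {
  cat("Survival dataset:", nrow(x), "subjects,", sum(x$event), "events")
  if (!is.null(x$arm)) cat(" (arms: ", paste(unique(x$arm), collapse = ", "), ")",
                           sep = "")
  cat("\n  follow-up (years): ", format(min(x$time), digits = 3), " - ",
      format(max(x$time), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.interval_counts <- function(x, ...) {
  cat("Interval counts:", nrow(x), "intervals, ",
      sum(x$deaths), "deaths, ",
      format(sum(x$exposure), digits = 6), "person-years\n")
  invisible(x)
}
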