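#' Construct and validate a life table
#'
#' A life table holds, for a contiguous run of integer ages, the annual
#' probability of death `qx`. It is the external-evidence input for all
#' relative-survival (excess hazard) models in this package: combined with a
#' cohort starting age it defines the general-population background hazard.
#'
#' @param age Integer ages, contiguous and ascending (step 1).
#' @param qx Annual death probabilities, one per age, each in `[0, 1]`.
#' @param sex Optional sex label for the table (informational only).
#' @return An object of class `life_table`: a data frame with columns
#'   `age` and `qx`, plus a `sex` attribute.
#' @examples
#' lt <- life_table(age = 60:61, qx = c(0.01, 0.012))
#' @export
life_table <- function(age, qx, sex = NULL) {
  age <- as.integer(age)
  qx <- as.numeric(qx)
  if (length(age) < 2L) {
    stop("a life table needs at least 2 ages", call. = FALSE)
  }
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have the same length", call. = FALSE)
  }
  ord <- order(age)
  age <- age[ord]
  qx <- qx[ord]
  if (any(diff(age) != 1L)) {
    stop("life table ages must be contiguous (step 1): non-contiguous ages found",
         call. = FALSE)
  }
  bad <- which(!is.finite(qx) | qx < 0 | qx > 1)
  if (length(bad)) {
    stop(sprintf("qx outside [0, 1] at age %d", age[bad[1L]]), call. = FALSE)
  }
  out <- data.frame(age = age, qx = qx)
  attr(out, "sex") <- sex
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Accepts a Human-Mortality-Database-style layout: one row per age with an
#' age column and either an annual death probability (`qx`) or a central
#' death rate (`mx`). A central rate is converted to a probability with the
#' standard mid-year-exposure approximation `q = m / (1 + m / 2)`.
#'
#' @param path CSV file with a single header row.
#' @param age_col,qx_col,mx_col,sex_col Column names. `qx_col` takes
#'   precedence; if absent, `mx_col` is required and converted.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path, age_col = "Age", qx_col = "qx",
                            mx_col = "mx", sex_col = "Sex") {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!age_col %in% names(raw)) {
    stop("age column '", age_col, "' not found in ", path, call. = FALSE)
  }
  age <- suppressWarnings(as.integer(raw[[age_col]]))
  if (anyNA(age)) stop("age column is not parseable as integers", call. = FALSE)
  if (qx_col %in% names(raw)) {
    qx <- as.numeric(raw[[qx_col]])
  } else if (mx_col %in% names(raw)) {
    m <- as.numeric(raw[[mx_col]])
    qx <- m / (1 + m / 2)
  } else {
    stop("need a '", qx_col, "' or '", mx_col, "' column", call. = FALSE)
  }
  sex <- if (sex_col %in% names(raw)) unique(raw[[sex_col]])[1L] else NULL
  life_table(age = age, qx = qx, sex = sex)
}

#' Write a life table to CSV
#'
#' Inverse of [read_life_table()]; round-trips `age` and `qx` exactly
#' (full double precision).
#'
#' @param lt A [life_table()].
#' @param path Output CSV path.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  df <- data.frame(Age = lt$age, qx = format(lt$qx, digits = 17, trim = TRUE))
  sex <- attr(lt, "sex")
  if (!is.null(sex)) df$Sex <- sex
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthesize a Gompertz-Makeham life table
#'
#' Builds a life table from the Gompertz-Makeham adult mortality law
#' `h(age) = lambda + alpha * exp(beta * age)`: a constant background rate
#' plus an exponentially age-increasing senescent component. Annual death
#' probabilities are `q_a = 1 - exp(-H_a)` where `H_a` is the hazard
#' integrated over the age-year by quadrature.
#'
#' Defaults are tuned to resemble recent all-cause mortality of a
#' high-income general population at adult ages (about 1% annual mortality
#' at age 63, doubling roughly every 7.5 years).
#'
#' @param ages Integer ages to cover (contiguous).
#' @param lambda Makeham (age-constant) hazard component, per year.
#' @param alpha,beta Gompertz level and log-slope per year of age.
#' @return A [life_table()].
#' @export
synthetic_life_table <- function(ages = 50:110, lambda = 5e-4,
                                 alpha = 3e-5, beta = 0.092) {
  haz <- function(a) lambda + alpha * exp(beta * a)
  if (any(haz(range(ages)) < 0)) {
    stop("Gompertz-Makeham parameters give a negative hazard", call. = FALSE)
  }
  qx <- vapply(ages, function(a) {
    H <- stats::integrate(haz, a, a + 1, rel.tol = 1e-12)$value
    1 - exp(-H)
  }, numeric(1))
  life_table(age = ages, qx = qx)
}

#' Background hazard curve for a cohort
#'
#' Attaches a starting age to a life table, giving an evaluable
#' general-population hazard as a function of time since cohort entry.
#' Within each year of age the hazard follows the uniform-distribution-of-
#' deaths convention: at age `a + f` (with `f` in `[0, 1)`) the hazard is
#' `q_a / (1 - f * q_a)`. A piecewise-constant alternative (`h = -log(1 -
#' q_a)` across the whole age-year) is available via `convention`.
#'
#' @param lt A [life_table()].
#' @param start_age Cohort age at time zero (years; may be fractional).
#' @param convention `"uniform_deaths"` (default) or `"constant"`.
#' @return An object of class `pop_hazard`.
#' @export
pop_hazard <- function(lt, start_age,
                       convention = c("uniform_deaths", "constant")) {
  stopifnot(inherits(lt, "life_table"))
  convention <- match.arg(convention)
  if (start_age < min(lt$age) || start_age > max(lt$age)) {
    stop("start_age outside the life-table age range", call. = FALSE)
  }
  structure(list(lt = lt, start_age = start_age, convention = convention),
            class = "pop_hazard")
}

ph_lookup <- function(ph, t) {
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  age <- ph$start_age + t
  a <- floor(age)
  lt <- ph$lt
  if (any(a > max(lt$age))) {
    stop("time beyond the life-table range (age ", max(lt$age) + 1,
         "); extend the life table", call. = FALSE)
  }
  idx <- match(a, lt$age)
  list(q = lt$qx[idx], f = age - a, a = a)
}

#' Evaluate the background hazard
#'
#' @param ph A [pop_hazard()] curve.
#' @param t Times since cohort entry (years, vectorised).
#' @return Hazard per year at each `t`.
#' @export
population_hazard <- function(ph, t) {
  stopifnot(inherits(ph, "pop_hazard"))
  lk <- ph_lookup(ph, t)
  if (ph$convention == "uniform_deaths") {
    lk$q / (1 - lk$f * lk$q)
  } else {
    -log1p(-pmin(lk$q, 1 - 1e-12))
  }
}

#' Cumulative background hazard
#'
#' Closed form under uniform deaths: the contribution of a fraction `f` of
#' the year of age `a` is `-log(1 - f * q_a)`.
#'
#' @inheritParams population_hazard
#' @return Cumulative hazard from 0 to each `t`.
#' @export
population_cum_hazard <- function(ph, t) {
  stopifnot(inherits(ph, "pop_hazard"))
  lt <- ph$lt
  vapply(t, function(ti) {
    if (ti < 0) stop("t must be nonnegative", call. = FALSE)
    age <- ph$start_age + ti
    a_end <- floor(age)
    if (a_end > max(lt$age)) {
      stop("time beyond the life-table range (age ", max(lt$age) + 1,
           "); extend the life table", call. = FALSE)
    }
    cum <- 0
    a0 <- floor(ph$start_age)
    # partial first year if start_age is fractional
    ages_full <- if (a_end > a0) a0:(a_end - 1L) else integer(0)
    for (a in ages_full) {
      q <- lt$qx[match(a, lt$age)]
      f0 <- if (a == a0) ph$start_age - a0 else 0
      if (ph$convention == "uniform_deaths") {
        cum <- cum + (-log1p(-q)) - (-log1p(-f0 * q))
      } else {
        cum <- cum + (1 - f0) * (-log1p(-min(q, 1 - 1e-12)))
      }
    }
    f_end <- age - a_end
    if (f_end > 0) {
      q <- lt$qx[match(a_end, lt$age)]
      f0 <- if (a_end == a0) ph$start_age - a0 else 0
      if (ph$convention == "uniform_deaths") {
        cum <- cum + (-log1p(-f_end * q)) - (-log1p(-f0 * q))
      } else {
        cum <- cum + (f_end - f0) * (-log1p(-min(q, 1 - 1e-12)))
      }
    }
    cum
  }, numeric(1))
}

#' Background survival function
#'
#' @inheritParams population_hazard
#' @return Survival probability at each `t` for a population member aged
#'   `start_age` at time zero.
#' @export
population_survival <- function(ph, t) {
  exp(-population_cum_hazard(ph, t))
}

#' Sample general-population survival times
#'
#' Samples the year of death from the discrete distribution implied by the
#' annual probabilities (conditional on being alive at the starting age),
#' then a uniform fraction within that year — the uniform-deaths-within-year
#' convention. Draws that outlive the table are returned at the table end
#' and flagged in the `"truncated"` attribute.
#'
#' @param ph A [pop_hazard()] with an integer starting age.
#' @param n Number of draws.
#' @return Numeric vector of times (years since entry) with a logical
#'   attribute `"truncated"` marking administratively truncated draws.
#' @export
sample_population_time <- function(ph, n) {
  stopifnot(inherits(ph, "pop_hazard"))
  lt <- ph$lt
  a0 <- ph$start_age
  if (a0 != floor(a0)) {
    stop("sampling requires an integer start_age", call. = FALSE)
  }
  q <- lt$qx[lt$age >= a0]
  k <- length(q)
  # P(death in year j | alive at entry), j = 1..k
  surv <- cumprod(1 - q)
  pdie <- c(q[1], surv[-k] * q[-1])
  cdf <- cumsum(pdie)
  u <- stats::runif(n)
  j <- findInterval(u, c(0, cdf), rightmost.closed = FALSE)  # 1..k, k+1 => survived table
  truncated <- j > k
  tmax <- k  # years covered by the table beyond start age
  frac <- stats::runif(n)
  out <- ifelse(truncated, tmax, (j - 1) + frac)
  attr(out, "truncated") <- truncated
  out
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table:", nrow(x), "ages", min(x$age), "-", max(x$age))
  sex <- attr(x, "sex")
  if (!is.null(sex)) cat(" (sex:", sex, ")")
  cat("\n")
  NextMethod()
}

#' @export
print.pop_hazard <- function(x, ...) {
  cat("General-population hazard curve\n")
  cat("  start age:", x$start_age, " convention:", x$convention, "\n")
  cat("  life table ages:", min(x$lt$age), "-", max(x$lt$age), "\n")
  invisible(x)
}
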