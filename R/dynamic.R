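# Dynamic (relative) survival models: state-space models on the log hazard
# (DSM) or log excess hazard (DRSM) observed through interval death counts.
#
# Observation:  d_j ~ Poisson(e_j * h_j)
#   DSM:   h_j = exp(eta_j)
#   DRSM:  h_j = p_j + exp(eta_j)   (p_j = population hazard at the midpoint)
# States evolve on the log-time scale x_j = log t_j, step D_j = x_{j+1}-x_j:
#   local_level:  eta_{j+1} = eta_j + w_j,                w_j ~ N(0, sl^2 D_j)
#   local_trend:  eta_{j+1} = eta_j + delta_j D_j + w_j
#                 delta_{j+1} = delta_j + v_j,            v_j ~ N(0, st^2 D_j)
#   damped_trend: as local_trend with delta_{j+1} = phi^{D_j} delta_j + v_j
# With all innovation scales zero the local-trend log hazard is exactly
# affine in log time; the damped trend's extrapolated log hazard converges
# to a finite limit.

#' Specify a dynamic (relative) survival model
#'
#' @param structure `"local_level"`, `"local_trend"` or `"damped_trend"`.
#' @param relative Model the log *excess* hazard above a population curve
#'   (DRSM) rather than the log overall hazard (DSM)?
#' @param pop A [pop_hazard()] curve (required when `relative = TRUE`).
#' @param phi Damping factor in (0, 1): `NULL` (default) to estimate it
#'   under a Uniform(0.5, 1) prior, or a fixed numeric value. Damped
#'   structure only. Damping is applied as `phi^D_j` per log-time step so
#'   inference is invariant to re-discretization.
#' @param sigma_level,sigma_trend Innovation scales: `NULL` (default) to
#'   estimate under half-Normal(0, 1) priors, or fixed numeric values
#'   (`>= 0`; fixing both to 0 gives the deterministic reduction, e.g. a
#'   log-log-linear hazard for the local trend).
#' @param eta1_sd Prior SD of the initial log (excess) hazard around the
#'   crude rate (default 2).
#' @return A `dsm_spec` object.
#' @export
dsm_spec <- function(structure = c("local_trend", "local_level", "damped_trend"),
                     relative = FALSE, pop = NULL, phi = NULL,
                     sigma_level = NULL, sigma_trend = NULL, eta1_sd = 2) {
  structure <- match.arg(structure)
  if (relative && !inherits(pop, "pop_hazard")) {
    stop("relative = TRUE requires a `pop` hazard curve", call. = FALSE)
  }
  if (!is.null(phi)) {
    if (structure != "damped_trend") {
      stop("phi applies to the damped_trend structure only", call. = FALSE)
    }
    if (phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)", call. = FALSE)
  }
  for (s in list(sigma_level, sigma_trend)) {
    if (!is.null(s) && s < 0) stop("innovation scales must be >= 0", call. = FALSE)
  }
  structure(list(structure = structure, relative = relative, pop = pop,
                 phi = phi, sigma_level = sigma_level,
                 sigma_trend = sigma_trend, eta1_sd = eta1_sd),
            class = "dsm_spec")
}

has_trend <- function(spec) spec$structure %in% c("local_trend", "damped_trend")

#' Deterministic state path of a dynamic model
#'
#' Propagates the states through the transition equations with all
#' innovations set to zero: the point forecast. For the local trend this is
#' affine in log time; for the damped trend the increments attenuate
#' geometrically in cumulative log time, `delta(x) = delta0 * phi^(x - x0)`,
#' so the forecast log hazard converges to a finite limit.
#'
#' @param eta0,delta0 States at log time `x0`.
#' @param phi Damping factor (use 1 for an undamped local trend).
#' @param x0 Starting log time.
#' @param x Ascending log times beyond `x0`.
#' @return Numeric vector: the log (excess) hazard at each `x`.
#' @export
dsm_point_forecast <- function(eta0, delta0, phi, x0, x) {
  stopifnot(all(diff(c(x0, x)) > 0))
  eta <- numeric(length(x))
  e <- eta0
  dl <- delta0
  xprev <- x0
  for (k in seq_along(x)) {
    dx <- x[k] - xprev
    e <- e + dl * dx
    dl <- phi^dx * dl
    eta[k] <- e
    xprev <- x[k]
  }
  eta
}

# ---- log posterior and gradient (unconstrained parameterization) -----------
# theta layout: eta[1..J], (delta[1..J]), (log sigma_level), (log sigma_trend),
# (psi with phi = 0.5 + 0.5 * plogis(psi)); estimated blocks only.

dsm_parse_theta <- function(theta, layout) {
  J <- layout$J
  out <- list(eta = theta[seq_len(J)])
  pos <- J
  if (layout$trend) {
    out$delta <- theta[pos + seq_len(J)]
    pos <- pos + J
  }
  if (layout$est_sl) {
    out$sl <- exp(theta[pos + 1L]); pos <- pos + 1L
  } else out$sl <- layout$sigma_level
  if (layout$trend) {
    if (layout$est_st) {
      out$st <- exp(theta[pos + 1L]); pos <- pos + 1L
    } else out$st <- layout$sigma_trend
  }
  if (layout$est_phi) {
    out$psi <- theta[pos + 1L]
    out$phi <- 0.5 + 0.5 * stats::plogis(out$psi)
  } else out$phi <- layout$phi
  out
}

#' Build a dynamic survival model from interval counts
#'
#' Assembles the Poisson state-space model: data, parameter layout, and the
#' log-posterior density with its analytic gradient on the unconstrained
#' parameterization. Mostly an internal workhorse for [fit_dsm()], exposed
#' for inspection and testing.
#'
#' @param counts An [discretize()] `interval_counts` object (first midpoint
#'   must be positive).
#' @param spec A [dsm_spec()].
#' @return A list with elements `logpost(theta)`, `grad(theta)`, `layout`,
#'   `data` (d, e, x, dx, pop), and `init` (starting values).
#' @export
dsm_model <- function(counts, spec) {
  stopifnot(inherits(counts, "interval_counts"), inherits(spec, "dsm_spec"))
  J <- nrow(counts)
  if (J < 2L) stop("need at least 2 intervals", call. = FALSE)
  d <- counts$deaths
  e <- counts$exposure
  x <- counts$log_mid
  if (x[1] <= -Inf || counts$mid[1] <= 0) {
    stop("first interval midpoint must be positive", call. = FALSE)
  }
  dx <- diff(x)
  pop <- if (spec$relative) population_hazard(spec$pop, counts$mid) else numeric(J)
  crude <- d / pmax(e, 1e-12)
  if (spec$relative && mean(pop >= crude) >= 0.5) {
    warning("population hazard exceeds the crude hazard in at least half ",
            "the intervals: the excess hazard is weakly identified",
            call. = FALSE)
  }
  exc0 <- max(sum(d) / sum(e) - mean(pop), 1e-3)
  m0 <- log(exc0)
  trend <- has_trend(spec)
  layout <- list(J = J, trend = trend,
                 est_sl = is.null(spec$sigma_level),
                 sigma_level = spec$sigma_level,
                 est_st = trend && is.null(spec$sigma_trend),
                 sigma_trend = spec$sigma_trend,
                 est_phi = spec$structure == "damped_trend" && is.null(spec$phi),
                 phi = if (spec$structure == "damped_trend")
                   spec$phi else if (trend) 1 else NA_real_)
  npar <- J + trend * J + layout$est_sl + (trend && layout$est_st) +
    layout$est_phi
  s0sq <- spec$eta1_sd^2

  logpost <- function(theta) {
    p <- dsm_parse_theta(theta, layout)
    eta <- p$eta
    h <- pop + exp(eta)
    lp <- sum(d * log(h) - e * h)
    lp <- lp - (eta[1] - m0)^2 / (2 * s0sq)
    mu <- eta[-J] + if (trend) p$delta[-J] * dx else 0
    r <- eta[-1] - mu
    sl2 <- p$sl^2
    if (sl2 > 0) {
      lp <- lp - sum(r^2 / (2 * sl2 * dx)) - (J - 1) / 2 * log(sl2) -
        sum(log(dx)) / 2
    } else if (any(abs(r) > 1e-8)) return(-Inf)
    if (trend) {
      dl <- p$delta
      lp <- lp - dl[1]^2 / 2
      u <- dl[-1] - p$phi^dx * dl[-J]
      st2 <- p$st^2
      if (st2 > 0) {
        lp <- lp - sum(u^2 / (2 * st2 * dx)) - (J - 1) / 2 * log(st2)
      } else if (any(abs(u) > 1e-8)) return(-Inf)
    }
    if (layout$est_sl) lp <- lp - p$sl^2 / 2 + log(p$sl)
    if (trend && layout$est_st) lp <- lp - p$st^2 / 2 + log(p$st)
    if (layout$est_phi) {
      s <- stats::plogis(p$psi)
      lp <- lp + log(0.5 * s * (1 - s))
    }
    if (!is.finite(lp)) -Inf else lp
  }

  grad <- function(theta) {
    p <- dsm_parse_theta(theta, layout)
    eta <- p$eta
    h <- pop + exp(eta)
    g_eta <- (d / h - e) * exp(eta)
    g_eta[1] <- g_eta[1] - (eta[1] - m0) / s0sq
    mu <- eta[-J] + if (trend) p$delta[-J] * dx else 0
    r <- eta[-1] - mu
    sl2 <- p$sl^2
    rs <- r / (sl2 * dx)
    g_eta[-1] <- g_eta[-1] - rs
    g_eta[-J] <- g_eta[-J] + rs
    g <- g_eta
    if (trend) {
      dl <- p$delta
      u <- dl[-1] - p$phi^dx * dl[-J]
      st2 <- p$st^2
      us <- u / (st2 * dx)
      g_dl <- numeric(J)
      g_dl[-J] <- rs * dx + us * p$phi^dx
      g_dl[-1] <- g_dl[-1] - us
      g_dl[1] <- g_dl[1] - dl[1]
      g <- c(g, g_dl)
    }
    if (layout$est_sl) {
      g <- c(g, sum(r^2 / (sl2 * dx)) - (J - 1) - p$sl^2 + 1)
    }
    if (trend && layout$est_st) {
      g <- c(g, sum(u^2 / (st2 * dx)) - (J - 1) - p$st^2 + 1)
    }
    if (layout$est_phi) {
      dphi <- sum(us * dl[-J] * dx * p$phi^(dx - 1))
      s <- stats::plogis(p$psi)
      g <- c(g, dphi * 0.5 * s * (1 - s) + (1 - 2 * s))
    }
    g
  }

  init <- {
    eta0 <- rep(m0, J)
    th <- eta0
    if (trend) th <- c(th, numeric(J))
    if (layout$est_sl) th <- c(th, log(0.25))
    if (trend && layout$est_st) th <- c(th, log(0.25))
    if (layout$est_phi) th <- c(th, 0)
    th
  }

  list(logpost = logpost, grad = grad, layout = layout, npar = npar,
       data = list(d = d, e = e, x = x, dx = dx, pop = pop, mid = counts$mid,
                   m0 = m0, eta1_sd = spec$eta1_sd),
       spec = spec, init = init)
}

# ---- Laplace engine --------------------------------------------------------
# Marginal (nested) Laplace approximation. The states are a Gaussian Markov
# field conditional on the hyperparameters psi = (log sigma_level,
# log sigma_trend, logit-type phi): for fixed psi the posterior over states
# is approximated by a Gaussian at its mode (Fisher-scoring Newton, expected
# Poisson curvature), and the hyperparameter marginal by the Laplace
# integral. A joint MAP over states and scales is deliberately avoided: it
# falls into the hierarchical funnel (scales collapse to zero).

mvn_draws_from_precision <- function(mode, H, n) {
  p <- length(mode)
  ridge <- 0
  U <- NULL
  for (k in 0:8) {
    U <- tryCatch(chol(H + diag(ridge, p)), error = function(e) NULL)
    if (!is.null(U)) break
    ridge <- if (ridge == 0) 1e-8 * mean(abs(diag(H))) else ridge * 10
  }
  if (is.null(U)) stop("Hessian could not be regularized", call. = FALSE)
  z <- matrix(stats::rnorm(n * p), p, n)
  t(mode + backsolve(U, z))
}

# hyperparameter vector <-> named values
dsm_parse_psi <- function(psi, layout) {
  out <- list()
  pos <- 0L
  if (layout$est_sl) {
    out$sl <- exp(psi[pos + 1L]); pos <- pos + 1L
  } else out$sl <- layout$sigma_level
  if (layout$trend) {
    if (layout$est_st) {
      out$st <- exp(psi[pos + 1L]); pos <- pos + 1L
    } else out$st <- layout$sigma_trend
  }
  if (layout$est_phi) {
    out$psi_phi <- psi[pos + 1L]
    out$phi <- 0.5 + 0.5 * stats::plogis(out$psi_phi)
  } else out$phi <- layout$phi
  out
}

# Gaussian prior over the state vector s = (eta[1..J], delta[1..J]?) for
# fixed hyperparameters: precision Q and linear term b
dsm_state_prior <- function(hp, dat, layout) {
  J <- layout$J
  trend <- layout$trend
  p <- J * (1L + trend)
  Q <- matrix(0, p, p)
  b <- numeric(p)
  s0sq <- dat$eta1_sd^2
  Q[1, 1] <- 1 / s0sq
  b[1] <- dat$m0 / s0sq
  dx <- dat$dx
  cl <- 1 / (hp$sl^2 * dx)
  for (j in seq_len(J - 1L)) {
    # level transition: eta[j+1] - eta[j] - delta[j] dx[j]
    idx <- c(j + 1L, j, if (trend) J + j)
    a <- c(1, -1, if (trend) -dx[j])
    Q[idx, idx] <- Q[idx, idx] + cl[j] * tcrossprod(a)
  }
  if (trend) {
    Q[J + 1L, J + 1L] <- Q[J + 1L, J + 1L] + 1  # delta_1 ~ N(0, 1)
    ct <- 1 / (hp$st^2 * dx)
    damp <- hp$phi^dx
    for (j in seq_len(J - 1L)) {
      idx <- c(J + j + 1L, J + j)
      a <- c(1, -damp[j])
      Q[idx, idx] <- Q[idx, idx] + ct[j] * tcrossprod(a)
    }
  }
  list(Q = Q, b = b)
}

# Fisher-scoring Newton for the conditional state mode.
# f(eta) = sum d*log(pop + exp(eta)) - e*(pop + exp(eta));
# expected curvature W = e * E^2 / h (E = exp(eta), h = pop + E).
dsm_state_mode <- function(Qb, dat, layout, s_init, tol = 1e-8, maxit = 60L) {
  J <- layout$J
  idx <- seq_len(J)
  p <- length(s_init)
  Q <- Qb$Q
  b <- Qb$b
  s <- s_init
  lik <- function(eta) {
    h <- dat$pop + exp(eta)
    sum(dat$d * log(h) - dat$e * h)
  }
  Qs <- drop(Q %*% s)
  g_old <- lik(s[idx]) - 0.5 * sum(s * Qs) + sum(b * s)
  for (it in seq_len(maxit)) {
    E <- exp(s[idx])
    h <- dat$pop + E
    W <- dat$e * E^2 / h
    grad <- b - Qs
    grad[idx] <- grad[idx] + (dat$d / h - dat$e) * E
    H <- Q
    diag(H)[idx] <- diag(H)[idx] + W
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(H + diag(1e-8 * mean(abs(diag(H))), p), grad)
    }
    Qstep <- drop(Q %*% step)
    lam <- 1
    repeat {
      s_new <- s + lam * step
      Qs_new <- Qs + lam * Qstep
      g_new <- lik(s_new[idx]) - 0.5 * sum(s_new * Qs_new) + sum(b * s_new)
      if (is.finite(g_new) && g_new >= g_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { s_new <- s; Qs_new <- Qs; g_new <- g_old; break }
    }
    done <- max(abs(s_new - s)) < tol
    s <- s_new
    Qs <- Qs_new
    g_old <- g_new
    if (done) break
  }
  E <- exp(s[idx])
  h <- dat$pop + E
  H <- Q
  diag(H)[idx] <- diag(H)[idx] + dat$e * E^2 / h
  list(mode = s, H = H, obj = g_old)
}

# log marginal posterior of the hyperparameters (up to a constant)
dsm_marginal_lp <- function(psi, dat, layout, env) {
  hp <- dsm_parse_psi(psi, layout)
  if (!is.finite(hp$sl) || hp$sl <= 0) return(-Inf)
  if (layout$trend && (!is.finite(hp$st) || hp$st <= 0)) return(-Inf)
  if (layout$est_phi && !is.finite(hp$phi)) return(-Inf)
  Qb <- dsm_state_prior(hp, dat, layout)
  cQ <- tryCatch(chol(Qb$Q), error = function(e) NULL)
  if (is.null(cQ)) return(-Inf)
  sm <- dsm_state_mode(Qb, dat, layout, env$s_warm)
  env$s_warm <- sm$mode
  cH <- tryCatch(chol(sm$H), error = function(e) NULL)
  if (is.null(cH)) return(-Inf)
  mu <- backsolve(cQ, forwardsolve(t(cQ), Qb$b))
  lp <- sm$obj - 0.5 * sum(Qb$b * mu) +
    sum(log(diag(cQ))) - sum(log(diag(cH)))
  # hyperpriors (with log-scale / logit-scale Jacobians)
  pos <- 0L
  if (layout$est_sl) {
    lp <- lp - hp$sl^2 / 2 + log(hp$sl)
  }
  if (layout$trend && layout$est_st) {
    lp <- lp - hp$st^2 / 2 + log(hp$st)
  }
  if (layout$est_phi) {
    sg <- stats::plogis(hp$psi_phi)
    lp <- lp + log(0.5 * sg * (1 - sg))
  }
  if (!is.finite(lp)) -Inf else lp
}

fit_dsm_laplace <- function(model, n_draws, seed) {
  layout <- model$layout
  dat <- model$data
  J <- layout$J
  p <- J * (1L + layout$trend)
  m <- layout$est_sl + (layout$trend && layout$est_st) + layout$est_phi
  env <- new.env()
  env$s_warm <- c(rep(dat$m0, J), if (layout$trend) numeric(J))

  psi_hat <- numeric(0)
  Sigma_psi <- NULL
  if (m > 0) {
    psi0 <- c(if (layout$est_sl) log(0.3),
              if (layout$trend && layout$est_st) log(0.3),
              if (layout$est_phi) 0)
    neg <- function(psi) -dsm_marginal_lp(psi, dat, layout, env)
    opt <- stats::optim(psi0, neg, method = if (m == 1) "Brent" else "BFGS",
                        lower = if (m == 1) -12 else -Inf,
                        upper = if (m == 1) 5 else Inf,
                        control = list(maxit = 500, reltol = 1e-10))
    psi_hat <- opt$par
    Hpsi <- tryCatch(stats::optimHess(psi_hat, neg), error = function(e) NULL)
    Sigma_psi <- if (!is.null(Hpsi)) {
      tryCatch(solve((Hpsi + t(Hpsi)) / 2), error = function(e) NULL)
    } else NULL
    if (is.null(Sigma_psi) || any(!is.finite(Sigma_psi)) ||
        any(diag(Sigma_psi) <= 0)) {
      Sigma_psi <- diag(1e-6, m)
    }
    converged <- opt$convergence == 0
  } else {
    converged <- TRUE
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  psi_draws <- if (m > 0) {
    ch <- chol((Sigma_psi + t(Sigma_psi)) / 2)
    matrix(psi_hat, n_draws, m, byrow = TRUE) +
      matrix(stats::rnorm(n_draws * m), n_draws, m) %*% ch
  } else matrix(0, n_draws, 0)

  eta <- matrix(NA_real_, n_draws, J)
  delta <- if (layout$trend) matrix(NA_real_, n_draws, J) else NULL
  sl <- numeric(n_draws)
  st <- if (layout$trend) numeric(n_draws) else NULL
  phi <- if (model$spec$structure == "damped_trend") numeric(n_draws) else NULL
  # conditional mode at psi_hat as the warm start for every draw
  hp_hat <- dsm_parse_psi(psi_hat, layout)
  Qb_hat <- dsm_state_prior(hp_hat, dat, layout)
  sm_hat <- dsm_state_mode(Qb_hat, dat, layout, env$s_warm)
  for (i in seq_len(n_draws)) {
    hp <- dsm_parse_psi(psi_draws[i, ], layout)
    Qb <- dsm_state_prior(hp, dat, layout)
    sm <- dsm_state_mode(Qb, dat, layout, sm_hat$mode, tol = 1e-4, maxit = 2L)
    U <- tryCatch(chol(sm$H), error = function(e) NULL)
    if (is.null(U)) {
      U <- chol(sm$H + diag(1e-8 * mean(abs(diag(sm$H))), p))
    }
    s_draw <- sm$mode + backsolve(U, stats::rnorm(p))
    eta[i, ] <- s_draw[seq_len(J)]
    if (layout$trend) delta[i, ] <- s_draw[J + seq_len(J)]
    sl[i] <- hp$sl
    if (layout$trend) st[i] <- hp$st
    if (!is.null(phi)) phi[i] <- hp$phi
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(eta = eta, delta = delta, sl = sl, st = st, phi = phi,
       mode = sm_hat$mode, psi_hat = psi_hat, converged = converged)
}

# Deterministic reduction: all innovation scales fixed to zero, so the whole
# state path is a function of the initial states (and phi). MAP + Laplace
# over that low-dimensional parameter only.
fit_dsm_degenerate <- function(model, n_draws, seed) {
  layout <- model$layout
  spec <- model$spec
  dat <- model$data
  J <- layout$J
  trend <- layout$trend
  npar <- 1L + trend + layout$est_phi
  path_of <- function(th) {
    eta1 <- th[1]
    delta1 <- if (trend) th[2] else 0
    phi <- if (layout$est_phi) 0.5 + 0.5 * stats::plogis(th[npar]) else
      if (!is.na(layout$phi)) layout$phi else 1
    if (J > 1) {
      c(eta1, dsm_point_forecast(eta1, delta1, phi, dat$x[1], dat$x[-1]))
    } else eta1
  }
  neg <- function(th) {
    eta <- path_of(th)
    h <- dat$pop + exp(eta)
    lp <- sum(dat$d * log(h) - dat$e * h) -
      (th[1] - dat$m0)^2 / (2 * dat$eta1_sd^2)
    if (trend) lp <- lp - th[2]^2 / 2
    if (layout$est_phi) {
      s <- stats::plogis(th[npar])
      lp <- lp + log(0.5 * s * (1 - s))
    }
    if (!is.finite(lp)) 1e10 else -lp
  }
  opt <- stats::optim(c(dat$m0, numeric(npar - 1L)), neg, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  H <- stats::optimHess(opt$par, neg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  th_draws <- mvn_draws_from_precision(opt$par, H, n_draws)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  eta <- t(apply(th_draws, 1, path_of))
  delta <- if (trend) {
    phi_of <- function(th) if (layout$est_phi)
      0.5 + 0.5 * stats::plogis(th[npar]) else
        if (!is.na(layout$phi)) layout$phi else 1
    t(vapply(seq_len(nrow(th_draws)), function(i) {
      th <- th_draws[i, ]
      phi <- phi_of(th)
      th[2] * phi^(dat$x - dat$x[1])
    }, numeric(J)))
  } else NULL
  list(eta = eta, delta = delta,
       sl = rep(0, n_draws),
       st = if (trend) rep(0, n_draws) else NULL,
       phi = if (spec$structure == "damped_trend") {
         if (layout$est_phi) 0.5 + 0.5 * stats::plogis(th_draws[, npar])
         else rep(spec$phi, n_draws)
       } else NULL,
       mode = opt$par, converged = opt$convergence == 0)
}

# ---- MCMC engine (JAGS) ----------------------------------------------------

dsm_jags_string <- function(layout, spec) {
  trend <- layout$trend
  lines <- c(
    "model {",
    "  for (j in 1:J) {",
    "    h[j] <- pop[j] + exp(eta[j])",
    "    d[j] ~ dpois(e[j] * h[j] + 1e-12)",
    "  }",
    "  eta[1] ~ dnorm(m0, prec0)")
  if (trend) {
    damp <- if (spec$structure == "damped_trend") "pow(phi, dx[j-1])" else "1"
    lines <- c(lines,
      "  delta[1] ~ dnorm(0, 1)",
      "  for (j in 2:J) {",
      "    eta[j] ~ dnorm(eta[j-1] + delta[j-1] * dx[j-1], 1 / (sl2 * dx[j-1]))",
      paste0("    delta[j] ~ dnorm(", damp, " * delta[j-1], 1 / (st2 * dx[j-1]))"),
      "  }")
  } else {
    lines <- c(lines,
      "  for (j in 2:J) {",
      "    eta[j] ~ dnorm(eta[j-1], 1 / (sl2 * dx[j-1]))",
      "  }")
  }
  if (layout$est_sl) {
    lines <- c(lines, "  sig_l ~ dnorm(0, 1) T(0,)", "  sl2 <- pow(sig_l, 2)")
  } else {
    lines <- c(lines, "  sl2 <- pow(sig_l_fix, 2)")
  }
  if (trend) {
    if (layout$est_st) {
      lines <- c(lines, "  sig_t ~ dnorm(0, 1) T(0,)", "  st2 <- pow(sig_t, 2)")
    } else {
      lines <- c(lines, "  st2 <- pow(sig_t_fix, 2)")
    }
  }
  if (layout$est_phi) {
    lines <- c(lines, "  phi ~ dunif(0.5, 1)")
  }
  paste(c(lines, "}"), collapse = "\n")
}

fit_dsm_mcmc <- function(model, chains, iter, warmup, seed) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("engine = 'mcmc' requires the rjags package", call. = FALSE)
  }
  layout <- model$layout
  spec <- model$spec
  dat <- list(J = layout$J, d = model$data$d, e = model$data$e,
              pop = model$data$pop, m0 = model$data$m0,
              prec0 = 1 / model$data$eta1_sd^2)
  if (layout$J > 1) dat$dx <- model$data$dx
  if (!layout$est_sl) dat$sig_l_fix <- layout$sigma_level
  if (layout$trend && !layout$est_st) dat$sig_t_fix <- layout$sigma_trend
  if (spec$structure == "damped_trend" && !layout$est_phi) dat$phi <- spec$phi
  monitors <- c("eta",
                if (layout$trend) "delta",
                if (layout$est_sl) "sig_l",
                if (layout$trend && layout$est_st) "sig_t",
                if (layout$est_phi) "phi")
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch))
  })
  jm <- rjags::jags.model(textConnection(dsm_jags_string(layout, spec)),
                          data = dat, inits = inits, n.chains = chains,
                          quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = iter,
                            progress.bar = "none")
  sm
}

split_rhat <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(c) {
    cbind(mat[seq_len(n), c], mat[n + seq_len(n), c])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a dynamic (relative) survival model
#'
#' Fits the Poisson state-space model of [dsm_model()] and returns posterior
#' draws of the state paths and hyperparameters. Two engines are available:
#'
#' * `"mcmc"` (default): Gibbs/slice sampling via JAGS (package rjags);
#'   2 chains of 1000 retained draws after 1000 warmup iterations by
#'   default, with split-R-hat convergence diagnostics per parameter.
#' * `"laplace"`: posterior mode (L-BFGS with the analytic gradient)
#'   followed by Gaussian draws from the inverse observed-information
#'   Hessian. Orders of magnitude faster; used for simulation studies.
#'
#' @param counts An `interval_counts` object from [discretize()].
#' @param spec A [dsm_spec()].
#' @param engine `"mcmc"` or `"laplace"`.
#' @param chains,iter,warmup MCMC settings (per chain).
#' @param n_draws Number of posterior draws for the Laplace engine.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A `dsm_fit` object: matrices of posterior draws (`eta`, `delta`),
#'   vectors `sigma_level`, `sigma_trend`, `phi`, diagnostics, the spec and
#'   the interval data.
#' @export
fit_dsm <- function(counts, spec, engine = c("mcmc", "laplace"),
                    chains = 2L, iter = 1000L, warmup = 1000L,
                    n_draws = 1000L, seed = 1L) {
  engine <- match.arg(engine)
  model <- dsm_model(counts, spec)
  layout <- model$layout
  J <- layout$J
  trend <- layout$trend

  sl_zero <- !layout$est_sl && layout$sigma_level == 0
  st_zero <- !trend || (!layout$est_st && isTRUE(layout$sigma_trend == 0))
  if (sl_zero || (trend && !layout$est_st && isTRUE(layout$sigma_trend == 0))) {
    if (!(sl_zero && st_zero)) {
      stop("fixing one innovation scale to zero requires fixing all of them ",
           "to zero (the deterministic reduction)", call. = FALSE)
    }
    dg <- fit_dsm_degenerate(model, n_draws = n_draws, seed = seed)
    fit <- list(spec = spec, counts_data = model$data, eta = dg$eta,
                delta = dg$delta, sigma_level = dg$sl, sigma_trend = dg$st,
                phi = dg$phi,
                diagnostics = list(engine = "laplace", converged = dg$converged,
                                   rhat = data.frame(parameter = "(laplace)",
                                                     rhat = NA_real_),
                                   divergences = 0L),
                mode = NULL, engine = "laplace", seed = seed,
                n_draws = nrow(dg$eta))
    class(fit) <- "dsm_fit"
    return(fit)
  }

  if (engine == "laplace") {
    lp <- fit_dsm_laplace(model, n_draws = n_draws, seed = seed)
    eta <- lp$eta
    delta <- lp$delta
    sl <- lp$sl
    st <- lp$st
    phi <- lp$phi
    diag_df <- data.frame(parameter = "(laplace)", rhat = NA_real_)
    diagnostics <- list(engine = "laplace", converged = lp$converged,
                        rhat = diag_df, divergences = 0L)
    mode_parsed <- list(state_mode = lp$mode, psi_hat = lp$psi_hat)
  } else {
    sm <- fit_dsm_mcmc(model, chains, iter, warmup, seed)
    arr <- lapply(sm, as.matrix)       # per chain: iter x params
    nms <- colnames(arr[[1]])
    stack <- do.call(rbind, arr)
    get_block <- function(prefix, J) {
      cols <- paste0(prefix, "[", seq_len(J), "]")
      stack[, cols, drop = FALSE]
    }
    eta <- get_block("eta", J)
    delta <- if (trend) get_block("delta", J) else NULL
    sl <- if (layout$est_sl) stack[, "sig_l"] else rep(layout$sigma_level, nrow(stack))
    st <- if (trend) {
      if (layout$est_st) stack[, "sig_t"] else rep(layout$sigma_trend, nrow(stack))
    } else NULL
    phi <- if (spec$structure == "damped_trend") {
      if (layout$est_phi) stack[, "phi"] else rep(spec$phi, nrow(stack))
    } else NULL
    rhats <- vapply(nms, function(nm) {
      split_rhat(vapply(arr, function(a) a[, nm], numeric(nrow(arr[[1]]))))
    }, numeric(1))
    diag_df <- data.frame(parameter = nms, rhat = unname(rhats))
    if (any(is.finite(rhats) & rhats > 1.05)) {
      warning("split R-hat > 1.05 for: ",
              paste(nms[is.finite(rhats) & rhats > 1.05], collapse = ", "),
              call. = FALSE)
    }
    diagnostics <- list(engine = "mcmc", converged = TRUE, rhat = diag_df,
                        divergences = 0L)
    mode_parsed <- NULL
  }

  fit <- list(spec = spec, counts_data = model$data, eta = eta, delta = delta,
              sigma_level = sl, sigma_trend = st, phi = phi,
              diagnostics = diagnostics, mode = mode_parsed,
              engine = engine, seed = seed, n_draws = nrow(eta))
  class(fit) <- "dsm_fit"
  fit
}

#' Posterior hazard at the interval midpoints
#'
#' @param fit A `dsm_fit`.
#' @param type `"overall"` or `"excess"`.
#' @return Data frame `time`, `median`, `lower`, `upper` (central 95%).
#' @export
fitted_hazard <- function(fit, type = c("overall", "excess")) {
  stopifnot(inherits(fit, "dsm_fit"))
  type <- match.arg(type)
  hx <- exp(fit$eta)
  if (type == "overall") {
    hx <- sweep(hx, 2, fit$counts_data$pop, "+")
  }
  qs <- apply(hx, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(time = fit$counts_data$mid, median = qs[1, ],
             lower = qs[2, ], upper = qs[3, ])
}

#' Posterior trend path
#'
#' Pointwise posterior summaries of the trend state (the local slope of the
#' log (excess) hazard in log time) over the observation intervals.
#'
#' @param fit A `dsm_fit` with a trend state.
#' @return Data frame `time`, `median`, `lower`, `upper`.
#' @export
trend_path <- function(fit) {
  stopifnot(inherits(fit, "dsm_fit"))
  if (is.null(fit$delta)) {
    stop("the local_level structure has no trend state", call. = FALSE)
  }
  qs <- apply(fit$delta, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(time = fit$counts_data$mid, median = qs[1, ],
             lower = qs[2, ], upper = qs[3, ])
}

#' @rdname drsurv-generics
#' @param include_innovations Propagate fresh process noise into the
#'   forecast (the default), so extrapolation fans widen with horizon; with
#'   `FALSE` only state/hyperparameter uncertainty is carried forward.
#' @param seed Seed for the forecast innovations.
#' @export
extrapolate.dsm_fit <- function(object, times, include_innovations = TRUE,
                                seed = object$seed + 1L, ...) {
  stopifnot(inherits(object, "dsm_fit"))
  times <- as.numeric(times)
  xlast <- fit_last_x(object)
  if (any(times <= exp(xlast))) {
    stop("extrapolation grid must lie beyond the last data interval",
         call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("extrapolation grid must be strictly ascending", call. = FALSE)
  }
  spec <- object$spec
  pop <- if (spec$relative) population_hazard(spec$pop, times) else
    numeric(length(times))
  x <- log(times)
  M <- object$n_draws
  J <- ncol(object$eta)
  eta <- object$eta[, J]
  delta <- if (!is.null(object$delta)) object$delta[, J] else numeric(M)
  phi <- if (!is.null(object$phi)) object$phi else rep(1, M)
  sl <- object$sigma_level
  st <- if (!is.null(object$sigma_trend)) object$sigma_trend else numeric(M)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  K <- length(x)
  eta_path <- matrix(NA_real_, M, K)
  delta_path <- matrix(NA_real_, M, K)
  xprev <- xlast
  for (k in seq_len(K)) {
    dx <- x[k] - xprev
    eta <- eta + delta * dx
    if (include_innovations) eta <- eta + stats::rnorm(M, 0, sl * sqrt(dx))
    delta_new <- phi^dx * delta
    if (include_innovations && !is.null(object$delta)) {
      delta_new <- delta_new + stats::rnorm(M, 0, st * sqrt(dx))
    }
    delta <- delta_new
    eta_path[, k] <- eta
    delta_path[, k] <- delta
    xprev <- x[k]
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  h_draws <- sweep(exp(eta_path), 2, pop, "+")
  qs <- apply(h_draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  dqs <- apply(delta_path, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  out <- list(curve = hazard_curve(times, qs[1, ], lower = qs[2, ],
                                   upper = qs[3, ]),
              trend = data.frame(time = times, median = dqs[1, ],
                                 lower = dqs[2, ], upper = dqs[3, ]),
              hazard_draws = h_draws, eta_draws = eta_path,
              population = pop, relative = spec$relative)
  class(out) <- "dsm_extrap"
  out
}

fit_last_x <- function(fit) {
  log(fit$counts_data$mid[length(fit$counts_data$mid)])
}

#' Information score for a fitted dynamic model
#'
#' A deviance-information-style score: the Poisson deviance at the
#' posterior mean of the states plus twice the effective number of
#' parameters (mean deviance minus deviance at the mean). Comparable
#' between dynamic fits on the same interval data; *not* comparable with
#' the likelihoodist AIC of the parametric and spline models, whose
#' likelihood is subject-level.
#'
#' @param fit A `dsm_fit`.
#' @return A single numeric score (smaller is better).
#' @export
information_criterion <- function(fit) {
  stopifnot(inherits(fit, "dsm_fit"))
  d <- fit$counts_data$d
  e <- fit$counts_data$e
  pop <- fit$counts_data$pop
  dev_of <- function(eta) {
    h <- pop + exp(eta)
    -2 * sum(stats::dpois(d, e * h, log = TRUE))
  }
  devs <- apply(fit$eta, 1, dev_of)
  dev_mean <- dev_of(colMeans(fit$eta))
  p_eff <- max(mean(devs) - dev_mean, 0)
  dev_mean + 2 * p_eff
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat(if (x$spec$relative) "Dynamic relative survival model (DRSM):"
      else "Dynamic survival model (DSM):", x$spec$structure, "\n")
  cat("  engine:", x$engine, " draws:", x$n_draws,
      " intervals:", ncol(x$eta), "\n")
  if (!is.null(x$phi)) {
    cat("  phi: median", format(stats::median(x$phi), digits = 3), "\n")
  }
  cat("  sigma_level: median",
      format(stats::median(x$sigma_level), digits = 3), "\n")
  if (!is.null(x$sigma_trend)) {
    cat("  sigma_trend: median",
        format(stats::median(x$sigma_trend), digits = 3), "\n")
  }
  if (x$engine == "mcmc") {
    rr <- x$diagnostics$rhat$rhat
    cat("  max split R-hat:", format(max(rr, na.rm = TRUE), digits = 4), "\n")
  }
  invisible(x)
}

#' @export
fit_summary.dsm_fit <- function(fit) {
  list(model = paste0(if (fit$spec$relative) "drsm_" else "dsm_",
                      fit$spec$structure),
       engine = fit$engine, n_draws = fit$n_draws,
       sigma_level = stats::median(fit$sigma_level),
       sigma_trend = if (!is.null(fit$sigma_trend))
         stats::median(fit$sigma_trend) else NULL,
       phi = if (!is.null(fit$phi)) stats::median(fit$phi) else NULL,
       information_criterion = information_criterion(fit),
       max_rhat = if (fit$engine == "mcmc")
         max(fit$diagnostics$rhat$rhat, na.rm = TRUE) else NULL)
}
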