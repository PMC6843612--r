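# Poisson dynamic survival models (DGLMs) for life-table hazards.
#
# State-space formulation: the log hazard is the level component of a state
# vector that evolves by beta_t = F beta_{t-1} + innovation; observation
# y_t ~ Poisson(mu_t tau_t) with log mu_t equal to the level.  Filtering
# uses the conjugate-gamma moment-matched update for log-link Poisson
# counts: the prior (f, q) for the log hazard is matched to a Gamma(alpha,
# gamma) on the hazard scale via digamma/trigamma moments, updated in closed
# form to Gamma(alpha + y, gamma + tau), and the state posterior follows by
# linear Bayes.  Innovations enter by discounting the state covariance.

# Invert trigamma: alpha with trigamma(alpha) = q.  Newton on log(alpha)
# against log(trigamma), which is close to linear over the whole range and
# keeps the iterate positive.
trigamma_inv <- function(q) {
  a <- if (q > 1) 1 / sqrt(q) else 0.5 + 1 / q
  for (i in 1:100) {
    f <- log(trigamma(a)) - log(q)
    if (abs(f) < 1e-13) break
    slope <- a * psigamma(a, 2) / trigamma(a)  # d log trigamma / d log a
    a <- a * exp(-f / slope)
  }
  a
}

#' Specify a dynamic survival model
#'
#' @param structure \code{"local_level"} (1-D state, flat extrapolation),
#'   \code{"level_with_drift"} (level plus a fixed, non-evolving drift), or
#'   \code{"local_trend"} (level and trend both receive innovations).
#' @param b0 initial mean of the log-hazard level.
#' @param Z0 initial variance of the level (and, for \code{local_trend},
#'   optionally a length-2 vector with the trend variance).
#' @param delta discount factor in (0, 1]; 1 means no state evolution.
#' @param drift drift/trend initial value (log-hazard units per interval).
#' @return a \code{dsm_spec} list.
#' @export
dsm_spec <- function(structure = c("local_level", "level_with_drift",
                                   "local_trend"),
                     b0 = -3, Z0 = 1, delta = 0.95, drift = 0) {
  structure <- match.arg(structure)
  if (delta <= 0 || delta > 1) stop("discount factor must be in (0, 1]")
  if (any(Z0 < 0)) stop("initial variances must be nonnegative")
  if (structure == "local_trend" && length(Z0) == 1) Z0 <- c(Z0, Z0 / 100)
  structure(list(structure = structure, b0 = b0, Z0 = Z0, delta = delta,
                 drift = drift), class = "dsm_spec")
}

#' Run the conjugate-gamma DGLM filter over a life table
#'
#' Sequentially assimilates interval counts: at each interval the state
#' prior is propagated by the transition matrix with discount inflation, the
#' implied log-hazard prior is moment-matched to a gamma distribution on the
#' hazard scale, updated conjugately with the Poisson count and exposure,
#' and folded back into the state by linear Bayes. Intervals with zero
#' exposure are skipped (no update, no forecast contribution) and recorded.
#'
#' @param lt a \code{lifetable}.
#' @param spec a \code{dsm_spec}.
#' @return a \code{dsm_fit} with per-interval one-step-ahead hazard
#'   forecasts, forecast SSE against the empirical hazard, one-step
#'   predictive log-likelihood, filtered state means, and the final state.
#' @export
dsm_filter <- function(lt, spec) {
  stopifnot(inherits(lt, "lifetable"), inherits(spec, "dsm_spec"))
  if (nrow(lt) == 0L) stop("validation error: empty life table")
  N <- nrow(lt)
  y <- lt$events; tau <- lt$at_risk; lam <- lt$hazard
  dim2 <- spec$structure != "local_level"
  if (dim2) {
    F <- matrix(c(1, 0, 1, 1), 2, 2)
    m <- c(spec$b0, spec$drift)
    C <- diag(c(spec$Z0[1],
                if (spec$structure == "local_trend") spec$Z0[2] else 0))
    x <- c(1, 0)
  } else {
    F <- matrix(1, 1, 1)
    m <- spec$b0
    C <- matrix(spec$Z0[1], 1, 1)
    x <- 1
  }
  delta <- spec$delta
  forecasts <- rep(NA_real_, N)
  filtered <- rep(NA_real_, N)
  plog <- rep(NA_real_, N)
  states <- matrix(NA_real_, N, length(m))
  skipped <- integer(0)
  alpha_post <- gamma_post <- NA_real_
  for (t in seq_len(N)) {
    a <- as.vector(F %*% m)
    R <- F %*% C %*% t(F)
    if (spec$structure == "local_level") {
      R <- R / delta
    } else if (spec$structure == "level_with_drift") {
      R[1, 1] <- R[1, 1] / delta  # innovation on the level only
    } else {
      R <- R / delta
    }
    if (tau[t] <= 0) {
      skipped <- c(skipped, t)
      m <- a; C <- R
      states[t, ] <- m
      next
    }
    f <- sum(x * a)
    q <- as.numeric(t(x) %*% R %*% x)
    q <- max(q, 1e-12)
    alpha <- trigamma_inv(q)
    gam <- exp(digamma(alpha) - f)
    forecasts[t] <- alpha / gam
    plog[t] <- lgamma(alpha + y[t]) - lgamma(alpha) - lfactorial(y[t]) +
      alpha * log(gam / (gam + tau[t])) + y[t] * log(tau[t] / (gam + tau[t]))
    alpha_post <- alpha + y[t]
    gamma_post <- gam + tau[t]
    filtered[t] <- alpha_post / gamma_post
    fstar <- digamma(alpha_post) - log(gamma_post)
    qstar <- trigamma(alpha_post)
    Rx <- as.vector(R %*% x)
    m <- a + Rx * (fstar - f) / q
    C <- R - (Rx %*% t(Rx)) * (1 - qstar / q) / q
    states[t, ] <- m
  }
  used <- which(!is.na(forecasts))
  sse <- sum((forecasts[used] - lam[used])^2)
  # within-sample plug-in likelihood at the filtered (posterior) hazards
  filtered_logL <- poisson_loglik(y[used], filtered[used], tau[used])
  structure(list(spec = spec, forecasts = forecasts, filtered = filtered,
                 filtered_logL = filtered_logL, sse = sse,
                 pred_logL = sum(plog[used]), states = states,
                 final_mean = m, final_cov = C,
                 final_gamma = c(alpha = alpha_post, gamma = gamma_post),
                 skipped = skipped, lifetable = lt,
                 k = NA_real_, aic = NA_real_),
            class = "dsm_fit")
}

#' Fit a dynamic survival model by one-step-ahead forecast error
#'
#' Chooses the filter hyperparameters to minimize the sum of squared
#' one-step-ahead forecast errors against the empirical interval hazards:
#' for the local level, the initial level mean and variance and the discount
#' factor (3 parameters); with a global drift, additionally the drift value
#' (4); for the local trend, initial means and variances of level and trend
#' plus the discount (5). The AIC column uses the one-step predictive
#' log-likelihood with this parameter count.
#'
#' @param lt a \code{lifetable} with at least 10 intervals.
#' @param structure DSM structure (see \code{\link{dsm_spec}}).
#' @param delta_range search range for the discount factor.
#' @return a \code{dsm_fit} with \code{k}, \code{aic}, \code{logL} (one-step
#'   predictive), and a \code{predict_hazard} function covering both the
#'   observed range (one-step forecasts) and extrapolation.
#' @export
fit_dsm <- function(lt, structure = c("local_level", "level_with_drift",
                                      "local_trend"),
                    delta_range = c(0.8, 1)) {
  structure <- match.arg(structure)
  if (nrow(lt) < 10) stop("validation error: need at least 10 intervals")
  base_rate <- sum(lt$events) / sum(lt$at_risk)
  b0_start <- log(max(base_rate, 1e-6))
  to_delta <- function(u) delta_range[1] +
    (delta_range[2] - delta_range[1]) * stats::plogis(u)
  make_spec <- function(par) {
    switch(structure,
      local_level = dsm_spec("local_level", b0 = par[1], Z0 = exp(par[2]),
                             delta = to_delta(par[3])),
      level_with_drift = dsm_spec("level_with_drift", b0 = par[1],
                                  drift = par[2], Z0 = exp(par[3]),
                                  delta = to_delta(par[4])),
      local_trend = dsm_spec("local_trend", b0 = par[1], drift = par[2],
                             Z0 = c(exp(par[3]), exp(par[4])),
                             delta = to_delta(par[5])))
  }
  start <- switch(structure,
    local_level = c(b0_start, 0, 2),
    level_with_drift = c(b0_start, 0, 0, 2),
    local_trend = c(b0_start, 0, 0, -4, 2))
  obj <- function(par) {
    fit <- tryCatch(dsm_filter(lt, make_spec(par)), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$sse)) return(1e10)
    fit$sse
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (!is.finite(opt$value) || opt$value >= 1e10)
    stop("fitting error: DSM hyperparameter search failed")
  fit <- dsm_filter(lt, make_spec(opt$par))
  fit$k <- length(opt$par)
  fit$logL <- fit$pred_logL
  fit$aic <- aic(fit$pred_logL, fit$k)
  fit$name <- switch(structure, local_level = "DSM local level",
                     level_with_drift = "DSM local level with drift",
                     local_trend = "DSM local trend")
  width <- lt_width(lt)
  N <- nrow(lt)
  fc <- fit$forecasts
  # within-range: one-step forecasts; beyond: structural extrapolation
  fit$predict_hazard <- function(times) {
    idx <- floor(times / width) + 1L
    out <- numeric(length(times))
    inside <- idx <= N
    if (any(inside)) {
      v <- fc[pmin(idx[inside], N)]
      # zero-exposure intervals carried no forecast; use last available
      v <- ifelse(is.na(v), fc[max(which(!is.na(fc)))], v)
      out[inside] <- v
    }
    if (any(!inside)) {
      h <- max(idx[!inside]) - N
      out[!inside] <- dsm_forecast(fit, h)[idx[!inside] - N]
    }
    out
  }
  fit
}

#' Extrapolate hazards from a fitted dynamic model
#'
#' Local level: constant at the last filtered level. With a drift or trend
#' state: the log hazard continues linearly with the drift/trend component.
#'
#' @param fit a \code{dsm_fit}.
#' @param horizon number of intervals ahead (positive integer).
#' @return a positive hazard vector of length \code{horizon}.
#' @export
dsm_forecast <- function(fit, horizon) {
  stopifnot(inherits(fit, "dsm_fit"))
  if (horizon <= 0) stop("validation error: horizon must be positive")
  horizon <- as.integer(horizon)
  m <- fit$final_mean
  level <- m[1]
  slope <- if (length(m) > 1) m[2] else 0
  exp(level + seq_len(horizon) * slope)
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat(sprintf("<dsm_fit> %s\n", x$spec$structure))
  cat(sprintf("  delta = %.4f, forecast SSE = %.6g, predictive logL = %.4f\n",
              x$spec$delta, x$sse, x$pred_logL))
  if (!is.na(x$k))
    cat(sprintf("  k = %g, AIC = %.4f\n", x$k, x$aic))
  invisible(x)
}

#' @export
predict.dsm_fit <- function(object, times, ...) {
  if (is.null(object$predict_hazard))
    stop("predictions require a model fitted with fit_dsm()")
  object$predict_hazard(times)
}
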