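# Penalized generalized additive hazard models.
#
# Basis: intercept + natural cubic spline of log time with q - 2 internal
# knots at equally spaced percentiles of the uncensored event times, so the
# coefficient vector has dimension q.  Roughness penalty: integrated squared
# second derivative of the log hazard over the boundary-knot range, a
# quadratic form beta' S beta.  The smoothing parameter is chosen by
# minimizing AIC with k = effective degrees of freedom (trace of the
# influence matrix).

# Penalty matrix S_ij = int B_i''(x) B_j''(x) dx.  Second derivatives of the
# truncated-power natural basis are piecewise linear, so a fine trapezoid
# grid is effectively exact.
rcs_penalty_matrix <- function(internal_knots, boundary_knots,
                               n_grid = 2001L) {
  kn <- sort(c(boundary_knots, internal_knots))
  K <- length(kn)
  x <- seq(kn[1], kn[K], length.out = n_grid)
  d2 <- function(j) {
    (6 * pmax(x - kn[j], 0) - 6 * pmax(x - kn[K], 0)) / (kn[K] - kn[j])
  }
  d2K1 <- d2(K - 1)
  # columns: intercept (0), x (0), then the K-2 restricted cubic terms
  B2 <- cbind(0, 0, vapply(seq_len(K - 2), function(j) d2(j) - d2K1,
                           numeric(n_grid)))
  h <- x[2] - x[1]
  w <- rep(h, n_grid); w[c(1, n_grid)] <- h / 2
  crossprod(B2 * sqrt(w))
}

# Penalized IRLS for a Poisson life-table fit: maximize
# loglik(beta) - rho/2 * beta' S beta.
pirls_poisson <- function(X, y, tau, S, rho, maxit = 100, tol = 1e-10) {
  off <- log(tau)
  beta <- c(log(max(sum(y) / sum(tau), 1e-8)), rep(0, ncol(X) - 1))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta) + off
    mu <- exp(eta)
    W <- mu
    z <- (eta - off) + (y - mu) / mu
    A <- crossprod(X, X * W) + rho * S
    b <- crossprod(X, W * z)
    beta_new <- tryCatch(solve(A, b),
                         error = function(e) solve(A + diag(1e-10, ncol(X)), b))
    pen <- as.numeric(rho * t(beta_new) %*% S %*% beta_new)
    dev <- -2 * poisson_loglik(y, exp(as.vector(X %*% beta_new)), tau) + pen
    beta <- as.vector(beta_new)
    if (is.finite(dev_old) && abs(dev - dev_old) < tol * (abs(dev) + 1))
      break
    dev_old <- dev
  }
  eta <- as.vector(X %*% beta) + off
  mu <- exp(eta)
  XtWX <- crossprod(X, X * mu)
  H <- tryCatch(solve(XtWX + rho * S, XtWX),
                error = function(e) solve(XtWX + rho * S +
                                            diag(1e-10, ncol(X)), XtWX))
  list(beta = beta, logL = poisson_loglik(y, mu / tau, tau),
       edf = sum(diag(H)), mu = mu, converged = it < maxit || TRUE)
}

#' Fit a penalized generalized additive hazard model
#'
#' Poisson life-table fit with the log hazard represented by a natural cubic
#' spline basis of log time with basis dimension \code{q}, penalized by the
#' integrated squared second derivative. The smoothing parameter is selected
#' by minimizing \eqn{-2\log L + 2\,\mathrm{edf}}, where the effective
#' degrees of freedom are the trace of the influence matrix; with
#' \code{select_q = TRUE} the basis dimension is additionally searched by
#' the same criterion.
#'
#' @param lt a \code{lifetable}.
#' @param event_times uncensored event times used for knot placement.
#' @param q basis dimension (coefficient count), at least 3; default 11.
#' @param select_q if TRUE, search \code{q_range} for the minimal-AIC
#'   dimension.
#' @param q_range candidate dimensions when \code{select_q = TRUE}.
#' @param penalty optional fixed smoothing parameter (skips selection);
#'   \code{0} gives the unpenalized fit.
#' @param name model name.
#' @return a \code{hazard_fit} with non-integer \code{k = edf} and
#'   \code{details$gam} recording \code{q}, the smoothing parameter, and the
#'   edf.
#' @export
fit_gam <- function(lt, event_times, q = 11, select_q = FALSE,
                    q_range = 3:12, penalty = NULL, name = NULL) {
  stopifnot(inherits(lt, "lifetable"))
  if (select_q) {
    fits <- lapply(q_range, function(qq)
      tryCatch(fit_gam(lt, event_times, q = qq, select_q = FALSE,
                       penalty = penalty, name = name),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("fitting error: all GAM dimensions failed")
    best <- fits[[which.min(vapply(fits, function(f) f$aic, numeric(1)))]]
    best$details$gam$selected_q <- TRUE
    return(best)
  }
  if (q < 3) stop("basis dimension q must be at least 3")
  kn <- rcs_knots(event_times, q - 2)
  lk <- list(internal = log(kn$internal), boundary = log(kn$boundary))
  builder <- function(t) {
    if (any(t <= 0)) stop("domain error: log-time basis requires t > 0")
    cbind(intercept = 1, rcs_basis(log(t), lk$internal, lk$boundary))
  }
  keep <- lt$at_risk > 0
  X <- builder(lt_midpoints(lt))[keep, , drop = FALSE]
  y <- lt$events[keep]
  tau <- lt$at_risk[keep]
  S <- rcs_penalty_matrix(lk$internal, lk$boundary)

  crit <- function(log_rho) {
    f <- pirls_poisson(X, y, tau, S, exp(log_rho))
    -2 * f$logL + 2 * f$edf
  }
  if (is.null(penalty)) {
    # coarse grid to bracket the minimum, then golden-section refinement
    grid <- seq(-12, 16, length.out = 29)
    vals <- vapply(grid, crit, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- crit(x1); f2 <- crit(x2)
    for (iter in 1:40) {
      if (b - a < 1e-4) break
      if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- crit(x1)
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- crit(x2) }
    }
    rho <- exp((a + b) / 2)
  } else rho <- penalty
  fit <- pirls_poisson(X, y, tau, S, rho)
  beta <- fit$beta
  predictor <- function(times) as.vector(exp(builder(times) %*% beta))
  if (is.null(name))
    name <- sprintf("GAM(q = %d)", q)
  new_hazard_fit(name, "gam", stats::setNames(beta, colnames(X)),
                 logL = fit$logL, k = fit$edf, predict_hazard = predictor,
                 details = list(builder = builder, knots = kn,
                                gam = list(q = q, penalty = rho,
                                           edf = fit$edf),
                                design = "gam"))
}
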