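# Interval-level Gaussian frailty (GLMM) for life-table hazards.
#
# Adds an independent N(0, psi^2) random intercept b_t to each life-table
# interval's log hazard.  Because the random effects are independent across
# intervals, the marginal likelihood factorizes into one-dimensional
# integrals, evaluated by a Laplace approximation (with an adaptive
# Gauss-Hermite alternative used as a numerical cross-check).

# Gauss-Hermite nodes/weights (Golub-Welsch) for weight exp(-z^2).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Per-interval integrand exponent and derivatives:
# g(b) = y (eta + b) - tau e^{eta + b} - b^2/(2 psi2), plus constants.
frailty_modes <- function(eta, y, tau, psi2) {
  b <- numeric(length(eta))
  for (it in 1:50) {
    mu <- tau * exp(eta + b)
    g1 <- y - mu - b / psi2
    g2 <- -mu - 1 / psi2
    step <- g1 / g2
    # damped Newton for stability at large psi2
    step <- pmax(pmin(step, 2), -2)
    b <- b - step
    if (max(abs(g1)) < 1e-10) break
  }
  b
}

#' Marginal log-likelihood of the interval-frailty model
#'
#' @param beta fixed-effect coefficients.
#' @param psi2 frailty variance.
#' @param X design matrix (including intercept).
#' @param y,tau event counts and exposures.
#' @param method \code{"laplace"} or \code{"agq"} (adaptive Gauss-Hermite).
#' @param nodes quadrature nodes for \code{"agq"}.
#' @return the marginal log-likelihood.
#' @export
frailty_loglik <- function(beta, psi2, X, y, tau, method = c("laplace", "agq"),
                           nodes = 20) {
  method <- match.arg(method)
  eta <- as.vector(X %*% beta)
  if (psi2 < 1e-12) {
    return(poisson_loglik(y, exp(eta), tau))
  }
  bhat <- frailty_modes(eta, y, tau, psi2)
  g <- function(b) y * (eta + b) - tau * exp(eta + b) - b^2 / (2 * psi2)
  # y log(tau) completes the Poisson mass y log(mu tau) - mu tau - log y!
  const <- ifelse(y > 0, y * log(tau), 0) - lfactorial(y) -
    0.5 * log(2 * pi * psi2)
  g2 <- -tau * exp(eta + bhat) - 1 / psi2
  if (method == "laplace") {
    sum(g(bhat) + const + 0.5 * log(2 * pi) - 0.5 * log(-g2))
  } else {
    gh <- gauss_hermite(nodes)
    s <- 1 / sqrt(-g2)
    ll <- numeric(length(eta))
    for (t in seq_along(eta)) {
      b <- bhat[t] + sqrt(2) * s[t] * gh$nodes
      vals <- y[t] * (eta[t] + b) - tau[t] * exp(eta[t] + b) -
        b^2 / (2 * psi2) + gh$nodes^2
      m <- max(vals)
      ll[t] <- m + log(sum(gh$weights * exp(vals - m))) +
        log(sqrt(2) * s[t]) + const[t]
    }
    sum(ll)
  }
}

#' Fit an interval-level frailty (GLMM) hazard model
#'
#' Adds an independent Gaussian random intercept per life-table interval to
#' a fixed-effects Poisson hazard design and maximizes the
#' Laplace-approximate marginal likelihood over the fixed effects and the
#' frailty variance \eqn{\psi^2}. The parameter count adds one (for
#' \eqn{\psi^2}) to the fixed-effect count.
#'
#' @param lt a \code{lifetable}.
#' @param design a \code{design_spec}, or a numeric vector of FP powers as a
#'   shorthand for a fractional polynomial design.
#' @param psi2_fixed optionally hold \eqn{\psi^2} fixed (e.g. for profiling
#'   or shrinkage checks).
#' @param name model name.
#' @return a \code{hazard_fit} with \code{details$frailty} carrying
#'   \eqn{\psi^2}, the predicted interval effects \code{b}, and a boundary
#'   flag. The hazard predictor uses the fixed effects only (random effects
#'   exist only on observed intervals).
#' @export
fit_frailty <- function(lt, design, psi2_fixed = NULL, name = NULL) {
  stopifnot(inherits(lt, "lifetable"))
  if (is.numeric(design)) {
    powers <- design
    builder <- function(t) cbind(intercept = 1, fp_design(t, powers))
    label <- paste0("FP(", paste(powers, collapse = ", "), ")")
  } else {
    stopifnot(inherits(design, "design_spec"))
    builder <- design$builder
    label <- design$label
  }
  if (is.null(name)) name <- paste0(label, " + frailty")
  keep <- lt$at_risk > 0
  tmid <- lt_midpoints(lt)[keep]
  X <- builder(tmid)
  y <- lt$events[keep]
  tau <- lt$at_risk[keep]

  glm0 <- fit_poisson_design(lt, builder(lt_midpoints(lt)), name = label,
                             details = list(builder = builder))
  p <- ncol(X)
  obj <- function(par) {
    beta <- par[1:p]
    lpsi <- if (is.null(psi2_fixed)) par[p + 1] else log(sqrt(psi2_fixed))
    ll <- frailty_loglik(beta, exp(2 * lpsi), X, y, tau, method = "laplace")
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- c(glm0$coefficients, if (is.null(psi2_fixed)) log(0.3))
  lower <- c(rep(-Inf, p), if (is.null(psi2_fixed)) -8)
  upper <- c(rep(Inf, p), if (is.null(psi2_fixed)) 3)
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("fitting error: frailty optimization did not converge (code ",
         opt$convergence, ")")
  beta <- opt$par[1:p]
  psi2 <- if (is.null(psi2_fixed)) exp(2 * opt$par[p + 1]) else psi2_fixed
  boundary <- psi2 < 1e-6
  bhat <- if (boundary) numeric(length(y))
          else frailty_modes(as.vector(X %*% beta), y, tau, psi2)
  logL <- -opt$value
  predictor <- function(times) as.vector(exp(builder(times) %*% beta))
  k <- p + 1
  fit <- new_hazard_fit(name, "frailty_glmm", stats::setNames(beta, colnames(X)),
                        logL = logL, k = k, predict_hazard = predictor,
                        details = list(builder = builder, design = label,
                                       frailty = list(psi2 = psi2, b = bhat,
                                                      boundary = boundary,
                                                      intervals = which(keep))))
  fit
}
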