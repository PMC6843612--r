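#' Poisson life-table log-likelihood
#'
#' \eqn{\sum_t [y_t \log(\lambda_t \tau_t) - \lambda_t \tau_t - \log y_t!]},
#' the grouped Poisson likelihood for interval event counts with at-risk
#' exposure entering as an offset.
#'
#' @param y event counts per interval.
#' @param lambda per-interval hazards.
#' @param tau at-risk exposures.
#' @return the log-likelihood (a finite scalar).
#' @export
poisson_loglik <- function(y, lambda, tau) {
  stopifnot(length(y) == length(lambda), length(y) == length(tau))
  if (any(tau < 0)) stop("exposures must be nonnegative")
  mu <- lambda * tau
  if (any(y > 0 & mu == 0))
    stop("domain error: positive count with zero expected events")
  term <- -mu - lfactorial(y)
  pos <- y > 0
  term[pos] <- term[pos] + y[pos] * log(mu[pos])
  sum(term)
}

#' Binomial cumulative-failure log-likelihood
#'
#' \eqn{\sum_t [y_t \log(\pi_t/(1-\pi_t)) + n_t \log(1-\pi_t) +
#' \log{n_t \choose y_t}]} for cumulative failure counts \eqn{y_t} out of
#' \eqn{n_t} trials. Non-integer counts (actuarially adjusted) are accepted;
#' the binomial coefficient uses the gamma function.
#'
#' @param y cumulative failure counts.
#' @param pi cumulative failure probabilities.
#' @param n trial counts.
#' @return the log-likelihood.
#' @export
binomial_loglik <- function(y, pi, n) {
  stopifnot(length(y) == length(pi), length(y) == length(n))
  if (any(y < 0) || any(y > n)) stop("counts must satisfy 0 <= y <= n")
  interior <- y > 0 & y < n
  if (any(interior & (pi <= 0 | pi >= 1)))
    stop("domain error: probabilities must lie in (0, 1) for non-boundary counts")
  term <- numeric(length(y))
  pos <- y > 0
  term[pos] <- term[pos] + y[pos] * log(pi[pos])
  comp <- y < n
  term[comp] <- term[comp] + (n[comp] - y[comp]) * log1p(-pi[comp])
  sum(term + lchoose(n, y))
}

#' AIC from a log-likelihood and parameter count
#'
#' @param logL log-likelihood.
#' @param k parameter count (may be non-integer for penalized fits).
#' @return \eqn{-2 \log L + 2k}.
#' @export
aic <- function(logL, k) {
  stopifnot(k >= 0)
  -2 * logL + 2 * k
}

#' Exponential-family specification for a hazard GLM
#'
#' @param distribution \code{"poisson"} (interval event counts, exposure as
#'   offset) or \code{"binomial"} (cumulative failure among the initial
#'   cohort).
#' @param response response function mapping the linear predictor to the
#'   rate/probability: \code{"exponential"}, \code{"logistic"}, or
#'   \code{"inverse-probit"}.
#' @return a \code{family_spec} list.
#' @export
family_spec <- function(distribution = c("poisson", "binomial"),
                        response = c("exponential", "logistic",
                                     "inverse-probit")) {
  distribution <- match.arg(distribution)
  response <- match.arg(response)
  if (distribution == "poisson" && response != "exponential")
    stop("the Poisson pathway uses the exponential response (log link)")
  if (distribution == "binomial" && response == "exponential")
    stop("the binomial pathway uses the logistic or inverse-probit response")
  structure(list(distribution = distribution, response = response),
            class = "family_spec")
}

#' Time-covariate design for a hazard GLM
#'
#' Describes how interval time (evaluated at the interval midpoint, in years)
#' enters the linear predictor.
#'
#' @param transform \code{"none"} (intercept only), \code{"time"}, or
#'   \code{"log_time"}; or supply \code{builder} for a custom basis.
#' @param builder optional function mapping a vector of times (years) to a
#'   design matrix including the intercept column.
#' @param label name for the design; defaults to the transform.
#' @return a \code{design_spec} list with elements \code{label} and
#'   \code{builder}.
#' @export
design_spec <- function(transform = c("none", "time", "log_time"),
                        builder = NULL, label = NULL) {
  if (is.null(builder)) {
    transform <- match.arg(transform)
    builder <- switch(transform,
      none = function(t) cbind(intercept = rep(1, length(t))),
      time = function(t) cbind(intercept = 1, time = t),
      log_time = function(t) {
        if (any(t <= 0))
          stop("domain error: log-time design requires positive times")
        cbind(intercept = 1, log_time = log(t))
      })
    if (is.null(label)) label <- transform
  } else {
    transform <- "custom"
    if (is.null(label)) label <- "custom"
  }
  structure(list(label = label, transform = transform, builder = builder),
            class = "design_spec")
}

#' Standard survival models as GLM specifications
#'
#' Maps a standard survival model to its GLM components (outcome
#' distribution, response function, time covariate): exponential and
#' Gompertz/Weibull model the hazard as Poisson counts with an exponential
#' response and no/time/log-time covariate; log-logistic and lognormal model
#' cumulative failure as binomial with a logistic/inverse-probit response of
#' log time.
#'
#' @param name one of \code{"exponential"}, \code{"gompertz"},
#'   \code{"weibull"}, \code{"log-logistic"}, \code{"lognormal"}.
#' @return a list with elements \code{family} (a \code{family_spec}) and
#'   \code{design} (a \code{design_spec}).
#' @export
standard_spec <- function(name) {
  specs <- list(
    exponential = list(family_spec("poisson", "exponential"),
                       design_spec("none")),
    gompertz = list(family_spec("poisson", "exponential"),
                    design_spec("time")),
    weibull = list(family_spec("poisson", "exponential"),
                   design_spec("log_time")),
    `log-logistic` = list(family_spec("binomial", "logistic"),
                          design_spec("log_time")),
    lognormal = list(family_spec("binomial", "inverse-probit"),
                     design_spec("log_time")))
  if (!name %in% names(specs))
    stop("unknown model '", name, "'; valid names: ",
         paste(names(specs), collapse = ", "))
  stats::setNames(specs[[name]], c("family", "design"))
}

# Internal constructor for fitted hazard models.
new_hazard_fit <- function(name, kind, coefficients, logL, k,
                           predict_hazard, details = list()) {
  structure(list(name = name, kind = kind, coefficients = coefficients,
                 logL = logL, k = k, aic = aic(logL, k),
                 predict_hazard = predict_hazard, details = details),
            class = "hazard_fit")
}

# Poisson life-table GLM on an explicit design matrix (IRLS via glm.fit).
# Rows with zero exposure carry no information and are dropped.
fit_poisson_design <- function(lt, X, name, details = list(),
                               predictor = NULL) {
  keep <- lt$at_risk > 0
  Xk <- X[keep, , drop = FALSE]
  if (qr(Xk)$rank < ncol(Xk))
    stop("fitting error: design matrix is rank deficient")
  y <- lt$events[keep]
  tau <- lt$at_risk[keep]
  fit <- suppressWarnings(
    stats::glm.fit(Xk, y, offset = log(tau), family = stats::poisson(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 200)))
  if (!fit$converged)
    stop("fitting error: IRLS did not converge for model '", name, "'")
  beta <- fit$coefficients
  mu <- fit$fitted.values
  logL <- poisson_loglik(y, mu / tau, tau)
  if (is.null(predictor)) {
    builder <- details$builder
    predictor <- function(times) {
      as.vector(exp(builder(times) %*% beta))
    }
  }
  new_hazard_fit(name, "poisson_glm", beta, logL, k = length(beta),
                 predict_hazard = predictor,
                 details = c(details, list(fitted = mu, kept = which(keep))))
}

#' Fit a hazard GLM on a life table
#'
#' Maximum-likelihood fit of a hazard (Poisson) or cumulative-failure
#' (binomial) GLM. The Poisson pathway models per-interval event counts with
#' log at-risk exposure as offset, so \eqn{\hat\lambda(t) =
#' \exp(x_t^T\beta)} is the per-interval hazard. The binomial pathway models
#' the cumulative failure fraction of the initial cohort (estimated
#' actuarially to account for censoring) with \eqn{n = \tau_1} trials.
#'
#' @param lt a \code{lifetable}.
#' @param family a \code{family_spec}.
#' @param design a \code{design_spec}.
#' @param name model name for reporting.
#' @return a \code{hazard_fit} with coefficients, \code{logL}, \code{k},
#'   \code{aic}, and a hazard predictor.
#' @export
fit_glm <- function(lt, family, design, name = NULL) {
  stopifnot(inherits(lt, "lifetable"), inherits(family, "family_spec"),
            inherits(design, "design_spec"))
  if (nrow(lt) == 0L) stop("validation error: empty life table")
  tmid <- lt_midpoints(lt)
  if (is.null(name))
    name <- paste0(family$distribution, ":", design$label)
  if (family$distribution == "poisson") {
    X <- design$builder(tmid)
    fit_poisson_design(lt, X, name,
                       details = list(builder = design$builder,
                                      family = family, design = design$label))
  } else {
    fit_binomial_cumulative(lt, family, design, name)
  }
}

# Binomial cumulative-failure pathway: response is the actuarial cumulative
# failure probability among the initial cohort, n = tau_1 trials per
# interval.  Reported on the binomial likelihood scale (not comparable with
# the Poisson life-table logL).
fit_binomial_cumulative <- function(lt, family, design, name) {
  link <- switch(family$response, logistic = "logit",
                 `inverse-probit` = "probit",
                 stop("unsupported binomial response"))
  tmid <- lt_midpoints(lt)
  surv <- cumprod(1 - lt$hazard)
  p <- 1 - surv
  n1 <- lt$at_risk[1]
  keep <- p > 0 & p < 1
  X <- design$builder(tmid[keep])
  if (qr(X)$rank < ncol(X))
    stop("fitting error: design matrix is rank deficient")
  fam <- stats::binomial(link = link)
  fit <- suppressWarnings(
    stats::glm.fit(X, p[keep], weights = rep(n1, sum(keep)), family = fam,
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 200)))
  if (!fit$converged)
    stop("fitting error: IRLS did not converge for model '", name, "'")
  beta <- fit$coefficients
  logL <- binomial_loglik(p[keep] * n1, fit$fitted.values,
                          rep(n1, sum(keep)))
  width <- lt_width(lt)
  builder <- design$builder
  linkinv <- fam$linkinv
  cumfail <- function(times) as.vector(linkinv(builder(times) %*% beta))
  predictor <- function(times) {
    # derived per-interval hazard: conditional failure over one interval
    p2 <- cumfail(times)
    p1 <- ifelse(times - width > 0, cumfail(pmax(times - width, 1e-12)), 0)
    pmax((p2 - p1) / pmax(1 - p1, 1e-12), 0)
  }
  new_hazard_fit(name, "binomial_glm", beta, logL, k = length(beta),
                 predict_hazard = predictor,
                 details = list(builder = builder, family = family,
                                design = design$label, cumfail = cumfail,
                                trials = n1))
}

#' Fit a standard survival model as a GLM
#'
#' @param lt a \code{lifetable}.
#' @param name a standard model name (see \code{\link{standard_spec}}).
#' @return a \code{hazard_fit}.
#' @export
fit_standard <- function(lt, name) {
  spec <- standard_spec(name)
  fit_glm(lt, spec$family, spec$design, name = name)
}

#' Predict per-interval hazards from a fitted model
#'
#' @param model a \code{hazard_fit}.
#' @param times evaluation times in years (interval midpoints).
#' @return numeric vector of per-interval hazards.
#' @export
predict_hazard <- function(model, times) {
  stopifnot(inherits(model, c("hazard_fit", "dsm_fit")))
  model$predict_hazard(times)
}

#' @export
predict.hazard_fit <- function(object, times, ...) {
  predict_hazard(object, times)
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> %s (%s)\n", x$name, x$kind))
  cat(sprintf("  logL = %.4f, k = %.4g, AIC = %.4f\n", x$logL, x$k, x$aic))
  if (length(x$coefficients))
    print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$logL, df = object$k, class = "logLik")
}
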