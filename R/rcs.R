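#' Knot placement for restricted cubic splines
#'
#' Internal knots at equally spaced percentiles of the observed uncensored
#' event times (for m knots: the 100i/(m+1)th percentiles), boundary knots at
#' the extreme event times.
#'
#' @param event_times uncensored event times (years).
#' @param n_internal number of internal knots (1-5).
#' @return list with \code{internal} and \code{boundary} knot vectors
#'   (years).
#' @export
rcs_knots <- function(event_times, n_internal) {
  stopifnot(n_internal >= 1)
  ut <- sort(unique(event_times))
  if (length(ut) < n_internal + 2)
    stop("validation error: too few distinct event times for ",
         n_internal, " internal knots")
  probs <- seq_len(n_internal) / (n_internal + 1)
  internal <- as.vector(stats::quantile(event_times, probs, names = FALSE))
  boundary <- range(event_times)
  if (any(diff(c(boundary[1], internal, boundary[2])) <= 0))
    stop("validation error: knots are not strictly increasing")
  list(internal = internal, boundary = boundary)
}

#' Restricted (natural) cubic spline basis
#'
#' Truncated-power construction: with combined knots \eqn{t_1 < \dots < t_K}
#' (boundary knots first and last), the basis is \eqn{x} together with
#' \eqn{N_j(x) = d_j(x) - d_{K-1}(x)}, \eqn{j = 1, \dots, K-2}, where
#' \eqn{d_j(x) = [(x - t_j)_+^3 - (x - t_K)_+^3]/(t_K - t_j)}. The basis is
#' exactly linear beyond the boundary knots (zero second derivative
#' outside).
#'
#' @param x evaluation points (same scale as the knots).
#' @param internal_knots internal knot locations.
#' @param boundary_knots length-2 boundary knot locations.
#' @return a matrix with \code{length(internal_knots) + 1} columns
#'   (intercept not included).
#' @export
rcs_basis <- function(x, internal_knots, boundary_knots) {
  kn <- sort(c(boundary_knots, internal_knots))
  K <- length(kn)
  stopifnot(K >= 3)
  d <- function(j) {
    (pmax(x - kn[j], 0)^3 - pmax(x - kn[K], 0)^3) / (kn[K] - kn[j])
  }
  dK1 <- d(K - 1)
  cols <- c(list(x), lapply(seq_len(K - 2), function(j) d(j) - dK1))
  X <- do.call(cbind, cols)
  colnames(X) <- c("x", paste0("rcs", seq_len(K - 2)))
  X
}

#' Fit a restricted cubic spline hazard GLM
#'
#' Poisson life-table GLM with the log hazard a natural cubic spline of log
#' time; internal knots at equally spaced percentiles of the uncensored
#' event times, boundary knots at the extreme event times (knots placed on
#' the time scale and mapped through the log transform).
#'
#' @param lt a \code{lifetable}.
#' @param event_times uncensored event times (years) used to place the
#'   knots.
#' @param n_internal number of internal knots.
#' @param name model name.
#' @return a \code{hazard_fit}; \code{details$knots} records knot locations
#'   in years.
#' @export
fit_rcs <- function(lt, event_times, n_internal, name = NULL) {
  kn <- rcs_knots(event_times, n_internal)
  if (is.null(name)) name <- sprintf("RCS(%d knots)", n_internal)
  builder <- function(t) {
    if (any(t <= 0)) stop("domain error: log-time spline requires t > 0")
    cbind(intercept = 1,
          rcs_basis(log(t), log(kn$internal), log(kn$boundary)))
  }
  fit_poisson_design(lt, builder(lt_midpoints(lt)), name,
                     details = list(builder = builder, knots = kn,
                                    n_internal = n_internal, design = "rcs"))
}

#' Select a restricted cubic spline model by AIC
#'
#' Fits one model per internal-knot count and returns the minimal-AIC fit;
#' AIC ties break toward fewer knots.
#'
#' @param lt a \code{lifetable}.
#' @param event_times uncensored event times used for knot placement.
#' @param knot_range candidate internal-knot counts (default 1:5).
#' @return the selected \code{hazard_fit}.
#' @export
select_rcs <- function(lt, event_times, knot_range = 1:5) {
  fits <- lapply(knot_range, function(m)
    tryCatch(fit_rcs(lt, event_times, m), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    stop("fitting error: all RCS candidates failed: ",
         paste(msgs, collapse = " | "))
  }
  aics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "error")) Inf else f$aic, numeric(1)), Inf)
  # strict minimum: ties resolved toward the earlier (fewer-knot) candidate
  best <- which.min(round(aics, 10))
  fit <- fits[[best]]
  fit$details$knot_range <- knot_range
  fit$details$candidate_aic <- stats::setNames(aics, knot_range)
  fit
}
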