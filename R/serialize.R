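#' Serialize a fitted model to JSON
#'
#' Writes the model name, kind, coefficients, log-likelihood, parameter
#' count, AIC, and the design metadata needed for exact refitting (FP
#' powers, spline knots, GAM dimension/penalty, frailty variance, DSM
#' hyperparameters).
#'
#' @param model a \code{hazard_fit} or \code{dsm_fit}.
#' @param path optional output file; if NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  if (inherits(model, "dsm_fit")) {
    obj <- list(name = model$name, kind = "dsm",
                structure = model$spec$structure,
                hyperparameters = list(b0 = model$spec$b0,
                                       Z0 = model$spec$Z0,
                                       delta = model$spec$delta,
                                       drift = model$spec$drift),
                logL = model$pred_logL, k = model$k, aic = model$aic,
                forecast_sse = model$sse)
  } else {
    d <- model$details
    obj <- list(name = model$name, kind = model$kind,
                coefficients = as.list(model$coefficients),
                logL = model$logL, k = model$k, aic = model$aic)
    if (!is.null(d$powers)) obj$fp_powers <- d$powers
    if (!is.null(d$knots)) obj$knots <- d$knots
    if (!is.null(d$gam)) obj$gam <- d$gam
    if (!is.null(d$frailty))
      obj$frailty <- list(psi2 = d$frailty$psi2, b = d$frailty$b,
                          boundary = d$frailty$boundary)
    if (!is.null(d$fixed) && length(d$fixed)) obj$fixed <- d$fixed
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a serialized model description
#'
#' @param path JSON file written by \code{\link{model_to_json}}.
#' @return the parsed description as a list.
#' @export
model_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
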