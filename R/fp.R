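#' Fractional polynomial design columns
#'
#' Power-transformed copies of time: column \eqn{j} is \eqn{x^{p_j}}, with
#' the conventions that power 0 encodes \eqn{\log x} and a repeated power
#' \eqn{(p, p)} encodes \eqn{(x^p, x^p \log x)}.
#'
#' @param times positive times (years).
#' @param powers vector of 1 or 2 powers from the permitted set
#'   \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}.
#' @param power_set the permitted power set.
#' @return a matrix with one column per power (intercept not included).
#' @export
fp_design <- function(times, powers,
                      power_set = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)) {
  if (any(times <= 0))
    stop("domain error: fractional polynomial transforms require positive times")
  if (!length(powers) %in% 1:2)
    stop("powers must have length 1 or 2")
  if (!all(powers %in% power_set))
    stop("powers must be drawn from {", paste(power_set, collapse = ", "), "}")
  xp <- function(p) if (p == 0) log(times) else times^p
  cols <- list(xp(powers[1]))
  if (length(powers) == 2) {
    cols[[2]] <- if (powers[2] == powers[1]) xp(powers[1]) * log(times)
                 else xp(powers[2])
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste0("fp", seq_along(powers), "_p", powers)
  X
}

#' Fit a fractional polynomial hazard GLM
#'
#' Poisson life-table GLM with log hazard \eqn{\beta_0 + \sum_j \beta_j
#' x^{p_j}}, time in years evaluated at interval midpoints.
#'
#' @param lt a \code{lifetable}.
#' @param powers FP powers (length 1 or 2).
#' @param name model name.
#' @return a \code{hazard_fit} with the powers recorded in
#'   \code{details$powers}.
#' @export
fit_fp <- function(lt, powers, name = NULL) {
  if (is.null(name))
    name <- paste0("FP(", paste(powers, collapse = ", "), ")")
  builder <- function(t) cbind(intercept = 1, fp_design(t, powers))
  fit_poisson_design(lt, builder(lt_midpoints(lt)), name,
                     details = list(builder = builder, powers = powers,
                                    design = "fp"))
}

#' Select a fractional polynomial by the closed-test procedure
#'
#' Within each order the best powers are chosen by minimal AIC over the power
#' set; the order is then fixed by a closed sequence of chi-square deviance
#' tests, each FP power contributing 2 degrees of freedom (power choice +
#' coefficient): best FP(2) against the intercept-only null (4 df), against
#' the straight line in time (3 df), then against the best FP(1) (2 df),
#' stopping at the first non-rejection.
#'
#' @param lt a \code{lifetable}.
#' @param alpha test level for the closed test (default 0.05).
#' @param power_set permitted powers.
#' @param max_order maximum FP order (2).
#' @return the selected \code{hazard_fit}; \code{details$closed_test} records
#'   each stage's deviance, df, and p-value, and \code{details$powers} the
#'   chosen powers (NULL for the null model).
#' @export
select_fp <- function(lt, alpha = 0.05,
                      power_set = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                      max_order = 2) {
  stopifnot(max_order == 2)
  null_fit <- fit_glm(lt, family_spec("poisson", "exponential"),
                      design_spec("none"), name = "FP null (constant)")
  linear_fit <- fit_fp(lt, 1, name = "FP linear (t)")

  fit_or_null <- function(powers, nm) {
    tryCatch(fit_fp(lt, powers, name = nm), error = function(e) NULL)
  }
  best_of <- function(cands) {
    fits <- Filter(Negate(is.null), cands)
    if (!length(fits))
      stop("fitting error: all candidate FP fits failed")
    fits[[which.min(vapply(fits, function(f) f$aic, numeric(1)))]]
  }
  fp1 <- best_of(lapply(power_set, function(p)
    fit_or_null(p, sprintf("FP(%g)", p))))
  pairs <- list()
  for (i in seq_along(power_set))
    for (j in i:length(power_set))
      pairs[[length(pairs) + 1L]] <- c(power_set[i], power_set[j])
  fp2 <- best_of(lapply(pairs, function(p)
    fit_or_null(p, sprintf("FP(%g, %g)", p[1], p[2]))))

  stage <- function(ref, df) {
    dev <- 2 * (fp2$logL - ref$logL)
    pval <- stats::pchisq(max(dev, 0), df = df, lower.tail = FALSE)
    list(deviance = dev, df = df, p = pval, reject = pval < alpha)
  }
  s1 <- stage(null_fit, 4)
  s2 <- stage(linear_fit, 3)
  s3 <- stage(fp1, 2)
  trace <- data.frame(
    comparison = c("FP(2) vs null", "FP(2) vs linear", "FP(2) vs FP(1)"),
    deviance = c(s1$deviance, s2$deviance, s3$deviance),
    df = c(4, 3, 2),
    p_value = c(s1$p, s2$p, s3$p))

  chosen <- if (!s1$reject) null_fit
            else if (!s2$reject) linear_fit
            else if (!s3$reject) fp1
            else fp2
  chosen$details$closed_test <- trace
  chosen$details$alpha <- alpha
  chosen$details$candidates <- list(fp1_powers = fp1$details$powers,
                                    fp2_powers = fp2$details$powers)
  chosen
}
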