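#' At-risk exposure for a life-table interval
#'
#' Actuarial adjustment for the effective denominator of an interval hazard:
#' subjects censored during an interval contribute half an interval of
#' exposure, subjects experiencing the event contribute a full interval, so
#' \eqn{\tau = n - c/2}.
#'
#' @param n integer vector, sample size entering each interval.
#' @param events integer vector, events in each interval.
#' @param censorings integer vector, censorings in each interval.
#' @return numeric vector of at-risk exposures (subject-intervals).
#' @examples
#' at_risk_exposure(686, 0, 7)   # 682.5
#' at_risk_exposure(458, 8, 12)  # 452
#' @export
at_risk_exposure <- function(n, events, censorings) {
  stopifnot(length(n) == length(events), length(n) == length(censorings))
  if (any(n < 0) || any(events < 0) || any(censorings < 0))
    stop("counts must be nonnegative")
  if (any(events + censorings > n))
    stop("events + censorings cannot exceed the sample size entering the interval")
  n - censorings / 2
}

#' Read individual-level time-to-event records
#'
#' Reads a delimited text file with one row per subject carrying an outcome
#' time (in years) and a binary event indicator (1 = event, 0 = censored).
#' The delimiter is sniffed from the header line (comma or tab).
#'
#' @param path path to a CSV/TSV file.
#' @param time_col,event_col names of the outcome-time and event-indicator
#'   columns.
#' @param sep field separator; by default inferred from the header line.
#' @return a data frame of class \code{subject_records} with columns
#'   \code{time} and \code{event}, one row per input row, order preserved.
#' @export
read_subjects <- function(path, time_col = "time", event_col = "event",
                          sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df))
      stop("configuration error: column '", col, "' not present in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")")
  }
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  event <- suppressWarnings(as.numeric(df[[event_col]]))
  bad_t <- which(is.na(time) | time < 0)
  if (length(bad_t))
    stop("validation error: nonnegative outcome time required at row ",
         bad_t[1])
  bad_e <- which(is.na(event) | !(event %in% c(0, 1)))
  if (length(bad_e))
    stop("validation error: event indicator must be 0 or 1 at row ", bad_e[1])
  subject_records(time, event)
}

#' Construct subject records
#'
#' @param time nonnegative outcome times in years.
#' @param event binary event indicators (1 = event, 0 = censored).
#' @return a \code{subject_records} data frame.
#' @export
subject_records <- function(time = numeric(), event = integer()) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("validation error: negative outcome time")
  if (any(!event %in% c(0, 1))) stop("validation error: event must be 0 or 1")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            class = c("subject_records", "data.frame"))
}

#' Restructure individual records into a life table
#'
#' Discretizes follow-up into half-open intervals \eqn{[start, end)} of equal
#' width and tallies per interval: the sample size entering, events,
#' censorings, the actuarially adjusted at-risk exposure
#' \eqn{\tau_t = n_t - c_t/2}, and the empirical per-interval hazard
#' \eqn{\lambda_t = y_t/\tau_t} (0 where \eqn{\tau_t = 0}). A subject whose
#' time falls exactly on an interval boundary is assigned to the interval
#' beginning at that boundary.
#'
#' @param records a \code{subject_records} data frame (or any data frame with
#'   \code{time} and \code{event} columns).
#' @param width interval width in years; default one month (1/12).
#' @return a data frame of class \code{lifetable} with columns
#'   \code{interval}, \code{start}, \code{end} (years), \code{n},
#'   \code{events}, \code{censorings}, \code{at_risk}, \code{hazard}, and a
#'   \code{width} attribute.
#' @export
build_lifetable <- function(records, width = 1 / 12) {
  if (NROW(records) == 0L) stop("validation error: no records")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("interval width must be a positive number")
  time <- records$time
  event <- records$event
  if (any(time < 0)) stop("validation error: negative outcome time")
  idx <- floor(time / width) + 1L  # half-open [start, end): boundary -> later
  N <- max(idx)
  y <- tabulate(idx[event == 1], nbins = N)
  cns <- tabulate(idx[event == 0], nbins = N)
  n <- length(time) - cumsum(c(0L, (y + cns)[-N]))
  tau <- at_risk_exposure(n, y, cns)
  lam <- ifelse(tau > 0, y / tau, 0)
  lt <- data.frame(interval = seq_len(N),
                   start = (seq_len(N) - 1) * width,
                   end = seq_len(N) * width,
                   n = n, events = y, censorings = cns,
                   at_risk = tau, hazard = lam)
  structure(lt, class = c("lifetable", "data.frame"), width = width)
}

#' Interval width of a life table (years)
#' @param lt a \code{lifetable}.
#' @return the interval width in years.
#' @export
lt_width <- function(lt) attr(lt, "width")

#' Interval midpoints of a life table (years)
#' @param lt a \code{lifetable}.
#' @return numeric vector of interval midpoints in years.
#' @export
lt_midpoints <- function(lt) (lt$start + lt$end) / 2

#' Administratively censor follow-up at a cutoff
#'
#' Records with outcome time beyond the cutoff are recoded as censored at the
#' cutoff; all other records are unchanged.
#'
#' @param records a \code{subject_records} data frame.
#' @param cutoff positive time in years.
#' @return a \code{subject_records} data frame.
#' @export
truncate_followup <- function(records, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  over <- records$time > cutoff
  subject_records(pmin(records$time, cutoff),
                  ifelse(over, 0L, records$event))
}

#' Training life table for a data split
#'
#' Builds the life table on records censored at the cutoff, keeping only
#' intervals that end at or before the cutoff: subjects censored exactly at
#' the cutoff exit at the boundary and do not open a new interval.
#'
#' @param records a \code{subject_records} data frame.
#' @param cutoff split time in years (default 3).
#' @param width interval width in years.
#' @return a \code{lifetable}.
#' @export
training_lifetable <- function(records, cutoff = 3, width = 1 / 12) {
  lt <- build_lifetable(truncate_followup(records, cutoff), width)
  keep <- lt$end <= cutoff + 1e-9
  out <- lt[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lifetable", "data.frame"), width = width)
}

#' Write a life table as CSV
#'
#' Column layout: \code{month_start, month_end, n, events, censorings,
#' at_risk, hazard}, with interval boundaries expressed in months.
#'
#' @param lt a \code{lifetable}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  out <- data.frame(month_start = lt$start * 12,
                    month_end = lt$end * 12,
                    n = lt$n, events = lt$events,
                    censorings = lt$censorings,
                    at_risk = lt$at_risk, hazard = lt$hazard)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("Life table: %d intervals of width %.4g years, %d subjects, %d events\n",
              nrow(x), attr(x, "width"), x$n[1], sum(x$events)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more intervals)\n", sep = "")
  invisible(x)
}
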