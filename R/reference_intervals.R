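# Reference-interval aggregation: per-analyte summaries (n, mean, SD,
# median, range), weight-gain tracking, exclusion rules, and flagging of
# values against published intervals.

#' Summarize measurements into a reference interval
#'
#' Sample mean, SD (n-1 denominator), median and range. With a single value
#' the SD is undefined and reported as \code{NA} with \code{sd_defined =
#' FALSE}. With n this small (cohorts of about six animals) these are
#' descriptive summaries, not parametric 95% reference limits.
#'
#' @param values numeric measurements; \code{NA}s are dropped.
#' @param source \code{"internal"} or a citation label for published bounds.
#' @return an object of class \code{reference_interval}: list with \code{n},
#'   \code{mean}, \code{sd}, \code{sd_defined}, \code{median}, \code{min},
#'   \code{max}, \code{source}.
#' @export
#' @examples
#' reference_interval(c(331.50, 303.13, 321.08, 316.71, 362.13, 351.50))
reference_interval <- function(values, source = "internal") {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("no values to summarize after removing missing entries", call. = FALSE)
  structure(list(n = length(values),
                 mean = mean(values),
                 sd = if (length(values) > 1L) sd(values) else NA_real_,
                 sd_defined = length(values) > 1L,
                 median = median(values),
                 min = min(values), max = max(values),
                 source = source),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf(
    "<reference_interval> n = %d: mean %.2f +/- %s, median %.2f, range %.2f-%.2f (%s)\n",
    x$n, x$mean, if (x$sd_defined) sprintf("%.2f", x$sd) else "NA", x$median,
    x$min, x$max, x$source))
  invisible(x)
}

#' Per-interval weight gain
#'
#' Percent change of each weight relative to the previous measurement:
#' \eqn{100 (w_i - w_{i-1}) / w_{i-1}}.
#'
#' @param weights weekly weights (g), > 0, length >= 2.
#' @return numeric vector of length \code{length(weights) - 1}.
#' @export
#' @examples
#' weight_gain_per_measure(c(390.70, 390.30, 406.70, 418.20))
weight_gain_per_measure <- function(weights) {
  if (length(weights) < 2L)
    stop("need at least 2 weights to compute gains", call. = FALSE)
  if (any(weights <= 0) || anyNA(weights))
    stop("weights must be positive and complete", call. = FALSE)
  100 * diff(weights) / weights[-length(weights)]
}

#' Final weight gain
#'
#' Percent change between the first and last weight,
#' \eqn{100 (w_{last} - w_{first}) / w_{first}}. For a subjects-by-weeks
#' matrix the group aggregate applies the same formula to the column mean
#' weights.
#'
#' @param weights numeric vector of one subject's weights, or a numeric
#'   matrix/data.frame with one row per subject and one column per week.
#' @return a percentage; for a matrix, a list with \code{per_subject} and
#'   \code{group} (formula on the mean first/last weights).
#' @export
#' @examples
#' final_weight_gain(c(390.70, 390.30, 406.70, 418.20))
final_weight_gain <- function(weights) {
  if (is.matrix(weights) || is.data.frame(weights)) {
    w <- as.matrix(weights)
    if (ncol(w) < 2L) stop("need at least 2 timepoints", call. = FALSE)
    per <- 100 * (w[, ncol(w)] - w[, 1L]) / w[, 1L]
    mw <- colMeans(w)
    return(list(per_subject = per,
                group = 100 * (mw[length(mw)] - mw[1L]) / mw[1L]))
  }
  if (length(weights) < 2L)
    stop("need at least 2 weights", call. = FALSE)
  100 * (weights[length(weights)] - weights[1L]) / weights[1L]
}

#' Flag a value against an interval
#'
#' Strict comparison against ordered bounds; values equal to a bound are
#' "within". The bounds may come from a \code{\link{reference_interval}}
#' (its range) or be given directly.
#'
#' @param value numeric value(s) to flag.
#' @param lower,upper interval bounds, \code{lower <= upper}; alternatively
#'   pass a \code{reference_interval} as \code{lower}.
#' @return character vector: "below", "within" or "above".
#' @export
#' @examples
#' flag_against_interval(44.50, 64.1, 168.1)  # "below"
#' flag_against_interval(1.74, 0.0, 0.3)      # "above"
flag_against_interval <- function(value, lower, upper = NULL) {
  if (inherits(lower, "reference_interval")) {
    upper <- lower$max
    lower <- lower$min
  }
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  ifelse(value < lower, "below", ifelse(value > upper, "above", "within"))
}

#' Construct an analyte panel
#'
#' Long-format per-subject analyte measurements with per-entry exclusion and
#' censoring flags. Censored entries (e.g. below the assay detection limit)
#' carry \code{censored = TRUE} and a missing value; they are excluded from
#' summaries but kept in the table.
#'
#' @param data data.frame with columns \code{subject_id}, \code{week},
#'   \code{analyte}, \code{value} and optionally \code{units},
#'   \code{censored}.
#' @return an object of class \code{analyte_panel}: the data.frame with
#'   added \code{excluded} (logical) and \code{exclusion_reason} columns.
#' @export
analyte_panel <- function(data) {
  req <- c("subject_id", "week", "analyte", "value")
  if (!all(req %in% names(data)))
    stop("panel needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (!"units" %in% names(data)) data$units <- NA_character_
  if (!"censored" %in% names(data)) data$censored <- FALSE
  data$excluded <- FALSE
  data$exclusion_reason <- NA_character_
  structure(data, class = c("analyte_panel", "data.frame"))
}

#' Apply exclusion rules to an analyte panel
#'
#' Each rule names an analyte, the weeks to discard and a reason (e.g. a
#' laboratory handling problem in early determinations). Flagged entries are
#' excluded from all downstream summaries; an exclusion log is attached.
#'
#' @param panel an \code{\link{analyte_panel}}.
#' @param rules list of rules, each \code{list(analyte =, weeks =, reason =)};
#'   an empty list is the identity.
#' @return the panel with updated exclusion flags; the log (data.frame of
#'   analyte, week, n_excluded, reason) is in attribute
#'   \code{"exclusion_log"}.
#' @export
apply_exclusions <- function(panel, rules = list()) {
  stopifnot(inherits(panel, "analyte_panel"))
  log <- list()
  for (r in rules) {
    if (!all(c("analyte", "weeks", "reason") %in% names(r)))
      stop("each rule needs `analyte`, `weeks` and `reason`", call. = FALSE)
    hit <- panel$analyte == r$analyte & panel$week %in% r$weeks
    panel$excluded[hit] <- TRUE
    panel$exclusion_reason[hit] <- r$reason
    log[[length(log) + 1L]] <- data.frame(
      analyte = r$analyte, week = r$weeks,
      n_excluded = vapply(r$weeks, function(w)
        sum(panel$analyte == r$analyte & panel$week == w), 0L),
      reason = r$reason)
  }
  attr(panel, "exclusion_log") <- if (length(log)) do.call(rbind, log)
    else data.frame(analyte = character(), week = numeric(),
                    n_excluded = integer(), reason = character())
  panel
}

#' Summarize an analyte panel per analyte and week
#'
#' Excluded and censored entries are dropped first; an analyte-week with no
#' usable data is reported with \code{n = 0} and missing summaries (never
#' zero).
#'
#' @param panel an \code{\link{analyte_panel}}.
#' @return data.frame: analyte, week, units, n, mean, sd, median, min, max.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  keys <- unique(data.frame(analyte = panel$analyte, week = panel$week))
  keys <- keys[order(keys$analyte, keys$week), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- panel$analyte == keys$analyte[i] & panel$week == keys$week[i]
    use <- sel & !panel$excluded & !panel$censored & !is.na(panel$value)
    base <- data.frame(analyte = keys$analyte[i], week = keys$week[i],
                       units = panel$units[sel][1L])
    if (!any(use))
      return(cbind(base, n = 0L, mean = NA_real_, sd = NA_real_,
                   median = NA_real_, min = NA_real_, max = NA_real_))
    ri <- reference_interval(panel$value[use])
    cbind(base, n = ri$n, mean = ri$mean, sd = ri$sd, median = ri$median,
          min = ri$min, max = ri$max)
  }))
}
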