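# ICG plasma-clearance kinetics: clearance percentages, the semilog
# elimination constant ICG-K, and the per-minute decay rate R = 1 - d.
#
# All logarithms are base 10. R itself is invariant to the base used in the
# d-formula (the exponent and logarithm cancel), which the tests assert.

#' Construct an ICG plasma concentration series
#'
#' @param subject_id subject label.
#' @param times sampling times (minutes post-injection), strictly increasing.
#' @param concentrations plasma ICG concentrations (ug/mL), one per time;
#'   means over technical replicates.
#' @param replicate_sd optional per-time SD over replicates (ug/mL).
#' @return an object of class \code{concentration_series}.
#' @export
#' @examples
#' concentration_series("rat4", c(1, 5, 10), c(189.16, 38.13, 3.47))
concentration_series <- function(subject_id, times, concentrations,
                                 replicate_sd = NULL) {
  check_increasing(times, "times")
  if (length(concentrations) != length(times))
    stop("`concentrations` and `times` must have the same length", call. = FALSE)
  if (anyNA(concentrations) || any(!is.finite(concentrations)))
    stop("`concentrations` must be finite", call. = FALSE)
  if (!is.null(replicate_sd) && length(replicate_sd) != length(times))
    stop("`replicate_sd` must match `times` in length", call. = FALSE)
  structure(list(subject_id = as.character(subject_id)[1L],
                 times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 replicate_sd = replicate_sd),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> subject %s, %d timepoints\n",
              x$subject_id, length(x$times)))
  print(data.frame(time_min = x$times, concentration_ugml = x$concentrations))
  invisible(x)
}

#' Percent ICG cleared relative to a reference time
#'
#' Clearance at time \eqn{t} is \eqn{100 (1 - C(t)/C(t_{ref}))}; the entry at
#' the reference time is exactly 0.
#'
#' @param series a \code{\link{concentration_series}}.
#' @param ref_time reference time (minutes); must be one of the sampled times.
#' @return named numeric vector of percentages, one per sampled time.
#' @export
#' @examples
#' s <- concentration_series("avg", c(1, 5, 10), c(155.99, 31.01, 5.31))
#' round(clearance_percent(s, ref_time = 1), 2)
clearance_percent <- function(series, ref_time = series$times[1L]) {
  stopifnot(inherits(series, "concentration_series"))
  i <- match(ref_time, series$times)
  if (is.na(i))
    stop(sprintf("ref_time %g is not a sampled time", ref_time), call. = FALSE)
  c_ref <- series$concentrations[i]
  if (c_ref <= 0)
    stop("concentration at the reference time must be positive", call. = FALSE)
  out <- 100 * (1 - series$concentrations / c_ref)
  out[i] <- 0
  setNames(out, paste0("min", series$times))
}

#' Per-minute retention fraction d and decay rate R between two samples
#'
#' From two concentrations on the exponential phase,
#' \deqn{\log_{10} d = \frac{\log_{10} C_2 - \log_{10} C_1}{t_2 - t_1},
#'       \qquad R = 1 - d,}
#' so \eqn{d} is the fraction of ICG remaining after one minute and \eqn{R}
#' the fraction cleared per minute. \eqn{R} does not depend on the logarithm
#' base used.
#'
#' @param C1,C2 plasma concentrations (ug/mL), > 0.
#' @param t1,t2 their sampling times (minutes), \code{t2 > t1}.
#' @return list with elements \code{d} and \code{R}.
#' @export
#' @examples
#' decay_rate(C1 = 100, t1 = 0, C2 = 10, t2 = 5)  # d = 10^-0.2, R = 0.369
decay_rate <- function(C1, t1, C2, t2) {
  check_scalar(C1, "C1", lower = 0, strict_lower = TRUE)
  check_scalar(C2, "C2", lower = 0, strict_lower = TRUE)
  if (!is.numeric(t1) || !is.numeric(t2) || t2 <= t1)
    stop("`t2` must be greater than `t1`", call. = FALSE)
  d <- 10^((log10(C2) - log10(C1)) / (t2 - t1))
  list(d = d, R = 1 - d)
}

#' Fit the ICG elimination constant on the semilog exponential phase
#'
#' Least-squares regression of \eqn{\log_{10} C} on time over the points that
#' fall inside \code{window}; \code{icg_k} is the negated slope, the
#' per-minute retention fraction is \eqn{d = 10^{-k}} and the decay rate
#' \eqn{R = 1 - d}. With exactly two usable points the fit reduces to
#' \code{\link{decay_rate}}. Non-positive concentrations (or values below
#' \code{detection_limit}) cannot be log-transformed and are dropped with a
#' warning.
#'
#' @param series a \code{\link{concentration_series}}.
#' @param window numeric length-2, the exponential-phase window in minutes
#'   (inclusive). Default \code{c(1, 5)}: decay is exponential over the first
#'   five minutes and the first sample is drawn at one minute.
#' @param ref_time reference time for the clearance percentages; defaults to
#'   the first sampled time.
#' @param detection_limit concentrations at or below this value are dropped
#'   before the log transform.
#' @return an object of class \code{clearance_result}: list with
#'   \code{clearance_pct}, \code{icg_k}, \code{d}, \code{R}, \code{window},
#'   \code{n_points}, \code{subject_id}.
#' @export
#' @examples
#' s <- concentration_series("avg", c(1, 5, 10), c(155.99, 31.01, 5.31))
#' fit_icg_k(s, window = c(1, 5))$icg_k  # 0.1754
fit_icg_k <- function(series, window = c(1, 5), ref_time = series$times[1L],
                      detection_limit = 0) {
  stopifnot(inherits(series, "concentration_series"),
            length(window) == 2L, window[1] < window[2])
  keep <- series$times >= window[1] & series$times <= window[2]
  usable <- keep & series$concentrations > detection_limit
  if (any(keep & !usable))
    warning(sprintf("dropped %d point(s) at or below the detection limit (%g)",
                    sum(keep & !usable), detection_limit), call. = FALSE)
  if (sum(usable) < 2L)
    stop("need at least 2 points with positive concentration in the window",
         call. = FALSE)
  t <- series$times[usable]
  y <- log10(series$concentrations[usable])
  slope <- if (sum(usable) == 2L) diff(y) / diff(t)
           else unname(coef(lm(y ~ t))[2L])
  d <- 10^slope
  structure(list(clearance_pct = clearance_percent(series, ref_time),
                 icg_k = -slope, d = d, R = 1 - d,
                 window = as.numeric(window), n_points = sum(usable),
                 subject_id = series$subject_id),
            class = "clearance_result")
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf(
    "<clearance_result> subject %s: ICG-K = %.4f /min (log10), d = %.4f, R = %.4f\n",
    x$subject_id, x$icg_k, x$d, x$R))
  cat(sprintf("  window [%g, %g] min, %d points; clearance %%: %s\n",
              x$window[1], x$window[2], x$n_points,
              paste(sprintf("%.2f", x$clearance_pct), collapse = " / ")))
  invisible(x)
}

#' Group-level ICG decay summary
#'
#' The per-minute decay rate can be computed in two modes: once on the
#' group-averaged concentrations, or per subject and then averaged. Which of
#' the two a published group value reflects is often ambiguous, so both are
#' returned.
#'
#' @param series_list list of \code{\link{concentration_series}}.
#' @param window exponential-phase window, as in \code{\link{fit_icg_k}}.
#' @return list with \code{per_subject} (data.frame of icg_k, d, R),
#'   \code{mean_of_subjects} (mean R over subjects) and
#'   \code{on_averaged_concentrations} (R from the fit on the
#'   time-wise mean series).
#' @export
icg_group_summary <- function(series_list, window = c(1, 5)) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "concentration_series")))
  fits <- lapply(series_list, fit_icg_k, window = window)
  per <- data.frame(
    subject_id = vapply(fits, `[[`, "", "subject_id"),
    icg_k = vapply(fits, `[[`, 0, "icg_k"),
    d = vapply(fits, `[[`, 0, "d"),
    R = vapply(fits, `[[`, 0, "R"))
  t0 <- series_list[[1L]]$times
  if (!all(vapply(series_list, function(s) identical(s$times, t0), TRUE)))
    stop("all series must share the same time grid for group averaging",
         call. = FALSE)
  avg <- concentration_series(
    "group-average", t0,
    rowMeans(vapply(series_list, `[[`, numeric(length(t0)), "concentrations")))
  list(per_subject = per,
       mean_of_subjects = mean(per$R),
       on_averaged_concentrations = fit_icg_k(avg, window = window)$R)
}
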