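# Doppler waveform feature extraction (PSV, EDV, VTI, TAV per cardiac cycle)
# and the derived hemodynamic indices: resistive index, portal congestion
# index, arterio-portal ratio, stroke-volume cardiac output and renal blood
# flow.
#
# Unit conventions: velocities in mm/s, VTI in mm (integral of velocity over
# one cycle), areas in mm^2, diameters/radii in mm, HR in bpm, CO and RBF in
# mL/min. RI and A/P are dimensionless.

#' Construct a Doppler velocity trace
#'
#' @param samples velocity samples (mm/s) at a uniform sampling rate.
#' @param fs sampling rate (Hz), > 0.
#' @param vessel vessel label (e.g. "portal vein", "hepatic artery").
#' @return an object of class \code{velocity_trace}.
#' @export
velocity_trace <- function(samples, fs, vessel = "unknown") {
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(samples) < 2L || anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite and of length >= 2", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 vessel = as.character(vessel)[1L]),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %s: %d samples @ %g Hz (%.2f s)\n",
              x$vessel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Detect cardiac cycles from systolic peaks
#'
#' Systolic peaks are located by prominence-based peak picking: local maxima
#' on a lightly smoothed copy of the trace, separated by at least 80% of the
#' shortest plausible cycle (from \code{hr_band}), and retained when their
#' prominence (height above the higher of the two flanking inter-peak minima)
#' exceeds \code{min_prominence_frac} of the trace's dynamic range. Cycles
#' are delimited peak-to-peak.
#'
#' @param trace a \code{\link{velocity_trace}}.
#' @param min_cycles minimum number of complete cycles required (averages in
#'   the field use at least five consecutive cycles).
#' @param hr_band plausible heart-rate band in bpm, used only to set the
#'   minimum peak separation and smoothing scale.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   dynamic range.
#' @return a data.frame of class \code{cycle_bounds} with columns
#'   \code{start}, \code{end} (sample indices of consecutive systolic peaks;
#'   cycle i spans \code{start[i]:end[i]}); detected peak indices are kept in
#'   the \code{"peaks"} attribute.
#' @export
#' @examples
#' tr <- simulate_velocity_trace(waveform_sim_params(noise_sd = 0))
#' nrow(detect_cycles(tr))
detect_cycles <- function(trace, min_cycles = 5, hr_band = c(150, 500),
                          min_prominence_frac = 0.25) {
  stopifnot(inherits(trace, "velocity_trace"),
            length(hr_band) == 2L, hr_band[1] > 0, hr_band[1] < hr_band[2])
  x <- trace$samples
  rng <- diff(range(x))
  if (rng <= 0)
    stop("trace is constant: no systolic peaks detectable", call. = FALSE)
  min_period <- trace$fs * 60 / hr_band[2]     # samples at the fastest HR
  # light smoothing at ~1/10 of the shortest cycle suppresses sample noise
  w <- max(1L, round(min_period / 10))
  if (w %% 2L == 0L) w <- w + 1L
  xs <- if (w > 1L)
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L)) else x
  xs[is.na(xs)] <- x[is.na(xs)]

  cand <- which(diff(sign(diff(xs))) < 0) + 1L   # local maxima
  if (length(cand)) {
    # greedy min-distance enforcement, tallest first
    keep <- logical(length(cand))
    for (i in order(xs[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[i]) < 0.8 * min_period)) keep[i] <- TRUE
    }
    peaks <- sort(cand[keep])
    # prominence: height above the higher flanking inter-peak minimum
    if (length(peaks) >= 2L) {
      prom <- vapply(seq_along(peaks), function(i) {
        lo <- if (i == 1L) 1L else peaks[i - 1L]
        hi <- if (i == length(peaks)) length(xs) else peaks[i + 1L]
        xs[peaks[i]] - max(min(xs[lo:peaks[i]]), min(xs[peaks[i]:hi]))
      }, 0)
      peaks <- peaks[prom >= min_prominence_frac * rng]
    }
  } else peaks <- integer(0)

  if (length(peaks) < min_cycles + 1L)
    stop(sprintf(paste0("detected %d peak(s), need %d for %d complete ",
                        "cycle(s); check heart-rate band, noise level and ",
                        "trace duration"),
                 length(peaks), min_cycles + 1L, min_cycles), call. = FALSE)
  out <- data.frame(start = peaks[-length(peaks)], end = peaks[-1L])
  class(out) <- c("cycle_bounds", "data.frame")
  attr(out, "peaks") <- peaks
  out
}

#' Per-cycle waveform features and their averages
#'
#' For each peak-to-peak cycle: PSV is the maximum velocity within the cycle,
#' EDV the minimum between the two delimiting systolic peaks, VTI the
#' trapezoidal integral of velocity over the cycle (mm), and TAV = VTI
#' divided by the cycle duration.
#'
#' @param trace a \code{\link{velocity_trace}}.
#' @param cycles cycle bounds from \code{\link{detect_cycles}}, or any
#'   data.frame with \code{start}/\code{end} sample indices.
#' @return an object of class \code{cycle_features}: list with
#'   \code{per_cycle} (data.frame: psv, edv, vti, tav, duration_s, start,
#'   end) and \code{averages} (named list of psv, edv, vti, tav, plus the
#'   implied heart rate in bpm).
#' @export
cycle_features <- function(trace, cycles = detect_cycles(trace)) {
  stopifnot(inherits(trace, "velocity_trace"), is.data.frame(cycles),
            all(c("start", "end") %in% names(cycles)), nrow(cycles) >= 1L)
  x <- trace$samples
  per <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(i) {
    s <- cycles$start[i]; e <- cycles$end[i]
    seg <- x[s:e]
    dur <- (e - s) / trace$fs
    vti <- trapz_uniform(seg, 1 / trace$fs)
    data.frame(psv = max(seg), edv = min(seg), vti = vti,
               tav = vti / dur, duration_s = dur, start = s, end = e)
  }))
  avg <- list(psv = mean(per$psv), edv = mean(per$edv),
              vti = mean(per$vti), tav = mean(per$tav),
              hr_bpm = 60 / mean(per$duration_s))
  structure(list(per_cycle = per, averages = avg), class = "cycle_features")
}

#' @export
print.cycle_features <- function(x, ...) {
  a <- x$averages
  cat(sprintf(
    "<cycle_features> %d cycles: PSV %.2f, EDV %.2f, VTI %.2f, TAV %.2f (HR %.1f bpm)\n",
    nrow(x$per_cycle), a$psv, a$edv, a$vti, a$tav, a$hr_bpm))
  invisible(x)
}

#' Resistive index
#'
#' The standard downstream-resistance index \eqn{RI = (PSV - EDV)/PSV},
#' in [0, 1] for non-negative EDV.
#'
#' @param psv peak systolic velocity (mm/s), > 0.
#' @param edv end-diastolic velocity (mm/s).
#' @return dimensionless RI (vectorized).
#' @export
#' @examples
#' resistance_index(864.37, 424.33)
resistance_index <- function(psv, edv) {
  if (any(psv <= 0)) stop("`psv` must be positive", call. = FALSE)
  (psv - edv) / psv
}

#' Portal congestion index
#'
#' Portal cross-sectional area divided by the portal velocity summary
#' (average PSV); rises with portal hypertension.
#'
#' @param portal_area portal vein cross-sectional area (mm^2), >= 0.
#' @param portal_psv portal average peak systolic velocity (mm/s), > 0.
#' @return PCI in mm^2 per (mm/s) (vectorized).
#' @export
#' @examples
#' portal_congestion_index(3.41, 150.72)
portal_congestion_index <- function(portal_area, portal_psv) {
  if (any(portal_psv <= 0)) stop("`portal_psv` must be positive", call. = FALSE)
  if (any(portal_area < 0)) stop("`portal_area` must be >= 0", call. = FALSE)
  portal_area / portal_psv
}

#' Arterio-portal velocity ratio
#'
#' Ratio of a hepatic-artery velocity summary to the portal one. Which
#' summary is meant by "average" is ambiguous in the field; the conventional
#' choice here is PSV/PSV, with TAV/TAV available via the same call.
#'
#' @param ha_value hepatic artery summary velocity (mm/s).
#' @param portal_value portal vein summary velocity (mm/s), > 0.
#' @return dimensionless ratio (vectorized).
#' @export
ap_ratio <- function(ha_value, portal_value) {
  if (any(portal_value <= 0)) stop("`portal_value` must be positive", call. = FALSE)
  ha_value / portal_value
}

#' Renal blood flow
#'
#' \eqn{RBF = HR \cdot VTI \cdot \pi r^2}, converted from mm^3/min to
#' mL/min.
#'
#' @param hr heart rate (bpm), >= 0.
#' @param vti renal artery velocity-time integral (mm), >= 0.
#' @param radius vessel radius (mm), >= 0; half the caliper diameter.
#' @return RBF in mL/min (vectorized).
#' @export
#' @examples
#' renal_blood_flow(hr = 331.5, vti = 64.37, radius = 0.91 / 2)
renal_blood_flow <- function(hr, vti, radius) {
  if (any(hr < 0) || any(vti < 0) || any(radius < 0))
    stop("`hr`, `vti` and `radius` must be non-negative", call. = FALSE)
  hr * vti * pi * radius^2 / 1000
}

#' Cardiac output
#'
#' \eqn{CO = SV \cdot HR}.
#'
#' @param sv stroke volume (mL), >= 0.
#' @param hr heart rate (bpm), >= 0.
#' @return CO in mL/min (vectorized).
#' @export
cardiac_output <- function(sv, hr) {
  if (any(sv < 0) || any(hr < 0))
    stop("`sv` and `hr` must be non-negative", call. = FALSE)
  sv * hr
}

#' Vessel measurement from repeated calipers
#'
#' Averages repeated diameter (or area) caliper measurements and derives the
#' circular cross-sectional area \eqn{\pi (d/2)^2} when only diameters are
#' given. Protocols in the field repeat the caliper at least 3 times for
#' areas and 5 for renal diameters.
#'
#' @param diameters repeated diameter measurements (mm), or NULL.
#' @param areas repeated area measurements (mm^2), or NULL.
#' @param min_repeats minimum number of repeats required.
#' @return list of class \code{vessel_measurement}: \code{diameter} (mm, or
#'   NA), \code{area} (mm^2), \code{n_measurements}.
#' @export
vessel_measurement <- function(diameters = NULL, areas = NULL,
                               min_repeats = 3) {
  if (is.null(diameters) && is.null(areas))
    stop("provide `diameters` or `areas`", call. = FALSE)
  n <- length(diameters %||% areas)
  if (n < min_repeats)
    stop(sprintf("need at least %d repeated measurements, got %d",
                 min_repeats, n), call. = FALSE)
  d <- if (!is.null(diameters)) mean(diameters) else NA_real_
  a <- if (!is.null(areas)) mean(areas) else pi * (d / 2)^2
  structure(list(diameter = d, area = a, n_measurements = n),
            class = "vessel_measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
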