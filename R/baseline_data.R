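# Published healthy-rat baseline measurements bundled as plain data frames.
# Six male Sprague-Dawley rats, 12-16 weeks of age: weekly body weights, ICG
# plasma concentrations at 1/5/10 min post-injection, per-animal Doppler
# hemodynamic summaries, and selected serum biochemistry with published
# comparison intervals. These are the inputs the aggregation and index
# operations are validated against.

#' Baseline weekly body weights of six healthy rats
#'
#' @return data.frame: \code{subject_id} plus columns \code{week1} ..
#'   \code{week4} (g). The per-measure and final weight-gain percentages as
#'   originally published are in attributes \code{"published_gain_per_measure"}
#'   (subjects x intervals) and \code{"published_final_gain"}; the published
#'   weekly group means in \code{"published_mean_weight"}.
#' @export
#' @examples
#' w <- baseline_weights()
#' final_weight_gain(w[, -1])$group   # 8.88
baseline_weights <- function() {
  out <- data.frame(
    subject_id = paste0("rat", 1:6),
    week1 = c(390.70, 369.00, 367.40, 328.10, 355.20, 413.70),
    week2 = c(390.30, 367.30, 372.20, 340.00, 350.50, 427.20),
    week3 = c(406.70, 376.00, 392.00, 353.90, 370.20, 435.90),
    week4 = c(418.20, 385.30, 408.50, 372.00, 383.20, 454.40))
  attr(out, "published_gain_per_measure") <- matrix(
    c(-0.10, 4.20, 2.83,
      -0.46, 2.37, 2.47,
       1.31, 5.32, 4.21,
       3.63, 4.68, 4.52,   # weeks 3-4 are inconsistent with the weights
      -1.32, 5.62, 3.51,
       3.26, 2.04, 4.24),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("rat", 1:6), c("w1_w2", "w2_w3", "w3_w4")))
  attr(out, "published_final_gain") <-
    c(rat1 = 7.04, rat2 = 4.42, rat3 = 11.19, rat4 = 13.38, rat5 = 7.88,
      rat6 = 9.84, group = 8.88)
  attr(out, "published_mean_weight") <-
    c(week1 = 370.68, week2 = 374.58, week3 = 389.45, week4 = 403.60)
  out
}

#' Baseline ICG plasma concentrations
#'
#' Per-rat mean plasma ICG concentration (ug/mL) at 1, 5 and 10 minutes
#' post-injection, with replicate SDs.
#'
#' @return data.frame: \code{subject_id}, \code{min1}, \code{min5},
#'   \code{min10} and the matching \code{*_sd} columns. The published group
#'   averages and clearance percentages are in attributes
#'   \code{"published_average"} and \code{"published_clearance_pct"}.
#' @export
#' @examples
#' icg <- baseline_icg()
#' reference_interval(icg$min5)$mean  # 31.01
baseline_icg <- function() {
  out <- data.frame(
    subject_id = paste0("rat", 1:6),
    min1 = c(128.10, 161.47, 160.63, 189.16, 165.91, 130.65),
    min5 = c(19.45, 28.58, 33.14, 38.13, 47.51, 19.24),
    min10 = c(5.41, 5.75, 7.44, 3.47, 2.90, 6.91),
    min1_sd = c(55.618, 65.82, 27.68, 51.05, 23.91, 10.21),
    min5_sd = c(2.28, 9.23, 6.95, 2.86, 8.82, 3.54),
    min10_sd = c(3.32, 3.60, 0.52, 0.05, 0.76, 0.99))
  attr(out, "published_average") <- c(min1 = 155.99, min5 = 31.01,
                                      min10 = 5.31)
  attr(out, "published_clearance_pct") <- c(min1 = 0.00, min5 = 80.12,
                                            min10 = 96.59)
  out
}

#' Baseline Doppler hemodynamic summaries
#'
#' Per-rat cardiovascular, hepatic and renal perfusion summaries: portal
#' area (mm^2), portal and hepatic-artery PSV/EDV (mm/s), hepatic-artery VTI
#' (mm), resistive index, portal congestion index, arterio-portal ratio,
#' heart rate (bpm), cardiac output (mL/min), left renal artery diameter
#' (mm), renal VTI (mm) and renal blood flow (mL/min).
#'
#' @return data.frame with one row per quantity (\code{quantity},
#'   \code{units}, \code{rat1} .. \code{rat6}, \code{published_mean},
#'   \code{published_sd}).
#' @export
#' @examples
#' h <- baseline_hemodynamics()
#' h[h$quantity == "portal_area", ]
baseline_hemodynamics <- function() {
  rows <- list(
    #            units            rat1    rat2    rat3    rat4    rat5    rat6    mean     sd
    portal_area = list("mm^2",  c(3.09,   3.60,   3.53,   2.67,   3.12,   4.48),  3.41,    0.62),
    portal_psv  = list("mm/s",  c(131.25, 161.00, 148.60, 176.20, 130.55, 156.75), 150.72, 17.80),
    ha_psv      = list("mm/s",  c(864.37, 687.47, 643.69, 627.48, 581.00, 755.47), 693.24, 102.53),
    ha_edv      = list("mm/s",  c(424.33, 266.29, 309.93, 262.63, 232.95, 304.78), 300.15, 67.24),
    ha_vti      = list("mm",    c(110.03, 82.37,  79.06,  73.06,  60.09,  84.23),  81.47,  16.47),
    ha_ri       = list("",      c(0.52,   0.59,   0.51,   0.57,   0.62,   0.61),   0.57,   0.04),
    pci         = list("mm^2/(mm/s)", c(0.02, 0.02, 0.02, 0.02,   0.03,   0.03),   0.023,  0.005),
    ap_ratio    = list("",      c(6.64,   4.39,   4.44,   3.84,   4.64,   4.98),   4.82,   0.96),
    hr          = list("bpm",   c(331.50, 303.13, 321.08, 316.71, 362.13, 351.50), 331.01, 22.22),
    co          = list("mL/min", c(79.64, 67.09,  74.03,  67.91,  74.12,  90.71),  75.58,  8.72),
    lrad        = list("mm",    c(0.91,   0.90,   0.81,   0.85,   0.92,   0.90),   0.88,   0.04),
    renal_vti   = list("mm",    c(64.37,  71.04,  67.21,  68.91,  63.59,  72.01),  67.86,  3.44),
    rbf         = list("mL/min", c(14.07, 13.27,  11.01,  12.07,  15.18,  16.28),  13.65,  1.95))
  out <- do.call(rbind, lapply(names(rows), function(q) {
    r <- rows[[q]]
    data.frame(quantity = q, units = r[[1]],
               rat1 = r[[2]][1], rat2 = r[[2]][2], rat3 = r[[2]][3],
               rat4 = r[[2]][4], rat5 = r[[2]][5], rat6 = r[[2]][6],
               published_mean = r[[3]], published_sd = r[[4]])
  }))
  rownames(out) <- NULL
  out
}

#' Baseline serum biochemistry and published comparison intervals
#'
#' Weekly group means (+/- SD) for selected liver-relevant analytes in the
#' baseline cohort, alongside published reference intervals for male
#' Sprague-Dawley rats used for flagging.
#'
#' @return list with two data.frames: \code{weekly} (analyte, units, week,
#'   mean, sd) and \code{published} (analyte, source, lower, upper).
#' @export
#' @examples
#' b <- baseline_biochemistry()
#' ast4 <- b$weekly[b$weekly$analyte == "AST" & b$weekly$week == 4, "mean"]
#' flag_against_interval(ast4, 64.1, 168.1)  # "below"
baseline_biochemistry <- function() {
  weekly <- rbind(
    data.frame(analyte = "AST", units = "IU/L", week = 1:4,
               mean = c(62.68, 51.70, 54.92, 44.50),
               sd = c(10.18, 6.20, 6.42, 3.24)),
    data.frame(analyte = "ALT", units = "IU/L", week = 1:4,
               mean = c(36.62, 34.25, 37.77, 31.42),
               sd = c(6.83, 3.89, 3.87, 3.74)),
    data.frame(analyte = "bilirubin", units = "mg/dL", week = 1:4,
               mean = c(1.74, 0.99, 1.18, 1.31),
               sd = c(0.71, 0.35, 0.46, 0.36)),
    data.frame(analyte = "total_protein", units = "g/dL", week = 1:4,
               mean = c(4.58, 4.93, 4.84, 4.59),
               sd = c(0.39, 0.45, 0.37, 0.24)),
    data.frame(analyte = "prothrombin_time", units = "s", week = 1:4,
               mean = c(41.57, 74.30, 18.83, 17.73),
               sd = c(29.44, 9.51, 1.47, 1.36)))
  published <- data.frame(
    analyte = c("AST", "AST", "ALT", "bilirubin", "total_protein",
                "prothrombin_time"),
    source = c("han2010", "he2017", "han2010", "petterino2006", "han2010",
               "han2010"),
    lower = c(64.1, 60, 30.8, 0.0, 5.68, 8.1),
    upper = c(168.1, 139, 73.4, 0.3, 9.25, 18.3))
  list(weekly = weekly, published = published)
}
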