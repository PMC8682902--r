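# Micro-CT volumetry: VOI attenuation statistics and Hounsfield-unit
# threshold segmentation with lower-bound sweeps.
#
# Conventions: voxel indices are 1-based (R arrays); world position of a
# voxel center is origin + (index - 0.5) * pitch; volumes in cm^3 come from
# exact voxel-count arithmetic, count * pitch^3 / 1000.

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of attenuation values in Hounsfield units.
#'   The conventional scale spans -1000 HU (air) to +1000 HU (dense bone);
#'   values outside it raise a warning, not an error.
#' @param pitch voxel edge length in mm; scalar (isotropic) or length 3
#'   (anisotropic, accepted with a warning).
#' @param origin world-space offset of the grid corner (mm), length 3.
#' @return an object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, pitch, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  stopifnot(length(pitch) == 3L, all(pitch > 0), length(origin) == 3L)
  if (length(unique(pitch)) > 1L)
    warning("anisotropic voxel pitch; volumes use the product of the edges",
            call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < -1000 || rng[2] > 1000)
    warning(sprintf("HU values outside [-1000, 1000] (range %.1f..%.1f)",
                    rng[1], rng[2]), call. = FALSE)
  structure(list(voxels = voxels, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, pitch %s mm, HU %.1f..%.1f\n",
              d[1], d[2], d[3], paste(signif(x$pitch, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Define a cubic volume of interest
#'
#' @param center voxel coordinates of the VOI center (1-based, length 3).
#' @param side VOI edge length in mm. The default 2 mm gives the
#'   conventional 8 mm^3 VOI.
#' @return an object of class \code{voi}.
#' @export
voi <- function(center, side = 2) {
  stopifnot(length(center) == 3L, all(center >= 1))
  check_scalar(side, "side", lower = 0, strict_lower = TRUE)
  structure(list(center = as.numeric(center), side = side), class = "voi")
}

voi_index_ranges <- function(volume, v) {
  n_side <- round(v$side / volume$pitch)
  lapply(1:3, function(i) {
    lo <- floor(v$center[i] - n_side[i] / 2) + 1L
    hi <- lo + n_side[i] - 1L
    if (lo < 1L || hi > dim(volume$voxels)[i])
      stop("VOI extends outside the grid", call. = FALSE)
    lo:hi
  })
}

#' Attenuation statistics over a VOI
#'
#' Mean and SD of the HU values inside a cubic VOI, after removing voxels
#' covered by an optional exclusion mask (used in practice to keep
#' macroscopic vessels out of parenchyma statistics).
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param voi a \code{\link{voi}}.
#' @param exclusion_mask optional logical array, same shape as the volume;
#'   TRUE voxels are excluded.
#' @return list: \code{mean_hu}, \code{sd_hu}, \code{n_voxels}.
#' @export
#' @examples
#' vol <- ct_volume(array(135, c(20, 20, 20)), pitch = 0.125)
#' voi_stats(vol, voi(center = c(10, 10, 10), side = 2))
voi_stats <- function(volume, voi, exclusion_mask = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(voi, "voi"))
  idx <- voi_index_ranges(volume, voi)
  vals <- volume$voxels[idx[[1]], idx[[2]], idx[[3]]]
  if (!is.null(exclusion_mask)) {
    stopifnot(identical(dim(exclusion_mask), dim(volume$voxels)))
    excl <- exclusion_mask[idx[[1]], idx[[2]], idx[[3]]]
    vals <- vals[!excl]
  }
  if (length(vals) == 0L)
    stop("VOI is empty after applying the exclusion mask", call. = FALSE)
  list(mean_hu = mean(vals),
       sd_hu = if (length(vals) > 1L) sd(vals) else NA_real_,
       n_voxels = length(vals))
}

#' Segment a CT volume by HU thresholding
#'
#' The mask keeps voxels with \code{lower_hu <= HU <= upper_hu}. Under the
#' \code{"largest-component"} policy only the largest connected component
#' (26-connectivity by default) survives — the operational reading of
#' outlining an organ with a 3D isocontour. Volume is exact voxel-count
#' arithmetic; the mean HU of an empty mask is reported as \code{NA} and
#' flagged, never as 0.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param lower_hu,upper_hu window bounds (HU), \code{lower_hu < upper_hu}.
#' @param component_policy \code{"all-voxels"} or \code{"largest-component"}.
#' @param connectivity 6, 18 or 26 (neighborhood used for components).
#' @return an object of class \code{segmentation_result}: list with
#'   \code{mask} (logical array), \code{lower_hu}, \code{upper_hu},
#'   \code{n_voxels}, \code{volume_cm3}, \code{mean_hu}, \code{empty},
#'   \code{component_policy}.
#' @export
#' @examples
#' vol <- ct_volume(array(135, c(8, 8, 8)), pitch = 0.125)
#' threshold_segment(vol, 0, 1000)$volume_cm3
threshold_segment <- function(volume, lower_hu, upper_hu,
                              component_policy = c("all-voxels",
                                                   "largest-component"),
                              connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"))
  component_policy <- match.arg(component_policy)
  if (!(lower_hu < upper_hu))
    stop("`lower_hu` must be smaller than `upper_hu`", call. = FALSE)
  mask <- volume$voxels >= lower_hu & volume$voxels <= upper_hu
  if (component_policy == "largest-component" && any(mask)) {
    labs <- .label_components(mask, dim(mask), as.integer(connectivity))
    tab <- tabulate(labs[labs > 0L])
    mask <- array(labs == which.max(tab), dim = dim(mask))
  }
  n <- sum(mask)
  structure(list(mask = mask, lower_hu = lower_hu, upper_hu = upper_hu,
                 n_voxels = n,
                 volume_cm3 = n * prod(volume$pitch) / 1000,
                 mean_hu = if (n > 0L) mean(volume$voxels[mask]) else NA_real_,
                 empty = n == 0L,
                 component_policy = component_policy),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> window [%g, %g] HU (%s): %d voxels, %.4f cm^3, mean %s HU\n",
    x$lower_hu, x$upper_hu, x$component_policy, x$n_voxels, x$volume_cm3,
    if (x$empty) "NA (empty mask)" else sprintf("%.2f", x$mean_hu)))
  invisible(x)
}

#' Sweep the lower HU threshold
#'
#' Re-segments the volume once per lower bound against a fixed open upper
#' bound. Raising the lower bound can only shrink the mask, so volumes are
#' non-increasing and (for heterogeneous tissue) mean HU non-decreasing
#' across the sweep; the returned summary reports whether each monotonicity
#' holds.
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param lower_list ascending lower bounds in HU; the conventional liver
#'   sweep is \code{c(0, 50, 100, 120)} (0 HU excludes fat).
#' @param upper_hu fixed upper bound (HU), default +1000 (open window).
#' @param ... passed to \code{\link{threshold_segment}}
#'   (\code{component_policy}, \code{connectivity}).
#' @return an object of class \code{threshold_sweep}: list with
#'   \code{results} (list of \code{segmentation_result}), \code{summary}
#'   (data.frame: lower_hu, upper_hu, n_voxels, volume_cm3, mean_hu) and
#'   \code{monotone} (list: volume_nonincreasing, mean_hu_nondecreasing).
#' @export
threshold_sweep <- function(volume, lower_list = c(0, 50, 100, 120),
                            upper_hu = 1000, ...) {
  check_increasing(lower_list, "lower_list")
  res <- lapply(lower_list, function(lo)
    threshold_segment(volume, lo, upper_hu, ...))
  summ <- data.frame(
    lower_hu = lower_list,
    upper_hu = upper_hu,
    n_voxels = vapply(res, `[[`, 0L, "n_voxels"),
    volume_cm3 = vapply(res, `[[`, 0, "volume_cm3"),
    mean_hu = vapply(res, `[[`, 0, "mean_hu"))
  mhu <- summ$mean_hu[!is.na(summ$mean_hu)]
  structure(list(results = res, summary = summ,
                 monotone = list(
                   volume_nonincreasing = !is.unsorted(rev(summ$volume_cm3)),
                   mean_hu_nondecreasing = length(mhu) < 2L || !is.unsorted(mhu))),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("volume non-increasing: %s; mean HU non-decreasing: %s\n",
              x$monotone$volume_nonincreasing,
              x$monotone$mean_hu_nondecreasing))
  invisible(x)
}

#' Percent of a total mask covered by a segmentation
#'
#' @param seg a \code{\link{threshold_segment}} result, or a logical array.
#' @param total_mask logical array of the same shape, non-empty.
#' @return percentage, \code{100 * |seg| / |total|}.
#' @export
segmented_fraction <- function(seg, total_mask) {
  m <- if (inherits(seg, "segmentation_result")) seg$mask else seg
  stopifnot(is.logical(m), is.logical(total_mask),
            identical(dim(m), dim(total_mask)))
  n_tot <- sum(total_mask)
  if (n_tot == 0L) stop("`total_mask` is empty", call. = FALSE)
  100 * sum(m) / n_tot
}
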