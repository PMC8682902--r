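# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: exponential ICG decay with plate-reader-like
# multiplicative noise, pulsatile Doppler velocity traces, and voxelized
# liver phantoms with known (label) ground truth.

#' Parameters for the ICG plasma-decay simulator
#'
#' The simulator works in the elimination phase of a one-compartment model
#' (distribution after bolus injection takes only seconds in the rat and is
#' not modeled): the noise-free concentration at time \eqn{t} minutes is
#' \eqn{C_0 \cdot 10^{-kt}}. Technical replicates receive multiplicative
#' lognormal noise with the stated coefficient of variation, so the
#' expectation of a replicate equals the noise-free mean.
#'
#' @param C0 initial plasma concentration (ug/mL), > 0.
#' @param k elimination rate constant per minute on the log10 scale, >= 0.
#' @param t_grid sampling times in minutes, strictly increasing, >= 0.
#' @param noise_cv coefficient of variation of the multiplicative measurement
#'   noise (fraction), >= 0.
#' @param n_replicates technical replicates per timepoint, >= 1.
#' @param seed integer RNG seed.
#' @return an object of class \code{icg_sim_params}.
#' @export
#' @examples
#' p <- icg_sim_params(C0 = 155.99, k = 0.1754, t_grid = c(1, 5, 10))
icg_sim_params <- function(C0 = 155.99, k = 0.1754, t_grid = c(1, 5, 10),
                           noise_cv = 0.1, n_replicates = 3, seed = 1L) {
  check_scalar(C0, "C0", lower = 0, strict_lower = TRUE)
  check_scalar(k, "k", lower = 0)
  if (any(t_grid < 0)) stop("`t_grid` times must be non-negative", call. = FALSE)
  check_increasing(t_grid, "t_grid")
  check_scalar(noise_cv, "noise_cv", lower = 0)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  structure(list(C0 = C0, k = k, t_grid = as.numeric(t_grid),
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "icg_sim_params")
}

#' Simulate an ICG plasma concentration series
#'
#' Draws \code{n_replicates} lognormal replicates around the noise-free decay
#' \eqn{C_0 \cdot 10^{-kt}} at each time in \code{t_grid}. The lognormal is
#' parameterized so that the replicate mean is unbiased for the noise-free
#' value: \code{sdlog = sqrt(log(1 + cv^2))}, \code{meanlog = -sdlog^2/2}.
#'
#' @param params an \code{\link{icg_sim_params}} object.
#' @param subject_id label for the simulated subject.
#' @return a \code{\link{concentration_series}} whose concentrations are the
#'   replicate means; the full replicate matrix (times x replicates) is kept
#'   in the \code{"replicates"} attribute.
#' @export
#' @examples
#' s <- simulate_icg_series(icg_sim_params(noise_cv = 0, seed = 7))
#' s$concentrations  # exactly C0 * 10^(-k * t)
simulate_icg_series <- function(params, subject_id = "sim") {
  stopifnot(inherits(params, "icg_sim_params"))
  mu <- params$C0 * 10^(-params$k * params$t_grid)
  nt <- length(params$t_grid)
  reps <- with_seed(params$seed, {
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log(1 + params$noise_cv^2))
      fac <- matrix(stats::rlnorm(nt * params$n_replicates,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nt)
      mu * fac
    } else {
      matrix(rep(mu, params$n_replicates), nrow = nt)
    }
  })
  out <- concentration_series(
    subject_id = subject_id,
    times = params$t_grid,
    concentrations = rowMeans(reps),
    replicate_sd = if (params$n_replicates > 1L) apply(reps, 1L, stats::sd) else NULL
  )
  attr(out, "replicates") <- reps
  attr(out, "params") <- params
  out
}

#' Parameters for the pulsatile velocity-trace simulator
#'
#' @param hr heart rate (beats per minute), > 0.
#' @param psv_true peak systolic velocity (mm/s), >= \code{edv_true}.
#' @param edv_true end-diastolic velocity (mm/s), >= 0.
#' @param pulse_width_frac systolic pulse width as a fraction of the cardiac
#'   cycle, in (0, 1).
#' @param duration trace length in seconds; must cover at least 5 cycles.
#' @param fs sampling rate (Hz); must resolve >= 20 samples per cycle.
#' @param noise_sd additive Gaussian noise (mm/s), >= 0.
#' @param seed integer RNG seed.
#' @return an object of class \code{waveform_sim_params}.
#' @export
waveform_sim_params <- function(hr = 331.5, psv_true = 864.37,
                                edv_true = 424.33, pulse_width_frac = 0.4,
                                duration = 2, fs = 2000, noise_sd = 0,
                                seed = 1L) {
  check_scalar(hr, "hr", lower = 0, strict_lower = TRUE)
  check_scalar(edv_true, "edv_true", lower = 0)
  check_scalar(psv_true, "psv_true", lower = edv_true)
  check_scalar(pulse_width_frac, "pulse_width_frac", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  n_cycles <- duration * hr / 60
  if (n_cycles < 5)
    stop(sprintf("duration must cover at least 5 cardiac cycles (got %.2f)",
                 n_cycles), call. = FALSE)
  if (fs * 60 / hr < 20)
    stop(sprintf("fs too low to resolve pulses: %.1f samples/cycle < 20",
                 fs * 60 / hr), call. = FALSE)
  structure(list(hr = hr, psv_true = psv_true, edv_true = edv_true,
                 pulse_width_frac = pulse_width_frac, duration = duration,
                 fs = fs, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "waveform_sim_params")
}

#' Simulate a Doppler velocity trace
#'
#' A raised-cosine systolic pulse of height \code{psv_true - edv_true} rides
#' on a flat end-diastolic baseline, one pulse per cardiac cycle, centered at
#' mid-cycle. The raised cosine was chosen because it is differentiable, has
#' an unambiguous per-cycle maximum (the pulse apex) and minimum (the
#' baseline), and admits a closed-form velocity-time integral:
#' over one cycle \eqn{VTI = EDV \cdot T + (PSV - EDV) \cdot wT/2}, with
#' \eqn{T} the cycle period and \eqn{w} the pulse width fraction.
#'
#' @param params a \code{\link{waveform_sim_params}} object.
#' @param vessel vessel label attached to the trace.
#' @return a \code{\link{velocity_trace}}; the simulation truth is kept in the
#'   \code{"params"} attribute.
#' @export
#' @examples
#' tr <- simulate_velocity_trace(waveform_sim_params(noise_sd = 0))
#' range(tr$samples)
simulate_velocity_trace <- function(params, vessel = "hepatic artery") {
  stopifnot(inherits(params, "waveform_sim_params"))
  n <- floor(params$duration * params$fs)
  t <- (seq_len(n) - 1L) / params$fs
  period <- 60 / params$hr
  phase <- (t %% period) / period          # in [0, 1)
  w <- params$pulse_width_frac
  amp <- params$psv_true - params$edv_true
  in_pulse <- abs(phase - 0.5) <= w / 2
  v <- rep(params$edv_true, n)
  v[in_pulse] <- params$edv_true +
    amp * 0.5 * (1 + cos(2 * pi * (phase[in_pulse] - 0.5) / w))
  if (params$noise_sd > 0)
    v <- v + with_seed(params$seed, rnorm(n, sd = params$noise_sd))
  out <- velocity_trace(v, fs = params$fs, vessel = vessel)
  attr(out, "params") <- params
  out
}

#' Parameters for the voxelized liver phantom
#'
#' The phantom is a statistical stand-in for an ex-vivo micro-CT liver scan,
#' not an anatomical model: an ellipsoidal parenchyma (Gaussian HU about
#' \code{parenchyma_hu_mean}) wrapped in a thin higher-attenuation capsule
#' shell, pierced by axis-aligned cylindrical vessels near blood attenuation,
#' with optional sub-zero-HU fat pockets, all embedded in air at -1000 HU.
#'
#' @param grid_shape voxels per axis (length 3 or scalar).
#' @param voxel_pitch mm per voxel edge (isotropic), > 0.
#' @param liver_semiaxes ellipsoid semi-axes in mm (length 3).
#' @param parenchyma_hu_mean,parenchyma_hu_sd parenchyma attenuation (HU);
#'   the per-voxel noise SD defaults to \code{noise_sd}.
#' @param capsule_hu_range capsule attenuation range (HU), low then high.
#' @param capsule_thickness capsule shell thickness in mm; 0 removes it.
#' @param vessel_hu vessel (blood) attenuation in HU.
#' @param vessel_radii radii (mm) of the axis-aligned cylindrical vessels;
#'   \code{numeric(0)} removes vessels.
#' @param fat_hu_mean mean fat attenuation (HU), < 0.
#' @param fat_radii radii (mm) of spherical fat pockets; \code{numeric(0)}
#'   removes fat.
#' @param noise_sd additive Gaussian HU noise, >= 0.
#' @param seed integer RNG seed.
#' @return an object of class \code{phantom_params}.
#' @export
phantom_params <- function(grid_shape = c(96, 96, 96), voxel_pitch = 0.125,
                           liver_semiaxes = c(5, 4, 3.5),
                           parenchyma_hu_mean = 135,
                           capsule_hu_range = c(150, 200),
                           capsule_thickness = 0.25,
                           vessel_hu = 40, vessel_radii = c(0.4, 0.25),
                           fat_hu_mean = -100, fat_radii = c(0.6, 0.45),
                           noise_sd = 12, seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4))
  check_scalar(voxel_pitch, "voxel_pitch", lower = 0, strict_lower = TRUE)
  stopifnot(length(liver_semiaxes) == 3L, all(liver_semiaxes > 0))
  check_scalar(parenchyma_hu_mean, "parenchyma_hu_mean",
               lower = 0, upper = 1000, strict_lower = TRUE)
  stopifnot(length(capsule_hu_range) == 2L,
            capsule_hu_range[1] <= capsule_hu_range[2])
  check_scalar(capsule_thickness, "capsule_thickness", lower = 0)
  check_scalar(fat_hu_mean, "fat_hu_mean", upper = 0, strict_upper = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  # the liver (plus capsule) must fit in the grid with a one-voxel margin
  half_extent <- grid_shape * voxel_pitch / 2
  if (any(liver_semiaxes + capsule_thickness + voxel_pitch >= half_extent))
    stop("liver does not fit in the grid with margin; enlarge grid_shape ",
         "or shrink liver_semiaxes", call. = FALSE)
  if (capsule_thickness > 0 && capsule_thickness < voxel_pitch)
    warning("capsule_thickness < voxel_pitch: the capsule may be unresolved",
            call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_pitch = voxel_pitch,
                 liver_semiaxes = as.numeric(liver_semiaxes),
                 parenchyma_hu_mean = parenchyma_hu_mean,
                 capsule_hu_range = as.numeric(capsule_hu_range),
                 capsule_thickness = capsule_thickness,
                 vessel_hu = vessel_hu, vessel_radii = as.numeric(vessel_radii),
                 fat_hu_mean = fat_hu_mean, fat_radii = as.numeric(fat_radii),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Phantom label codes
#'
#' Integer codes used in the ground-truth label volume returned by
#' \code{\link{generate_liver_phantom}}.
#' @return named integer vector: background 0, fat 1, parenchyma 2,
#'   capsule 3, vessel 4.
#' @export
phantom_labels <- function() {
  c(background = 0L, fat = 1L, parenchyma = 2L, capsule = 3L, vessel = 4L)
}

#' Generate a voxelized liver phantom with ground-truth labels
#'
#' @param params a \code{\link{phantom_params}} object.
#' @return a list of class \code{liver_phantom} with elements
#'   \describe{
#'     \item{volume}{a \code{\link{ct_volume}} of HU values}
#'     \item{labels}{integer array, codes per \code{\link{phantom_labels}}}
#'     \item{truth}{list: per-label voxel counts, ground-truth liver volume
#'       in cm^3 (all non-background labels), and the label-weighted expected
#'       mean HU of the tissue within [0, 1000]}
#'     \item{params}{the generating parameters}
#'   }
#' @export
#' @examples
#' ph <- generate_liver_phantom(phantom_params(grid_shape = 32,
#'   liver_semiaxes = c(1.5, 1.2, 1.1), noise_sd = 0))
#' ph$truth$liver_volume_cm3
generate_liver_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$grid_shape
  p <- params$voxel_pitch
  # voxel-center coordinates (mm), origin at grid center
  ax <- lapply(1:3, function(i) ((seq_len(g[i]) - 0.5) - g[i] / 2) * p)
  X <- array(rep(ax[[1]], times = g[2] * g[3]), dim = g)
  Y <- array(rep(rep(ax[[2]], each = g[1]), times = g[3]), dim = g)
  Z <- array(rep(ax[[3]], each = g[1] * g[2]), dim = g)

  a <- params$liver_semiaxes
  rho <- sqrt((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2)
  labels <- array(0L, dim = g)
  inside <- rho <= 1
  labels[inside] <- phantom_labels()[["parenchyma"]]
  if (params$capsule_thickness > 0) {
    rho_in <- 1 - params$capsule_thickness / min(a)
    labels[inside & rho > rho_in] <- phantom_labels()[["capsule"]]
  }
  # axis-aligned cylindrical vessels along x, offset in z to avoid overlap
  if (length(params$vessel_radii)) {
    z_off <- seq_along(params$vessel_radii) - (length(params$vessel_radii) + 1) / 2
    z_off <- z_off * min(a) / 2
    for (i in seq_along(params$vessel_radii)) {
      r <- params$vessel_radii[i]
      cyl <- (Y^2 + (Z - z_off[i])^2) <= r^2
      labels[cyl & labels == phantom_labels()[["parenchyma"]]] <-
        phantom_labels()[["vessel"]]
    }
  }
  # spherical fat pockets at fixed relative positions inside the parenchyma
  if (length(params$fat_radii)) {
    centers <- rbind(c(0.45, 0.35, -0.3), c(-0.4, -0.3, 0.35))
    for (i in seq_along(params$fat_radii)) {
      cc <- centers[1 + (i - 1) %% nrow(centers), ] * a
      sph <- ((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2) <=
        params$fat_radii[i]^2
      labels[sph & labels == phantom_labels()[["parenchyma"]]] <-
        phantom_labels()[["fat"]]
    }
  }

  hu <- array(-1000, dim = g)  # air background
  lab <- phantom_labels()
  hu[labels == lab[["parenchyma"]]] <- params$parenchyma_hu_mean
  hu[labels == lab[["vessel"]]] <- params$vessel_hu
  hu[labels == lab[["fat"]]] <- params$fat_hu_mean
  n_cap <- sum(labels == lab[["capsule"]])
  hu_final <- with_seed(params$seed, {
    if (n_cap > 0)
      hu[labels == lab[["capsule"]]] <- runif(n_cap, params$capsule_hu_range[1],
                                              params$capsule_hu_range[2])
    if (params$noise_sd > 0) {
      tissue <- labels != lab[["background"]] & labels != lab[["capsule"]]
      hu[tissue] <- hu[tissue] + rnorm(sum(tissue), sd = params$noise_sd)
    }
    hu
  })
  hu_final[hu_final > 1000] <- 1000
  hu_final[hu_final < -1000] <- -1000

  counts <- table(factor(labels, levels = lab, labels = names(lab)))
  counts <- setNames(as.integer(counts), names(counts))
  n_liver <- sum(counts[c("fat", "parenchyma", "capsule", "vessel")])
  # expected mean HU of in-window ([0,1000]) tissue, weighted by label counts
  exp_means <- c(parenchyma = params$parenchyma_hu_mean,
                 capsule = mean(params$capsule_hu_range),
                 vessel = params$vessel_hu)
  w <- counts[names(exp_means)]
  truth <- list(
    label_counts = counts,
    liver_volume_cm3 = n_liver * p^3 / 1000,
    inwindow_mean_hu = sum(exp_means * w) / sum(w)
  )
  structure(list(volume = ct_volume(hu_final, pitch = p),
                 labels = labels, truth = truth, params = params),
            class = "liver_phantom")
}
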