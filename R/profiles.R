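#' Cohort phenotype profile
#'
#' A `cohort_profile` holds the generative parameters of one mechanophenotype:
#' baseline traction force and its dependence on spread area, the biphasic
#' stimulus response (peak increase, time-to-peak, relaxation), the mHz-band
#' actomyosin force oscillation, calcium-transient parameters, and actin
#' texture parameters. The packaged defaults (see [cohort_defaults()])
#' describe young, old, AngII-treated young ("induced premature aging") and
#' siPiezo1-treated old ("Piezo1-reversed aging") vascular smooth muscle
#' cells.
#'
#' @param name Cohort label.
#' @param baseline_force Mean cell-total baseline traction force F0, nN.
#' @param force_area_slope Slope of the per-cell baseline force vs spread
#'   area relation, nN/um^2 (cells with larger footprints pull harder).
#' @param force_area_intercept Intercept of that relation, nN.
#' @param force_sd Per-cell SD of baseline force about the area relation, nN.
#' @param peak_increase Mean fractional increase of total force at peak
#'   contraction over baseline (dimensionless, e.g. 0.57 = +57%).
#' @param peak_increase_sd Per-cell SD of the fractional increase.
#' @param time_to_peak Mean time from stimulus onset to peak contraction, min.
#' @param time_to_peak_sd Per-cell SD of time-to-peak, min.
#' @param relaxation_tau Exponential relaxation time constant, min.
#' @param residual_fraction Fraction of the peak force excess still present
#'   as t -> end of observation (0 = full return to baseline).
#' @param osc_center_freq Center frequency of the actomyosin force
#'   oscillation band, mHz.
#' @param osc_amplitude Mean instantaneous amplitude of the oscillation on
#'   the pillar-velocity scale, um/min (envelope mean of d|u|/dt).
#' @param fast_freq Center frequency of the fast, low-amplitude actomyosin
#'   flicker band, mHz. This near-Nyquist component is the first intrinsic
#'   mode of the measured velocity series, which is why the slower
#'   `osc_center_freq` band is analyzed on IMF2.
#' @param fast_amplitude Velocity-envelope amplitude of the flicker band,
#'   um/min.
#' @param ca_peak Calcium transient peak, fold over the pre-stimulus level.
#' @param ca_peak_sd Per-cell SD of the calcium peak.
#' @param ca_recovery_15min Fraction of the calcium peak excess decayed
#'   15 min after stimulus (1 = full return to baseline).
#' @param actin_intensity_mean,actin_intensity_sd Per-cell mean and SD of
#'   masked F-actin fluorescence intensity, a.u.
#' @param orientation_kappa von Mises concentration of stress-fiber
#'   orientations about the cell axis (large = aligned, 0 = isotropic).
#' @param cell_area_mean,cell_area_sd Per-cell mean and SD of spread area,
#'   um^2.
#' @return An object of class `cohort_profile`.
#' @seealso [cohort_defaults()]
#' @export
cohort_profile <- function(name,
                           baseline_force, force_area_slope,
                           force_area_intercept, force_sd,
                           peak_increase, peak_increase_sd,
                           time_to_peak, time_to_peak_sd,
                           relaxation_tau, residual_fraction,
                           osc_center_freq, osc_amplitude,
                           fast_freq, fast_amplitude,
                           ca_peak, ca_peak_sd, ca_recovery_15min,
                           actin_intensity_mean, actin_intensity_sd,
                           orientation_kappa,
                           cell_area_mean, cell_area_sd) {
  p <- list(name = name, baseline_force = baseline_force,
            force_area_slope = force_area_slope,
            force_area_intercept = force_area_intercept,
            force_sd = force_sd,
            peak_increase = peak_increase,
            peak_increase_sd = peak_increase_sd,
            time_to_peak = time_to_peak, time_to_peak_sd = time_to_peak_sd,
            relaxation_tau = relaxation_tau,
            residual_fraction = residual_fraction,
            osc_center_freq = osc_center_freq, osc_amplitude = osc_amplitude,
            fast_freq = fast_freq, fast_amplitude = fast_amplitude,
            ca_peak = ca_peak, ca_peak_sd = ca_peak_sd,
            ca_recovery_15min = ca_recovery_15min,
            actin_intensity_mean = actin_intensity_mean,
            actin_intensity_sd = actin_intensity_sd,
            orientation_kappa = orientation_kappa,
            cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd)
  num <- p[setdiff(names(p), c("name", "orientation_kappa"))]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) < 0, na.rm = TRUE))
    stop("profile parameters must be non-negative numbers")
  if (p$residual_fraction > 1) stop("residual_fraction must be in [0, 1]")
  if (p$ca_recovery_15min > 1) stop("ca_recovery_15min must be in [0, 1]")
  if (p$orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  structure(p, class = "cohort_profile")
}

#' Packaged cohort defaults
#'
#' Default `cohort_profile`s for the four study conditions. The young/old
#' pair encodes the aging phenotype: young cells respond to a transient
#' stimulus with a larger peak force increase reached sooner, carry
#' faster and larger mHz-band force oscillations, show a smaller but fully
#' recovering calcium transient, brighter and more aligned F-actin, and a
#' smaller spread area with a steeper force-vs-area slope. AngII-treated
#' young cells mimic old cells (with a 2.4-fold F-actin reduction relative
#' to young); siPiezo1-treated old cells keep old static properties but
#' recover young-like force dynamics and calcium handling.
#'
#' The force-program parameters are calibrated at the pipeline level: the
#' defaults are set so that the *measured* cohort metrics (normalized peak
#' force, time-to-peak, IMF2 amplitude/frequency), after rendering,
#' detection, tracking and spectral analysis, land on the young/old
#' phenotype values; see the methods vignette for the calibration
#' procedure.
#'
#' @param name One of `"young"`, `"old"`, `"young_angii"`, `"old_sipiezo1"`.
#' @return A `cohort_profile`.
#' @examples
#' cohort_defaults("young")
#' cohort_defaults("old")$time_to_peak
#' @export
cohort_defaults <- function(name = c("young", "old", "young_angii",
                                     "old_sipiezo1")) {
  name <- match.arg(name)
  switch(name,
    young = cohort_profile("young",
      baseline_force = 120, force_area_slope = 0.060,
      force_area_intercept = 0, force_sd = 8,
      peak_increase = 0.55, peak_increase_sd = 0.06,
      time_to_peak = 28.2, time_to_peak_sd = 2.3,
      relaxation_tau = 10, residual_fraction = 0.05,
      osc_center_freq = 4.5, osc_amplitude = 0.140,
      fast_freq = 15, fast_amplitude = 0.50,
      ca_peak = 2.0, ca_peak_sd = 0.15, ca_recovery_15min = 0.90,
      actin_intensity_mean = 120, actin_intensity_sd = 15,
      orientation_kappa = 8,
      cell_area_mean = 2000, cell_area_sd = 250),
    old = cohort_profile("old",
      baseline_force = 150, force_area_slope = 0.030,
      force_area_intercept = 45, force_sd = 10,
      peak_increase = 0.18, peak_increase_sd = 0.04,
      time_to_peak = 37.0, time_to_peak_sd = 6.6,
      relaxation_tau = 15, residual_fraction = 0.50,
      osc_center_freq = 1.2, osc_amplitude = 0.050,
      fast_freq = 12, fast_amplitude = 0.05,
      ca_peak = 2.5, ca_peak_sd = 0.20, ca_recovery_15min = 0.25,
      actin_intensity_mean = 80, actin_intensity_sd = 12,
      orientation_kappa = 2,
      cell_area_mean = 3500, cell_area_sd = 400),
    young_angii = cohort_profile("young_angii",
      baseline_force = 140, force_area_slope = 0.032,
      force_area_intercept = 38, force_sd = 10,
      peak_increase = 0.18, peak_increase_sd = 0.04,
      time_to_peak = 35, time_to_peak_sd = 6,
      relaxation_tau = 15, residual_fraction = 0.50,
      osc_center_freq = 1.2, osc_amplitude = 0.050,
      fast_freq = 12, fast_amplitude = 0.05,
      ca_peak = 2.8, ca_peak_sd = 0.20, ca_recovery_15min = 0.20,
      actin_intensity_mean = 50, actin_intensity_sd = 8,
      orientation_kappa = 2,
      cell_area_mean = 3200, cell_area_sd = 400),
    old_sipiezo1 = cohort_profile("old_sipiezo1",
      baseline_force = 150, force_area_slope = 0.030,
      force_area_intercept = 45, force_sd = 10,
      peak_increase = 0.45, peak_increase_sd = 0.06,
      time_to_peak = 29, time_to_peak_sd = 3,
      relaxation_tau = 11, residual_fraction = 0.10,
      osc_center_freq = 4.0, osc_amplitude = 0.110,
      fast_freq = 14, fast_amplitude = 0.40,
      ca_peak = 2.2, ca_peak_sd = 0.15, ca_recovery_15min = 0.85,
      actin_intensity_mean = 80, actin_intensity_sd = 12,
      orientation_kappa = 2,
      cell_area_mean = 3500, cell_area_sd = 400))
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> %s\n", x$name))
  cat(sprintf("  F0 %.3g nN (+%.0f%% peak @ %.1f min, tau %.3g min)\n",
              x$baseline_force, 100 * x$peak_increase, x$time_to_peak,
              x$relaxation_tau))
  cat(sprintf("  oscillation %.3g mHz / %.3g um/min; Ca peak %.3gx, rec %.0f%%\n",
              x$osc_center_freq, x$osc_amplitude, x$ca_peak,
              100 * x$ca_recovery_15min))
  invisible(x)
}

#' Simulation configuration
#'
#' Global settings shared by the synthetic generators: recording length and
#' frame interval, stimulus timing, rendering and noise parameters. A single
#' integer seed fixes all randomness end-to-end.
#'
#' @param seed Integer seed controlling every random draw.
#' @param duration Recording length, min (55 min at a 30-s frame interval
#'   mirrors a 1-h micropillar movie with a short pre-stimulus baseline).
#' @param dt Frame interval, min (0.5 min = 30 s).
#' @param prestim_frames Number of frames recorded before stimulus onset;
#'   stimulus time is `prestim_frames * dt`.
#' @param n_cells Cells per cohort for cohort-level generators.
#' @param pixel_size Rendered image pixel size, um/px.
#' @param psf_sigma Gaussian point-spread sigma of a rendered pillar top, px.
#' @param jitter_sd Frame-to-frame localization jitter of each rendered
#'   spot, um (thermal/stage noise; also applied to truth tables).
#' @param image_noise_sd Additive Gaussian image noise, a.u. (uint16 counts).
#' @param ca_dt Calcium sampling interval, min (10-s sampling).
#' @param ca_duration Calcium recording length, min.
#' @param ca_prestim Calcium pre-stimulus baseline, min.
#' @param ca_noise_sd Multiplicative calcium noise SD (fraction).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration = 55, dt = 0.5,
                       prestim_frames = 10L, n_cells = 8L,
                       pixel_size = 0.8, psf_sigma = 1.0,
                       jitter_sd = 0.005, image_noise_sd = 15,
                       ca_dt = 1 / 6, ca_duration = 30, ca_prestim = 2,
                       ca_noise_sd = 0.01) {
  if (dt <= 0 || duration <= 0) stop("duration and dt must be positive")
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    stop("duration must be an integer multiple of dt")
  structure(list(seed = as.integer(seed), duration = duration, dt = dt,
                 prestim_frames = as.integer(prestim_frames),
                 n_cells = as.integer(n_cells), pixel_size = pixel_size,
                 psf_sigma = psf_sigma, jitter_sd = jitter_sd,
                 image_noise_sd = image_noise_sd, ca_dt = ca_dt,
                 ca_duration = ca_duration, ca_prestim = ca_prestim,
                 ca_noise_sd = ca_noise_sd),
            class = "sim_config")
}

#' Frame times of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Frame times in min (t = 0 at recording start).
#' @export
config_times <- function(config) {
  n <- round(config$duration / config$dt)
  seq(0, by = config$dt, length.out = n + 1L)[-(n + 1L)]
}

#' Stimulus onset time of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Stimulus time in min (`prestim_frames * dt`).
#' @export
config_stim_time <- function(config) config$prestim_frames * config$dt
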