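# Synthetic single-cell force program: biphasic response + mHz oscillation.

# normal draw truncated to [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (lo >= hi) stop("empty truncation interval")
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Zero-mean Gaussian band-limited noise
#'
#' Unit-variance Gaussian noise confined to a frequency band: white noise
#' shaped in the Fourier domain by a Gaussian transfer function of center
#' `fc` and full-width-at-half-maximum bandwidth `bw` (both in cycles per
#' time unit of `dt`). This is the oscillation primitive of the synthetic
#' force generator: band-limited rather than a deterministic tone, so the
#' instantaneous-frequency analysis sees a well-defined dominant frequency
#' with natural amplitude modulation.
#'
#' @param n Number of samples.
#' @param dt Sample interval.
#' @param fc Band center, cycles per unit of `dt`.
#' @param bw FWHM bandwidth, same units.
#' @return Numeric vector of length `n`, unit variance (or zeros when the
#'   band carries no energy).
#' @export
band_limited_noise <- function(n, dt, fc, bw) {
  white <- stats::rnorm(n)
  f <- seq(0, n - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)                      # two-sided frequency axis
  sig_f <- bw / (2 * sqrt(2 * log(2)))
  H <- exp(-(f - fc)^2 / (2 * sig_f^2))
  y <- Re(stats::fft(stats::fft(white) * H, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < .Machine$double.eps) return(rep(0, n))
  y / s
}

# biphasic global force program: raised-cosine rise to F0*(1+rho) at
# t_stim + t_peak, then exponential relaxation toward
# F0*(1 + rho*residual_fraction)
force_program <- function(times, t_stim, F0, rho, t_peak, tau, residual) {
  g <- rep(F0, length(times))
  rise <- times >= t_stim & times < t_stim + t_peak
  g[rise] <- F0 * (1 + rho * 0.5 *
                     (1 - cos(pi * (times[rise] - t_stim) / t_peak)))
  rel <- times >= t_stim + t_peak
  g[rel] <- F0 * (1 + rho * (residual + (1 - residual) *
                               exp(-(times[rel] - t_stim - t_peak) / tau)))
  g
}

#' Simulate the traction-force response of one cell on a pillar array
#'
#' Generates ground-truth per-pillar deflection series for a single cell
#' with the biphasic mechanoresponse of the cohort: a baseline total force
#' `F0`, a raised-cosine reinforcement to `F0 * (1 + rho)` reached
#' `time_to_peak` minutes after the stimulus, and an exponential relaxation
#' toward `F0 * (1 + rho * residual_fraction)`. The total force is
#' partitioned over the engaged pillars (a disk-shaped footprint) with
#' multiplicative log-normal heterogeneity, pointed at the cell centroid,
#' and mean-vector-balanced so the net traction is ~0 in every frame. A
#' zero-mean Gaussian band-limited oscillation (center `osc_center_freq`,
#' bandwidth 40% of center, amplitude set on the velocity-envelope scale by
#' `osc_amplitude`) is added radially per pillar. Deflections obey
#' `u_i = T_i / k` exactly.
#'
#' @param profile A [cohort_profile()].
#' @param lattice A [make_lattice()] lattice large enough to hold the cell
#'   footprint plus free pillars.
#' @param config A [sim_config()]. Randomness is taken from the current RNG
#'   state; seed at the cohort level (see [simulate_cohort()]).
#' @param center Cell centroid in lattice coordinates (um); default slightly
#'   off the lattice center so no pillar sits exactly at the centroid.
#' @return A list of class `cell_sim` with elements `deflections`
#'   (n_pillars x n_frames x 2 array, um, all pillars; free pillars stay at
#'   rest), `times` (min), `engaged` (logical per pillar), `force_true`
#'   (programmed global force G(t), nN), `cell` (drawn per-cell parameters:
#'   area, radius, center, F0, rho, t_peak), `lattice`, `config`.
#' @export
simulate_cell_force <- function(profile, lattice, config,
                                center = NULL) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(lattice, "pillar_lattice"),
            inherits(config, "sim_config"))
  if (profile$peak_increase < 0) stop("peak_increase must be >= 0")
  times <- config_times(config)
  t_stim <- config_stim_time(config)
  nfr <- length(times)
  rest <- lattice$rest_positions
  npil <- nrow(rest)
  sp <- lattice$spacing

  area <- rnorm_trunc(1, profile$cell_area_mean, profile$cell_area_sd,
                      lo = (3 * sp)^2)
  radius <- sqrt(area / pi)
  if (is.null(center)) {
    ctr <- c(mean(range(rest[, 1])), mean(range(rest[, 2]))) +
      c(0.23, 0.31) * sp
  } else ctr <- center

  dvec <- cbind(ctr[1] - rest[, 1], ctr[2] - rest[, 2])
  dist <- sqrt(rowSums(dvec^2))
  engaged <- dist <= radius
  if (!any(engaged)) stop("cell footprint engages no pillars")
  xr <- range(rest[, 1]); yr <- range(rest[, 2])
  if (ctr[1] - radius < xr[1] - sp / 2 || ctr[1] + radius > xr[2] + sp / 2 ||
      ctr[2] - radius < yr[1] - sp / 2 || ctr[2] + radius > yr[2] + sp / 2)
    stop("cell footprint extends outside the pillar lattice")

  ne <- sum(engaged)
  F0 <- max(1e-6, profile$force_area_intercept +
              profile$force_area_slope * area +
              stats::rnorm(1, 0, profile$force_sd))
  rho <- rnorm_trunc(1, profile$peak_increase,
                     profile$peak_increase_sd, lo = 0)
  post <- config$duration - t_stim
  lo_t <- 4 * config$dt
  hi_t <- post - 4 * config$dt
  tpk <- if (hi_t <= lo_t) post / 2     # recording too short to resolve
  else rnorm_trunc(1, profile$time_to_peak, profile$time_to_peak_sd,
                   lo = lo_t, hi = hi_t)

  G <- force_program(times, t_stim, F0, rho, tpk,
                     profile$relaxation_tau, profile$residual_fraction)

  # centripetal unit directions and heterogeneous force shares
  dirs <- dvec[engaged, , drop = FALSE] /
    pmax(dist[engaged], 1e-9)
  w <- stats::rlnorm(ne, 0, 0.3)
  w <- w / sum(w)

  # static force: T_i(t) = G(t) * w_i * dir_i, then mean-vector balance
  Tx <- outer(w * dirs[, 1], G)          # ne x nfr
  Ty <- outer(w * dirs[, 2], G)
  Tx <- sweep(Tx, 2, colMeans(Tx))
  Ty <- sweep(Ty, 2, colMeans(Ty))

  # oscillations: radial deflection noise in two bands (slow cohort band +
  # fast flicker filling the first intrinsic mode), each with the requested
  # velocity-envelope mean.  Rayleigh envelope mean = sigma * sqrt(pi/2);
  # velocity sigma of a narrowband process = 2*pi*fc * deflection sigma.
  band_series <- function(freq_mHz, amp) {
    fc <- freq_mHz * 0.06                # mHz -> cycles/min
    if (amp <= 0 || fc <= 0) return(rep(0, nfr))
    sig_d <- amp / (sqrt(pi / 2) * 2 * pi * fc)
    band_limited_noise(nfr, config$dt, fc, 0.4 * fc) * sig_d
  }
  osc <- t(vapply(seq_len(ne), function(i)
    band_series(profile$osc_center_freq, profile$osc_amplitude) +
      band_series(profile$fast_freq, profile$fast_amplitude),
    numeric(nfr)))
  # balance the oscillation field too, so the net traction stays ~0 in
  # every frame (common-mode removal, O(1/n) per pillar)
  ox <- osc * dirs[, 1]; oy <- osc * dirs[, 2]
  if (ne > 1) {
    ox <- sweep(ox, 2, colMeans(ox))
    oy <- sweep(oy, 2, colMeans(oy))
  }

  u <- array(0, dim = c(npil, nfr, 2))
  u[engaged, , 1] <- Tx / lattice$k + ox
  u[engaged, , 2] <- Ty / lattice$k + oy

  structure(list(deflections = u, times = times, engaged = engaged,
                 force_true = G, t_stim = t_stim,
                 cell = list(area = area, radius = radius, center = ctr,
                             F0 = F0, rho = rho, t_peak = tpk),
                 lattice = lattice, config = config),
            class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  cat(sprintf(
    "<cell_sim> %d pillars (%d engaged), %d frames; F0 %.3g nN, rho %.2f\n",
    dim(x$deflections)[1], sum(x$engaged), length(x$times),
    x$cell$F0, x$cell$rho))
  invisible(x)
}

#' Draw passive (unstimulated) cells of a cohort
#'
#' Samples per-cell spread area and baseline total traction force from the
#' cohort's static model (`F0 = intercept + slope * area + noise`), the
#' quantities behind force-vs-area regressions and passive-state group
#' comparisons, without simulating any dynamics.
#'
#' @inheritParams simulate_cell_force
#' @param n Number of cells.
#' @return data.frame with columns `area_um2`, `force_nN`, `cohort`.
#' @export
simulate_static_force <- function(profile, n) {
  stopifnot(inherits(profile, "cohort_profile"), n >= 1)
  area <- rnorm_trunc(n, profile$cell_area_mean, profile$cell_area_sd,
                      lo = 100)
  force <- pmax(1e-6, profile$force_area_intercept +
                  profile$force_area_slope * area +
                  stats::rnorm(n, 0, profile$force_sd))
  data.frame(area_um2 = area, force_nN = force, cohort = profile$name)
}

#' Size a lattice to hold one cell of a cohort
#'
#' Convenience constructor: a square lattice whose extent comfortably holds
#' the cohort's mean cell footprint (plus ~3 spacings of margin on each
#' side) so that well over 20% of pillars remain free for rest-lattice
#' registration.
#'
#' @inheritParams simulate_cell_force
#' @param spacing,diameter,height,youngs_modulus Lattice geometry passed to
#'   [make_lattice()].
#' @return A `pillar_lattice`.
#' @export
lattice_for_cohort <- function(profile, spacing = 4, diameter = 2,
                               height = 9, youngs_modulus = 0.6) {
  rmax <- sqrt((profile$cell_area_mean + 4 * profile$cell_area_sd) / pi)
  extent <- ceiling((2 * rmax + 6 * spacing) / spacing)
  make_lattice(spacing, diameter, height, youngs_modulus,
               extent = c(extent, extent))
}
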