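# Analytic signal, instantaneous amplitude/frequency, cohort spectra.

# analytic signal via FFT (standard one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# phase unwrapping (cumulative wrapped differences)
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1], phi[1] + cumsum(d))
}

#' Instantaneous amplitude and frequency of an IMF
#'
#' Hilbert--Huang step: the analytic signal of the chosen intrinsic mode
#' function gives the instantaneous amplitude `A(t)` (modulus) and, from
#' the unwrapped phase differentiated by central differences, the
#' instantaneous frequency `F(t)` in mHz. Samples with non-positive or
#' super-Nyquist frequency are masked (NA) rather than clamped -- they are
#' Hilbert edge artifacts -- and a 10% margin at each end of the series is
#' flagged for exclusion from summary statistics.
#'
#' @param imf Numeric series (one IMF), or an `imf_set` with `imf_index`.
#' @param dt Sample interval, min.
#' @param imf_index Which IMF to analyze when an `imf_set` is given
#'   (default 2, the mode with optimal noise reduction for 30-s-sampled
#'   pillar velocities).
#' @return An object of class `inst_spectrum`: `amplitude` (um/min),
#'   `frequency_mHz` (NA where masked), `interior` (logical: inside the
#'   10% edge margins), `dt`, `imf_index`.
#' @export
hilbert_instantaneous <- function(imf, dt, imf_index = 2L) {
  if (inherits(imf, "imf_set")) {
    if (imf_index > imf$n_imfs)
      stop(sprintf("IMF %d not available; decomposition has %d IMF(s)",
                   imf_index, imf$n_imfs))
    imf <- imf$imfs[, imf_index]
  }
  n <- length(imf)
  if (n < 16) stop("need at least 16 samples")
  z <- analytic_signal(imf)
  A <- Mod(z)
  phi <- unwrap_phase(Arg(z))
  f_cpm <- numeric(n)
  f_cpm[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) / (2 * dt) / (2 * pi)
  f_cpm[1] <- (phi[2] - phi[1]) / dt / (2 * pi)
  f_cpm[n] <- (phi[n] - phi[n - 1]) / dt / (2 * pi)
  f_mHz <- f_cpm / 0.06                       # cycles/min -> mHz
  nyq <- 1 / (2 * dt) / 0.06
  f_mHz[f_mHz <= 0 | f_mHz > nyq] <- NA_real_
  margin <- ceiling(0.1 * n)
  interior <- rep(TRUE, n)
  interior[c(seq_len(margin), (n - margin + 1L):n)] <- FALSE
  structure(list(amplitude = A, frequency_mHz = f_mHz,
                 interior = interior, dt = dt,
                 imf_index = as.integer(imf_index)),
            class = "inst_spectrum")
}

#' Per-cell instantaneous spectrum over engaged pillars
#'
#' Runs velocity -> EMD -> Hilbert on every engaged pillar of a cell and
#' averages: per-cell mean `A(t)` and `F(t)` curves (pointwise mean over
#' pillars), interior-time means, and the per-pillar maximum time-averaged
#' power. Instantaneous power per pillar is `p(t) = k |u(t)| A(t)`
#' (force x velocity-envelope), averaged in sliding windows of
#' `power_window` minutes; the per-pillar maximum window value is reported.
#'
#' @param maps A `force_maps`.
#' @param imf_index IMF used for the Hilbert spectrum (default 2).
#' @param power_window Sliding-window length for time-averaged power, min.
#' @param max_pillars Optional cap on the number of engaged pillars
#'   analyzed (random subsample; useful for quick estimates).
#' @return A list of class `cell_spectrum`: `A_t`, `F_t` (per-cell mean
#'   curves; F pointwise mean over unmasked pillars), `times`, `interior`,
#'   `mean_A`, `mean_F` (interior means), `max_power` (per-pillar max
#'   time-averaged power, nN um/min; cell mean), `n_pillars`.
#' @export
cell_spectrum <- function(maps, imf_index = 2L, power_window = 5,
                          max_pillars = NULL) {
  stopifnot(inherits(maps, "force_maps"))
  dt <- diff(maps$times[1:2])
  sel <- which(maps$engaged & !maps$excluded)
  if (!is.null(max_pillars) && length(sel) > max_pillars)
    sel <- sort(sample(sel, max_pillars))
  n <- ncol(maps$ux)
  Amat <- Fmat <- matrix(NA_real_, length(sel), n)
  pw <- numeric(length(sel))
  wlen <- max(1L, round(power_window / dt))
  interior <- NULL
  for (ii in seq_along(sel)) {
    p <- sel[ii]
    umag <- sqrt(maps$ux[p, ]^2 + maps$uy[p, ]^2)
    v <- pillar_velocity(umag, dt)
    dec <- emd_decompose(v)
    if (dec$n_imfs < imf_index) next
    sp <- hilbert_instantaneous(dec, dt, imf_index)
    Amat[ii, ] <- sp$amplitude
    Fmat[ii, ] <- sp$frequency_mHz
    interior <- sp$interior
    power <- maps$k * umag * sp$amplitude
    pw[ii] <- max(moving_average(power, wlen), na.rm = TRUE)
  }
  ok <- !is.na(Amat[, 1])
  if (!any(ok)) stop("no pillar yielded the requested IMF")
  A_t <- colMeans(Amat[ok, , drop = FALSE])
  F_t <- colMeans(Fmat[ok, , drop = FALSE], na.rm = TRUE)
  structure(list(A_t = A_t, F_t = F_t, times = maps$times,
                 interior = interior,
                 mean_A = mean(A_t[interior]),
                 mean_F = mean(F_t[interior], na.rm = TRUE),
                 max_power = mean(pw[ok]), n_pillars = sum(ok)),
            class = "cell_spectrum")
}

#' Cohort-level instantaneous spectrum and power
#'
#' Pointwise mean and SEM of per-cell `A(t)` and `F(t)` curves (cells on
#' different time bases are resampled to the first cell's base by linear
#' interpolation), plus cohort means of the interior-mean amplitude,
#' frequency, and per-pillar maximum time-averaged power.
#'
#' @param spectra List of `cell_spectrum` objects (>= 2 cells).
#' @return A list of class `cohort_spectrum`: `times`, `A_mean`, `A_sem`,
#'   `F_mean`, `F_sem`, `interior`, and scalars `mean_A`, `mean_F`,
#'   `max_power` (cohort means over cells).
#' @export
cohort_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 2,
            all(vapply(spectra, inherits, logical(1), "cell_spectrum")))
  base <- spectra[[1]]$times
  get_curve <- function(s, what) {
    if (isTRUE(all.equal(s$times, base))) return(s[[what]])
    stats::approx(s$times, s[[what]], xout = base, rule = 2)$y
  }
  Am <- t(vapply(spectra, get_curve, numeric(length(base)), "A_t"))
  Fm <- t(vapply(spectra, get_curve, numeric(length(base)), "F_t"))
  sem <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
  structure(list(times = base,
                 A_mean = colMeans(Am), A_sem = sem(Am),
                 F_mean = colMeans(Fm), F_sem = sem(Fm),
                 interior = spectra[[1]]$interior,
                 mean_A = mean(vapply(spectra, `[[`, numeric(1), "mean_A")),
                 mean_F = mean(vapply(spectra, `[[`, numeric(1), "mean_F")),
                 max_power = mean(vapply(spectra, `[[`, numeric(1),
                                         "max_power"))),
            class = "cohort_spectrum")
}
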