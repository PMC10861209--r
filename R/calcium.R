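# Calcium transient generation and quantification.

#' Simulate a Fluo-4-like calcium trace
#'
#' Normalized fluorescence (fold over the pre-stimulus level): 1 before the
#' stimulus, a fast half-cosine rise to `ca_peak` shortly after it, and an
#' exponential decay whose time constant is set so that the fraction of the
#' peak excess lost 15 min after stimulus equals `ca_recovery_15min`.
#' Multiplicative Gaussian noise is applied per sample.
#'
#' @param profile A [cohort_profile()] (`ca_peak` must exceed 1).
#' @param config A [sim_config()] (`ca_dt`, `ca_duration`, `ca_prestim`,
#'   `ca_noise_sd`).
#' @param rise_time Time from stimulus onset to peak, min.
#' @return An object of class `calcium_trace`: data.frame `t_min`,
#'   `f_norm`, plus `stim_time` and `cohort` attributes.
#' @export
simulate_calcium <- function(profile, config, rise_time = 1) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(config, "sim_config"))
  peak <- rnorm_trunc(1, profile$ca_peak, profile$ca_peak_sd, lo = 1.05)
  if (peak <= 1) stop("ca_peak must exceed 1")
  rec <- profile$ca_recovery_15min
  t <- seq(0, config$ca_duration, by = config$ca_dt)
  ts <- config$ca_prestim
  f <- rep(1, length(t))
  rise <- t >= ts & t < ts + rise_time
  f[rise] <- 1 + (peak - 1) * 0.5 * (1 - cos(pi * (t[rise] - ts) / rise_time))
  dec <- t >= ts + rise_time
  if (rec >= 1) {
    tau <- rise_time / 20                       # effectively instant return
  } else if (rec <= 0) {
    tau <- Inf
  } else {
    tau <- -(15 - rise_time) / log(1 - rec)
  }
  decay <- if (is.finite(tau)) exp(-(t[dec] - ts - rise_time) / tau) else 1
  f[dec] <- 1 + (peak - 1) * decay
  if (config$ca_noise_sd > 0)
    f <- f * (1 + stats::rnorm(length(f), 0, config$ca_noise_sd))
  structure(list(trace = data.frame(t_min = t, f_norm = f),
                 stim_time = ts, cohort = profile$name),
            class = "calcium_trace")
}

#' Quantify one calcium trace
#'
#' Renormalizes to the value at T = 0 if needed, picks the post-stimulus
#' peak on a 3-point median-smoothed trace, and computes the recovery
#' fraction at the horizon: `(peak - f(t_h)) / (peak - 1)`, clipped to
#' [0, 1], with `f(t_h)` by linear interpolation. The horizon is measured
#' from stimulus onset. A trace with no response (peak <= 1) yields
#' missing metrics.
#'
#' @param trace A `calcium_trace`, or a data.frame with columns `t_min`,
#'   `f_norm` (then `stim_time` must be given).
#' @param horizon Recovery horizon, min after stimulus (default 15).
#' @param stim_time Stimulus onset, min (taken from the object if present).
#' @return A list of class `calcium_metrics`: `peak`, `t_peak_min`,
#'   `recovery`, `f_horizon`.
#' @export
analyze_trace <- function(trace, horizon = 15, stim_time = NULL) {
  if (inherits(trace, "calcium_trace")) {
    stim_time <- trace$stim_time
    trace <- trace$trace
  }
  if (is.null(stim_time)) stop("stim_time required for raw traces")
  t <- trace$t_min; f <- trace$f_norm
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  f0 <- f[which.min(abs(t))]
  if (abs(f0 - 1) > 1e-9) f <- f / f0
  t_h <- stim_time + horizon
  if (max(t) < t_h) stop("trace does not span the recovery horizon")
  fs <- stats::runmed(f, 3)
  post <- which(t >= stim_time)
  ipk <- post[which.max(fs[post])]
  peak <- fs[ipk]
  if (peak <= 1)
    return(structure(list(peak = NA_real_, t_peak_min = NA_real_,
                          recovery = NA_real_, f_horizon = NA_real_),
                     class = "calcium_metrics"))
  f_h <- stats::approx(t, f, xout = t_h)$y
  rec <- min(max((peak - f_h) / (peak - 1), 0), 1)
  structure(list(peak = peak, t_peak_min = t[ipk] - stim_time,
                 recovery = rec, f_horizon = f_h),
            class = "calcium_metrics")
}

#' Cohort calcium time-courses and metric table
#'
#' Resamples all traces to the first trace's time base, returns the
#' pointwise mean and SEM per cohort plus per-trace metrics and cohort
#' metric means.
#'
#' @param traces List of `calcium_trace` objects (>= 2 per cohort).
#' @param horizon Recovery horizon, min after stimulus.
#' @return A list of class `cohort_calcium`: `curves` (data.frame cohort,
#'   t_min, mean, sem), `metrics` (per-trace data.frame cohort, peak,
#'   t_peak_min, recovery), `summary` (cohort means).
#' @export
cohort_calcium <- function(traces, horizon = 15) {
  stopifnot(length(traces) >= 2,
            all(vapply(traces, inherits, logical(1), "calcium_trace")))
  cohorts <- vapply(traces, `[[`, character(1), "cohort")
  if (any(table(cohorts) < 2)) stop("need >= 2 traces per cohort")
  base <- traces[[1]]$trace$t_min
  mat <- t(vapply(traces, function(tr)
    stats::approx(tr$trace$t_min, tr$trace$f_norm, xout = base,
                  rule = 2)$y, numeric(length(base))))
  curves <- do.call(rbind, lapply(unique(cohorts), function(co) {
    m <- mat[cohorts == co, , drop = FALSE]
    data.frame(cohort = co, t_min = base, mean = colMeans(m),
               sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
  }))
  met <- do.call(rbind, lapply(seq_along(traces), function(i) {
    m <- analyze_trace(traces[[i]], horizon)
    data.frame(cohort = cohorts[i], peak = m$peak,
               t_peak_min = m$t_peak_min, recovery = m$recovery)
  }))
  summ <- do.call(rbind, lapply(split(met, met$cohort), function(d)
    data.frame(cohort = d$cohort[1], n = nrow(d),
               peak = mean(d$peak, na.rm = TRUE),
               recovery = mean(d$recovery, na.rm = TRUE))))
  rownames(summ) <- NULL
  structure(list(curves = curves, metrics = met, summary = summ),
            class = "cohort_calcium")
}
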