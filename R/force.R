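# Deflection -> force maps, force metrics, strain energy.

# interpolate interior NA runs of length <= maxgap; returns NULL if an
# interior gap is longer (pillar should be excluded)
fill_gaps <- function(z, maxgap = 2L) {
  na <- is.na(z)
  if (!any(na)) return(z)
  r <- rle(na)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    s <- starts[seg]; e <- ends[seg]
    if (s == 1L || e == length(z)) return(NULL)     # edge gap
    if (r$lengths[seg] > maxgap) return(NULL)
    z[s:e] <- z[s - 1L] + (z[e + 1L] - z[s - 1L]) *
      (seq_len(e - s + 1L)) / (e - s + 2L)
  }
  z
}

#' Convert tracked centroids to per-pillar deflections and forces
#'
#' Deflection `u_i(t)` = detected position minus registered rest position;
#' traction force `T_i(t) = k u_i(t)` under the linear-spring pillar model.
#' Gaps of at most 2 consecutive missing frames are filled by linear
#' interpolation; pillars with longer gaps or flagged as ambiguous by the
#' tracker are excluded from all downstream metrics. The engaged (under
#' cell) set comes from a supplied cell mask when available, otherwise from
#' a robust rule: mean deflection magnitude above
#' `median + 3 * scaled MAD` over all pillars.
#'
#' @param tracks A `centroid_tracks`.
#' @param rest A `rest_lattice` from [register_rest_lattice()], or an
#'   n_pillars x 2 matrix of rest positions (um).
#' @param k Pillar spring constant, nN/um.
#' @param mask Optional cell-footprint raster (0/1 matrix, same image frame
#'   as the tracks) used with `mask_pixel_size` to set the engaged set and
#'   the cell area.
#' @param mask_pixel_size um/px of `mask`.
#' @param engaged Optional logical vector overriding the engaged rule.
#' @return An object of class `force_maps`: matrices `ux`, `uy`, `Tx`, `Ty`
#'   (n_pillars x n_frames; um and nN), `times`, logical `engaged` and
#'   `excluded`, `k`, `cell_area` (um^2; from the mask when given, else
#'   engaged pillar count x fitted spacing^2).
#' @export
deflection_to_force <- function(tracks, rest, k, mask = NULL,
                                mask_pixel_size = NULL, engaged = NULL) {
  stopifnot(inherits(tracks, "centroid_tracks"), k > 0)
  spacing <- NULL
  if (inherits(rest, "rest_lattice")) {
    spacing <- rest$spacing
    rest <- rest$rest
  }
  np <- nrow(tracks$x); nfr <- ncol(tracks$x)
  stopifnot(nrow(rest) == np)
  ux <- tracks$x - rest[, 1]
  uy <- tracks$y - rest[, 2]
  excluded <- tracks$ambiguous
  for (p in seq_len(np)) {
    if (excluded[p]) next
    zx <- fill_gaps(ux[p, ]); zy <- fill_gaps(uy[p, ])
    if (is.null(zx) || is.null(zy)) {
      excluded[p] <- TRUE
    } else {
      ux[p, ] <- zx; uy[p, ] <- zy
    }
  }
  umag_mean <- rowMeans(sqrt(ux^2 + uy^2))
  if (is.null(engaged)) {
    if (!is.null(mask)) {
      if (is.null(mask_pixel_size))
        stop("mask_pixel_size required with mask")
      iy <- pmin(pmax(round(rest[, 2] / mask_pixel_size) + 1L, 1L),
                 nrow(mask))
      ix <- pmin(pmax(round(rest[, 1] / mask_pixel_size) + 1L, 1L),
                 ncol(mask))
      engaged <- mask[cbind(iy, ix)] > 0
    } else {
      m <- umag_mean[!excluded]
      engaged <- umag_mean > stats::median(m) + 3 * stats::mad(m)
    }
  }
  cell_area <- if (!is.null(mask) && !is.null(mask_pixel_size))
    sum(mask > 0) * mask_pixel_size^2
  else if (!is.null(spacing)) sum(engaged & !excluded) * spacing^2
  else NA_real_
  structure(list(ux = ux, uy = uy, Tx = k * ux, Ty = k * uy,
                 times = tracks$times, engaged = engaged,
                 excluded = excluded, k = k, cell_area = cell_area),
            class = "force_maps")
}

#' Build force maps directly from a deflection array
#'
#' Bypasses detection/registration when ground-truth deflections are
#' available (e.g. straight from [simulate_cell_force()]).
#'
#' @param sim A `cell_sim`.
#' @return A `force_maps` object (exact Hooke forces `T = k u`).
#' @export
force_maps_from_sim <- function(sim) {
  stopifnot(inherits(sim, "cell_sim"))
  ux <- sim$deflections[, , 1]; uy <- sim$deflections[, , 2]
  k <- sim$lattice$k
  structure(list(ux = ux, uy = uy, Tx = k * ux, Ty = k * uy,
                 times = sim$times, engaged = sim$engaged,
                 excluded = rep(FALSE, nrow(ux)), k = k,
                 cell_area = sim$cell$area),
            class = "force_maps")
}

#' @export
print.force_maps <- function(x, ...) {
  cat(sprintf(
    "<force_maps> %d pillars (%d engaged, %d excluded) x %d frames, k=%.3g\n",
    nrow(x$ux), sum(x$engaged & !x$excluded), sum(x$excluded),
    ncol(x$ux), x$k))
  invisible(x)
}

# moving average, NA outside the fully-covered region
moving_average <- function(z, width) {
  if (width <= 1L) return(z)
  as.numeric(stats::filter(z, rep(1 / width, width), sides = 2))
}

# one-frame active/quiescent split of engaged |T| by the scaled-MAD rule;
# stats::mad already includes the 1.4826 normal-consistency constant
active_split <- function(tmag, two_sided = FALSE) {
  med <- stats::median(tmag)
  m <- stats::mad(tmag)
  if (m == 0) return(rep(FALSE, length(tmag)))    # degenerate rule
  if (two_sided) abs(tmag - med) > 3 * m else tmag > med + 3 * m
}

#' Static and dynamic force metrics of one cell
#'
#' Computes, per frame over engaged pillars: total force `sum |T_i|`, mean
#' force per pillar, the active/quiescent split (active = pillars whose
#' force magnitude exceeds the engaged median by more than three scaled
#' median absolute deviations, per frame), and strain energy
#' `E = 1/2 sum T_i . u_i`. The total-force trace is normalized to its
#' pre-stimulus baseline mean; the normalized peak and the time-to-peak
#' are read off a moving-average-smoothed trace (default 5 frames =
#' 2.5 min) restricted to post-stimulus frames.
#'
#' @param maps A `force_maps`.
#' @param stim_time Stimulus onset, min.
#' @param baseline_frames Frame indices of the baseline window; default all
#'   frames strictly before `stim_time`.
#' @param smooth_frames Moving-average width for peak detection, frames.
#' @param two_sided If TRUE the active rule also counts unusually low
#'   forces (deviation in either direction); default one-sided (high).
#' @return An object of class `force_metrics`: data.frame `trace` (frame,
#'   t_min, total_nN, normalized, smoothed, active_nN, quiescent_nN,
#'   energy_nNum), scalars `peak_normalized`, `time_to_peak_min` (NA when
#'   the trace has no post-stimulus rise), `baseline_nN`,
#'   `per_pillar_mean_nN`, `n_engaged`, `cell_area`, `stim_time`.
#' @export
force_metrics <- function(maps, stim_time, baseline_frames = NULL,
                          smooth_frames = 5L, two_sided = FALSE) {
  stopifnot(inherits(maps, "force_maps"))
  sel <- maps$engaged & !maps$excluded
  if (!any(sel)) stop("no engaged pillars")
  tmag <- sqrt(maps$Tx[sel, , drop = FALSE]^2 +
                 maps$Ty[sel, , drop = FALSE]^2)
  total <- colSums(tmag)
  active <- vapply(seq_along(total), function(t) {
    a <- active_split(tmag[, t], two_sided)
    sum(tmag[a, t])
  }, numeric(1))
  energy <- 0.5 * colSums(
    maps$Tx[sel, , drop = FALSE] * maps$ux[sel, , drop = FALSE] +
      maps$Ty[sel, , drop = FALSE] * maps$uy[sel, , drop = FALSE])

  times <- maps$times
  if (is.null(baseline_frames)) baseline_frames <- which(times < stim_time)
  if (!length(baseline_frames)) stop("baseline window is empty")
  if (any(times[baseline_frames] >= stim_time))
    stop("baseline window must be entirely pre-stimulus")
  base <- mean(total[baseline_frames])
  norm <- total / base
  sm <- moving_average(norm, smooth_frames)

  post <- which(times >= stim_time & !is.na(sm))
  if (stats::sd(norm) == 0 || !length(post)) {
    peak <- 1; tpk <- NA_real_
  } else {
    ipk <- post[which.max(sm[post])]
    peak <- sm[ipk]
    tpk <- times[ipk] - stim_time
  }
  structure(list(
    trace = data.frame(frame = seq_along(times), t_min = times,
                       total_nN = total, normalized = norm, smoothed = sm,
                       active_nN = active, quiescent_nN = total - active,
                       energy_nNum = energy),
    peak_normalized = peak, time_to_peak_min = tpk,
    baseline_nN = base, per_pillar_mean_nN = mean(total) / sum(sel),
    n_engaged = sum(sel), cell_area = maps$cell_area,
    stim_time = stim_time), class = "force_metrics")
}

#' @export
print.force_metrics <- function(x, ...) {
  cat(sprintf(
    "<force_metrics> baseline %.3g nN over %d pillars; peak %.3f, t_peak %s min\n",
    x$baseline_nN, x$n_engaged, x$peak_normalized,
    ifelse(is.na(x$time_to_peak_min), "NA",
           sprintf("%.1f", x$time_to_peak_min))))
  invisible(x)
}

#' Strain energy stored in deflected pillars
#'
#' `E = 1/2 sum_i T_i . u_i` over the pillars supplied; with `T = k u` this
#' equals `1/2 k sum |u_i|^2` and is always non-negative.
#'
#' @param T n x 2 matrix of force vectors, nN, or a `force_maps` object
#'   (then `u` is ignored and a per-frame energy vector over engaged
#'   pillars is returned).
#' @param u n x 2 matrix of deflection vectors, um.
#' @return Scalar energy (nN um), or a per-frame vector for `force_maps`.
#' @examples
#' strain_energy(rbind(c(3, 0), c(0, 4)), rbind(c(0.3, 0), c(0, 0.4)))
#' # 1.25 nN um
#' @export
strain_energy <- function(T, u = NULL) {
  if (inherits(T, "force_maps")) {
    sel <- T$engaged & !T$excluded
    return(0.5 * colSums(T$Tx[sel, , drop = FALSE] *
                           T$ux[sel, , drop = FALSE] +
                         T$Ty[sel, , drop = FALSE] *
                           T$uy[sel, , drop = FALSE]))
  }
  T <- rbind(T); u <- rbind(u)
  stopifnot(ncol(T) == 2, all(dim(T) == dim(u)))
  0.5 * sum(T * u)
}
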