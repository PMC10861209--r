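# Spot detection, sub-pixel refinement and frame-to-frame linking.

# sub-pixel refinement by separable 3-point parabolic interpolation of
# log intensity about the brightest pixel: exact for a Gaussian spot over
# a locally constant background.  img: raw matrix (0-based pixel-center
# coords), cx/cy: integer-ish initial centers (px), w: background window
# half-width; returns list(cx, cy)
refine_centroids <- function(img, cx, cy, w) {
  nx <- ncol(img); ny <- nrow(img)
  x0 <- pmin(pmax(round(cx), w), nx - 1L - w)
  y0 <- pmin(pmax(round(cy), w), ny - 1L - w)
  n <- length(x0)
  # local background: median of the window border
  bg <- vapply(seq_len(n), function(i) {
    xs <- (x0[i] - w):(x0[i] + w) + 1L
    ys <- (y0[i] - w):(y0[i] + w) + 1L
    win <- img[ys, xs]
    stats::median(c(win[1, ], win[2 * w + 1, ], win[, 1], win[, 2 * w + 1]))
  }, numeric(1))
  val <- function(dx, dy)
    pmax(img[cbind(y0 + dy + 1L, x0 + dx + 1L)] - bg, 1e-9)
  para <- function(vm, v0, vp) {
    den <- log(vm) - 2 * log(v0) + log(vp)
    d <- ifelse(abs(den) > 1e-12, 0.5 * (log(vm) - log(vp)) / den, 0)
    pmin(pmax(d, -1), 1)
  }
  list(cx = x0 + para(val(-1L, 0L), val(0L, 0L), val(1L, 0L)),
       cy = y0 + para(val(0L, -1L), val(0L, 0L), val(0L, 1L)))
}

# band-pass (difference of Gaussians) + 8-neighbour local maxima above a
# robust threshold; returns refined 0-based px centers
detect_spots_frame <- function(img, spacing_px, psf_sigma = 1) {
  eb <- EBImage::Image(img)
  lo <- EBImage::gblur(eb, sigma = max(0.75, psf_sigma / 2))
  hi <- EBImage::gblur(eb, sigma = spacing_px)
  dog <- EBImage::imageData(lo - hi)
  thr <- stats::median(dog) + 0.3 * (max(dog) - stats::median(dog))
  ny <- nrow(dog); nx <- ncol(dog)
  core <- dog[2:(ny - 1), 2:(nx - 1)]
  ismax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & core >= dog[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cy <- idx[, 1]; cx <- idx[, 2]          # already 0-based in full image
  # snap to the raw-image brightest pixel in a 3x3 neighbourhood, then
  # refine on the raw image (the band-pass is for detection only)
  ny2 <- nrow(img); nx2 <- ncol(img)
  for (i in seq_along(cx)) {
    xs <- max(1, cx[i] - 1):min(nx2 - 2, cx[i] + 1)
    ys <- max(1, cy[i] - 1):min(ny2 - 2, cy[i] + 1)
    win <- img[ys + 1, xs + 1, drop = FALSE]
    m <- which(win == max(win), arr.ind = TRUE)[1, ]
    cy[i] <- ys[m[1]]; cx[i] <- xs[m[2]]
  }
  w <- max(2L, floor(spacing_px / 2))
  refine_centroids(img, cx, cy, w)
}

#' Detect and track pillar tops in a fluorescence stack
#'
#' Per frame: band-pass filtering (difference of Gaussians), local-maximum
#' detection, and sub-pixel refinement by iterative intensity-weighted
#' centroid in a window of half-width `spacing/2`. Detections are linked
#' frame to frame by nearest neighbour with a maximum step of `spacing/4`;
#' a pillar with two link candidates within tolerance is flagged ambiguous,
#' one with no candidate is marked missing in that frame.
#'
#' @param stack ny x nx x n_frames array of counts, or a path to a
#'   multi-page TIFF (read via [read_stack()]).
#' @param spacing Lattice spacing hint, um.
#' @param pixel_size um per px.
#' @param times Optional frame times (min); default `0, dt, 2*dt, ...`.
#' @param dt Frame interval (min) used when `times` is NULL.
#' @param psf_sigma Expected spot sigma, px (detection band-pass scale).
#' @return An object of class `centroid_tracks`: matrices `x`, `y`
#'   (n_pillars x n_frames, um, image frame: pixel (0,0) center = 0 um),
#'   `times`, logical matrix `missing`, logical vector `ambiguous`.
#' @export
detect_and_track <- function(stack, spacing, pixel_size, times = NULL,
                             dt = 0.5, psf_sigma = 1) {
  if (is.character(stack)) stack <- read_stack(stack)
  nfr <- dim(stack)[3]
  if (is.na(nfr) || nfr < 2) stop("need at least 2 frames")
  if (is.null(times)) times <- (seq_len(nfr) - 1L) * dt
  spacing_px <- spacing / pixel_size
  if (spacing_px <= 4 * psf_sigma)
    warning("pillar spacing close to PSF size: spots may not be resolvable")
  det <- lapply(seq_len(nfr), function(t)
    detect_spots_frame(stack[, , t], spacing_px, psf_sigma))
  if (is.null(det[[1]]) || !length(det[[1]]$cx))
    stop("no spots detected in first frame")

  maxstep <- spacing_px / 4
  np <- length(det[[1]]$cx)
  X <- Y <- matrix(NA_real_, np, nfr)
  X[, 1] <- det[[1]]$cx; Y[, 1] <- det[[1]]$cy
  last_x <- X[, 1]; last_y <- Y[, 1]
  ambiguous <- rep(FALSE, np)
  for (t in 2:nfr) {
    d <- det[[t]]
    if (is.null(d) || !length(d$cx)) next
    for (p in seq_len(np)) {
      dd <- sqrt((d$cx - last_x[p])^2 + (d$cy - last_y[p])^2)
      cand <- which(dd <= maxstep)
      if (length(cand) == 1L) {
        X[p, t] <- d$cx[cand]; Y[p, t] <- d$cy[cand]
        last_x[p] <- d$cx[cand]; last_y[p] <- d$cy[cand]
      } else if (length(cand) > 1L) {
        ambiguous[p] <- TRUE
      }
    }
  }
  structure(list(x = X * pixel_size, y = Y * pixel_size, times = times,
                 missing = is.na(X), ambiguous = ambiguous,
                 pixel_size = pixel_size),
            class = "centroid_tracks")
}

#' Build a track set from a centroid table
#'
#' Accepts the centroid CSV schema written by the synthetic generator
#' (columns `frame`, `pillar_id`, `x_um`, `y_um`) as a data.frame or file
#' path, so pre-tracked data can enter the force pipeline directly.
#'
#' @param tab data.frame or CSV path with columns frame, pillar_id, x_um,
#'   y_um.
#' @param times Optional frame times (min); default `0, dt, ...`.
#' @param dt Frame interval, min.
#' @return A `centroid_tracks` object.
#' @export
tracks_from_table <- function(tab, times = NULL, dt = 0.5) {
  if (is.character(tab)) tab <- utils::read.csv(tab)
  stopifnot(all(c("frame", "pillar_id", "x_um", "y_um") %in% names(tab)))
  frames <- sort(unique(tab$frame))
  ids <- sort(unique(tab$pillar_id))
  nfr <- length(frames); np <- length(ids)
  X <- Y <- matrix(NA_real_, np, nfr)
  fi <- match(tab$frame, frames); pi_ <- match(tab$pillar_id, ids)
  X[cbind(pi_, fi)] <- tab$x_um
  Y[cbind(pi_, fi)] <- tab$y_um
  if (is.null(times)) times <- (frames - min(frames)) * dt
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(x = X, y = Y, times = times, missing = is.na(X),
                 ambiguous = rep(FALSE, np), pixel_size = NA_real_),
            class = "centroid_tracks")
}

#' @export
print.centroid_tracks <- function(x, ...) {
  cat(sprintf("<centroid_tracks> %d pillars x %d frames (%d ambiguous)\n",
              nrow(x$x), ncol(x$x), sum(x$ambiguous)))
  invisible(x)
}
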