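# Rest-lattice registration: fit an ideal regular grid to free pillars.

#' Register the rest lattice of a tracked pillar array
#'
#' Deflections are defined relative to each pillar's rest position, which is
#' not observed under the cell. The rest geometry is recovered by fitting an
#' ideal square lattice (translation + rotation + spacing) to the time-mean
#' positions of *free* pillars by least squares; every pillar's rest
#' position is then the fitted lattice node nearest its mean position.
#'
#' Free pillars are taken from `free` if supplied; otherwise they are the
#' pillars whose temporal displacement variance is below 3x the median
#' variance across pillars (cell-engaged pillars move, free ones only
#' jitter).
#'
#' @param tracks A `centroid_tracks`.
#' @param free Optional logical vector marking free (not under cell)
#'   pillars.
#' @return A list of class `rest_lattice`: `rest` (n_pillars x 2 matrix,
#'   um), `spacing`, `angle` (rad), `origin`, `residual_rms` (free-pillar
#'   fit residual, um), `free` (logical).
#' @export
register_rest_lattice <- function(tracks, free = NULL) {
  stopifnot(inherits(tracks, "centroid_tracks"))
  mx <- rowMeans(tracks$x, na.rm = TRUE)
  my <- rowMeans(tracks$y, na.rm = TRUE)
  np <- length(mx)
  if (is.null(free)) {
    v <- apply(tracks$x, 1, stats::var, na.rm = TRUE) +
      apply(tracks$y, 1, stats::var, na.rm = TRUE)
    v[is.na(v)] <- Inf
    free <- v < 3 * stats::median(v, na.rm = TRUE)
  }
  if (mean(free) < 0.2)
    stop("fewer than 20% of pillars are free: cannot register rest lattice")

  fx <- mx[free]; fy <- my[free]
  # initial spacing: median nearest-neighbour distance among free pillars
  nn <- vapply(seq_along(fx), function(i) {
    d <- sqrt((fx - fx[i])^2 + (fy - fy[i])^2)
    min(d[d > 0])
  }, numeric(1))
  s0 <- stats::median(nn)
  # initial angle (mod 90 deg) from nearest-neighbour vectors, via
  # 4-fold angle doubling
  ang <- vapply(seq_along(fx), function(i) {
    d <- sqrt((fx - fx[i])^2 + (fy - fy[i])^2)
    j <- which(d == min(d[d > 0]))[1]
    atan2(fy[j] - fy[i], fx[j] - fx[i])
  }, numeric(1))
  th0 <- Arg(mean(exp(4i * ang))) / 4

  fit_once <- function(th, s, px, py) {
    # integer indices in the rotated frame
    xr <- cos(th) * px + sin(th) * py
    yr <- -sin(th) * px + cos(th) * py
    i <- round((xr - min(xr)) / s)
    j <- round((yr - min(yr)) / s)
    # linear LS:  x = a*i - b*j + tx ;  y = b*i + a*j + ty
    A <- rbind(cbind(i, -j, 1, 0), cbind(j, i, 0, 1))
    rhs <- c(px, py)
    beta <- unname(stats::lm.fit(A, rhs)$coefficients)
    list(a = beta[1], b = beta[2], tx = beta[3], ty = beta[4], i = i, j = j)
  }
  f <- fit_once(th0, s0, fx, fy)
  s1 <- sqrt(f$a^2 + f$b^2); th1 <- atan2(f$b, f$a)
  f <- fit_once(th1, s1, fx, fy)
  a <- f$a; b <- f$b; tx <- f$tx; ty <- f$ty
  spacing <- sqrt(a^2 + b^2); angle <- atan2(b, a)

  node <- function(i, j) cbind(a * i - b * j + tx, b * i + a * j + ty)
  resid <- node(f$i, f$j) - cbind(fx, fy)
  rms <- sqrt(mean(rowSums(resid^2)))
  if (rms > spacing / 4)
    stop("lattice fit residual exceeds spacing/4: not a regular array")

  # indices (and rest nodes) for every pillar from the inverse transform
  inv <- function(x, y) {
    u <- x - tx; v <- y - ty
    cbind(round(( a * u + b * v) / spacing^2),
          round((-b * u + a * v) / spacing^2))
  }
  ij <- inv(mx, my)
  rest <- node(ij[, 1], ij[, 2])
  colnames(rest) <- c("x", "y")
  structure(list(rest = rest, spacing = spacing, angle = angle,
                 origin = c(tx, ty), residual_rms = rms, free = free),
            class = "rest_lattice")
}
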