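# Empirical mode decomposition by classical sifting.

#' Per-pillar deflection velocity
#'
#' Signed rate of change of the deflection magnitude, `v(t) =
#' d|u|/dt`, by central differences (one-sided at the endpoints). This is
#' the series the instantaneous force-frequency spectrum is built on: it is
#' near zero-mean over the oscillatory band while keeping the
#' contraction/relaxation sign.
#'
#' @param umag Numeric vector `|u|(t)` (um), or a `force_maps` object
#'   (then a matrix of velocities for engaged pillars is returned, one row
#'   per pillar).
#' @param dt Frame interval, min.
#' @return Velocity in um/min: vector, or matrix with attribute
#'   `pillar_id` for `force_maps` input.
#' @export
pillar_velocity <- function(umag, dt) {
  if (inherits(umag, "force_maps")) {
    sel <- which(umag$engaged & !umag$excluded)
    m <- sqrt(umag$ux[sel, , drop = FALSE]^2 +
                umag$uy[sel, , drop = FALSE]^2)
    v <- t(apply(m, 1, pillar_velocity, dt = dt))
    attr(v, "pillar_id") <- sel
    return(v)
  }
  n <- length(umag)
  if (n < 16) stop("need at least 16 frames for velocity/EMD analysis")
  v <- numeric(n)
  v[2:(n - 1)] <- (umag[3:n] - umag[1:(n - 2)]) / (2 * dt)
  v[1] <- (umag[2] - umag[1]) / dt
  v[n] <- (umag[n] - umag[n - 1]) / dt
  v
}

# indices of strict-or-plateau local maxima/minima of z
local_extrema <- function(z) {
  n <- length(z)
  dz <- diff(z)
  s <- sign(dz)
  # collapse zero slopes to the previous non-zero sign (plateau handling)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0) + 1L
  list(max = idx[s[idx - 1L] > 0], min = idx[s[idx - 1L] < 0])
}

# cubic-spline envelope through extrema with mirror extension of next
# `next_n` extrema beyond each boundary
envelope <- function(z, idx, next_n = 2L) {
  n <- length(z)
  if (length(idx) < 2) return(NULL)
  k <- min(next_n, length(idx))
  # mirror extrema about the series ends
  xl <- 2 * 1 - rev(idx[seq_len(k)])
  xr <- 2 * n - rev(idx)[seq_len(k)]
  xs <- c(xl, idx, rev(xr))
  ys <- c(z[rev(idx[seq_len(k)])], z[idx], z[rev(rev(idx)[seq_len(k)])])
  o <- order(xs)
  f <- stats::splinefun(xs[o], ys[o], method = "fmm")
  f(seq_len(n))
}

#' Empirical mode decomposition
#'
#' Classical EMD by envelope-mean sifting: cubic-spline upper and lower
#' envelopes through local maxima/minima (with mirror extension of two
#' extrema at each boundary), subtract the envelope mean, repeat until the
#' Cauchy standard-deviation criterion falls below `stop_sd`, extract the
#' intrinsic mode function (IMF), and continue on the remainder until the
#' residue is monotone or `max_imfs` is reached. The decomposition is
#' complete: IMFs + residue reconstruct the input to machine precision.
#'
#' @param x Numeric series (finite, non-constant for a useful result).
#' @param max_imfs Maximum number of IMFs.
#' @param stop_sd Cauchy sifting stop criterion (default 0.2).
#' @param max_sift Maximum sifting iterations per IMF.
#' @return An object of class `imf_set`: `imfs` (matrix, one column per
#'   IMF; zero columns if the input has too few extrema), `residue`,
#'   `n_imfs`, `sift_counts`.
#' @export
emd_decompose <- function(x, max_imfs = 8L, stop_sd = 0.2, max_sift = 50L) {
  stopifnot(all(is.finite(x)))
  n <- length(x)
  imfs <- NULL
  sift_counts <- integer(0)
  r <- x
  for (m in seq_len(max_imfs)) {
    ex <- local_extrema(r)
    if (length(ex$max) + length(ex$min) < 2) break   # monotone residue
    h <- r
    count <- 0L
    repeat {
      ex <- local_extrema(h)
      if (length(ex$max) < 2 || length(ex$min) < 2) break
      up <- envelope(h, ex$max)
      lo <- envelope(h, ex$min)
      if (is.null(up) || is.null(lo)) break
      mean_env <- (up + lo) / 2
      h1 <- h - mean_env
      count <- count + 1L
      sd_crit <- sum((h - h1)^2) / max(sum(h^2), .Machine$double.xmin)
      h <- h1
      # stop on the Cauchy criterion once h satisfies the mode condition
      # (extrema and zero-crossing counts differing by at most one)
      n_ext <- sum(diff(sign(diff(h))) != 0)
      n_zc <- sum(abs(diff(sign(h))) > 0)
      if ((sd_crit < stop_sd && abs(n_ext - n_zc) <= 1) ||
          count >= max_sift) break
    }
    if (count == 0L) break
    imfs <- cbind(imfs, h)
    sift_counts <- c(sift_counts, count)
    r <- r - h
  }
  if (is.null(imfs)) imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs)))
  structure(list(imfs = imfs, residue = r, n_imfs = ncol(imfs),
                 sift_counts = sift_counts),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples (sifts: %s)\n",
              x$n_imfs, length(x$residue),
              paste(x$sift_counts, collapse = ", ")))
  invisible(x)
}

#' IMF orthogonality index
#'
#' Huang's index of orthogonality: sum over IMF pairs of cross-energy over
#' total energy. Small values (< 0.1) indicate a clean decomposition.
#'
#' @param dec An `imf_set`.
#' @return Scalar index.
#' @export
orthogonality_index <- function(dec) {
  stopifnot(inherits(dec, "imf_set"))
  comp <- cbind(dec$imfs, dec$residue)
  tot <- sum(rowSums(comp)^2)
  io <- 0
  m <- ncol(comp)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    io <- io + abs(sum(comp[, i] * comp[, j]))
  2 * io / tot
}
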