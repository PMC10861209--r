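# Synthetic actin-texture images with controllable orientation dispersion.

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

# sample axial fiber orientations in [0, pi): von Mises on doubled angles
sample_fiber_angles <- function(n, axis, kappa) {
  phi <- rvonmises(n, 2 * axis, kappa)
  (phi / 2) %% pi
}

#' Render a synthetic actin (stress-fiber) image
#'
#' Draws anti-aliased fluorescent line segments inside an elliptical cell
#' mask. Fiber orientations follow an axial von Mises law with
#' concentration `orientation_kappa` about a random cell axis (kappa = 0:
#' isotropic; large kappa: parallel bundles). The fiber intensity is scaled
#' so the masked mean equals the per-cell intensity drawn from the
#' profile's `actin_intensity_mean`/`_sd`; a constant background plus
#' Gaussian noise is added.
#'
#' @param profile A [cohort_profile()].
#' @param config A [sim_config()] (`image_noise_sd` is reused as the actin
#'   image noise, a.u.).
#' @param size Image side, px.
#' @param pixel_size um/px.
#' @param fiber_density Fibers per 100 um^2 of cell area.
#' @param background Background level, a.u.
#' @return A list of class `actin_render`: `image` (size x size matrix,
#'   a.u.), `mask` (0/1 matrix), `intensity_true` (the per-cell target
#'   masked mean), `axis` (cell axis, rad), `background`.
#' @export
render_actin_image <- function(profile, config, size = 192L,
                               pixel_size = 0.5, fiber_density = 10,
                               background = 20) {
  stopifnot(inherits(profile, "cohort_profile"))
  if (profile$orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  intensity <- rnorm_trunc(1, profile$actin_intensity_mean,
                           profile$actin_intensity_sd, lo = 1)
  area <- rnorm_trunc(1, profile$cell_area_mean, profile$cell_area_sd,
                      lo = 100)
  # elliptical footprint, aspect 2:1, clipped to the frame
  half <- size / 2
  a_um <- sqrt(2 * area / pi); b_um <- area / (pi * a_um)
  a_px <- min(a_um / pixel_size, 0.45 * size)
  b_px <- min(b_um / pixel_size, 0.45 * size)
  axis <- stats::runif(1, 0, pi)
  ca <- cos(axis); sa <- sin(axis)
  xg <- matrix(rep(seq_len(size) - half, each = size), size)
  yg <- matrix(rep(seq_len(size) - half, times = size), size)
  xr <- ca * xg + sa * yg; yr <- -sa * xg + ca * yg
  mask <- (xr / a_px)^2 + (yr / b_px)^2 <= 1

  n_fib <- max(10L, round(fiber_density * area / 100))
  ang <- sample_fiber_angles(n_fib, axis, profile$orientation_kappa)
  img <- matrix(0, size, size)
  inside <- which(mask, arr.ind = TRUE)
  starts <- inside[sample.int(nrow(inside), n_fib, replace = TRUE), ,
                   drop = FALSE]
  len_px <- 0.35 * min(a_px, 2 * b_px)
  sig <- 1                                     # fiber cross-section, px
  for (i in seq_len(n_fib)) {
    # sample points along the segment, splat a small Gaussian at each
    L <- len_px * stats::runif(1, 0.6, 1.4)
    tseq <- seq(-L / 2, L / 2, by = 0.5)
    cxs <- starts[i, 2] + cos(ang[i]) * tseq
    cys <- starts[i, 1] + sin(ang[i]) * tseq
    keep <- cxs >= 3 & cxs <= size - 2 & cys >= 3 & cys <= size - 2
    for (p in which(keep)) {
      x0 <- round(cxs[p]); y0 <- round(cys[p])
      xs <- (x0 - 2):(x0 + 2); ys <- (y0 - 2):(y0 + 2)
      g <- outer(exp(-(ys - cys[p])^2 / (2 * sig^2)),
                 exp(-(xs - cxs[p])^2 / (2 * sig^2)))
      img[ys, xs] <- img[ys, xs] + g
    }
  }
  img[!mask] <- 0
  m <- mean(img[mask])
  if (m > 0) img <- img * intensity / m
  img <- img + background
  if (config$image_noise_sd > 0)
    img <- img + matrix(stats::rnorm(size^2, 0, config$image_noise_sd),
                        size, size)
  img <- pmax(img, 0)
  structure(list(image = img, mask = mask * 1,
                 intensity_true = intensity, axis = axis,
                 background = background),
            class = "actin_render")
}
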