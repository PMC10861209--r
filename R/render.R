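# Rendering of pillar-top fluorescence movies from simulated deflections.

# render all spots of one frame into a ny x nx matrix (0-based px centers)
render_spots <- function(ny, nx, cx, cy, amp, sig, w, background) {
  img <- matrix(background, ny, nx)
  for (i in seq_along(cx)) {
    x0 <- round(cx[i]); y0 <- round(cy[i])
    xs <- max(0, x0 - w):min(nx - 1, x0 + w)
    ys <- max(0, y0 - w):min(ny - 1, y0 + w)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - cx[i])^2 / (2 * sig^2))
    gy <- exp(-(ys - cy[i])^2 / (2 * sig^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * outer(gy, gx)
  }
  img
}

#' Render a pillar-top fluorescence stack from simulated deflections
#'
#' Draws every pillar as a diffraction-limited Gaussian spot at its rest +
#' deflected position, adds per-frame localization jitter and additive
#' Gaussian camera noise, and returns both the uint16 image stack and the
#' ground-truth sub-pixel spot centers per frame (the jittered positions
#' actually rendered). Image coordinates: origin at the top-left pixel
#' center, x rightward, y downward, 0-based pixel centers, `pixel_size`
#' um/px.
#'
#' @param sim A `cell_sim` from [simulate_cell_force()].
#' @param config A [sim_config()]; `psf_sigma` must be >= 0.5 px.
#' @param amplitude Peak spot intensity above background, counts.
#' @param background Constant background level, counts.
#' @return A list of class `pillar_render`: `frames` (ny x nx x n_frames
#'   array of uint16 counts), `truth` (data.frame frame, pillar_id, x_um,
#'   y_um), `mask` (ny x nx 0/1 cell-footprint matrix), `origin_um`
#'   (um position of pixel (0,0) in lattice coordinates), `pixel_size`,
#'   `times`.
#' @export
render_frames <- function(sim, config = sim$config,
                          amplitude = 3000, background = 100) {
  stopifnot(inherits(sim, "cell_sim"))
  if (config$psf_sigma < 0.5) stop("psf_sigma must be >= 0.5 px")
  if (!all(is.finite(sim$deflections))) stop("deflections must be finite")
  lat <- sim$lattice
  sp <- lat$spacing
  maxdef <- sqrt(max(sim$deflections[, , 1]^2 + sim$deflections[, , 2]^2))
  if (maxdef > sp / 2)
    warning("deflection exceeds spacing/2: pillar collision regime")
  px <- config$pixel_size
  margin <- 2 * sp
  origin <- c(min(lat$rest_positions[, 1]) - margin,
              min(lat$rest_positions[, 2]) - margin)
  nx <- ceiling((diff(range(lat$rest_positions[, 1])) + 2 * margin) / px) + 1L
  ny <- ceiling((diff(range(lat$rest_positions[, 2])) + 2 * margin) / px) + 1L
  nfr <- length(sim$times)
  npil <- nrow(lat$rest_positions)
  w <- ceiling(4 * config$psf_sigma)

  frames <- array(0, dim = c(ny, nx, nfr))
  truth <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    pos <- lat$rest_positions + sim$deflections[, t, ]
    if (config$jitter_sd > 0)
      pos <- pos + matrix(stats::rnorm(2L * npil, 0, config$jitter_sd),
                          npil, 2L)
    cx <- (pos[, 1] - origin[1]) / px
    cy <- (pos[, 2] - origin[2]) / px
    img <- render_spots(ny, nx, cx, cy, amplitude, config$psf_sigma, w,
                        background)
    if (config$image_noise_sd > 0)
      img <- img + matrix(stats::rnorm(ny * nx, 0, config$image_noise_sd),
                          ny, nx)
    frames[, , t] <- pmin(pmax(round(img), 0), 65535)
    truth[[t]] <- data.frame(frame = t, pillar_id = seq_len(npil),
                             x_um = pos[, 1], y_um = pos[, 2])
  }

  # rasterized cell footprint (0/1)
  xs <- origin[1] + (seq_len(nx) - 1L) * px
  ys <- origin[2] + (seq_len(ny) - 1L) * px
  mask <- outer(ys, xs, function(y, x)
    as.numeric((x - sim$cell$center[1])^2 + (y - sim$cell$center[2])^2 <=
                 sim$cell$radius^2))

  structure(list(frames = frames, truth = do.call(rbind, truth),
                 mask = mask, origin_um = origin, pixel_size = px,
                 times = sim$times),
            class = "pillar_render")
}

#' Write a rendered stack, mask and truth table to disk
#'
#' Writes `stack.tif` (multi-page uint16), `mask.tif` (single-page 0/1) and
#' `truth.csv` (frame, pillar_id, x_um, y_um) into `dir`.
#'
#' @param render A `pillar_render`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_render <- function(render, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nfr <- dim(render$frames)[3]
  pages <- lapply(seq_len(nfr), function(t) render$frames[, , t] / 65535)
  paths <- c(stack = file.path(dir, "stack.tif"),
             mask = file.path(dir, "mask.tif"),
             truth = file.path(dir, "truth.csv"))
  tiff::writeTIFF(pages, paths["stack"], bits.per.sample = 16L)
  tiff::writeTIFF(render$mask, paths["mask"], bits.per.sample = 8L)
  utils::write.csv(render$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a multi-page TIFF stack into an array of counts
#'
#' @param path TIFF file path.
#' @param bits Bit depth used when the file was written (values are
#'   rescaled back to integer counts).
#' @return ny x nx x n_frames numeric array.
#' @export
read_stack <- function(path, bits = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * (2^bits - 1)
  arr
}
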