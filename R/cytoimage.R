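# Fluorescence intensity quantification and actin orientation dispersion.

#' Background-subtracted masked intensity, with group normalization
#'
#' Per-cell marker intensity: mean of the masked pixels minus the
#' background (median of the pixels outside the mask unless a constant is
#' supplied), floored at 0. When a vector of reference-group per-cell
#' values is supplied the result is also expressed relative to the
#' reference-group mean (reference mean = 1 by construction). The ratio of
#' two `intensity_result`s for the same cell (e.g. alpha-SMA over
#' gamma-SMA) is the cytoskeletal "stiffening index".
#'
#' @param image Numeric matrix (a.u.) or TIFF path.
#' @param mask 0/1 matrix (nonempty) or TIFF path.
#' @param background Constant background estimate; default median outside
#'   the mask.
#' @param reference Optional numeric vector of per-cell values of the
#'   reference group for normalization.
#' @param marker Marker label carried through.
#' @return A list of class `intensity_result`: `mean` (background
#'   subtracted, a.u.), `normalized` (or NA), `background`, `marker`.
#' @export
quantify_intensity <- function(image, mask, background = NULL,
                               reference = NULL, marker = "marker") {
  if (is.character(image)) image <- tiff::readTIFF(image)
  if (is.character(mask)) mask <- tiff::readTIFF(mask)
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  if (is.null(background))
    background <- if (all(mask)) 0 else stats::median(image[!mask])
  raw <- mean(image[mask])
  val <- raw - background
  if (val < 0) {
    warning("background exceeds masked mean; intensity floored at 0")
    val <- 0
  }
  norm <- if (!is.null(reference)) val / mean(reference) else NA_real_
  structure(list(mean = val, normalized = norm, background = background,
                 marker = marker),
            class = "intensity_result")
}

#' Local fiber orientation by the structure tensor
#'
#' Gaussian-derivative gradients, tensor smoothing at `tensor_sigma`, and
#' the eigen-decomposition in closed form: the fiber direction is
#' orthogonal to the dominant gradient direction,
#' `theta = (1/2) atan2(2 Jxy, Jxx - Jyy) + pi/2 (mod pi)`, with coherence
#' `(l1 - l2)/(l1 + l2)` in [0, 1]. Pixels with negligible gradient energy
#' are masked out.
#'
#' @param image Numeric matrix (>= 32 x 32) or TIFF path.
#' @param gradient_sigma Derivative scale, px.
#' @param tensor_sigma Tensor smoothing scale, px.
#' @param energy_floor Fraction of the maximum tensor trace below which a
#'   pixel is masked.
#' @return A list of class `orientation_field`: `theta` (rad in [0, pi)),
#'   `coherence`, `energy` (tensor trace), `valid` (logical matrix).
#' @export
orientation_field <- function(image, gradient_sigma = 1, tensor_sigma = 4,
                              energy_floor = 1e-4) {
  if (is.character(image)) image <- tiff::readTIFF(image)
  if (nrow(image) < 32 || ncol(image) < 32) stop("image must be >= 32x32")
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(image),
                                          sigma = gradient_sigma))
  ny <- nrow(sm); nx <- ncol(sm)
  gx <- gy <- matrix(0, ny, nx)
  gy[2:(ny - 1), ] <- (sm[3:ny, ] - sm[1:(ny - 2), ]) / 2
  gx[, 2:(nx - 1)] <- (sm[, 3:nx] - sm[, 1:(nx - 2)]) / 2
  blur <- function(m) EBImage::imageData(
    EBImage::gblur(EBImage::Image(m), sigma = tensor_sigma))
  Jxx <- blur(gx * gx); Jyy <- blur(gy * gy); Jxy <- blur(gx * gy)
  energy <- Jxx + Jyy
  valid <- energy > energy_floor * max(energy)
  # dominant gradient orientation; fiber is orthogonal
  theta <- (0.5 * atan2(2 * Jxy, Jxx - Jyy) + pi / 2) %% pi
  disc <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  coherence <- ifelse(energy > 0, disc / (energy + 1e-12), 0)
  structure(list(theta = theta, coherence = coherence, energy = energy,
                 valid = valid),
            class = "orientation_field")
}

#' Actin deviation: orientation dispersion in square tiles
#'
#' The image is partitioned into non-overlapping square tiles; tiles whose
#' mean gradient energy is below `min_energy_frac` of the maximum tile
#' energy are dropped. Per retained tile the deviation is `1 - R`, where
#' `R = |mean exp(2 i theta)|` is the axial resultant length of the pixel
#' orientations (0 = perfectly parallel fibers, -> 1 = isotropic). The
#' cell-level value is the mean over retained tiles.
#'
#' @param field An `orientation_field`.
#' @param tile Tile side, px (>= 8).
#' @param min_energy_frac Minimum tile mean energy as a fraction of the
#'   maximum tile energy.
#' @return A list of class `actin_deviation`: `tile_values` (numeric),
#'   `mean` (NA if no tile retained), `n_tiles`.
#' @export
actin_deviation <- function(field, tile = 16L, min_energy_frac = 0.1) {
  stopifnot(inherits(field, "orientation_field"))
  if (tile < 8) stop("tile must be >= 8 px")
  ny <- nrow(field$theta); nx <- ncol(field$theta)
  ti <- seq(1, ny - tile + 1, by = tile)
  tj <- seq(1, nx - tile + 1, by = tile)
  en <- outer(ti, tj, Vectorize(function(i, j)
    mean(field$energy[i:(i + tile - 1), j:(j + tile - 1)])))
  keep <- which(en >= min_energy_frac * max(en), arr.ind = TRUE)
  if (!nrow(keep))
    return(structure(list(tile_values = numeric(0), mean = NA_real_,
                          n_tiles = 0L), class = "actin_deviation"))
  vals <- apply(keep, 1, function(idx) {
    i <- ti[idx[1]]; j <- tj[idx[2]]
    th <- field$theta[i:(i + tile - 1), j:(j + tile - 1)]
    vv <- field$valid[i:(i + tile - 1), j:(j + tile - 1)]
    if (!any(vv)) return(NA_real_)
    1 - Mod(mean(exp(2i * th[vv])))
  })
  vals <- vals[!is.na(vals)]
  structure(list(tile_values = vals, mean = mean(vals),
                 n_tiles = length(vals)),
            class = "actin_deviation")
}
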