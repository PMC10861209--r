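#' Construct a micropillar lattice
#'
#' Defines the rest geometry and stiffness of a square PDMS micropillar
#' array. The bending stiffness of a cylindrical pillar of diameter `d`,
#' height `L` and Young's modulus `E` follows Euler--Bernoulli beam theory,
#'
#' \deqn{k = \frac{3 \pi E d^4}{64 L^3},}
#'
#' the standard small-deflection model for micropillar traction force
#' microscopy. The traction force a cell exerts on a pillar tip is then
#' `T = k * u` for tip deflection `u`.
#'
#' @param spacing Center-to-center pillar spacing, um. Must exceed `diameter`.
#' @param diameter Pillar diameter, um.
#' @param height Pillar height, um.
#' @param youngs_modulus Young's modulus of the pillar material, MPa.
#' @param extent Integer vector of length 1 or 2: number of pillars along
#'   x and y.
#' @return An object of class `pillar_lattice`: a list with the geometry
#'   arguments, the derived spring constant `k` (nN/um) and a two-column
#'   matrix `rest_positions` of pillar centers (um, x rightward, y downward,
#'   origin at the first pillar).
#' @examples
#' lat <- make_lattice(4, 2, 9, 0.6, extent = c(10, 10))
#' lat$k  # ~1.94 nN/um
#' @export
make_lattice <- function(spacing, diameter, height, youngs_modulus,
                         extent = c(16L, 16L)) {
  if (length(extent) == 1L) extent <- rep(extent, 2L)
  ok <- all(c(spacing, diameter, height, youngs_modulus, extent) > 0)
  if (!ok) stop("all lattice parameters must be positive")
  if (spacing <= diameter)
    stop("pillar spacing must exceed pillar diameter")
  # k in nN/um: E [MPa = N/m^2 * 1e6], d,L [um].  With lengths in um and
  # E in MPa, 3*pi*E*d^4/(64*L^3) comes out in uN/um; multiply by 1e3.
  k <- 3 * pi * youngs_modulus * diameter^4 / (64 * height^3) * 1e3
  ij <- expand.grid(i = seq_len(extent[1]) - 1L, j = seq_len(extent[2]) - 1L)
  rest <- cbind(x = ij$i * spacing, y = ij$j * spacing)
  structure(
    list(spacing = spacing, diameter = diameter, height = height,
         youngs_modulus = youngs_modulus, k = k,
         extent = as.integer(extent), rest_positions = rest),
    class = "pillar_lattice")
}

#' @export
print.pillar_lattice <- function(x, ...) {
  cat(sprintf(
    "<pillar_lattice> %d x %d pillars, spacing %.3g um, d %.3g um, L %.3g um\n",
    x$extent[1], x$extent[2], x$spacing, x$diameter, x$height))
  cat(sprintf("  E = %.3g MPa, k = %.4g nN/um\n", x$youngs_modulus, x$k))
  invisible(x)
}
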