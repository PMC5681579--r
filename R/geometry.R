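#' Funiculus geometry
#'
#' Describes the physical dimensions of the funiculus (third antennal
#' segment) and the layout of the EAG recording electrodes along its
#' proximo-distal axis. Position 0 is adjacent to the base of the arista,
#' position 1 is the funiculus tip; electrodes sit on the lateral face at
#' the medial (mid-circumference) axis. These dimensions define the
#' unfolded-surface rectangles used as current-source supports by
#' [compartmentize()] and [forward_matrix()].
#'
#' @param length_mm Proximo-distal extent of the funiculus (arista base to
#'   tip), in mm.
#' @param width_mm,thickness_mm Cross-section axes of the funiculus, in mm.
#'   The cross-section is modelled as an ellipse with these diameters.
#' @param n_positions Number of electrode positions (default 4).
#' @param positions_norm Electrode coordinates on `[0, 1]` along the
#'   proximo-distal axis; must be strictly increasing with first 0 and
#'   last 1. Defaults to `n_positions` regularly interleaved positions
#'   (`0, 1/3, 2/3, 1` for the default layout).
#' @param sigma Surface conductivity scalar (default 10). All barycenters
#'   and response-area ratios are invariant to its value; it only scales
#'   the source units.
#' @param species Optional species label carried through outputs.
#'
#' @return An object of class `funiculus_geometry` (a named list).
#' @examples
#' geom <- funiculus_geometry(length_mm = 0.6, width_mm = 0.3,
#'                            thickness_mm = 0.25, species = "Zcuc")
#' compartmentize(geom)
#' @export
funiculus_geometry <- function(length_mm, width_mm, thickness_mm,
                               n_positions = 4L,
                               positions_norm = NULL,
                               sigma = 10,
                               species = NULL) {
  check_scalar_positive(length_mm, "length_mm")
  check_scalar_positive(width_mm, "width_mm")
  check_scalar_positive(thickness_mm, "thickness_mm")
  check_scalar_positive(sigma, "sigma")
  if (length(n_positions) != 1L || n_positions < 2L) {
    stop_validation("`n_positions` must be a single integer >= 2.")
  }
  n_positions <- as.integer(n_positions)
  if (is.null(positions_norm)) {
    positions_norm <- seq(0, 1, length.out = n_positions)
  }
  positions_norm <- as.numeric(positions_norm)
  if (length(positions_norm) != n_positions) {
    stop_validation("`positions_norm` must have length `n_positions` (%d).",
                    n_positions)
  }
  if (any(diff(positions_norm) <= 0)) {
    stop_validation("`positions_norm` must be strictly increasing.")
  }
  if (abs(positions_norm[1L]) > 1e-12 ||
      abs(positions_norm[n_positions] - 1) > 1e-12) {
    stop_validation("`positions_norm` must start at 0 and end at 1.")
  }
  structure(
    list(
      length_mm = length_mm,
      width_mm = width_mm,
      thickness_mm = thickness_mm,
      n_positions = n_positions,
      positions_norm = positions_norm,
      sigma = sigma,
      species = species
    ),
    class = "funiculus_geometry"
  )
}

#' @export
print.funiculus_geometry <- function(x, ...) {
  cat("<funiculus_geometry>",
      if (!is.null(x$species)) paste0(" ", x$species), "\n", sep = "")
  cat(sprintf("  length %g mm, width %g mm, thickness %g mm\n",
              x$length_mm, x$width_mm, x$thickness_mm))
  cat(sprintf("  %d electrode positions at {%s} (normalized), sigma = %g\n",
              x$n_positions,
              paste(signif(x$positions_norm, 4), collapse = ", "),
              x$sigma))
  invisible(x)
}

#' Ramanujan approximation for the circumference of an ellipse
#'
#' First Ramanujan approximation,
#' \eqn{\pi (3(a+b) - \sqrt{(3a+b)(a+3b)})}, used to estimate the
#' circumference of the elliptical funiculus cross-section from its two
#' semi-axes. Exact for circles; relative error below 1e-3 for aspect
#' ratios down to 0.2.
#'
#' @param a,b Semi-axes in mm (vectorized, recycled).
#' @return Circumference in mm.
#' @examples
#' ellipse_circumference(1, 1)   # 2*pi
#' ellipse_circumference(2, 1)   # pi * (9 - sqrt(35))
#' @export
ellipse_circumference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) ||
      any(!is.finite(a)) || any(!is.finite(b)) ||
      any(a <= 0) || any(b <= 0)) {
    stop_validation("Ellipse semi-axes must be positive finite numbers.")
  }
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Build the compartment layout of the unfolded funiculus surface
#'
#' Tiles the proximo-distal axis `[0, length_mm]` with one rectangular
#' current-source compartment per electrode. Interior compartments span
#' `[x_i - h/2, x_i + h/2]` where `h` is the electrode spacing. The two
#' end compartments are half-width: the proximal compartment spans
#' `[x_1, x_1 + h/2]` (essentially no olfactory sensilla lie proximal to
#' the arista) and the distal compartment spans `[x_N - h/2, x_N]` (no
#' neurons beyond the funiculus tip). Each compartment extends
#' circumferentially over `[-q, q]` on the unfolded surface, with `q` half
#' the Ramanujan circumference of the elliptical cross-section.
#'
#' @param geom A [funiculus_geometry()].
#' @return A tibble of class `compartment_set` with columns `compartment`,
#'   `x_lo_mm`, `x_hi_mm`, `center_x_mm`, `width_mm`, `position_norm`, and
#'   attributes `h_mm`, `q_mm` and `geometry`.
#' @export
compartmentize <- function(geom) {
  if (!inherits(geom, "funiculus_geometry")) {
    stop_validation("`geom` must be a `funiculus_geometry` object.")
  }
  L <- geom$length_mm
  x <- geom$positions_norm * L
  n <- geom$n_positions
  # For a non-uniform layout the half-spacing to each neighbour is used;
  # for the default regular layout this reduces to a constant h.
  h <- mean(diff(x))
  lo <- c(x[1L], x[-1L] - diff(x) / 2)
  hi <- c(x[-n] + diff(x) / 2, x[n])
  q <- ellipse_circumference(geom$width_mm / 2, geom$thickness_mm / 2) / 2
  out <- tibble::tibble(
    compartment = seq_len(n),
    x_lo_mm = lo,
    x_hi_mm = hi,
    center_x_mm = x,
    width_mm = hi - lo,
    position_norm = geom$positions_norm
  )
  attr(out, "h_mm") <- h
  attr(out, "q_mm") <- q
  attr(out, "geometry") <- geom
  class(out) <- c("compartment_set", class(out))
  out
}
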