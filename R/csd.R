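# Forward potential model on the unfolded funiculus surface and its
# inversion to compartmental current source densities (CSD).
#
# A point current source I_c in a medium of conductivity sigma generates a
# potential phi = I_c / (4 pi sigma r) at distance r. Integrating over a
# rectangular source of uniform density on the unfolded surface gives the
# entry of the forward matrix:
#
#   F[i, j] = (1 / 4 pi sigma) * int_{-q}^{q} int_{x_lo_i}^{x_hi_i}
#               dx dy / sqrt((x - x_j)^2 + y^2)
#
# with the electrode at (x_j, 0). The double integral has the closed-form
# antiderivative G(u, v) = u*log(v + r) + v*log(u + r), r = sqrt(u^2 + v^2),
# evaluated at the rectangle corners; the improper integral with the
# electrode inside the source is finite and handled by the same formula.

# log(s + sqrt(s^2 + t^2)) computed stably when s < 0 and |t| << |s|
# (s + r would cancel); uses s + r = t^2 / (r - s).
.log_s_plus_r <- function(s, r, t) {
  n <- max(length(s), length(r), length(t))
  s <- rep_len(s, n); r <- rep_len(r, n); t <- rep_len(t, n)
  out <- numeric(n)
  pos <- s >= 0
  out[pos] <- log(s[pos] + r[pos])
  out[!pos] <- 2 * log(abs(t[!pos])) - log(r[!pos] - s[!pos])
  out
}

# Antiderivative of the 1/r rectangle integral, with the singular limits
# u -> 0 or v -> 0 taken as 0 for the corresponding term.
.rect_antideriv <- function(u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  r <- sqrt(u^2 + v^2)
  term_u <- ifelse(u == 0, 0, u * .log_s_plus_r(v, r, u))
  term_v <- ifelse(v == 0, 0, v * .log_s_plus_r(u, r, v))
  term_u + term_v
}

#' Potential integral of a uniform rectangular source
#'
#' Closed-form evaluation of
#' \eqn{\int\int_{rect} dx\,dy / \sqrt{(x-x_e)^2 + y^2}} for a rectangle
#' `[x_lo, x_hi] x [y_lo, y_hi]` and an observation point `(x_e, 0)`. The
#' improper integral with the observation point inside the rectangle is
#' finite and evaluated exactly.
#'
#' @param x_lo,x_hi,y_lo,y_hi Rectangle bounds (mm).
#' @param x_e Observation x-coordinate (mm); observation y is 0.
#' @return The integral value (mm).
#' @keywords internal
#' @export
rect_potential_integral <- function(x_lo, x_hi, y_lo, y_hi, x_e) {
  u1 <- x_lo - x_e
  u2 <- x_hi - x_e
  .rect_antideriv(u2, y_hi) - .rect_antideriv(u1, y_hi) -
    .rect_antideriv(u2, y_lo) + .rect_antideriv(u1, y_lo)
}

#' Forward model: compartment sources to electrode potentials
#'
#' Builds the square matrix mapping per-compartment current source
#' densities to the potentials observed at the electrode positions, using
#' the closed-form rectangle potential integral with prefactor
#' `1 / (4 pi sigma)`. End compartments use their corrected (half-width)
#' bounds. The matrix is stored electrode-major (`M[j, i]`), so
#' `phi = M %*% C`.
#'
#' @param compartments A `compartment_set` from [compartmentize()], or a
#'   [funiculus_geometry()] (compartmentized internally).
#' @param sigma Conductivity scalar; defaults to the geometry's value.
#' @return An object of class `forward_model` with elements `matrix`
#'   (N x N, electrode-major), `compartments`, `sigma`, `q_mm`,
#'   `positions_mm`, `condition` (2-norm condition number).
#' @examples
#' geom <- funiculus_geometry(0.6, 0.3, 0.25)
#' fm <- forward_matrix(compartmentize(geom))
#' round(fm$matrix, 4)
#' @export
forward_matrix <- function(compartments, sigma = NULL) {
  if (inherits(compartments, "funiculus_geometry")) {
    compartments <- compartmentize(compartments)
  }
  if (!inherits(compartments, "compartment_set")) {
    stop_validation("`compartments` must come from compartmentize().")
  }
  geom <- attr(compartments, "geometry")
  sigma <- sigma %||% geom$sigma
  check_scalar_positive(sigma, "sigma")
  q <- attr(compartments, "q_mm")
  x_e <- compartments$center_x_mm  # electrodes sit at the compartment centres
  L <- geom$length_mm
  if (any(x_e < 0 | x_e > L)) {
    stop_validation("Electrode positions must lie within [0, length_mm].")
  }
  n <- nrow(compartments)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    M[, i] <- rect_potential_integral(
      compartments$x_lo_mm[i], compartments$x_hi_mm[i], -q, q, x_e
    ) / (4 * pi * sigma)
  }
  if (!all(is.finite(M)) || any(M <= 0)) {
    stop_numerical("Forward matrix has non-finite or non-positive entries; check the geometry.")
  }
  structure(
    list(
      matrix = M,
      compartments = compartments,
      sigma = sigma,
      q_mm = q,
      h_mm = attr(compartments, "h_mm"),
      positions_mm = x_e,
      positions_norm = compartments$position_norm,
      condition = kappa(M, exact = TRUE)
    ),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d electrodes/compartments, sigma = %g\n",
              nrow(x$matrix), x$sigma))
  cat(sprintf("  q = %.4g mm, h = %.4g mm, condition number = %.3g\n",
              x$q_mm, x$h_mm, x$condition))
  invisible(x)
}

#' Predict electrode potentials from compartment sources
#'
#' @param model A [forward_matrix()] model.
#' @param sources Numeric vector of per-compartment source densities.
#' @return Numeric vector of potentials, one per electrode.
#' @export
forward_potentials <- function(model, sources) {
  if (!inherits(model, "forward_model")) {
    stop_validation("`model` must be a `forward_model`.")
  }
  if (length(sources) != nrow(model$matrix)) {
    stop_validation("`sources` must have length %d.", nrow(model$matrix))
  }
  as.numeric(model$matrix %*% sources)
}

#' Invert electrode potentials to compartment sources
#'
#' Solves the square linear system of the forward model (no
#' regularization), recovering the per-compartment current source
#' densities that generate the observed potentials.
#'
#' @param model A [forward_matrix()] model.
#' @param potentials Numeric vector (one value per electrode) or a matrix
#'   with one column per electrode and one row per time sample.
#' @return Sources in the same shape as `potentials`.
#' @export
invert_csd <- function(model, potentials) {
  if (!inherits(model, "forward_model")) {
    stop_validation("`model` must be a `forward_model`.")
  }
  if (model$condition >= 1e8) {
    stop_numerical(paste0(
      "Forward matrix condition number %.3g >= 1e8; the inversion is ",
      "unreliable. Check the geometry (degenerate electrode layouts are ",
      "not supported)."), model$condition)
  }
  n <- nrow(model$matrix)
  if (is.matrix(potentials)) {
    if (ncol(potentials) != n) {
      stop_validation("`potentials` must have %d columns.", n)
    }
    t(solve(model$matrix, t(potentials)))
  } else {
    if (length(potentials) != n) {
      stop_validation("`potentials` must have length %d.", n)
    }
    as.numeric(solve(model$matrix, potentials))
  }
}

#' Compartmental CSD time courses from an EAG recording
#'
#' Applies [invert_csd()] independently at every time sample of a
#' preprocessed (smoothed, control-subtracted) multi-position EAG
#' recording. Use [csd_analyze()] for the full pipeline including
#' preprocessing, response areas and the spatial barycenter.
#'
#' @param model A [forward_matrix()] model.
#' @param recording An [eag_recording()]; its traces are used as-is.
#' @return An object of class `csd_result` holding the time base, the
#'   sources matrix (time x compartment) and the model.
#' @export
csd_timecourse <- function(model, recording) {
  if (!inherits(recording, "eag_recording")) {
    stop_validation("`recording` must be an `eag_recording`.")
  }
  if (ncol(recording$traces) != nrow(model$matrix)) {
    stop_validation("Recording has %d positions but the model expects %d.",
                    ncol(recording$traces), nrow(model$matrix))
  }
  sources <- invert_csd(model, recording$traces)
  structure(
    list(
      time_s = recording$time_s,
      sources = sources,
      model = model,
      recording = recording,
      areas = NULL,
      barycenter_norm = NA_real_
    ),
    class = "csd_result"
  )
}

#' Per-compartment CSD response areas
#'
#' Integrates each compartment's source time course over the 1.5 s
#' following stimulus onset (trapezoidal rule on the recording's time
#' base) and flips the sign once, so the canonical negative-going
#' odor-evoked deflection yields a positive activation area.
#'
#' @param sources A `csd_result` or a time-by-compartment matrix.
#' @param time_s Time base in seconds (taken from the result if omitted).
#' @param onset_s Stimulus onset in seconds.
#' @param window_s Integration window after onset (default 1.5 s).
#' @return Numeric vector of response areas (source units x s), or, for a
#'   `csd_result` input, the result with `areas` and `barycenter_norm`
#'   filled in.
#' @export
csd_response_area <- function(sources, time_s = NULL, onset_s,
                              window_s = 1.5) {
  is_result <- inherits(sources, "csd_result")
  if (is_result) {
    res <- sources
    time_s <- res$time_s
    sources <- res$sources
  }
  if (!is.matrix(sources)) sources <- matrix(sources, ncol = 1L)
  if (length(time_s) != nrow(sources)) {
    stop_validation("`time_s` must match the number of time samples.")
  }
  if (max(time_s) < onset_s + window_s - 1e-9) {
    stop_validation(
      "Recording ends %.3g s after onset; %.3g s are required for the response area.",
      max(time_s) - onset_s, window_s)
  }
  keep <- time_s >= onset_s - 1e-12 & time_s <= onset_s + window_s + 1e-12
  tt <- time_s[keep]
  areas <- -apply(sources[keep, , drop = FALSE], 2L,
                  function(col) pracma::trapz(tt, col))
  if (!is_result) return(areas)
  res$areas <- areas
  res$barycenter_norm <- tryCatch(
    csd_barycenter(areas, res$model$positions_norm),
    error = function(e) NA_real_
  )
  res
}

#' Spatial barycenter of CSD response areas
#'
#' Activation-weighted mean electrode position: weights are the positive
#' parts of the response areas (compartments with net suppression do not
#' pull the barycenter). The scalar summary of where along the
#' proximo-distal axis an odorant activates the antenna.
#'
#' @param areas Per-compartment response areas (activation-positive).
#' @param positions_norm Electrode positions on `[0, 1]`.
#' @return Barycenter on `[0, 1]`.
#' @export
csd_barycenter <- function(areas, positions_norm) {
  if (length(areas) != length(positions_norm)) {
    stop_validation("`areas` and `positions_norm` must have equal length.")
  }
  w <- pmax(areas, 0)
  if (sum(w) <= 0) {
    stop_numerical("All response areas are <= 0: no detectable activation, barycenter undefined.")
  }
  sum(positions_norm * w) / sum(w)
}

#' Full CSD analysis of one recording
#'
#' Preprocesses the recording (Gaussian smoothing, control subtraction
#' when controls are present), inverts the forward model at every time
#' sample, and reduces the source time courses to response areas over the
#' post-stimulus window and their spatial barycenter.
#'
#' @param recording An [eag_recording()].
#' @param geometry A [funiculus_geometry()] (or prebuilt `forward_model`).
#' @param smooth_width_s Gaussian kernel standard deviation in seconds
#'   (default 0.02).
#' @param window_s Response-area integration window (default 1.5 s).
#' @return A `csd_result` with sources, areas and barycenter.
#' @examples
#' geom <- funiculus_geometry(0.6, 0.3, 0.25)
#' sim <- simulate_recording(sim_config(geom, center_norm = 2/3,
#'                                      noise_sd_mv = 0, seed = 1))
#' res <- csd_analyze(sim$recording, geom)
#' glance(res)
#' @export
csd_analyze <- function(recording, geometry, smooth_width_s = 0.02,
                        window_s = 1.5) {
  model <- if (inherits(geometry, "forward_model")) geometry
           else forward_matrix(compartmentize(geometry))
  rec <- preprocess_recording(recording, width_s = smooth_width_s)
  res <- csd_timecourse(model, rec)
  csd_response_area(res, onset_s = rec$stimulus_onset_s,
                    window_s = window_s)
}

#' @export
print.csd_result <- function(x, ...) {
  cat(sprintf("<csd_result> %d compartments, %d samples\n",
              ncol(x$sources), nrow(x$sources)))
  if (!is.null(x$areas)) {
    cat("  response areas:", paste(signif(x$areas, 4), collapse = ", "), "\n")
    cat(sprintf("  barycenter (normalized): %.4f\n", x$barycenter_norm))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CSD result into one row per compartment
#'
#' @param x A `csd_result`.
#' @param ... Unused.
#' @return A tibble with compartment index, normalized position, response
#'   area and peak source magnitude.
#' @method tidy csd_result
#' @export
tidy.csd_result <- function(x, ...) {
  tibble::tibble(
    compartment = seq_len(ncol(x$sources)),
    position_norm = x$model$positions_norm,
    response_area = if (is.null(x$areas)) NA_real_ else x$areas,
    peak_source = apply(abs(x$sources), 2L, max)
  )
}

#' One-row summary of a CSD result
#'
#' @param x A `csd_result`.
#' @param ... Unused.
#' @method glance csd_result
#' @export
glance.csd_result <- function(x, ...) {
  tibble::tibble(
    barycenter_norm = x$barycenter_norm,
    total_area = if (is.null(x$areas)) NA_real_ else sum(pmax(x$areas, 0)),
    n_compartments = ncol(x$sources),
    sigma = x$model$sigma,
    condition = x$model$condition
  )
}
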