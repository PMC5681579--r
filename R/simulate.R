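# Ground-truth-known synthetic data: EAG cohorts generated through the
# forward model, and sensilla point patterns with the qualitative spatial
# gradients seen on real funiculi (trichoid distal gradient, clavate
# ventro-proximal cluster, broad basiconic field, uniform coeloconic).

#' Simulation configuration for synthetic EAG recordings
#'
#' Bundles the geometry, the per-odorant source profile, the temporal
#' response kernel and the noise/jitter levels used by
#' [simulate_recording()] and [simulate_cohort()].
#'
#' @param geometry A [funiculus_geometry()].
#' @param center_norm Source centre(s) on `[0, 1]`, one per odorant.
#' @param width_norm Source Gaussian width(s) in normalized units
#'   (default 0.08).
#' @param amplitude Source amplitude(s) in source units (default 100,
#'   which yields EAG peaks of roughly 1 mV for typical geometries); the
#'   per-compartment magnitudes sum to this value.
#' @param odorant Odorant label(s); defaults to `odor1`, `odor2`, ...
#' @param tau_rise_s,tau_decay_s Difference-of-exponentials time constants
#'   (defaults 0.05 s and 0.4 s, so the response decays substantially
#'   within the 1.5 s integration window). `tau_decay_s > tau_rise_s`.
#' @param latency_s Response latency after stimulus onset (default 0.02).
#' @param noise_sd_mv White Gaussian noise SD in mV (default 0).
#' @param n_individuals Individuals per cohort (default 10).
#' @param jitter_center_sd,jitter_amplitude_sd Inter-individual SD of the
#'   source centre (normalized units) and of a multiplicative amplitude
#'   factor (defaults 0.02 and 0.1).
#' @param duration_s,onset_s Recording length and stimulus onset
#'   (defaults 3 s and 1 s, leaving a 0.5 s baseline margin and the full
#'   1.5 s integration window).
#' @param sampling_rate_hz Sampling rate (default 500).
#' @param species Species label (defaults to the geometry's).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(geometry,
                       center_norm = 0.5,
                       width_norm = 0.08,
                       amplitude = 100,
                       odorant = NULL,
                       tau_rise_s = 0.05,
                       tau_decay_s = 0.4,
                       latency_s = 0.02,
                       noise_sd_mv = 0,
                       n_individuals = 10L,
                       jitter_center_sd = 0.02,
                       jitter_amplitude_sd = 0.1,
                       duration_s = 3,
                       onset_s = 1,
                       sampling_rate_hz = 500,
                       species = NULL,
                       seed = NULL) {
  if (!inherits(geometry, "funiculus_geometry")) {
    stop_validation("`geometry` must be a `funiculus_geometry`.")
  }
  n_od <- max(length(center_norm), length(width_norm), length(amplitude))
  center_norm <- rep_len(center_norm, n_od)
  width_norm <- rep_len(width_norm, n_od)
  amplitude <- rep_len(amplitude, n_od)
  if (is.null(odorant)) odorant <- paste0("odor", seq_len(n_od))
  if (any(center_norm < 0 | center_norm > 1)) {
    stop_validation("`center_norm` must lie in [0, 1].")
  }
  if (any(width_norm <= 0)) stop_validation("`width_norm` must be > 0.")
  if (tau_rise_s <= 0 || tau_decay_s <= tau_rise_s) {
    stop_validation("Need `tau_decay_s` > `tau_rise_s` > 0.")
  }
  if (noise_sd_mv < 0) stop_validation("`noise_sd_mv` must be >= 0.")
  structure(
    list(geometry = geometry,
         odorants = tibble::tibble(odorant = odorant,
                                   center_norm = center_norm,
                                   width_norm = width_norm,
                                   amplitude = amplitude),
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         latency_s = latency_s, noise_sd_mv = noise_sd_mv,
         n_individuals = as.integer(n_individuals),
         jitter_center_sd = jitter_center_sd,
         jitter_amplitude_sd = jitter_amplitude_sd,
         duration_s = duration_s, onset_s = onset_s,
         sampling_rate_hz = sampling_rate_hz,
         species = species %||% (geometry$species %||% "synthetic"),
         seed = seed),
    class = "sim_config"
  )
}

#' Compartmental source vector from a Gaussian activation profile
#'
#' Distributes a total source amplitude `A` over the compartments in
#' proportion to the mass of a Gaussian bump (centre, width on the
#' normalized axis) falling in each compartment, with negative sign (the
#' activation convention: odor-evoked sources are negative-going at the
#' electrode). The magnitudes sum to `A` exactly for any centre/width; in
#' the narrow-width limit all mass lands in the compartment containing
#' the centre.
#'
#' @param center_norm Bump centre on `[0, 1]`.
#' @param width_norm Bump standard deviation in normalized units.
#' @param compartments A `compartment_set`.
#' @param amplitude Total source magnitude `A` (default 1).
#' @return Numeric source vector, one entry per compartment.
#' @export
simulate_source_profile <- function(center_norm, width_norm, compartments,
                                    amplitude = 1) {
  if (width_norm <= 0) stop_validation("`width_norm` must be > 0.")
  geom <- attr(compartments, "geometry")
  L <- geom$length_mm
  lo <- compartments$x_lo_mm / L
  hi <- compartments$x_hi_mm / L
  mass <- stats::pnorm(hi, center_norm, width_norm) -
    stats::pnorm(lo, center_norm, width_norm)
  if (sum(mass) <= 0) {
    # delta limit: pnorm underflows for very narrow bumps
    mass <- as.numeric(center_norm >= lo & center_norm < hi)
    if (sum(mass) == 0) mass[which.min(abs((lo + hi) / 2 - center_norm))] <- 1
  }
  -amplitude * mass / sum(mass)
}

# difference-of-exponentials response kernel, normalized to peak 1
.response_kernel <- function(t, t0, tau_rise, tau_decay) {
  dt <- t - t0
  k <- ifelse(dt >= 0,
              exp(-dt / tau_decay) - exp(-dt / tau_rise), 0)
  ratio <- tau_rise / tau_decay
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  k_peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  k / k_peak
}

#' Simulate one multi-position EAG recording
#'
#' Generates electrode potentials through the forward model,
#' `phi_j(t) = sum_i F[i, j] C_i k(t) + eps(t)`, where `C` is the
#' compartmental source vector of the configured odorant, `k(t)` a
#' difference-of-exponentials transient normalized to peak 1, and `eps`
#' white Gaussian noise. A control recording (noise only) and the ground
#' truth (source vector, barycenter) are returned alongside.
#'
#' @param config A [sim_config()]; its first odorant is simulated unless
#'   `odorant_index` says otherwise.
#' @param odorant_index Which odorant of the panel to simulate.
#' @param individual Individual label.
#' @param seed Integer seed (defaults to the config's).
#' @return List with `recording` (an [eag_recording()] carrying the
#'   control traces), `truth` (list: `sources`, `barycenter_norm`,
#'   `center_norm`, `peak_eag_mv`), and `model`.
#' @export
simulate_recording <- function(config, odorant_index = 1L,
                               individual = "ind01", seed = NULL) {
  if (!inherits(config, "sim_config")) {
    stop_validation("`config` must come from sim_config().")
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  comps <- compartmentize(config$geometry)
  model <- forward_matrix(comps)
  od <- config$odorants[odorant_index, ]
  C <- simulate_source_profile(od$center_norm, od$width_norm, comps,
                               amplitude = od$amplitude)
  t <- seq(0, config$duration_s, by = 1 / config$sampling_rate_hz)
  k <- .response_kernel(t, config$onset_s + config$latency_s,
                        config$tau_rise_s, config$tau_decay_s)
  clean <- outer(k, forward_potentials(model, C))
  noise <- matrix(stats::rnorm(length(clean), 0, config$noise_sd_mv),
                  nrow(clean), ncol(clean))
  ctrl <- matrix(stats::rnorm(length(clean), 0, config$noise_sd_mv),
                 nrow(clean), ncol(clean))
  rec <- eag_recording(
    traces = clean + noise,
    time_s = t,
    sampling_rate_hz = config$sampling_rate_hz,
    stimulus_onset_s = config$onset_s,
    control_traces = ctrl,
    odorant = od$odorant,
    individual = individual,
    species = config$species
  )
  w <- abs(C)
  truth <- list(
    sources = C,
    barycenter_norm = sum(config$geometry$positions_norm * w) / sum(w),
    center_norm = od$center_norm,
    peak_eag_mv = max(abs(clean))
  )
  list(recording = rec, truth = truth, model = model)
}

#' Simulate an inhomogeneous sensilla point pattern
#'
#' Draws one Poisson point pattern per morphotype on the normalized
#' funiculus face by thinning, with default intensity shapes emulating
#' the observed gradients: trichoid density zero proximal to x = 0.15 and
#' increasing along a ventro-proximal to dorso-distal gradient; clavate
#' clustered ventro-proximally; basiconic broadly distributed but rare at
#' the borders; coeloconic uniform. Intensities are scaled so each
#' morphotype's expected count matches `expected_counts`.
#'
#' @param expected_counts Named vector of expected counts per morphotype
#'   (default `c(trichoid = 450, basiconic = 300, clavate = 160,
#'   coeloconic = 180)`, in the range observed for medium-sized
#'   tephritids).
#' @param intensity_funs Optional named list of `function(x, y)` intensity
#'   shapes (non-negative, any scale) overriding the defaults.
#' @param fixed_n If `TRUE`, draw exactly `expected_counts` points per
#'   morphotype (conditional Poisson) instead of a Poisson-distributed
#'   count.
#' @param species,individual Labels for the output map.
#' @param face_area_mm2 Optional lateral-face area forwarded to the map.
#' @param seed Integer seed.
#' @return A [sensilla_map()].
#' @export
simulate_sensilla <- function(expected_counts = c(trichoid = 450,
                                                  basiconic = 300,
                                                  clavate = 160,
                                                  coeloconic = 180),
                              intensity_funs = NULL,
                              fixed_n = FALSE,
                              species = "synthetic",
                              individual = "ind01",
                              face_area_mm2 = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  defaults <- list(
    trichoid = function(x, y) pmax(0, x - 0.15) * (0.4 + 0.6 * y),
    clavate = function(x, y) {
      exp(-((x - 0.15)^2 / (2 * 0.12^2) + (y - 0.25)^2 / (2 * 0.15^2)))
    },
    basiconic = function(x, y) (x * (1 - x) * y * (1 - y))^0.5,
    coeloconic = function(x, y) rep(1, length(x))
  )
  funs <- utils::modifyList(defaults, intensity_funs %||% list())
  types <- names(expected_counts)
  if (!all(types %in% SENSILLA_TYPES)) {
    stop_validation("Unknown morphotype in `expected_counts`.")
  }
  pts <- purrr::map_dfr(types, function(ty) {
    f <- funs[[ty]]
    # scale so the intensity integrates to the expected count
    gx <- seq(0.005, 0.995, by = 0.01)
    gg <- expand.grid(x = gx, y = gx)
    vals <- f(gg$x, gg$y)
    if (any(vals < 0)) stop_validation("Intensity for %s is negative.", ty)
    mean_int <- mean(vals)
    if (mean_int <= 0 || expected_counts[[ty]] == 0) {
      return(tibble::tibble(x_norm = numeric(0), y_norm = numeric(0),
                            type = character(0)))
    }
    lambda_max <- max(vals) * expected_counts[[ty]] / mean_int
    accept_xy <- function(n) {
      x <- stats::runif(n); y <- stats::runif(n)
      keep <- stats::runif(n) < f(x, y) * (expected_counts[[ty]] / mean_int) /
        lambda_max
      cbind(x[keep], y[keep])
    }
    if (fixed_n) {
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < expected_counts[[ty]]) {
        out <- rbind(out, accept_xy(max(100L, expected_counts[[ty]])))
      }
      out <- out[seq_len(expected_counts[[ty]]), , drop = FALSE]
    } else {
      n_prop <- stats::rpois(1L, lambda_max)
      out <- accept_xy(n_prop)
    }
    tibble::tibble(x_norm = out[, 1L], y_norm = out[, 2L], type = ty)
  })
  pts$species <- species
  pts$individual <- individual
  sensilla_map(pts, face_area_mm2 = face_area_mm2)
}

#' Simulate a two-species cohort and extract its feature table
#'
#' Generates `n_individuals` recordings per species across the configured
#' odorant panel, runs the full analysis pipeline (smoothing, control
#' subtraction, CSD inversion, response areas, barycenter) on every
#' recording, and returns the grouped feature table of CSD barycenters
#' (one row per individual, one column per odorant) ready for
#' [distance_ratio()] / [bootstrap_ratio_test()] / [lda_projection()].
#' Per-individual jitter perturbs the source centres and amplitudes.
#'
#' @param config_a,config_b [sim_config()]s for the two species (their
#'   `species` labels name the groups; equal odorant panels required).
#' @param seed Integer seed.
#' @return List with `features` (tibble: species, individual, one
#'   barycenter column per odorant), `truth` (tibble of ground-truth
#'   barycenters), `amplitudes` (tibble of absolute response amplitudes).
#' @export
simulate_cohort <- function(config_a, config_b, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_group <- function(cfg, tag) {
    comps <- compartmentize(cfg$geometry)
    model <- forward_matrix(comps)
    n_od <- nrow(cfg$odorants)
    purrr::map_dfr(seq_len(cfg$n_individuals), function(ind) {
      id <- sprintf("%s_ind%02d", tag, ind)
      centers <- pmin(1, pmax(0, cfg$odorants$center_norm +
                                stats::rnorm(n_od, 0, cfg$jitter_center_sd)))
      amps <- cfg$odorants$amplitude *
        pmax(0.1, 1 + stats::rnorm(n_od, 0, cfg$jitter_amplitude_sd))
      purrr::map_dfr(seq_len(n_od), function(k) {
        C <- simulate_source_profile(centers[k], cfg$odorants$width_norm[k],
                                     comps, amplitude = amps[k])
        t <- seq(0, cfg$duration_s, by = 1 / cfg$sampling_rate_hz)
        kt <- .response_kernel(t, cfg$onset_s + cfg$latency_s,
                               cfg$tau_rise_s, cfg$tau_decay_s)
        clean <- outer(kt, forward_potentials(model, C))
        noise <- matrix(stats::rnorm(length(clean), 0, cfg$noise_sd_mv),
                        nrow(clean), ncol(clean))
        ctrl <- matrix(stats::rnorm(length(clean), 0, cfg$noise_sd_mv),
                       nrow(clean), ncol(clean))
        rec <- eag_recording(clean + noise, time_s = t,
                             sampling_rate_hz = cfg$sampling_rate_hz,
                             stimulus_onset_s = cfg$onset_s,
                             control_traces = ctrl,
                             odorant = cfg$odorants$odorant[k],
                             individual = id, species = cfg$species)
        res <- csd_analyze(rec, model)
        amp <- absolute_response_amplitude(
          response_amplitude(preprocess_recording(rec)$traces,
                             rec$time_s, rec$stimulus_onset_s))
        w <- abs(C)
        tibble::tibble(
          species = cfg$species, individual = id,
          odorant = cfg$odorants$odorant[k],
          barycenter = res$barycenter_norm,
          truth_barycenter = sum(cfg$geometry$positions_norm * w) / sum(w),
          abs_amplitude = amp
        )
      })
    })
  }
  long <- dplyr::bind_rows(one_group(config_a, "a"), one_group(config_b, "b"))
  features <- long |>
    dplyr::select("species", "individual", "odorant", "barycenter") |>
    tidyr::pivot_wider(names_from = "odorant", values_from = "barycenter")
  truth <- long |>
    dplyr::select("species", "individual", "odorant", "truth_barycenter") |>
    tidyr::pivot_wider(names_from = "odorant",
                       values_from = "truth_barycenter")
  amplitudes <- long |>
    dplyr::select("species", "individual", "odorant", "abs_amplitude") |>
    tidyr::pivot_wider(names_from = "odorant", values_from = "abs_amplitude")
  list(features = features, truth = truth, amplitudes = amplitudes)
}
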