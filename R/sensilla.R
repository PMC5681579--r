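SENSILLA_TYPES <- c("trichoid", "basiconic", "clavate", "coeloconic")

#' Annotated sensilla point pattern
#'
#' Validates a table of sensilla annotated on the lateral face of the
#' funiculus: normalized proximo-distal (`x_norm`) and ventro-dorsal
#' (`y_norm`) coordinates plus a morphotype label.
#'
#' @param data Data frame with columns `x_norm`, `y_norm`, `type` and
#'   optionally `individual` and `species`.
#' @param face_area_mm2 Optional lateral-face area in mm^2, needed only
#'   for densities per mm^2 in [count_summary()].
#' @return A tibble of class `sensilla_map` (attribute `face_area_mm2`).
#' @export
sensilla_map <- function(data, face_area_mm2 = NULL) {
  req <- c("x_norm", "y_norm", "type")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation("Sensilla table is missing column(s): %s.",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) > 0L) {
    if (any(data$x_norm < 0 | data$x_norm > 1 |
            data$y_norm < 0 | data$y_norm > 1, na.rm = TRUE) ||
        any(!is.finite(data$x_norm)) || any(!is.finite(data$y_norm))) {
      stop_validation("Sensilla coordinates must lie within [0, 1]^2.")
    }
    bad <- setdiff(unique(data$type), SENSILLA_TYPES)
    if (length(bad) > 0L) {
      stop_validation("Unknown sensilla type(s): %s. Allowed: %s.",
                      paste(bad, collapse = ", "),
                      paste(SENSILLA_TYPES, collapse = "|"))
    }
  }
  out <- tibble::as_tibble(data)
  if (!"individual" %in% names(out)) out$individual <- NA_character_
  if (!"species" %in% names(out)) out$species <- NA_character_
  if (!is.null(face_area_mm2)) check_scalar_positive(face_area_mm2, "face_area_mm2")
  attr(out, "face_area_mm2") <- face_area_mm2
  class(out) <- c("sensilla_map", class(out))
  out
}

#' Kernel density map of one sensilla morphotype
#'
#' Sums a unit-mass 2D Gaussian kernel centred on every sensillum of the
#' requested morphotype, evaluated on a regular lattice over the
#' normalized funiculus face. Kernel standard deviations default to 2% of
#' funiculus length and 5% of funiculus width; kernels are truncated at 4
#' standard deviations and clipped at the map boundary without
#' renormalization (edge densities are therefore attenuated, as for any
#' unrenormalized kernel estimate).
#'
#' @param map A [sensilla_map()].
#' @param type Morphotype to map (`trichoid`, `basiconic`, `clavate` or
#'   `coeloconic`).
#' @param grid_res Lattice resolution `c(nx, ny)` (default 200 x 100).
#' @param sigma_x,sigma_y Kernel standard deviations in normalized units.
#' @return An object of class `density_grid`: list with `x`, `y` (cell
#'   centres), `z` (nx x ny density matrix), `type`, `sigma_x`, `sigma_y`.
#' @export
density_map <- function(map, type, grid_res = c(200L, 100L),
                        sigma_x = 0.02, sigma_y = 0.05) {
  if (!inherits(map, "sensilla_map")) map <- sensilla_map(map)
  type <- match.arg(type, SENSILLA_TYPES)
  check_scalar_positive(sigma_x, "sigma_x")
  check_scalar_positive(sigma_y, "sigma_y")
  if (length(grid_res) != 2L || any(grid_res < 2)) {
    stop_validation("`grid_res` must be two integers >= 2.")
  }
  nx <- as.integer(grid_res[1L]); ny <- as.integer(grid_res[2L])
  gx <- (seq_len(nx) - 0.5) / nx
  gy <- (seq_len(ny) - 0.5) / ny
  pts <- map[map$type == type, , drop = FALSE]
  z <- matrix(0, nx, ny)
  for (k in seq_len(nrow(pts))) {
    dx <- gx - pts$x_norm[k]
    dy <- gy - pts$y_norm[k]
    kx <- ifelse(abs(dx) <= 4 * sigma_x, stats::dnorm(dx, sd = sigma_x), 0)
    ky <- ifelse(abs(dy) <= 4 * sigma_y, stats::dnorm(dy, sd = sigma_y), 0)
    z <- z + outer(kx, ky)
  }
  structure(
    list(x = gx, y = gy, z = z, type = type, n_points = nrow(pts),
         sigma_x = sigma_x, sigma_y = sigma_y),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s: %d points on a %d x %d lattice (sigma %g x %g)\n",
              x$type, x$n_points, length(x$x), length(x$y),
              x$sigma_x, x$sigma_y))
  invisible(x)
}

#' Tidy a density grid into long format
#'
#' @param x A `density_grid`.
#' @param ... Unused.
#' @return Tibble with `x_norm`, `y_norm`, `density`, `type`.
#' @method tidy density_grid
#' @export
tidy.density_grid <- function(x, ...) {
  tibble::tibble(
    x_norm = rep(x$x, times = length(x$y)),
    y_norm = rep(x$y, each = length(x$x)),
    density = as.vector(x$z),
    type = x$type
  )
}

.check_same_lattice <- function(grids) {
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(length(g$x), length(ref$x)) ||
        !identical(length(g$y), length(ref$y)) ||
        max(abs(g$x - ref$x)) > 1e-12 || max(abs(g$y - ref$y)) > 1e-12) {
      stop_validation("Density grids are on different lattices.")
    }
  }
  invisible(TRUE)
}

#' Sensilla dominance index along the proximo-distal axis
#'
#' Contrasts basiconic + clavate against trichoid sensilla density:
#' `(D_b + D_c - D_t) / (D_b + D_c + D_t)`, where each density is the
#' y-averaged kernel density at an x bin. The index is 1 where only
#' basiconic/clavate sensilla occur, -1 where only trichoid occur, and
#' `NA` (undefined) where the total density is zero.
#'
#' @param grid_b,grid_c,grid_t `density_grid`s for basiconic, clavate and
#'   trichoid sensilla, on the same lattice.
#' @return Tibble with `x_norm`, the three y-averaged densities and
#'   `dominance`.
#' @export
dominance_profile <- function(grid_b, grid_c, grid_t) {
  .check_same_lattice(list(grid_b, grid_c, grid_t))
  db <- rowMeans(grid_b$z)
  dc <- rowMeans(grid_c$z)
  dt <- rowMeans(grid_t$z)
  tot <- db + dc + dt
  idx <- ifelse(tot > 0, (db + dc - dt) / tot, NA_real_)
  tibble::tibble(
    x_norm = grid_b$x,
    d_basiconic = db,
    d_clavate = dc,
    d_trichoid = dt,
    dominance = idx
  )
}

#' Dominance profile straight from a sensilla map
#'
#' Builds the basiconic, clavate and trichoid density grids and reduces
#' them with [dominance_profile()].
#'
#' @inheritParams density_map
#' @return See [dominance_profile()].
#' @export
dominance_profile_map <- function(map, grid_res = c(200L, 100L),
                                  sigma_x = 0.02, sigma_y = 0.05) {
  g <- lapply(c("basiconic", "clavate", "trichoid"), function(ty) {
    density_map(map, ty, grid_res = grid_res,
                sigma_x = sigma_x, sigma_y = sigma_y)
  })
  dominance_profile(g[[1L]], g[[2L]], g[[3L]])
}

#' Sensilla count summary
#'
#' Per-individual and aggregated counts of each sensilla morphotype, the
#' basiconic + clavate pool (the two types are easily confused under SEM),
#' the total, the (basiconic + clavate) / trichoid ratio, and densities
#' per mm^2 when a lateral-face area is available. The aggregate rows
#' report the mean and SD across individuals; for the ratio both the mean
#' of per-individual ratios (`bc_t_ratio`) and the ratio of mean counts
#' (`bc_t_ratio_of_means`) are reported, which differ in general.
#'
#' @param maps A [sensilla_map()] (possibly several individuals in one
#'   table) or a list of them.
#' @return A tibble with one row per individual plus `mean` and `sd`
#'   rows (column `statistic` distinguishes them), per species.
#' @export
count_summary <- function(maps) {
  if (inherits(maps, "sensilla_map")) maps <- list(maps)
  pieces <- purrr::map(maps, function(m) {
    if (!inherits(m, "sensilla_map")) m <- sensilla_map(m)
    area <- attr(m, "face_area_mm2")
    tb <- tibble::as_tibble(m)
    tb$area_mm2 <- if (is.null(area)) NA_real_ else area
    tb
  })
  all_pts <- dplyr::bind_rows(pieces)
  counts <- all_pts |>
    dplyr::count(.data$species, .data$individual, .data$area_mm2,
                 .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0L)
  for (ty in SENSILLA_TYPES) {
    if (!ty %in% names(counts)) counts[[ty]] <- 0L
  }
  per_ind <- counts |>
    dplyr::mutate(
      basiconic_clavate = .data$basiconic + .data$clavate,
      total = .data$trichoid + .data$basiconic + .data$clavate +
        .data$coeloconic,
      bc_t_ratio = ifelse(.data$trichoid > 0,
                          .data$basiconic_clavate / .data$trichoid,
                          NA_real_),
      dplyr::across(dplyr::all_of(c(SENSILLA_TYPES, "basiconic_clavate",
                                    "total")),
                    ~ .x / .data$area_mm2,
                    .names = "density_{.col}_mm2"),
      statistic = "individual"
    ) |>
    dplyr::select("species", "individual", "statistic",
                  dplyr::all_of(SENSILLA_TYPES),
                  "basiconic_clavate", "total", "bc_t_ratio",
                  dplyr::starts_with("density_"))
  num_cols <- setdiff(names(per_ind),
                      c("species", "individual", "statistic"))
  agg <- per_ind |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols),
                    list(mean = ~ mean(.x), sd = ~ stats::sd(.x))),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"species",
                        names_to = c("name", "statistic"),
                        names_pattern = "(.*)_(mean|sd)$") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value") |>
    dplyr::mutate(individual = NA_character_)
  agg$bc_t_ratio_of_means <- NA_real_
  mean_rows <- agg$statistic == "mean"
  agg$bc_t_ratio_of_means[mean_rows] <-
    agg$basiconic_clavate[mean_rows] / agg$trichoid[mean_rows]
  per_ind$bc_t_ratio_of_means <- NA_real_
  dplyr::bind_rows(per_ind, agg) |>
    dplyr::arrange(.data$species, .data$statistic != "individual",
                   .data$individual)
}
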