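# Diagnostic ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an EAG recording
#'
#' One panel per electrode position with the stimulus window shaded.
#'
#' @param object An [eag_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eag_recording
#' @export
autoplot.eag_recording <- function(object, ...) {
  n <- ncol(object$traces)
  df <- tibble::tibble(
    time_s = rep(object$time_s, n),
    position = factor(rep(seq_len(n) - 1L, each = nrow(object$traces))),
    v_mv = as.vector(object$traces)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$v_mv)) +
    ggplot2::annotate(
      "rect", xmin = object$stimulus_onset_s,
      xmax = object$stimulus_onset_s + object$stimulus_duration_s,
      ymin = -Inf, ymax = Inf, alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~position, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (s)", y = "EAG (mV)",
                  title = paste(object$species, object$odorant, sep = " / "))
}

#' Plot CSD source time courses and response areas
#'
#' @param object A `csd_result`.
#' @param ... Unused.
#' @return A ggplot (time courses faceted by compartment).
#' @method autoplot csd_result
#' @export
autoplot.csd_result <- function(object, ...) {
  n <- ncol(object$sources)
  df <- tibble::tibble(
    time_s = rep(object$time_s, n),
    compartment = factor(rep(seq_len(n), each = nrow(object$sources))),
    source = as.vector(object$sources)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$source)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (s)", y = "Source density (a.u.)")
  if (!is.na(object$barycenter_norm)) {
    p <- p + ggplot2::labs(
      title = sprintf("CSD barycenter = %.3f", object$barycenter_norm))
  }
  p
}

#' Plot a sensilla density grid
#'
#' @param object A `density_grid`.
#' @param ... Unused.
#' @return A ggplot raster of the density field.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_norm, .data$y_norm,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Proximo-distal position", y = "Ventro-dorsal position",
                  title = paste(object$type, "sensilla density"))
}

#' Plot dominance-index profiles
#'
#' @param profiles A tibble from [dominance_profile()] (or several bound
#'   together with an `individual`/`species` column for grouping).
#' @param colour Optional column name used for line colour.
#' @return A ggplot.
#' @export
plot_dominance_profiles <- function(profiles, colour = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(.data$x_norm, .data$dominance))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "Proximo-distal position", y = "Sensilla dominance index")
}

#' Plot a discriminant projection
#'
#' @param object An `lda_projection`.
#' @param ... Unused.
#' @return A ggplot of the first two discriminant axes.
#' @method autoplot lda_projection
#' @export
autoplot.lda_projection <- function(object, ...) {
  grp <- object$group
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(.data$LD1,
                                    if (ncol(object$axes) > 1L) .data$LD2
                                    else 0,
                                    colour = .data[[grp]])) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "LD1", y = if (ncol(object$axes) > 1L) "LD2" else "",
                  colour = grp)
  p + ggplot2::geom_point(data = object$class_means, shape = 4, size = 3,
                          stroke = 1.5)
}
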