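# Plotting. ggplot2-based displays of the agreement analyses and the
# enface planes; all return ggplot objects.

#' Bland-Altman plot
#'
#' Per-pair differences against means with the bias and the 1.96-SD limits
#' of agreement drawn as horizontal lines.
#'
#' @param object a [bland_altman()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference",
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Display one enface plane
#'
#' @param stack an [extract_enface_stack()] result.
#' @param offset depth offset (pixels from the RPE surface) of the plane.
#' @return A ggplot raster of the plane (invalid pixels blank).
#' @export
plot_enface_plane <- function(stack, offset) {
  k <- match(offset, stack$offsets)
  if (is.na(k)) stop_enface("bad_params", "offset not in the stack.")
  p <- stack$planes[, , k]
  p[!stack$valid[, , k]] <- NA_real_
  df <- tidyr::expand_grid(y = seq_len(nrow(p)), x = seq_len(ncol(p)))
  df$intensity <- p[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey50") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Enface plane, offset %d (%.1f um)",
                                  offset, offset * stack$axial_pitch_um)) +
    ggplot2::theme_void()
}

#' Thickness-versus-age scatter of a pipeline run
#'
#' @param object an `enface_run`.
#' @param metric one of the subject-record metrics (default `"tc_um"`).
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.enface_run <- function(object, metric = "tc_um", ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$age_years, y = .data[[metric]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Age (years)", y = metric) +
    ggplot2::theme_minimal()
}
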