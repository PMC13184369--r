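#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a blood-volume result
#'
#' @param x An [imbv_map()] result.
#' @param rois Optional named list of ROI masks; defaults to the map mask.
#' @param ... Unused.
#' @return A tibble of per-ROI mean and SD fractions.
#' @export
tidy.imbv_result <- function(x, rois = NULL, ...) {
  if (is.null(rois)) rois <- list(global = x$imbv_map$mask)
  roi_stats(x, rois)
}

#' @rdname tidy.imbv_result
#' @export
glance.imbv_result <- function(x, ...) {
  v <- x$imbv_map$values[x$imbv_map$mask]
  tibble::tibble(phase = x$phase %||% NA_character_,
                 n_pixels = length(v), imbv_mean = mean(v),
                 imbv_sd = stats::sd(v),
                 blood_t1_pre = x$blood_t1_pre,
                 blood_t1_post = x$blood_t1_post,
                 n_excluded = x$n_excluded_dr1 + x$n_excluded_range)
}

#' Plot a quantitative map
#'
#' @param object A [map_image()].
#' @param ... Unused.
#' @return A ggplot raster plot in physical coordinates (mm).
#' @export
autoplot.map_image <- function(object, ...) {
  n1 <- nrow(object$values); n2 <- ncol(object$values)
  df <- data.frame(
    x = rep((seq_len(n1) - 0.5 - n1 / 2) * object$pixel_spacing[1], n2),
    y = rep((seq_len(n2) - 0.5 - n2 / 2) * object$pixel_spacing[2], each = n1),
    value = as.vector(ifelse(object$mask, Re(object$values), NA)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = object$units) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot a cyclic T1-tracking run
#'
#' @param object A [track_t1_timeseries()] result.
#' @param last_beats Number of final beats to show.
#' @param ... Unused.
#' @return A ggplot of true and estimated T1 against time.
#' @export
autoplot.t1track_tracking <- function(object, last_beats = 3, ...) {
  keep <- object$beat > max(object$beat) - last_beats
  df <- object[keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true_t1,
                                    colour = "true")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$est_t1,
                                    colour = "estimated")) +
    ggplot2::scale_colour_manual(values = c(true = "black",
                                            estimated = "purple"),
                                 name = NULL) +
    ggplot2::labs(x = "time (ms)", y = "myocardial T1 (ms)",
                  title = sprintf("FA %g deg, %g bpm", attr(object, "fa"),
                                  attr(object, "heart_rate")))
}

#' Plot a feasible-heart-rate table
#'
#' @param tbl A [feasible_hr_table()] result.
#' @return A ggplot of highest feasible heart rate against flip angle.
#' @export
plot_feasible_hr <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$fa, y = .data$max_hr_bpm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "drive flip angle (deg)",
                  y = "highest feasible heart rate (bpm)")
}

#' Plot fast- vs no-exchange convergence across flip angle
#'
#' @param tbl A [fv_convergence_table()] result.
#' @return A ggplot showing the two estimators converging with flip angle.
#' @export
plot_fv_convergence <- function(tbl) {
  long <- rbind(
    data.frame(fa = tbl$fa, fv_true = tbl$fv_true, estimate = tbl$fv_fast,
               regime = "fast-exchange"),
    data.frame(fa = tbl$fa, fv_true = tbl$fv_true, estimate = tbl$fv_noex,
               regime = "no-exchange"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fa, y = 100 * .data$estimate,
                                     colour = factor(.data$fv_true),
                                     linetype = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flip angle (deg)", y = "estimated fraction (%)",
                  colour = "true fraction", linetype = NULL)
}

#' @importFrom rlang .data
NULL
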