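# ggplot2 visualization helpers.

#' @importFrom ggplot2 ggplot aes autoplot geom_raster geom_boxplot
#'   geom_jitter facet_wrap labs scale_fill_gradient scale_fill_gradientn
#'   theme_minimal coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Plot an en-face map
#'
#' @param object an [en_face_map()].
#' @param ... unused.
#' @export
autoplot.en_face_map <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object$pixels)), times = ncol(object$pixels)),
    col = rep(seq_len(ncol(object$pixels)), each = nrow(object$pixels)),
    value = as.vector(object$pixels)
  )
  ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    scale_fill_gradient(low = "black",
                        high = if (object$channel == "GFP-structure")
                          "green3" else "red3") +
    coord_fixed() +
    labs(x = "fast axis [px]", y = "slow axis [px]", fill = object$channel) +
    theme_minimal()
}

#' Plot a local SSIM map in the inverted-hot display convention
#'
#' Black corresponds to a local SSIM of 1 (identical structure), orange to
#' 0, white to -1.
#'
#' @param x an [ssim()] result.
#' @export
plot_ssim_map <- function(x) {
  stopifnot(inherits(x, "ssim_result"))
  df <- tibble(
    row = rep(seq_len(nrow(x$local)), times = ncol(x$local)),
    col = rep(seq_len(ncol(x$local)), each = nrow(x$local)),
    ssim = as.vector(x$local)
  )
  ggplot(df, aes(.data$col, .data$row, fill = .data$ssim)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    scale_fill_gradientn(colours = c("white", "yellow", "orange", "red",
                                     "black"),
                         limits = c(-1, 1)) +
    coord_fixed() +
    labs(x = "col [px]", y = "row [px]", fill = "local SSIM",
         title = sprintf("global SSIM = %.2f", x$global)) +
    theme_minimal()
}

#' Box plots of the five topology metrics per group
#'
#' @param object a [run_study()] result.
#' @param channel which channel to plot (default `"OCTA"`).
#' @param ... unused.
#' @export
autoplot.vessel_study <- function(object, channel = "OCTA", ...) {
  lv <- object$larvae[object$larvae$channel == channel, ]
  long <- tidyr::pivot_longer(
    lv, dplyr::all_of(c(study_metric_cols, "ssim_flow_structure")),
    names_to = "metric")
  ggplot(long, aes(.data$group, .data$value, fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    geom_jitter(width = 0.15, size = 0.6, alpha = 0.6) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL,
         title = sprintf("Topology metrics (%s channel)", channel)) +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
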