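#' Plot the maximum-entropy criterion curve
#'
#' Entropy-sum criterion against the candidate threshold gray values, with
#' the selected threshold marked. Useful to audit auto-threshold stability
#' (CBCT segments can change sharply with small threshold shifts).
#'
#' @param object a `cv_threshold` from [max_entropy_threshold()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_threshold <- function(object, ...) {
  br <- object$histogram$breaks
  df <- tibble::tibble(
    threshold = br[2:(length(br) - 1)],
    criterion = object$criterion_curve
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$criterion)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "candidate threshold (gray value)",
                  y = "entropy sum H_below + H_above",
                  title = "Maximum-entropy threshold selection") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume or mask
#'
#' @param x a [voxel_volume()] or [binary_mask()].
#' @param z 1-based axial slice index (default: middle slice).
#' @param overlay optional [binary_mask()] on the same grid, drawn as a
#'   contour-like highlight.
#' @return A ggplot object.
#' @export
plot_slice <- function(x, z = NULL, overlay = NULL) {
  d <- dim(x$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  stopifnot(z >= 1, z <= d[3])
  sl <- x$data[, , z]
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    value = as.numeric(sl)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = x$spacing[2] / x$spacing[1]) +
    ggplot2::labs(x = NULL, y = NULL, fill = "gray",
                  title = paste0("axial slice z = ", z)) +
    ggplot2::theme_minimal()
  if (!is.null(overlay)) {
    stopifnot_same_geometry(x, overlay)
    ov <- overlay$data[, , z]
    if (any(ov)) {
      w <- which(ov, arr.ind = TRUE)
      p <- p + ggplot2::annotate("tile", x = w[, 1], y = w[, 2],
                                 fill = "red", alpha = 0.45)
    }
  }
  p
}

#' Plot the cohort comparisons of a staged analysis report
#'
#' Group means with +/- 1 SD bars for every comparison of the report, one
#' facet per stage/factor, colored by significance at 0.05.
#'
#' @param object a `condyle_report` from [run_analysis_plan()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.condyle_report <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) stop("report holds no comparisons to plot", call. = FALSE)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, .data$stage, .data$factor, .data$outcome,
                     group = "yes", mean = .data$mean_yes, sd = .data$sd_yes,
                     significant = .data$significant),
    dplyr::transmute(df, .data$stage, .data$factor, .data$outcome,
                     group = "no", mean = .data$mean_no, sd = .data$sd_no,
                     significant = .data$significant)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$mean,
                                     fill = .data$group,
                                     alpha = .data$significant)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.45)) +
    ggplot2::facet_wrap(~ stage + factor, scales = "free_y") +
    ggplot2::labs(y = "volume change (voxels), mean +/- SD", x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
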