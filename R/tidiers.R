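#' Tidy a segmentation run
#'
#' @param x A `"heartseg_run"`.
#' @param ... Unused.
#' @return The per-slice report tibble (subject, slice, thresholds,
#'   silhouette scores, mask areas, status).
#' @export
tidy.heartseg_run <- function(x, ...) {
  x$report
}

#' One-row summary of a segmentation run
#'
#' @param x A `"heartseg_run"`.
#' @param ... Unused.
#' @return Tibble with one row: subject, slice counts, mean thresholds and
#'   silhouette scores over successful slices, mean heart-mask area.
#' @export
glance.heartseg_run <- function(x, ...) {
  ok <- x$report[x$report$status == "ok", ]
  tibble::tibble(
    subject = x$subject,
    n_slices = nrow(x$report),
    n_ok = nrow(ok),
    mean_tau_fg = mean(ok$tau_fg),
    mean_tau_spine = mean(ok$tau_spine),
    mean_sil_fg = mean(ok$sil_fg, na.rm = TRUE),
    mean_sil_spine = mean(ok$sil_spine, na.rm = TRUE),
    mean_heart_area = mean(ok$area_heart)
  )
}

#' Tidy evaluation metrics
#'
#' @param x A `"heartseg_metrics"`.
#' @param ... Unused.
#' @return Per-subject tibble with `subject` and `iou`.
#' @export
tidy.heartseg_metrics <- function(x, ...) x$per_subject

#' One-row summary of evaluation metrics
#'
#' @param x A `"heartseg_metrics"`.
#' @param ... Unused.
#' @return Tibble with `OA`, `mIoU`, `n_subjects`, `M`.
#' @export
glance.heartseg_metrics <- function(x, ...) {
  tibble::tibble(OA = x$OA, mIoU = x$mIoU,
                 n_subjects = nrow(x$per_subject), M = x$M)
}

#' Plot per-slice silhouette scores of a run
#'
#' @param object A `"heartseg_run"`.
#' @param ... Unused.
#' @return A ggplot: silhouette score against slice index for the
#'   foreground and spine clusterings.
#' @export
autoplot.heartseg_run <- function(object, ...) {
  df <- object$report |>
    dplyr::filter(.data$status == "ok") |>
    tidyr::pivot_longer(c("sil_fg", "sil_spine"), names_to = "filter",
                        values_to = "score") |>
    dplyr::mutate(filter = dplyr::recode(.data$filter, sil_fg = "foreground",
                                         sil_spine = "spine"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$score,
                                   colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "slice (cranial to caudal)", y = "silhouette score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a binary mask or a mask overlaid on a grayscale slice
#'
#' @param mask Binary matrix.
#' @param gray Optional grayscale matrix in \[0, 255\] drawn underneath.
#' @param title Optional plot title.
#' @return A ggplot raster plot (rows drawn top-down, as in an axial CT
#'   viewer).
#' @export
plot_mask <- function(mask, gray = NULL, title = NULL) {
  assert_binary_mask(mask)
  idx <- expand.grid(row = seq_len(nrow(mask)), col = seq_len(ncol(mask)))
  df <- tibble::tibble(row = idx$row, col = idx$col,
                       mask = as.vector(mask) == 1L)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row))
  if (!is.null(gray)) {
    df$gray <- as.vector(gray) / 255
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(alpha = .data$gray),
                                  fill = "grey20")
  }
  p +
    ggplot2::geom_raster(data = df[df$mask, ],
                         fill = "firebrick", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::guides(alpha = "none") +
    ggplot2::theme_void()
}
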