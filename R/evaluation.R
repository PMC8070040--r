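#' Classify a segmented image against ground truth
#'
#' Automated stand-in for visual inspection: an image counts as a true
#' positive when the prediction covers the target (pixel recall >=
#' `r_min`) without spilling excessively into non-target tissue (precision
#' >= `p_min`); as a false negative when it misses the target (recall <
#' `r_min`); and as a false positive otherwise (target covered but
#' over-segmented). Both evaluation modes are returned: `whole_heart`
#' (chambers + coronary margin + descending aorta) and `four_chamber`
#' (without the aorta).
#'
#' @param pred Predicted binary mask.
#' @param gt_whole Whole-heart ground truth (must contain `gt_chambers`).
#' @param gt_chambers Chambers-only ground truth.
#' @param r_min Recall threshold (default 0.8).
#' @param p_min Precision threshold (default 0.5).
#' @return Named character vector `c(whole_heart =, four_chamber =)` with
#'   values in `TP`, `FP`, `FN`.
#' @export
#' @examples
#' gt <- matrix(0L, 8, 8); gt[3:6, 3:6] <- 1L
#' classify_image(gt, gt, gt)
classify_image <- function(pred, gt_whole, gt_chambers,
                           r_min = 0.8, p_min = 0.5) {
  assert_binary_mask(pred, "pred")
  assert_binary_mask(gt_whole, "gt_whole")
  assert_binary_mask(gt_chambers, "gt_chambers")
  if (mask_empty(gt_whole) || mask_empty(gt_chambers)) {
    stop("empty ground-truth mask", call. = FALSE)
  }
  if (!mask_subset(gt_chambers, gt_whole)) {
    stop("`gt_chambers` must be a subset of `gt_whole`", call. = FALSE)
  }
  # Recall is scored against the mode's own target; precision ("does the
  # prediction spill into non-heart tissue?") is scored against the whole
  # heart in both modes, since the coronary margin is heart, not spill.
  precision <- if (sum(pred) == 0L) 0 else sum(pred * gt_whole) / sum(pred)
  one <- function(gt) {
    recall <- sum(pred * gt) / sum(gt)
    if (recall < r_min) "FN"
    else if (precision >= p_min) "TP"
    else "FP"
  }
  c(whole_heart = one(gt_whole), four_chamber = one(gt_chambers))
}

#' Image-level IoU of one subject
#'
#' `TP / (TP + FP + FN)` over the subject's per-image classification
#' outcomes (an image-count ratio, not a pixel-overlap ratio).
#'
#' @param tp,fp,fn Non-negative image counts, not all zero.
#' @return IoU in \[0, 1\].
#' @export
#' @examples
#' subject_iou(15, 5, 10)
subject_iou <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fp + fn == 0) {
    stop("IoU undefined for all-zero counts", call. = FALSE)
  }
  tp / (tp + fp + fn)
}

#' Overall accuracy and mean IoU over subjects
#'
#' `OA = sum(TP) / M` where `M` is the total image count, and `mIoU` the
#' unweighted mean of per-subject IoU values (subjects whose IoU is
#' undefined are excluded with a warning).
#'
#' @param counts Data frame with columns `subject`, `tp`, `fp`, `fn` and
#'   optionally `images` (per-subject image count; defaults to
#'   `tp + fp + fn`).
#' @return List of class `"heartseg_metrics"`: `per_subject` tibble
#'   (`subject`, `iou`), `mIoU`, `OA`, `M`.
#' @export
#' @examples
#' overall_metrics(data.frame(subject = c("a", "b"), tp = c(10, 0),
#'                            fp = 0, fn = c(0, 10)))
overall_metrics <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("subject", "tp", "fp", "fn") %in% names(counts)))
  if (nrow(counts) == 0L) stop("no subjects", call. = FALSE)
  images <- if ("images" %in% names(counts)) counts$images
            else counts$tp + counts$fp + counts$fn
  m_total <- sum(images)
  if (m_total == 0) stop("no images (M = 0)", call. = FALSE)
  defined <- counts$tp + counts$fp + counts$fn > 0
  if (any(!defined)) {
    warning(sum(!defined), " subject(s) with undefined IoU excluded",
            call. = FALSE)
  }
  per <- tibble::tibble(
    subject = counts$subject[defined],
    iou = mapply(subject_iou, counts$tp[defined], counts$fp[defined],
                 counts$fn[defined])
  )
  structure(
    list(per_subject = per, mIoU = mean(per$iou),
         OA = sum(counts$tp) / m_total, M = m_total),
    class = "heartseg_metrics"
  )
}

#' @export
print.heartseg_metrics <- function(x, ...) {
  cat(sprintf("OA = %.2f%%, mIoU = %.2f%% over %d subject(s), M = %d images\n",
              100 * x$OA, 100 * x$mIoU, nrow(x$per_subject), x$M))
  invisible(x)
}

#' Load per-image labels from a CSV file
#'
#' Supports the manual-inspection pathway: a CSV with columns `subject`,
#' `slice`, `mode` (`whole_heart` or `four_chamber`) and `label` (`TP`,
#' `FP`, `FN`) is aggregated into per-subject counts per mode.
#'
#' @param csv_path Path to the label CSV.
#' @return Tibble with columns `mode`, `subject`, `tp`, `fp`, `fn`.
#' @export
load_labels <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("subject", "slice", "mode", "label")
  if (!all(need %in% names(df)) || nrow(df) == 0L) {
    stop("label CSV needs non-empty columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$label %in% c("TP", "FP", "FN"))) {
    bad <- setdiff(unique(df$label), c("TP", "FP", "FN"))
    stop("unknown label token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("subject", "slice", "mode")])) {
    stop("duplicate (subject, slice, mode) rows", call. = FALSE)
  }
  df |>
    dplyr::count(.data$mode, .data$subject, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (nm in c("TP", "FP", "FN")) if (!nm %in% names(d)) d[[nm]] <- 0L
      d
    })() |>
    dplyr::transmute(.data$mode, .data$subject, tp = .data$TP, fp = .data$FP,
                     fn = .data$FN)
}

#' Evaluate a segmentation run against phantom ground truth
#'
#' Classifies every successfully segmented slice in both evaluation modes
#' and aggregates image counts and metrics.
#'
#' @param run A `"heartseg_run"`.
#' @param phantom The `"heartseg_phantom"` the run was computed on.
#' @param r_min,p_min Classification thresholds, see [classify_image()].
#' @return List: `labels` tibble (subject, slice, mode, label), `counts`
#'   tibble, `metrics` named list of `"heartseg_metrics"` per mode.
#' @export
evaluate_run <- function(run, phantom, r_min = 0.8, p_min = 0.5) {
  stopifnot(inherits(run, "heartseg_run"),
            inherits(phantom, "heartseg_phantom"))
  rows <- list()
  for (i in seq_along(run$slices)) {
    s <- run$slices[[i]]
    if (is.null(s$masks)) next
    lab <- classify_image(s$masks$heart, phantom$gt$heart_whole[, , i],
                          phantom$gt$heart_chambers[, , i], r_min, p_min)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject = run$subject, slice = i,
      mode = names(lab), label = unname(lab)
    )
  }
  labels <- dplyr::bind_rows(rows)
  counts <- labels |>
    dplyr::count(.data$mode, .data$subject, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (nm in c("TP", "FP", "FN")) {
    if (!nm %in% names(counts)) counts[[nm]] <- 0L
  }
  counts <- dplyr::transmute(counts, .data$mode, .data$subject,
                             tp = .data$TP, fp = .data$FP, fn = .data$FN)
  metrics <- lapply(split(counts, counts$mode), overall_metrics)
  list(labels = labels, counts = counts, metrics = metrics)
}

#' Pixel IoU between two masks
#'
#' Plain overlap ratio used for phantom validation (distinct from the
#' image-count IoU of [subject_iou()]).
#'
#' @param a,b Binary masks of equal shape.
#' @return `|a & b| / |a | b|` (1 when both are empty).
#' @export
pixel_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}
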