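#' Construct an HU volume
#'
#' A CT volume in Hounsfield units: a rows x cols x slices integer array,
#' axial slices ordered cranial to caudal. Values outside the representable
#' CT range \[-1024, 3071\] are clamped with a warning.
#'
#' @param data 3-D numeric array (rows, cols, slices) or a single matrix.
#' @param spacing Optional `(dz, dy, dx)` voxel spacing in mm, carried as
#'   metadata.
#' @param subject_id Subject identifier string.
#' @return Object of class `"hu_volume"`.
#' @export
hu_volume <- function(data, spacing = NULL, subject_id = "subject") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a rows x cols x slices array", call. = FALSE)
  }
  if (dim(data)[3] < 1L) stop("volume needs at least one slice", call. = FALSE)
  storage.mode(data) <- "integer"
  if (anyNA(data)) stop("HU values must not contain NA", call. = FALSE)
  if (any(data < HU_MIN | data > HU_MAX)) {
    warning(sprintf("HU values outside [%d, %d] clamped", HU_MIN, HU_MAX),
            call. = FALSE)
    data[data < HU_MIN] <- HU_MIN
    data[data > HU_MAX] <- HU_MAX
  }
  structure(list(data = data, spacing = spacing, subject_id = subject_id),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("HU volume '%s': %d x %d x %d slices, range [%d, %d]\n",
              x$subject_id, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.hu_volume <- function(x) dim(x$data)

n_slices <- function(vol) dim(vol$data)[3]

#' Read a DICOM series directory into an HU volume
#'
#' Reads every single-frame CT DICOM file in `dir_path`, applies the rescale
#' slope/intercept to obtain Hounsfield units and stacks the slices sorted
#' by the image-position z coordinate (falling back to instance number, then
#' file name, when z is absent).
#'
#' @param dir_path Directory containing one DICOM file per axial slice.
#' @param pattern Regular expression selecting the files (default `.dcm`).
#' @return An [hu_volume()].
#' @export
read_dicom_series <- function(dir_path, pattern = "\\.dcm$") {
  files <- list.files(dir_path, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) {
    stop("no DICOM files found in ", dir_path, call. = FALSE)
  }
  slices <- lapply(files, dcm_read_file)
  shapes <- vapply(slices, function(s) paste(dim(s$hu), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent slice shapes in series: ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  }
  z <- vapply(slices, function(s) s$z, numeric(1))
  inst <- vapply(slices, function(s) as.numeric(s$instance), numeric(1))
  ord <- if (!anyNA(z)) order(z)
         else if (!anyNA(inst)) order(inst)
         else seq_along(slices)
  slices <- slices[ord]
  data <- array(0L, dim = c(dim(slices[[1]]$hu), length(slices)))
  for (i in seq_along(slices)) data[, , i] <- as.integer(round(slices[[i]]$hu))
  first <- slices[[1]]
  spacing <- NULL
  if (!anyNA(first$spacing) && !is.na(first$thickness)) {
    spacing <- c(dz = first$thickness, dy = first$spacing[1],
                 dx = first$spacing[2])
  }
  subject <- if (!is.na(first$subject)) first$subject else "subject"
  hu_volume(data, spacing = spacing, subject_id = subject)
}

#' Keep the first n axial slices
#'
#' Returns the first `min(n_slices, N)` slices in order (the study protocol
#' trims every volume to its first 56 slices, which cover the heart).
#'
#' @param vol An [hu_volume()].
#' @param n_slices Number of slices to keep (>= 1).
#' @return An [hu_volume()].
#' @export
trim_volume <- function(vol, n_slices = 56L) {
  stopifnot(inherits(vol, "hu_volume"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  keep <- seq_len(min(n_slices, dim(vol$data)[3]))
  hu_volume(vol$data[, , keep, drop = FALSE], spacing = vol$spacing,
            subject_id = vol$subject_id)
}

#' Convert an HU volume to grayscale
#'
#' Range normalization `X = 255 (Y - Ymin) / (Ymax - Ymin)`, rounded half-up
#' to integers in \[0, 255\]. By default `Ymin`/`Ymax` are the per-volume
#' extremes, so the darkest voxel maps to 0 and the brightest to 255. A
#' fixed `window = c(lo, hi)` clamps to the window first and normalizes with
#' those endpoints instead, for cross-volume comparability.
#'
#' @param vol An [hu_volume()].
#' @param window Optional fixed HU window `c(lo, hi)`.
#' @return Integer array (rows x cols x slices) of class `"gray_volume"`.
#' @export
to_grayscale <- function(vol, window = NULL) {
  stopifnot(inherits(vol, "hu_volume"))
  y <- vol$data
  if (is.null(window)) {
    lo <- min(y); hi <- max(y)
    if (hi == lo) {
      stop("constant volume: grayscale normalization undefined", call. = FALSE)
    }
  } else {
    if (length(window) != 2L || window[2] <= window[1]) {
      stop("`window` must be c(lo, hi) with hi > lo", call. = FALSE)
    }
    lo <- window[1]; hi <- window[2]
    y[y < lo] <- lo
    y[y > hi] <- hi
  }
  g <- floor(255 * (as.numeric(y) - lo) / (hi - lo) + 0.5)  # round half-up
  out <- array(as.integer(g), dim = dim(y))
  class(out) <- "gray_volume"
  out
}

gray_slice <- function(gray, i) {
  unclass(gray)[, , i]
}

#' Write a binary mask (or stack) to PNG or NIfTI
#'
#' PNG masks are 8-bit \{0, 255\}; NIfTI masks are uint8 \{0, 1\}. A 3-D
#' stack written to PNG produces one file per slice with a zero-padded slice
#' index appended to the base name. Reading the file(s) back with
#' [read_mask()] reproduces the input exactly.
#'
#' @param mask Binary matrix or rows x cols x slices array.
#' @param path Output path (for PNG stacks, the base name; `_%03d.png` is
#'   appended per slice).
#' @param format `"png"` or `"nifti"`.
#' @return Invisibly, the path(s) written.
#' @export
write_mask <- function(mask, path, format = c("png", "nifti")) {
  format <- match.arg(format)
  is_stack <- is.array(mask) && length(dim(mask)) == 3L
  if (!is_stack) assert_binary_mask(mask)
  if (format == "nifti") {
    arr <- if (is_stack) mask else array(mask, dim = c(dim(mask), 1L))
    storage.mode(arr) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
    return(invisible(path))
  }
  if (is_stack) {
    base <- sub("\\.png$", "", path)
    paths <- character(dim(mask)[3])
    for (i in seq_len(dim(mask)[3])) {
      paths[i] <- sprintf("%s_%03d.png", base, i)
      png::writePNG(mask[, , i] + 0, paths[i])   # writePNG wants doubles
    }
    return(invisible(paths))
  }
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path A PNG or NIfTI file.
#' @return Binary matrix (or array, for multi-slice NIfTI).
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(matrix(as.integer(img > 0.5), nrow(img), ncol(img)))
  }
  arr <- RNifti::readNifti(path)
  arr <- array(as.integer(arr != 0), dim = dim(arr))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  arr
}

#' Write a grayscale image or segmented HU slice preview to PNG
#'
#' Utility for saving per-slice previews; grayscale values are scaled from
#' \[0, 255\] to the unit range PNG expects.
#'
#' @param img Integer matrix in \[0, 255\].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
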