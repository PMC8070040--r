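#' Phantom specification
#'
#' Parameters of the synthetic chest-CT phantom: volume shape, per-organ
#' Hounsfield units, noise level, the slice at which the liver starts to
#' replace the receding lung bases, and table-artifact streaks. Defaults
#' emulate the acquisition the pipeline targets: 512 x 512 axial slices, 56
#' slices cranial to caudal, air around -1000 HU, lungs -700 HU, fat
#' -100 HU, myocardium +35 HU, vertebral bone 400-1000 HU, liver +60 HU.
#'
#' @param n_slices Number of axial slices (default 56).
#' @param shape `(rows, cols)` of each slice (default 512 x 512; tests use
#'   smaller frames).
#' @param hu_values Named HU map for organs: `air`, `lung`, `fat`, `muscle`,
#'   `heart`, `spine`, `da`, `liver`.
#' @param noise_sd Gaussian HU noise standard deviation inside the body
#'   (default 10).
#' @param liver_onset_slice First slice on which the lungs recede and the
#'   liver appears (default 31); set to `n_slices + 1` to disable.
#' @param bottom_streaks Draw random 1-pixel table-artifact lines in the
#'   bottom rows outside the body (default TRUE).
#' @param seed Integer seed; identical spec + seed give bit-identical
#'   volumes.
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_slices = 56L,
                         shape = c(512L, 512L),
                         hu_values = c(air = -1000, lung = -700, fat = -100,
                                       muscle = 40, heart = 35, spine = 700,
                                       da = 40, liver = 60),
                         noise_sd = 10,
                         liver_onset_slice = 31L,
                         bottom_streaks = TRUE,
                         seed = 0L) {
  n_slices <- as.integer(n_slices)
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  if (any(shape < 64L)) {
    stop("frame too small to place all organs (need >= 64 x 64)", call. = FALSE)
  }
  needed <- c("air", "lung", "fat", "muscle", "heart", "spine", "da", "liver")
  if (!all(needed %in% names(hu_values))) {
    stop("`hu_values` must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(hu_values < HU_MIN | hu_values > HU_MAX)) {
    stop("organ HU values must lie in [-1024, 3071]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  liver_onset_slice <- as.integer(liver_onset_slice)
  if (liver_onset_slice > n_slices + 1L || liver_onset_slice < 1L) {
    stop("`liver_onset_slice` must lie in [1, n_slices + 1]", call. = FALSE)
  }
  structure(
    list(n_slices = n_slices, shape = shape, hu_values = hu_values,
         noise_sd = noise_sd, liver_onset_slice = liver_onset_slice,
         bottom_streaks = isTRUE(bottom_streaks), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Organ geometry as fractions of the frame (x: columns, y: rows, origin
# top-left). Proportions follow a mid-thoracic axial section: each lung is
# an upper lobe drawn as a rounded-rectangular superellipse whose medial
# border hugs the cardiac silhouette (tops level with it, as the lungs wrap
# the heart), plus a lower lobe reaching down beside the vertebral column;
# the cardiac envelope (chambers plus pericardial/coronary margin) sits
# medially, the descending aorta left of midline between heart and spine,
# and the vertebral body begins at the heart's lower border.
phantom_geometry <- function() {
  list(
    body       = list(cx = 0.50, cy = 0.54, a = 0.46, b = 0.41),
    muscle_in  = 0.86, muscle_out = 0.97,      # subcostal muscle annulus
    lung_upper = list(dx = 0.275, cy = 0.52, a = 0.125, b = 0.155, p = 6),
    lung_lower = list(dx = 0.285, cy = 0.73, a = 0.110, b = 0.085, p = 2),
    chambers   = list(cx = 0.50, cy = 0.52, a = 0.110, b = 0.125),
    envelope   = list(cx = 0.50, cy = 0.52, a = 0.1450, b = 0.155, p = 6),
    da         = list(cx = 0.44, cy = 0.70, r = 0.020),
    spine      = list(cx = 0.50, cy = 0.725, r = 0.045)
  )
}

ellipse_mask <- function(fx, fy, cx, cy, a, b, p = 2) {
  m <- (abs(fx - cx) / a)^p + (abs(fy - cy) / b)^p <= 1
  matrix(as.integer(m), nrow(fx), ncol(fx))
}

#' Generate a labeled synthetic chest-CT phantom
#'
#' Builds an HU volume with ground-truth masks for body, lungs, whole heart
#' (chambers + coronary margin + descending aorta), heart chambers, spine
#' and liver. From `liver_onset_slice` onwards the lung lobes shrink
#' linearly and liver tissue (heart-like HU, deliberately so) fills the
#' right lung bed, reproducing the caudal-slice failure mode of lung-hull
#' based segmentation. Gaussian HU noise is added inside the body; optional
#' 1-pixel streak lines appear near the bottom of the frame outside the
#' body.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `"heartseg_phantom"`: list with `hu` (an
#'   [hu_volume()]), `gt` (named list of rows x cols x slices 0/1 arrays:
#'   `body`, `lungs`, `heart_whole`, `heart_chambers`, `spine`, `liver`) and
#'   the `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 2, shape = 96, seed = 1))
#' dim(ph$hu)
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]; n <- spec$n_slices
  hu <- spec$hu_values
  g <- phantom_geometry()

  fy <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)
  fx <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)

  body <- ellipse_mask(fx, fy, g$body$cx, g$body$cy, g$body$a, g$body$b)
  muscle <- ellipse_mask(fx, fy, g$body$cx, g$body$cy,
                         g$muscle_out * g$body$a, g$muscle_out * g$body$b) -
            ellipse_mask(fx, fy, g$body$cx, g$body$cy,
                         g$muscle_in * g$body$a, g$muscle_in * g$body$b)
  chambers <- ellipse_mask(fx, fy, g$chambers$cx, g$chambers$cy,
                           g$chambers$a, g$chambers$b)
  envelope <- ellipse_mask(fx, fy, g$envelope$cx, g$envelope$cy,
                           g$envelope$a, g$envelope$b, p = g$envelope$p)
  da <- ellipse_mask(fx, fy, g$da$cx, g$da$cy, g$da$r * nc / nr, g$da$r)
  spine <- ellipse_mask(fx, fy, g$spine$cx, g$spine$cy,
                        g$spine$r * nc / nr, g$spine$r)
  heart_whole <- as_mask(envelope | da)

  # Caudal lung remnants both shrink and sink towards the posterior lung
  # base (row fraction 0.80), so that near the liver the hull of what is
  # left of the lungs no longer surrounds the heart -- the failure mode the
  # cross-slice hull refinement exists for.
  lung_one <- function(side, scale = 1) {
    up <- g$lung_upper; lo <- g$lung_lower
    sink <- function(cy) cy + (1 - scale) * (0.80 - cy)
    as_mask(
      ellipse_mask(fx, fy, 0.5 + side * up$dx, sink(up$cy),
                   up$a * scale, up$b * scale, p = up$p) |
      ellipse_mask(fx, fy, 0.5 + side * lo$dx, sink(lo$cy),
                   lo$a * scale, lo$b * scale, p = lo$p)
    )
  }
  left_full <- lung_one(-1); right_full <- lung_one(+1)

  # vertebral bone: vertical density gradient, brightest superiorly,
  # re-centered so the pre-noise mean equals the nominal spine HU
  spine_vals <- function() {
    sel <- spine == 1L
    t <- (fy[sel] - (g$spine$cy - g$spine$r)) / (2 * g$spine$r)
    v <- 1000 - 600 * pmin(pmax(t, 0), 1)^2
    v + (hu[["spine"]] - mean(v))
  }

  base_slice <- function(lungs_l, lungs_r, liver) {
    y <- matrix(hu[["air"]], nr, nc)
    y[body == 1L] <- hu[["fat"]]
    y[muscle == 1L] <- hu[["muscle"]]
    y[liver == 1L] <- hu[["liver"]]
    y[lungs_l == 1L | lungs_r == 1L] <- hu[["lung"]]
    y[chambers == 1L] <- hu[["heart"]]
    y[da == 1L] <- hu[["da"]]
    y[spine == 1L] <- spine_vals()
    y
  }

  data <- array(0L, dim = c(nr, nc, n))
  gt_lungs <- array(0L, dim = c(nr, nc, n))
  gt_liver <- array(0L, dim = c(nr, nc, n))

  with_local_seed(spec$seed, {
    for (i in seq_len(n)) {
      if (i >= spec$liver_onset_slice) {
        f <- (i - spec$liver_onset_slice + 1) /
             (n - spec$liver_onset_slice + 1)
        scale <- 1 - 0.9 * f
        ll <- lung_one(-1, scale); lr <- lung_one(+1, scale)
        liver <- as_mask(right_full & !lr)   # liver fills the vacated bed
      } else {
        ll <- left_full; lr <- right_full
        liver <- matrix(0L, nr, nc)
      }
      y <- base_slice(ll, lr, liver)
      if (spec$noise_sd > 0) {
        inside <- body == 1L
        y[inside] <- y[inside] + rnorm(sum(inside), 0, spec$noise_sd)
      }
      if (spec$bottom_streaks) {
        n_streak <- sample(2:4, 1L)
        for (s in seq_len(n_streak)) {
          row <- max(1L, min(nr, round(nr * runif(1, 0.90, 0.99))))
          len <- round(nc * runif(1, 0.10, 0.30))
          start <- sample.int(max(1L, nc - len), 1L)
          cols <- start:(start + len - 1L)
          out_body <- cols[body[row, cols] == 0L]
          y[row, out_body] <- hu[["muscle"]]
        }
      }
      y <- pmin(pmax(round(y), HU_MIN), HU_MAX)
      data[, , i] <- as.integer(y)
      gt_lungs[, , i] <- as_mask(ll | lr)
      gt_liver[, , i] <- liver
    }
  })

  rep_slice <- function(m) array(rep(m, n), dim = c(nr, nc, n))
  structure(
    list(
      hu = hu_volume(data, spacing = c(dz = 2.5, dy = 250 / nr, dx = 250 / nc),
                     subject_id = sprintf("phantom%03d", spec$seed)),
      gt = list(
        body = rep_slice(body),
        lungs = gt_lungs,
        heart_whole = rep_slice(heart_whole),
        heart_chambers = rep_slice(chambers),
        spine = rep_slice(spine),
        liver = gt_liver
      ),
      spec = spec
    ),
    class = "heartseg_phantom"
  )
}

#' @export
print.heartseg_phantom <- function(x, ...) {
  d <- dim(x$hu$data)
  cat(sprintf("Synthetic chest-CT phantom: %d x %d x %d (seed %d)\n",
              d[1], d[2], d[3], x$spec$seed))
  cat("  ground truth:", paste(names(x$gt), collapse = ", "), "\n")
  invisible(x)
}

#' Write a phantom as a DICOM series
#'
#' One single-frame CT DICOM file per axial slice (explicit VR little
#' endian), with rescale slope 1 / intercept -1024, 2.5 mm slice spacing
#' encoded in the z positions, and zero-padded instance numbering. Reading
#' the directory back with [read_dicom_series()] reproduces the HU volume
#' exactly.
#'
#' @param phantom A `"heartseg_phantom"` (or any [hu_volume()] via `vol`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_phantom_dicom <- function(phantom, dir) {
  vol <- if (inherits(phantom, "heartseg_phantom")) phantom$hu else phantom
  stopifnot(inherits(vol, "hu_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_slices(vol)
  series <- dcm_uid(paste0("2.", abs(sum(as.numeric(vol$data[, , 1]))) %% 1e6))
  dz <- if (!is.null(vol$spacing)) vol$spacing[["dz"]] else 2.5
  dy <- if (!is.null(vol$spacing)) vol$spacing[["dy"]] else 1
  dx <- if (!is.null(vol$spacing)) vol$spacing[["dx"]] else 1
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.dcm", vol$subject_id, i))
    dcm_write_slice(vol$data[, , i], paths[i], instance = i, z = (i - 1) * dz,
                    subject = vol$subject_id, series_uid = series,
                    spacing = c(dy, dx), thickness = dz)
  }
  invisible(paths)
}

#' Write a phantom's HU volume and ground-truth masks as NIfTI
#'
#' @param phantom A `"heartseg_phantom"`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "heartseg_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "hu.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$hu$data), paths)
  for (nm in names(phantom$gt)) {
    p <- file.path(dir, paste0("gt_", nm, ".nii.gz"))
    write_mask(phantom$gt[[nm]], p, format = "nifti")
    paths <- c(paths, p)
  }
  invisible(paths)
}
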