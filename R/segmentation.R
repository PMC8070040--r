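#' Segmentation configuration
#'
#' Tunables of the cascade. Defaults follow the published pipeline where it
#' states them (56 slices, k = 2 foreground / k = 3 spine clusters, two
#' morphology iterations, strict threshold inequalities) and library
#' conventions elsewhere.
#'
#' @param n_slices Slices retained from the cranial end (default 56).
#' @param seed Seed for the K-Means restarts.
#' @param n_init K-Means restarts per clustering.
#' @param selem Structuring element, `"cross3"` or `"square3"`.
#' @param n_iter Morphology iterations (default 2).
#' @param hull_mode `"exact"` filled convex hull or the `"hitmiss"`
#'   iterative approximation.
#' @param spine_hull_side Which side(s) of the spine-top x coordinate the
#'   spine-hull fill extends to below the spine top: `"both"` (default),
#'   `"left"`, or `"right"`. The literal formulation fills only the left
#'   side; `"both"` matches the intended symmetric suppression.
#' @param spine_kmeans_scope `"all"` clusters every pixel of the injected
#'   image (zeros outside the mediastinal mask included); `"roi"` clusters
#'   only pixels inside it.
#' @param spine_silhouette_scope `"roi"` (default) scores the spine
#'   clustering over mediastinal pixels only, so the injected zeros do not
#'   dominate; `"all"` scores every pixel.
#' @param refine Apply the cross-slice lung-hull refinement (default TRUE).
#' @param window Optional fixed HU window passed to [to_grayscale()].
#' @return List of class `"heartseg_config"`.
#' @export
seg_config <- function(n_slices = 56L, seed = 0L, n_init = 10L,
                       selem = "cross3", n_iter = 2L,
                       hull_mode = c("exact", "hitmiss"),
                       spine_hull_side = c("both", "left", "right"),
                       spine_kmeans_scope = c("all", "roi"),
                       spine_silhouette_scope = c("roi", "all"),
                       refine = TRUE, window = NULL) {
  structure(
    list(
      n_slices = as.integer(n_slices), seed = as.integer(seed),
      n_init = as.integer(n_init),
      morph = morph_config(selem, n_iter),
      hull_mode = match.arg(hull_mode),
      spine_hull_side = match.arg(spine_hull_side),
      spine_kmeans_scope = match.arg(spine_kmeans_scope),
      spine_silhouette_scope = match.arg(spine_silhouette_scope),
      refine = isTRUE(refine), window = window
    ),
    class = "heartseg_config"
  )
}

#' Foreground stage: body mask and its convex hull
#'
#' k = 2 K-Means over the slice's intensity histogram separates air from
#' tissue; the threshold is the mean of the two centroids. The strict
#' `X > tau` mask is opened twice (removing table-artifact streak lines)
#' and convex-hulled to cover the whole body cross-section.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param cfg A [seg_config()].
#' @return List: `fg` (opened foreground), `fg_hull`, `tau_fg`, `sil_fg`,
#'   `centroids`.
#' @export
foreground_stage <- function(gray, cfg = seg_config()) {
  hist <- intensity_histogram(gray)
  cent <- kmeans_1d(hist, k = 2L, seed = cfg$seed, n_init = cfg$n_init)
  tau <- foreground_threshold(cent)
  sil <- silhouette_1d(hist, cent)$mean_score
  f <- matrix(as.integer(gray > tau), nrow(gray), ncol(gray))
  f <- opening_n(f, cfg$morph)
  if (mask_empty(f)) stop("foreground mask empty after opening", call. = FALSE)
  list(fg = f, fg_hull = convex_hull(f, cfg$hull_mode), tau_fg = tau,
       sil_fg = sil, centroids = cent)
}

#' Lung stage: lung mask and its convex hull
#'
#' Pixels outside the foreground hull are forced to 255 so only dark pixels
#' inside the body can become lung; the strict `E < tau_fg` mask is closed
#' twice (filling vessel holes) and convex-hulled. An empty lung mask is a
#' signal (the refinement supplies a fallback hull), not an error.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param fg_hull Foreground convex hull from [foreground_stage()].
#' @param tau_fg Foreground threshold.
#' @param cfg A [seg_config()].
#' @return List: `lung` (mask, possibly empty), `lung_hull` (NULL when
#'   empty).
#' @export
lung_stage <- function(gray, fg_hull, tau_fg, cfg = seg_config()) {
  if (mask_empty(fg_hull)) stop("empty foreground hull", call. = FALSE)
  e <- gray
  e[fg_hull == 0L] <- 255L
  l <- matrix(as.integer(e < tau_fg), nrow(gray), ncol(gray))
  l <- closing_n(l, cfg$morph)
  if (mask_empty(l)) {
    return(list(lung = l, lung_hull = NULL))
  }
  list(lung = l, lung_hull = convex_hull(l, cfg$hull_mode))
}

#' Cross-slice lung-hull refinement state and update
#'
#' Processing slices cranial to caudal, the last slice whose lungs still
#' surrounded the heart ("lungs-well-surrounded") is remembered via the top
#' row of its lung mask. When the current lung top row sits lower in the
#' frame (the lungs are receding towards the liver), the remembered hull is
#' OR-ed into the current one; otherwise the current hull becomes the new
#' reference. An empty lung mask falls back to the reference hull entirely.
#'
#' @param lung Current lung mask (may be empty).
#' @param lung_hull Current lung hull, or NULL when `lung` is empty.
#' @param state Refinement state (NULL initially): list with `ref_hull`,
#'   `ref_top_row`, `ref_slice_index`.
#' @param slice_index Current slice number.
#' @return List `(hull, state)` with the refined hull and updated state.
#' @export
refine_lung_hull <- function(lung, lung_hull, state, slice_index) {
  if (mask_empty(lung) || is.null(lung_hull)) {
    if (is.null(state)) {
      stop("no lungs found and no reference hull available", call. = FALSE)
    }
    return(list(hull = state$ref_hull, state = state))
  }
  y0 <- unname(region_anchors(lung)$top["y"])
  if (is.null(state)) {
    state <- list(ref_hull = lung_hull, ref_top_row = y0,
                  ref_slice_index = slice_index)
    return(list(hull = lung_hull, state = state))
  }
  if (y0 > state$ref_top_row) {
    # lungs receding: combine the remembered hull with the current one
    hull <- as_mask(lung_hull | state$ref_hull)
    list(hull = hull, state = state)
  } else {
    state <- list(ref_hull = lung_hull, ref_top_row = y0,
                  ref_slice_index = slice_index)
    list(hull = lung_hull, state = state)
  }
}

#' Intermediate (mediastinal) mask
#'
#' The lung hull minus the lungs: the mediastinal region containing the
#' heart, descending aorta and the upper spine.
#'
#' @param lung_hull Lung convex hull.
#' @param lung Lung mask.
#' @return Binary matrix `lung_hull AND NOT lung`.
#' @export
intermediate_stage <- function(lung_hull, lung) {
  stopifnot(all(dim(lung_hull) == dim(lung)))
  as_mask(lung_hull & !lung)
}

#' Spine stage: spine mask and its downward-filled hull
#'
#' Pixels outside the mediastinal mask are forced to 0; k = 3 K-Means
#' separates injected background, soft tissue and bone, and the strict
#' `E > max(centroid)` mask selects bone. After opening and closing, the
#' top `(x0, y0)` and centroid `(xc, yc)` of the largest component anchor
#' the fill: every pixel below the spine top (on the configured side(s) of
#' `x0`) and every full row below the centroid row is set, suppressing the
#' spine and everything beneath it. An empty spine mask yields an empty
#' fill (the heart mask then proceeds without spine suppression).
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param intermediate Mediastinal mask from [intermediate_stage()].
#' @param cfg A [seg_config()].
#' @return List: `spine` (mask), `spine_hull` (fill), `tau_spine`,
#'   `sil_spine`, `anchors` (NULL when no spine found).
#' @export
spine_stage <- function(gray, intermediate, cfg = seg_config()) {
  if (mask_empty(intermediate)) {
    stop("empty intermediate mask: no mediastinal region", call. = FALSE)
  }
  e <- gray
  e[intermediate == 0L] <- 0L
  hist_all <- intensity_histogram(e)
  hist_roi <- intensity_histogram(e[intermediate == 1L])
  hist_km <- if (cfg$spine_kmeans_scope == "all") hist_all else hist_roi
  cent <- kmeans_1d(hist_km, k = 3L, seed = cfg$seed, n_init = cfg$n_init)
  tau <- spine_threshold(cent)
  hist_sil <- if (cfg$spine_silhouette_scope == "roi") hist_roi else hist_all
  sil <- silhouette_restricted(hist_sil, cent)
  s <- matrix(as.integer(e > tau), nrow(gray), ncol(gray))
  s <- opening_n(s, cfg$morph)
  s <- closing_n(s, cfg$morph)
  p <- matrix(0L, nrow(gray), ncol(gray))
  anchors <- NULL
  if (!mask_empty(s)) {
    anchors <- region_anchors(s)
    p <- spine_fill(s, side = cfg$spine_hull_side)
  }
  list(spine = s, spine_hull = p, tau_spine = tau, sil_spine = sil,
       anchors = anchors)
}

#' Downward fill of a spine mask
#'
#' Builds the spine suppression mask from a detected spine mask: starting
#' from the mask itself, every pixel below the spine-top row (on the
#' configured side(s) of the spine-top column) is set, and then every full
#' row below the centroid row. Anchors come from the largest 8-connected
#' component.
#'
#' @param s Non-empty spine mask.
#' @param side `"both"` (default), `"left"` or `"right"` of the spine-top
#'   column for the first fill clause.
#' @return Binary matrix.
#' @export
spine_fill <- function(s, side = c("both", "left", "right")) {
  side <- match.arg(side)
  assert_binary_mask(s)
  if (mask_empty(s)) stop("empty spine mask", call. = FALSE)
  anchors <- region_anchors(s)
  x0 <- anchors$top["x"]; y0 <- anchors$top["y"]; yc <- anchors$centroid["y"]
  p <- s
  rows_below <- seq_len(nrow(p)) > y0
  cols_sel <- switch(side,
    both = rep(TRUE, ncol(p)),
    left = seq_len(ncol(p)) < x0,
    right = seq_len(ncol(p)) > x0
  )
  p[rows_below, cols_sel] <- 1L
  p[seq_len(nrow(p)) > yc, ] <- 1L
  p
}

# Silhouette over the clusters actually populated in the scoring scope:
# when scoring is restricted to the mediastinal region, the injected-zero
# background cluster usually has no members there and is dropped; NA when
# fewer than two populated clusters remain.
silhouette_restricted <- function(hist, centroids) {
  counts <- hist_as_counts(hist)
  vals <- which(counts > 0L) - 1L
  if (length(vals) == 0L) return(NA_real_)
  cv <- sort(centroid_values(centroids))
  lab <- nearest_center(as.numeric(vals), cv)
  keep <- sort(unique(lab))
  if (length(keep) < 2L) return(NA_real_)
  tryCatch(silhouette_1d(hist, cv[keep])$mean_score,
           error = function(e) NA_real_)
}

#' Heart mask
#'
#' The mediastinal mask minus the spine fill.
#'
#' @param intermediate Mediastinal mask.
#' @param spine_hull Spine fill from [spine_stage()].
#' @return Binary matrix `intermediate AND NOT spine_hull`.
#' @export
heart_stage <- function(intermediate, spine_hull) {
  stopifnot(all(dim(intermediate) == dim(spine_hull)))
  as_mask(intermediate & !spine_hull)
}

#' Extract segmented heart HU pixels
#'
#' HU values are kept where the heart mask is set; everything else becomes
#' -1000 (air).
#'
#' @param hu_slice Integer HU matrix.
#' @param heart Heart mask.
#' @return Integer HU matrix.
#' @export
extract_heart <- function(hu_slice, heart) {
  stopifnot(all(dim(hu_slice) == dim(heart)))
  z <- hu_slice
  z[heart == 0L] <- -1000L
  z
}

#' Run the full cascade over a CT volume
#'
#' Trims to `cfg$n_slices`, converts the whole volume to grayscale once,
#' then runs foreground, lung, refinement, intermediate, spine and heart
#' stages slice by slice in cranial-to-caudal order with a shared
#' refinement state. Per-slice failures are logged in the report (status
#' column) and do not abort the volume.
#'
#' @param vol An [hu_volume()].
#' @param cfg A [seg_config()].
#' @return Object of class `"heartseg_run"`: list with `slices` (per-slice
#'   mask lists), `report` (tibble: subject, slice, thresholds, silhouette
#'   scores, mask areas, status), `config`, `subject`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 1, shape = 96, seed = 1))
#' run <- run_volume(ph$hu, seg_config(n_slices = 1))
#' run$report$status
run_volume <- function(vol, cfg = seg_config()) {
  stopifnot(inherits(vol, "hu_volume"))
  vol <- trim_volume(vol, cfg$n_slices)
  gray <- to_grayscale(vol, window = cfg$window)
  n <- n_slices(vol)
  state <- NULL
  slices <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gray_slice(gray, i)
    res <- tryCatch({
      fg <- foreground_stage(g, cfg)
      lg <- lung_stage(g, fg$fg_hull, fg$tau_fg, cfg)
      if (cfg$refine) {
        rf <- refine_lung_hull(lg$lung, lg$lung_hull, state, i)
        state <- rf$state
        u <- rf$hull
      } else {
        if (is.null(lg$lung_hull)) stop("empty lung mask", call. = FALSE)
        u <- lg$lung_hull
      }
      im <- intermediate_stage(u, lg$lung)
      sp <- spine_stage(g, im, cfg)
      h <- heart_stage(im, sp$spine_hull)
      # cascade invariants
      stopifnot(mask_subset(h, im), mask_subset(im, u),
                sum(lg$lung * im) == 0L, sum(h * sp$spine_hull) == 0L)
      list(
        masks = list(foreground = fg$fg, foreground_hull = fg$fg_hull,
                     lung = lg$lung, lung_hull = u, intermediate = im,
                     spine = sp$spine, spine_hull = sp$spine_hull, heart = h),
        thresholds = c(tau_fg = fg$tau_fg, tau_spine = sp$tau_spine),
        silhouettes = c(fg = fg$sil_fg, spine = sp$sil_spine),
        segmented_hu = extract_heart(vol$data[, , i], h),
        status = "ok"
      )
    }, error = function(e) list(masks = NULL, status = paste0("failed: ",
                                                              conditionMessage(e))))
    slices[[i]] <- res
    area <- function(nm) if (is.null(res$masks)) NA_integer_
                         else sum(res$masks[[nm]])
    rows[[i]] <- tibble::tibble(
      subject = vol$subject_id, slice = i,
      tau_fg = if (is.null(res$masks)) NA_real_ else res$thresholds[["tau_fg"]],
      tau_spine = if (is.null(res$masks)) NA_real_
                  else res$thresholds[["tau_spine"]],
      sil_fg = if (is.null(res$masks)) NA_real_ else res$silhouettes[["fg"]],
      sil_spine = if (is.null(res$masks)) NA_real_
                  else res$silhouettes[["spine"]],
      area_foreground = area("foreground"), area_lung = area("lung"),
      area_lung_hull = area("lung_hull"),
      area_intermediate = area("intermediate"), area_spine = area("spine"),
      area_heart = area("heart"), status = res$status
    )
  }
  structure(
    list(slices = slices, report = dplyr::bind_rows(rows), config = cfg,
         subject = vol$subject_id),
    class = "heartseg_run"
  )
}

#' @export
print.heartseg_run <- function(x, ...) {
  ok <- sum(x$report$status == "ok")
  cat(sprintf("heartseg run '%s': %d/%d slices segmented\n", x$subject,
              ok, nrow(x$report)))
  invisible(x)
}

#' Heart mask stack of a run
#'
#' @param run A `"heartseg_run"`.
#' @return rows x cols x slices 0/1 array (failed slices all zero).
#' @export
heart_mask_stack <- function(run) {
  stopifnot(inherits(run, "heartseg_run"))
  ok <- which(run$report$status == "ok")
  if (length(ok) == 0L) stop("no successfully segmented slices", call. = FALSE)
  d <- dim(run$slices[[ok[1]]]$masks$heart)
  out <- array(0L, dim = c(d, length(run$slices)))
  for (i in seq_along(run$slices)) {
    if (!is.null(run$slices[[i]]$masks)) {
      out[, , i] <- run$slices[[i]]$masks$heart
    }
  }
  out
}

#' Aggregate silhouette scores over slice ranges
#'
#' Summarizes per-slice silhouette scores (foreground clustering, spine
#' clustering, and both pooled) over slice ranges, reporting min, max, mean
#' and sample standard deviation per range and filter.
#'
#' @param report Report tibble from [run_volume()] (rows from several
#'   subjects may be concatenated).
#' @param ranges List of `c(first, last)` slice ranges; default the study's
#'   three cases: 1-30, 31-56, 1-56.
#' @return Tibble with columns `range`, `filter`, `n`, `min`, `max`,
#'   `mean`, `sd`.
#' @export
aggregate_silhouette <- function(report,
                                 ranges = list(c(1L, 30L), c(31L, 56L),
                                               c(1L, 56L))) {
  stopifnot(is.data.frame(report), nrow(report) > 0)
  out <- list()
  for (rg in ranges) {
    sel <- report$slice >= rg[1] & report$slice <= rg[2]
    sub <- report[sel & report$status == "ok", ]
    label <- sprintf("%d-%d", rg[1], rg[2])
    if (nrow(sub) == 0L) {
      warning("no slices in range ", label, "; skipped", call. = FALSE)
      next
    }
    pools <- list(
      foreground = sub$sil_fg,
      spine = sub$sil_spine,
      overall = c(sub$sil_fg, sub$sil_spine)
    )
    for (nm in names(pools)) {
      v <- pools[[nm]][!is.na(pools[[nm]])]
      if (length(v) == 0L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        range = label, filter = nm, n = length(v),
        min = min(v), max = max(v), mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0
      )
    }
  }
  dplyr::bind_rows(out)
}
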