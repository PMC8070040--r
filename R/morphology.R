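#' Morphology configuration
#'
#' Structuring element and iteration count shared by the opening/closing
#' steps of the cascade. The cross (4-connected, "diamond") 3x3 element is
#' the default; `square3` selects the full 3x3 box.
#'
#' @param selem `"cross3"` or `"square3"`.
#' @param n_iter Number of times the operation is applied (default 2,
#'   matching the pipeline's iterated opening/closing).
#' @return List with the kernel matrix and iteration count.
#' @export
morph_config <- function(selem = c("cross3", "square3"), n_iter = 2L) {
  selem <- match.arg(selem)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("`n_iter` must be >= 1", call. = FALSE)
  kern <- switch(selem,
    cross3 = matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L),
    square3 = matrix(1, 3L, 3L)
  )
  list(selem = selem, kern = kern, n_iter = n_iter)
}

#' Iterated binary opening
#'
#' Erosion followed by dilation, applied `cfg$n_iter` times. Removes
#' foreground structures thinner than the structuring element (isolated
#' specks, 1-pixel streak lines) while preserving larger regions.
#'
#' @param mask Binary matrix over \{0, 1\}.
#' @param cfg Configuration from [morph_config()].
#' @return Binary matrix.
#' @export
opening_n <- function(mask, cfg = morph_config()) {
  assert_binary_mask(mask)
  m <- mask
  for (i in seq_len(cfg$n_iter)) m <- EBImage::opening(m, cfg$kern)
  as_mask(m)
}

#' Iterated binary closing
#'
#' Dilation followed by erosion, applied `cfg$n_iter` times. Fills holes up
#' to the scale of the structuring element (e.g. intrapulmonary vessels in a
#' lung mask).
#'
#' @inheritParams opening_n
#' @return Binary matrix (a superset of the input).
#' @export
closing_n <- function(mask, cfg = morph_config()) {
  assert_binary_mask(mask)
  m <- mask
  for (i in seq_len(cfg$n_iter)) m <- EBImage::closing(m, cfg$kern)
  as_mask(m)
}

#' Pixel-wise complement
#'
#' @param mask Binary matrix.
#' @return Binary matrix with 0 and 1 swapped.
#' @export
complement <- function(mask) {
  assert_binary_mask(mask)
  1L - mask
}

#' Filled convex hull of a binary mask
#'
#' Smallest convex pixel set containing all foreground pixels: a pixel
#' belongs to the hull iff its center lies inside (or on) the convex polygon
#' of the foreground pixel centers. The polygon comes from [grDevices::chull()];
#' filling is an exact scanline over rows. The result is a superset of the
#' input, convex (contiguous runs along every row and column), and
#' idempotent.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @param mode `"exact"` (default) computes the exact filled hull;
#'   `"hitmiss"` runs the iterative hit-or-miss approximation that grows the
#'   mask with four directional structuring elements until convergence,
#'   yielding a quadrant-limited approximate hull.
#' @return Binary matrix.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[1, 1] <- m[1, 5] <- 1L
#' sum(convex_hull(m))  # the whole first row
convex_hull <- function(mask, mode = c("exact", "hitmiss")) {
  mode <- match.arg(mode)
  assert_binary_mask(mask)
  if (mask_empty(mask)) stop("convex hull of an empty mask", call. = FALSE)
  if (mode == "hitmiss") return(convex_hull_hitmiss(mask))
  idx <- which(mask == 1L, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  if (nrow(idx) == 1L) return(mask)
  hull_idx <- grDevices::chull(c, r)   # x = col, y = row
  px <- c[hull_idx]; py <- r[hull_idx]
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(hull_idx) <= 2L || polygon_area(px, py) == 0) {
    return(fill_collinear(mask, r, c))
  }
  tol <- 1e-9
  nv <- length(px)
  for (row in min(py):max(py)) {
    xs <- numeric(0)
    for (e in seq_len(nv)) {
      x1 <- px[e]; y1 <- py[e]
      x2 <- px[e %% nv + 1L]; y2 <- py[e %% nv + 1L]
      if (y1 == y2) {
        if (y1 == row) xs <- c(xs, x1, x2)
      } else if ((row >= min(y1, y2)) && (row <= max(y1, y2))) {
        xs <- c(xs, x1 + (row - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs) == 0) next
    lo <- ceiling(min(xs) - tol); hi <- floor(max(xs) + tol)
    if (hi >= lo) out[row, lo:hi] <- 1L
  }
  out
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  abs(sum(px * py[j] - px[j] * py)) / 2
}

# Degenerate hull: all foreground pixels collinear. The hull is the set of
# pixels whose centers lie on the segment between the two extreme pixels.
fill_collinear <- function(mask, r, c) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  d2 <- (r - r[1])^2 + (c - c[1])^2
  a <- which.max(d2)
  d2b <- (r - r[a])^2 + (c - c[a])^2
  b <- which.max(d2b)
  r1 <- r[a]; c1 <- c[a]; r2 <- r[b]; c2 <- c[b]
  dr <- r2 - r1; dc <- c2 - c1
  g <- max(abs(dr), abs(dc))
  if (g == 0L) { out[r1, c1] <- 1L; return(out) }
  tol <- 1e-9
  for (rr in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      # on the infinite line, between the endpoints
      cross <- (rr - r1) * dc - (cc - c1) * dr
      if (abs(cross) > tol) next
      t <- if (abs(dr) >= abs(dc)) (rr - r1) / dr else (cc - c1) / dc
      if (t >= -tol && t <= 1 + tol) out[rr, cc] <- 1L
    }
  }
  out
}

# Iterative hit-or-miss hull approximation: four directional L-shaped
# elements each grow background pixels whose neighborhood matches, until a
# fixed point; the union over directions is the approximate hull.
convex_hull_hitmiss <- function(mask) {
  hits <- list(
    rbind(c(1, NA, NA), c(1, 0, NA), c(1, NA, NA)),   # grow rightwards
    rbind(c(1, 1, 1), c(NA, 0, NA), c(NA, NA, NA)),   # grow downwards
    rbind(c(NA, NA, 1), c(NA, 0, 1), c(NA, NA, 1)),   # grow leftwards
    rbind(c(NA, NA, NA), c(NA, 0, NA), c(1, 1, 1))    # grow upwards
  )
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (h in hits) {
    cur <- mask
    repeat {
      grown <- cur | hitmiss_once(cur, h)
      grown <- as_mask(grown)
      if (identical(grown, cur)) break
      cur <- grown
    }
    acc <- as_mask(acc | cur)
  }
  acc
}

# One hit-or-miss pass: background pixels whose 3x3 neighborhood matches the
# pattern (1 = required foreground, 0 = required background, NA = don't care).
hitmiss_once <- function(mask, pat) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dco in -1:1) {
    p <- pat[dr + 2L, dco + 2L]
    if (is.na(p)) next
    nb <- padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dco]
    ok <- ok & (nb == p)
  }
  out[ok] <- 1L
  out
}

# 8-connected labelling built on EBImage's 4-connected bwlabel by merging
# labels that touch diagonally.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  pair_merge <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      ps <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(ps))) union2(ps[i, 1], ps[i, 2])
    }
  }
  pair_merge(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
  pair_merge(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- ids[lab[lab > 0L]]
  out
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) stop("mask has no foreground component", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  as_mask(lab == which.max(sizes))
}

#' Top and centroid anchors of a mask's largest component
#'
#' Computed on the largest 8-connected component. The top anchor is the
#' foreground pixel with the smallest row index (ties broken by smallest
#' column); the centroid is the rounded mean (row, col) of the component.
#' Coordinates are reported `(x = column, y = row)`, 1-based.
#'
#' @param mask Non-empty binary matrix.
#' @return List with `top = c(x, y)` and `centroid = c(x, y)`.
#' @export
region_anchors <- function(mask) {
  assert_binary_mask(mask)
  if (mask_empty(mask)) stop("anchors of an empty mask", call. = FALSE)
  comp <- largest_component(mask)
  idx <- which(comp == 1L, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  top_row <- min(r)
  top_col <- min(c[r == top_row])
  list(
    top = c(x = top_col, y = top_row),
    centroid = c(x = round(mean(c)), y = round(mean(r)))
  )
}
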