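# Construction of the three training-annotation regimes from point markers:
# 3x3 point masks, Otsu-based partial masks in 100x100-pixel windows, and
# validation of full hand-drawn masks.

#' Create a point marker
#'
#' A digital marker placed near the distal extremity or at the center of a
#' visible reproductive structure, as produced by manual organ counting.
#'
#' @param x,y 0-based pixel coordinates.
#' @param category Organ category name.
#' @return An object of class `point_marker`.
#' @export
point_marker <- function(x, y, category) {
  category <- match.arg(category, CATEGORY_NAMES)
  structure(list(x = x, y = y, category = category), class = "point_marker")
}

#' Build a 3 x 3 point mask from a marker
#'
#' The mask is the 3 x 3 pixel square centered on the marker, clipped at
#' the image borders (a corner marker yields a 2 x 2 square, an edge marker
#' 2 x 3 or 3 x 2).
#'
#' @param marker A [point_marker()].
#' @param width,height Image dimensions in pixels.
#' @return A raster [mask_region()].
#' @examples
#' m <- make_point_mask(point_marker(100, 200, "bud"), 2048, 1024)
#' mask_bbox(m) # 99 199 3 3
#' @export
make_point_mask <- function(marker, width, height) {
  x <- as.integer(round(marker$x))
  y <- as.integer(round(marker$y))
  if (x < 0 || y < 0 || x >= width || y >= height) {
    stop(sprintf("marker (%d, %d) lies outside the %d x %d image", x, y, width, height))
  }
  x0 <- max(x - 1L, 0L)
  y0 <- max(y - 1L, 0L)
  x1 <- min(x + 1L, width - 1L)
  y1 <- min(y + 1L, height - 1L)
  mask_region(
    raster = matrix(TRUE, y1 - y0 + 1L, x1 - x0 + 1L),
    offset = c(x0, y0)
  )
}

#' Otsu threshold of a grayscale window
#'
#' Exhaustively scores every gray level t in 0..255 as a candidate
#' threshold splitting the window into a low class (levels <= t) and a high
#' class (levels > t), and returns the t maximizing the between-class
#' variance w0(t) * w1(t) * (mu0(t) - mu1(t))^2, with ties broken by the
#' smallest t. A window whose histogram occupies a single level is flagged
#' degenerate (threshold equal to that level, variance 0).
#'
#' @param window Matrix of 8-bit gray levels (integers 0..255), or values
#'   in `[0, 1]` which are scaled to 0..255.
#' @return List with `threshold`, `between_class_variance`, `degenerate`.
#' @export
otsu_threshold <- function(window) {
  v <- as.vector(window)
  if (length(v) == 0L) stop("empty window")
  if (max(v) <= 1 && any(v != as.integer(v))) v <- round(v * 255)
  v <- as.integer(v)
  stopifnot(all(v >= 0L & v <= 255L))
  counts <- tabulate(v + 1L, nbins = 256L)
  levels_used <- which(counts > 0L)
  if (length(levels_used) == 1L) {
    return(list(
      threshold = levels_used - 1L,
      between_class_variance = 0,
      degenerate = TRUE
    ))
  }
  p <- counts / length(v)
  lv <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * lv)
  mt <- m0[256]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  t <- which.max(sigma_b) - 1L # which.max returns the first (smallest) argmax
  list(
    threshold = t,
    between_class_variance = sigma_b[t + 1L],
    degenerate = FALSE
  )
}

# Window [x-half, x+half) x [y-half, y+half) around a marker, clipped to the
# image; even window sizes are left-biased. Returns 0-based pixel ranges.
marker_window <- function(marker, width, height, window_size) {
  half_lo <- floor(window_size / 2)
  half_hi <- window_size - half_lo
  x <- as.integer(round(marker$x))
  y <- as.integer(round(marker$y))
  list(
    x0 = max(x - half_lo, 0L), x1 = min(x + half_hi - 1L, width - 1L),
    y0 = max(y - half_lo, 0L), y1 = min(y + half_hi - 1L, height - 1L)
  )
}

#' Build a partial mask by Otsu segmentation around a marker
#'
#' Applies Otsu thresholding to the luminance of the `window_size` x
#' `window_size` pixel box centered on the marker (clipped to the image),
#' takes as foreground the Otsu class containing the marker pixel, and
#' keeps only the 8-connected component containing the marker (or, if no
#' component contains it, the one whose centroid is nearest to it). A
#' degenerate window (single gray level) falls back to the 3 x 3 point
#' mask with a warning.
#'
#' @param image Numeric `height x width x 3` array in `[0, 1]`.
#' @param marker A [point_marker()].
#' @param window_size Window side in pixels (default 100, spanning 0.84 cm
#'   at the default calibration).
#' @return A raster [mask_region()] in full-image coordinates.
#' @export
make_partial_mask <- function(image, marker, window_size = 100) {
  h <- dim(image)[1]
  w <- dim(image)[2]
  x <- as.integer(round(marker$x))
  y <- as.integer(round(marker$y))
  if (x < 0 || y < 0 || x >= w || y >= h) {
    stop(sprintf("marker (%d, %d) lies outside the %d x %d image", x, y, w, h))
  }
  win <- marker_window(marker, w, h, window_size)
  gray <- luminance255(image[(win$y0 + 1):(win$y1 + 1), (win$x0 + 1):(win$x1 + 1), , drop = FALSE])
  ot <- otsu_threshold(gray)
  if (ot$degenerate) {
    warning(sprintf(
      "degenerate window around marker (%d, %d): falling back to the point mask",
      x, y
    ))
    return(make_point_mask(marker, w, h))
  }
  marker_level <- gray[y - win$y0 + 1L, x - win$x0 + 1L]
  fg <- if (marker_level <= ot$threshold) gray <= ot$threshold else gray > ot$threshold
  labels <- label_components8(fg)
  marker_lab <- labels[y - win$y0 + 1L, x - win$x0 + 1L]
  if (marker_lab == 0L) {
    # foreground cannot miss the marker pixel by construction, but guard
    # against future polarity changes: pick the nearest component centroid
    idx <- which(labels > 0L, arr.ind = TRUE)
    cx <- tapply(idx[, 2], labels[labels > 0L], mean) - 1 + win$x0
    cy <- tapply(idx[, 1], labels[labels > 0L], mean) - 1 + win$y0
    marker_lab <- as.integer(names(which.min((cx - x)^2 + (cy - y)^2)))
  }
  mask_region(raster = labels == marker_lab, offset = c(win$x0, win$y0))
}

#' Build all point or partial masks for one sheet image
#'
#' @param image Numeric `height x width x 3` array in `[0, 1]`.
#' @param markers List of [point_marker()] objects.
#' @param mode `"points"` or `"partial"`.
#' @param image_id Identifier for the resulting sheet.
#' @param window_size Window side for partial masks.
#' @return A [sheet_annotation()] with the matching provenance.
#' @export
masks_from_markers <- function(image, markers, mode = c("points", "partial"),
                               image_id = "sheet", window_size = 100) {
  mode <- match.arg(mode)
  h <- dim(image)[1]
  w <- dim(image)[2]
  instances <- lapply(markers, function(mk) {
    mask <- if (mode == "points") {
      make_point_mask(mk, w, h)
    } else {
      make_partial_mask(image, mk, window_size)
    }
    organ_instance(mk$category, mask)
  })
  prov <- if (mode == "points") "points" else "partial"
  sheet_annotation(image_id, w, h, instances, provenance = prov)
}

#' Validate full hand-drawn masks
#'
#' Report-only checks on a full-provenance sheet: polygons that
#' self-intersect, have zero rasterized area, or duplicate another
#' instance's geometry exactly. An empty result means the sheet is valid.
#'
#' @param sheet A [sheet_annotation()] with provenance `full`.
#' @return Data frame with columns `instance` (index), `id` and `violation`.
#' @export
validate_full_masks <- function(sheet) {
  stopifnot(inherits(sheet, "sheet_annotation"))
  if (sheet$provenance != "full") stop("validate_full_masks expects provenance 'full'")
  out <- data.frame(
    instance = integer(0), id = integer(0),
    violation = character(0), stringsAsFactors = FALSE
  )
  add <- function(k, what) {
    rbind(out, data.frame(
      instance = k, id = sheet$instances[[k]]$id %||% NA_integer_,
      violation = what, stringsAsFactors = FALSE
    ))
  }
  keys <- character(length(sheet$instances))
  for (k in seq_along(sheet$instances)) {
    m <- sheet$instances[[k]]$mask
    if (mask_area(m) == 0) out <- add(k, "zero_area")
    if (m$type == "polygon") {
      if (polygon_self_intersects(m$polygon)) out <- add(k, "self_intersecting")
      keys[k] <- canonical_polygon_key(m$polygon)
    } else {
      ras <- m$raster
      keys[k] <- paste(ras$offset[1], ras$offset[2], paste(which(ras$mat), collapse = ","))
    }
  }
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  for (k in which(dup & nzchar(keys))) out <- add(k, "duplicate_geometry")
  out[order(out$instance), , drop = FALSE]
}

# Canonical form of a polygon under cyclic rotation and orientation reversal,
# used to detect exact duplicate geometry.
canonical_polygon_key <- function(polygon) {
  best <- NULL
  for (pts in list(polygon, polygon[rev(seq_len(nrow(polygon))), , drop = FALSE])) {
    n <- nrow(pts)
    for (r in seq_len(n)) {
      idx <- c(r:n, seq_len(r - 1L))
      key <- paste(sprintf("%.6g", t(pts[idx, , drop = FALSE])), collapse = ";")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

# Proper-crossing test between non-adjacent polygon edges.
polygon_self_intersects <- function(polygon) {
  n <- nrow(polygon)
  if (n < 4L) return(FALSE)
  seg <- cbind(polygon, polygon[c(2:n, 1L), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
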