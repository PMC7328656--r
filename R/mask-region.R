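# Mask geometry under the COCO pixel convention: origin at the top-left
# corner, x rightward, y downward, 0-based pixel indices, bounding boxes
# half-open [x, x+w) x [y, y+h) so that width and height are pixel counts.
# A pixel (px, py) belongs to a polygon iff its center (px+0.5, py+0.5)
# falls inside the polygon under the even-odd rule.

#' Create a mask region
#'
#' A mask is either a polygon (n x 2 matrix of x, y vertex coordinates in
#' pixels, at least 3 vertices) or a binary raster (logical matrix whose
#' rows are y and columns are x, plus the 0-based pixel offset of its
#' top-left element). Pixel area and bounding box are derived on
#' construction by rasterizing, so that rasterizing a polygon and
#' re-extracting its bounding box is idempotent.
#'
#' @param polygon Numeric n x 2 matrix of vertices `(x, y)`.
#' @param raster Logical matrix (rows = y, columns = x).
#' @param offset Integer `(x0, y0)` pixel position of `raster[1, 1]`.
#' @return An object of class `mask_region` with fields `type`, `polygon`
#'   or `raster`, `area` (pixel count) and `bbox` (`c(x, y, w, h)`).
#' @examples
#' sq <- mask_region(polygon = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' mask_area(sq) # 100
#' mask_bbox(sq) # 0 0 10 10
#' @export
mask_region <- function(polygon = NULL, raster = NULL, offset = c(0L, 0L)) {
  if (is.null(polygon) == is.null(raster)) {
    stop("supply exactly one of `polygon` or `raster`")
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
      stop("polygon must be an n x 2 matrix with at least 3 vertices")
    }
    ras <- rasterize_polygon(polygon[, 1], polygon[, 2])
    out <- list(type = "polygon", polygon = polygon)
  } else {
    raster <- matrix(as.logical(raster), nrow = nrow(raster))
    ras <- crop_raster(list(offset = as.numeric(offset), mat = raster))
    out <- list(type = "raster", raster = ras)
  }
  out$area <- sum(ras$mat)
  out$bbox <- raster_bbox(ras)
  structure(out, class = "mask_region")
}

#' @export
print.mask_region <- function(x, ...) {
  cat(sprintf(
    "<mask_region %s: area %d px^2, bbox (%g, %g, %g, %g)>\n",
    x$type, x$area, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]
  ))
  invisible(x)
}

#' Pixel area of a mask
#' @param mask A [mask_region()].
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) mask$area

#' Bounding box of a mask
#' @param mask A [mask_region()].
#' @return Numeric `c(x, y, w, h)`, half-open, 0-based.
#' @export
mask_bbox <- function(mask) mask$bbox

#' Rasterize a mask
#'
#' @param mask A [mask_region()].
#' @return List with `offset` (`c(x0, y0)`, 0-based) and `mat` (logical
#'   matrix, rows = y), cropped to the tight bounding box.
#' @export
mask_raster <- function(mask) {
  if (mask$type == "raster") mask$raster else {
    rasterize_polygon(mask$polygon[, 1], mask$polygon[, 2])
  }
}

# Even-odd scanline rasterization of a polygon at pixel centers. Returns a
# cropped raster (offset + logical matrix). A pixel column x is filled on a
# row when its center x+0.5 lies in a crossing interval [a, b): the half-open
# convention keeps adjacent polygons from double-claiming boundary pixels.
rasterize_polygon <- function(vx, vy) {
  n <- length(vx)
  xmin <- floor(min(vx))
  xmax <- ceiling(max(vx)) - 1
  ymin <- floor(min(vy))
  ymax <- ceiling(max(vy)) - 1
  if (xmax < xmin || ymax < ymin) {
    return(list(offset = c(0, 0), mat = matrix(FALSE, 0, 0)))
  }
  w <- as.integer(xmax - xmin + 1)
  h <- as.integer(ymax - ymin + 1)
  mat <- matrix(FALSE, h, w)
  jx <- vx[c(n, seq_len(n - 1L))]
  jy <- vy[c(n, seq_len(n - 1L))]
  for (py in ymin:ymax) {
    yc <- py + 0.5
    cross <- (vy > yc) != (jy > yc)
    if (!any(cross)) next
    xs <- sort(vx[cross] + (yc - vy[cross]) * (jx[cross] - vx[cross]) / (jy[cross] - vy[cross]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- max(ceiling(xs[k] - 0.5), xmin)
      hi <- min(ceiling(xs[k + 1L] - 0.5) - 1, xmax)
      if (hi >= lo) mat[py - ymin + 1L, (lo:hi) - xmin + 1L] <- TRUE
    }
  }
  crop_raster(list(offset = c(xmin, ymin), mat = mat))
}

# Trim all-FALSE margins so the raster is tight around its foreground.
crop_raster <- function(ras) {
  mat <- ras$mat
  if (!any(mat)) {
    return(list(offset = c(0, 0), mat = matrix(FALSE, 0, 0)))
  }
  rows <- which(rowSums(mat) > 0)
  cols <- which(colSums(mat) > 0)
  list(
    offset = c(
      ras$offset[1] + cols[1] - 1,
      ras$offset[2] + rows[1] - 1
    ),
    mat = mat[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)], drop = FALSE]
  )
}

raster_bbox <- function(ras) {
  if (!any(ras$mat)) return(c(0, 0, 0, 0))
  c(ras$offset[1], ras$offset[2], ncol(ras$mat), nrow(ras$mat))
}

# Count of overlapping foreground pixels between two cropped rasters.
raster_intersection_count <- function(ra, rb) {
  ax0 <- ra$offset[1]; ay0 <- ra$offset[2]
  bx0 <- rb$offset[1]; by0 <- rb$offset[2]
  x0 <- max(ax0, bx0); y0 <- max(ay0, by0)
  x1 <- min(ax0 + ncol(ra$mat), bx0 + ncol(rb$mat))
  y1 <- min(ay0 + nrow(ra$mat), by0 + nrow(rb$mat))
  if (x1 <= x0 || y1 <= y0) return(0L)
  sa <- ra$mat[(y0 - ay0 + 1):(y1 - ay0), (x0 - ax0 + 1):(x1 - ax0), drop = FALSE]
  sb <- rb$mat[(y0 - by0 + 1):(y1 - by0), (x0 - bx0 + 1):(x1 - bx0), drop = FALSE]
  sum(sa & sb)
}

#' Intersection over union of two masks
#'
#' Computed on the rasterized masks in a common image frame:
#' `|A intersect B| / |A union B|`; 0 when the masks are disjoint.
#'
#' @param a,b [mask_region()] objects in the same image frame.
#' @return IoU in `[0, 1]`.
#' @examples
#' a <- mask_region(polygon = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' b <- mask_region(polygon = cbind(c(5, 15, 15, 5), c(0, 0, 10, 10)))
#' iou(a, b) # 1/3
#' @export
iou <- function(a, b) {
  if (mask_area(a) == 0 || mask_area(b) == 0) stop("IoU is undefined for a zero-area mask")
  ra <- mask_raster(a)
  rb <- mask_raster(b)
  inter <- raster_intersection_count(ra, rb)
  if (inter == 0L) return(0)
  inter / (sum(ra$mat) + sum(rb$mat) - inter)
}

# IoU on pre-extracted rasters (avoids re-rasterizing inside matching loops).
iou_rasters <- function(ra, rb) {
  inter <- raster_intersection_count(ra, rb)
  if (inter == 0L) return(0)
  inter / (sum(ra$mat) + sum(rb$mat) - inter)
}

# Shoelace (signed polygon) area, used by full-mask validation.
shoelace_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Scale a mask by a uniform factor about the image origin (used by sheet
# resizing). Polygons scale exactly; rasters are resampled nearest-neighbor.
scale_mask <- function(mask, s) {
  if (mask$type == "polygon") {
    return(mask_region(polygon = mask$polygon * s))
  }
  ras <- mask$raster
  x0 <- ras$offset[1] * s
  y0 <- ras$offset[2] * s
  new_w <- max(1L, as.integer(round(ncol(ras$mat) * s)))
  new_h <- max(1L, as.integer(round(nrow(ras$mat) * s)))
  src_col <- pmin(ncol(ras$mat), pmax(1L, as.integer(ceiling((seq_len(new_w) - 0.5) / s))))
  src_row <- pmin(nrow(ras$mat), pmax(1L, as.integer(ceiling((seq_len(new_h) - 0.5) / s))))
  mask_region(
    raster = ras$mat[src_row, src_col, drop = FALSE],
    offset = c(round(x0), round(y0))
  )
}

# Translate a raster-backed mask by whole pixels.
translate_mask <- function(mask, dx, dy) {
  if (mask$type == "polygon") {
    mask_region(polygon = cbind(mask$polygon[, 1] + dx, mask$polygon[, 2] + dy))
  } else {
    mask_region(
      raster = mask$raster$mat,
      offset = c(mask$raster$offset[1] + dx, mask$raster$offset[2] + dy)
    )
  }
}
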