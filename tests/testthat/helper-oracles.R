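# Independent oracles and shared fixtures. Oracles are deliberately naive
# (explicit loops, pixel counting) and never share code with the package
# paths they check.

# Brute-force Otsu: score every threshold t in 0..255 by directly computing
# class proportions and means from the raw values.
otsu_brute <- function(values) {
  v <- as.integer(values)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_var + 1e-12) {
      best_var <- s
      best_t <- t
    }
  }
  list(threshold = best_t, between_class_variance = best_var)
}

# Brute-force AP: explicit cumulative-precision loop over the ranked list.
ap_brute <- function(scores, correct, ids, n_gt) {
  o <- order(-scores, ids)
  correct <- correct[o]
  total <- 0
  n_correct <- 0
  for (k in seq_along(correct)) {
    if (correct[k]) {
      n_correct <- n_correct + 1
      total <- total + n_correct / k
    }
  }
  total / n_gt
}

# Pixel-counting IoU straight from two logical image-sized matrices.
iou_pixels <- function(mask_a, mask_b, width, height) {
  a <- matrix(FALSE, height, width)
  b <- matrix(FALSE, height, width)
  ra <- mask_raster(mask_a)
  rb <- mask_raster(mask_b)
  a[ra$offset[2] + seq_len(nrow(ra$mat)), ra$offset[1] + seq_len(ncol(ra$mat))] <- ra$mat
  b[rb$offset[2] + seq_len(nrow(rb$mat)), rb$offset[1] + seq_len(ncol(rb$mat))] <- rb$mat
  sum(a & b) / sum(a | b)
}

# Random simple (convex) polygon: convex hull of random points.
random_convex_polygon <- function(center_x, center_y, radius_max = 30, n_pts = 8) {
  x <- center_x + stats::runif(n_pts, -radius_max, radius_max)
  y <- center_y + stats::runif(n_pts, -radius_max, radius_max)
  hull <- grDevices::chull(x, y)
  cbind(x[hull], y[hull])
}

# Assemble a match_set directly from ranked-prediction bookkeeping, for
# formula-level AP checks (structure documented in match_instances()).
synthetic_match_set <- function(matches, unmatched_pred, unmatched_gt,
                                iou_threshold = 0.5) {
  structure(
    list(
      matches = matches, unmatched_pred = unmatched_pred,
      unmatched_gt = unmatched_gt, iou_threshold = iou_threshold
    ),
    class = "match_set"
  )
}

# Square polygon mask with top-left corner (x, y) and side s.
square_mask <- function(x, y, s) {
  mask_region(polygon = cbind(c(x, x + s, x + s, x), c(y, y, y + s, y + s)))
}

# A small ground-truth scene: n_per_cat instances of each category on one
# annotation-only sheet.
tiny_scene <- function(n_per_cat = 2, seed = 42, width = 1024, height = 512) {
  generate_sheet(
    sheet_recipe(
      width = width, height = height,
      counts = stats::setNames(rep(n_per_cat, 4),
                               c("bud", "flower", "immature_fruit", "mature_fruit")),
      seed = seed
    ),
    render = FALSE, image_id = sprintf("tiny_%d", seed)
  )$sheet
}

# Memoized Table-1 fixture so the several tests that need it build it once.
.fixture_cache <- new.env(parent = emptyenv())
get_table1_fixture <- function(seed = 20) {
  key <- paste0("table1_", seed)
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, generate_fixture_table1(seed = seed), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
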