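# Pluggable instance-segmentation stage. The trained network the evaluation
# was designed around is treated as a black box: any detector whose COCO
# results file is read through read_predictions() satisfies the contract.
# The built-in baseline is a classical pipeline (global Otsu foreground
# split, connected components, shape/color rules) so the whole evaluation
# runs end to end on a desktop CPU.
#
# Segmenter contract: given an 8-bit RGB raster, return a
# predicted-provenance sheet_annotation whose instances carry scores in
# [0, 1] and masks within image bounds, deterministically for a fixed input
# and seed, with no two instances sharing identical geometry.

#' Baseline detector configuration
#'
#' Rule thresholds for [baseline_segment()], tuned once on the synthetic
#' suite and frozen. Components are classified by elongation (square root
#' of the ratio of the principal-axis variances of their pixel coordinates)
#' and mean hue: long thin components are fruits, with hue splitting
#' immature (green) from mature (brown); compact components are flowers
#' when purple-hued, buds otherwise.
#'
#' @param min_area Minimum component area in pixels.
#' @param elongation_fruit Elongation at or above which a component is a
#'   fruit.
#' @param green_hue Hue interval (degrees) read as immature fruit.
#' @param purple_hue Hue interval (degrees) read as flower.
#' @param max_fg_fraction Maximum plausible foreground fraction. Otsu
#'   always splits a histogram, so on an organ-free sheet the "foreground"
#'   class is just the darker half of the paper noise (roughly 40% of the
#'   pixels); pressed material on a sparse sheet covers far less. Splits
#'   whose foreground exceeds this fraction are treated as blank sheets.
#' @param file Optional YAML file of overrides (keys as above).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(min_area = 40, elongation_fruit = 3,
                            green_hue = c(60, 180), purple_hue = c(200, 330),
                            max_fg_fraction = 0.25, file = NULL) {
  cfg <- list(
    min_area = min_area, elongation_fruit = elongation_fruit,
    green_hue = green_hue, purple_hue = purple_hue,
    max_fg_fraction = max_fg_fraction
  )
  if (!is.null(file)) {
    overrides <- yaml::read_yaml(file)
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "baseline_config")
}

#' Segment a sheet image
#'
#' Entry point of the segmenter contract. The `baseline` backend runs
#' [baseline_segment()]; the `cocofile` backend reads a detector's COCO
#' results file via [read_predictions()] and returns the sheet whose image
#' id matches.
#'
#' @param image Numeric `height x width x 3` RGB array in `[0, 1]`.
#' @param seed Integer seed (the baseline is deterministic and ignores it,
#'   but the contract fixes the signature for stochastic backends).
#' @param backend `"baseline"` or `"cocofile"`.
#' @param config A [baseline_config()] for the baseline backend.
#' @param results_file COCO results path for the `cocofile` backend.
#' @param image_id Identifier of the sheet.
#' @return A predicted-provenance [sheet_annotation()].
#' @export
segment <- function(image, seed = 1, backend = c("baseline", "cocofile"),
                    config = baseline_config(), results_file = NULL,
                    image_id = "image") {
  backend <- match.arg(backend)
  if (backend == "cocofile") {
    if (is.null(results_file)) stop("the cocofile backend needs a results_file")
    sheets <- read_predictions(results_file)
    ids <- vapply(sheets, function(s) s$image_id, character(1))
    hit <- match(image_id, ids)
    if (is.na(hit)) stop("no predictions for image ", image_id, " in ", results_file)
    return(sheets[[hit]])
  }
  baseline_segment(image, config, image_id = image_id)
}

#' Classical baseline instance segmentation
#'
#' Splits foreground from background with Otsu thresholding on luminance
#' (the darker class is foreground: pressed plant material is darker than
#' mounting paper), labels connected components, measures per-component
#' shape and color features, and assigns categories by the rule table in
#' [baseline_config()]. The confidence score maps the rule margin (distance
#' of the deciding feature from its decision boundary) into `[0.5, 1]`.
#'
#' @param image Numeric `height x width x 3` RGB array in `[0, 1]`.
#' @param config A [baseline_config()].
#' @param image_id Identifier of the sheet.
#' @return A predicted-provenance [sheet_annotation()].
#' @export
baseline_segment <- function(image, config = baseline_config(), image_id = "image") {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("baseline_segment expects an RGB image (height x width x 3 array)")
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  empty <- function() sheet_annotation(image_id, w, h, list(), provenance = "predicted")
  gray <- luminance255(image)
  ot <- otsu_threshold(gray)
  if (ot$degenerate) return(empty())
  low <- gray <= ot$threshold
  mean_low <- mean(gray[low])
  mean_high <- mean(gray[!low])
  fg <- if (mean_low < mean_high) low else !low
  if (mean(fg) > config$max_fg_fraction) return(empty())
  labels <- EBImage::bwlabel(t(fg)) # EBImage works in (x, y) order
  labels <- t(labels)
  n_comp <- max(labels)
  if (n_comp == 0L) return(empty())
  instances <- list()
  pix_by_comp <- split(which(labels > 0L), labels[labels > 0L])
  for (lab in names(pix_by_comp)) {
    pix <- pix_by_comp[[lab]]
    if (length(pix) < config$min_area) next
    rows <- (pix - 1L) %% h + 1L
    cols <- (pix - 1L) %/% h + 1L
    feat <- component_features(image, pix, rows, cols)
    cls <- classify_component(feat, config)
    mat <- matrix(FALSE, max(rows) - min(rows) + 1L, max(cols) - min(cols) + 1L)
    mat[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- TRUE
    instances[[length(instances) + 1L]] <- organ_instance(
      cls$category,
      mask_region(raster = mat, offset = c(min(cols) - 1L, min(rows) - 1L)),
      score = cls$score,
      id = length(instances) + 1L
    )
  }
  sheet_annotation(image_id, w, h, instances, provenance = "predicted")
}

component_features <- function(image, pix, rows, cols) {
  n <- length(pix)
  if (n > 1L) {
    cv <- stats::cov(cbind(cols, rows))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    elongation <- sqrt(max(ev[1], 1e-9) / max(ev[2], 1e-9))
  } else {
    elongation <- 1
  }
  rgb_mean <- c(
    mean(image[, , 1][pix]), mean(image[, , 2][pix]), mean(image[, , 3][pix])
  )
  hsv <- grDevices::rgb2hsv(rgb_mean[1], rgb_mean[2], rgb_mean[3], maxColorValue = 1)
  list(area = n, elongation = elongation, hue = hsv[1] * 360, sat = hsv[2])
}

classify_component <- function(feat, config) {
  in_band <- function(hue, band) hue >= band[1] & hue <= band[2]
  hue_margin <- function(hue, band) min(abs(hue - band[1]), abs(hue - band[2]))
  if (feat$elongation >= config$elongation_fruit) {
    category <- if (in_band(feat$hue, config$green_hue)) "immature_fruit" else "mature_fruit"
    margin <- min(
      (feat$elongation - config$elongation_fruit) / config$elongation_fruit,
      hue_margin(feat$hue, config$green_hue) / 30
    )
  } else {
    category <- if (in_band(feat$hue, config$purple_hue)) "flower" else "bud"
    margin <- min(
      (config$elongation_fruit - feat$elongation) / config$elongation_fruit,
      hue_margin(feat$hue, config$purple_hue) / 30
    )
  }
  list(category = category, score = 0.5 + 0.5 * max(0, min(1, margin)))
}
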