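#' Reproductive-structure categories
#'
#' The four organ categories scored on each herbarium sheet, with their
#' stable integer ids. The two metacategories (`buds_flowers`, `fruits`)
#' are always derived from these and never stored in annotation files.
#'
#' @return A data frame with columns `id` (1--4) and `name`
#'   (`"bud"`, `"flower"`, `"immature_fruit"`, `"mature_fruit"`).
#' @examples
#' categories()
#' @export
categories <- function() {
  data.frame(
    id = 1:4,
    name = c("bud", "flower", "immature_fruit", "mature_fruit"),
    stringsAsFactors = FALSE
  )
}

CATEGORY_NAMES <- c("bud", "flower", "immature_fruit", "mature_fruit")

#' Metacategory membership
#'
#' @param meta `"buds_flowers"` or `"fruits"`.
#' @return Character vector of the member category names.
#' @export
metacategory_members <- function(meta = c("buds_flowers", "fruits")) {
  meta <- match.arg(meta)
  switch(meta,
    buds_flowers = c("bud", "flower"),
    fruits = c("immature_fruit", "mature_fruit")
  )
}

category_id <- function(name) {
  id <- match(name, CATEGORY_NAMES)
  if (anyNA(id)) stop("unknown category name: ", paste(name[is.na(id)], collapse = ", "))
  id
}

category_name <- function(id) {
  if (any(!id %in% 1:4)) stop("unknown category id: ", paste(setdiff(id, 1:4), collapse = ", "))
  CATEGORY_NAMES[id]
}

#' Pixel-to-centimeter scale calibration
#'
#' Links pixel measurements on a resized sheet (longest edge 2048 px) to
#' physical size. The default of 0.0084 cm/pixel corresponds to 100 pixels
#' spanning 0.84 cm.
#'
#' @param cm_per_pixel Positive scale factor in cm per pixel.
#' @return An object of class `scale_calibration`.
#' @examples
#' cal <- scale_calibration()
#' px_to_cm(100, cal) # 0.84
#' @export
scale_calibration <- function(cm_per_pixel = 0.0084) {
  stopifnot(is.numeric(cm_per_pixel), length(cm_per_pixel) == 1L, cm_per_pixel > 0)
  structure(list(cm_per_pixel = cm_per_pixel), class = "scale_calibration")
}

#' Convert a pixel length to centimeters
#'
#' @param px Pixel lengths.
#' @param calibration A [scale_calibration()].
#' @param digits Decimal places for reporting (half-up); `NULL` for no rounding.
#' @return Lengths in cm.
#' @export
px_to_cm <- function(px, calibration = scale_calibration(), digits = NULL) {
  cm <- px * calibration$cm_per_pixel
  if (!is.null(digits)) cm <- round_half_up(cm, digits)
  cm
}

#' Size bins for size-wise average precision
#'
#' Instances are binned by the maximum side of their mask bounding box:
#' Small 1--64 px, Medium 65--128 px, Large > 128 px. The cm equivalents
#' at the default calibration are 0.54 cm and 1.08 cm (rounded to 2
#' decimals). Note that binning uses the maximum bounding-box side whereas
#' size *measurement* uses the bounding-box diagonal; the two are
#' deliberately different definitions.
#'
#' @param calibration A [scale_calibration()] used for the cm columns.
#' @return Data frame with columns `name`, `min_px`, `max_px`,
#'   `min_cm`, `max_cm`.
#' @examples
#' size_bins()
#' @export
size_bins <- function(calibration = scale_calibration()) {
  b <- data.frame(
    name = c("small", "medium", "large"),
    min_px = c(1, 65, 129),
    max_px = c(64, 128, Inf),
    stringsAsFactors = FALSE
  )
  b$min_cm <- round_half_up(px_to_cm(b$min_px, calibration), 2)
  b$max_cm <- round_half_up(px_to_cm(b$max_px, calibration), 2)
  b
}

#' Assign sizes to bins
#'
#' @param max_side Maximum bounding-box side(s) in pixels.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
size_bin_of <- function(max_side) {
  cut(max_side,
    breaks = c(0, 64, 128, Inf),
    labels = c("small", "medium", "large"),
    right = TRUE
  )
}
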