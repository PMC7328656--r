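# Synthetic herbarium sheets with exact ground-truth masks. Organ shapes
# are procedural (ellipses, lobed discs, curved capsules) rather than
# photorealistic: the evaluation layer only needs masks with controllable
# geometry, category-distinctive shape/color statistics, and sizes spanning
# the three size bins.

#' Recipe for one synthetic sheet
#'
#' Defaults emulate the study's data regime: 2048 x 1024 pixel sheets and
#' per-category counts close to the annotated training material's average
#' per sheet. Shape parameters (pixel units): buds are ellipses with axes
#' 10--40 px; flowers lobed discs 30--90 px across; immature fruits thin
#' curved capsules 60--250 px long and 6--14 px wide; mature fruits
#' capsules 120--360 px long and 8--18 px wide. Instances are placed with
#' disjoint, margin-separated bounding boxes, which emulates the
#' foreground-only annotation rule (each pixel belongs to at most one
#' instance).
#'
#' @param width,height Sheet dimensions in pixels (>= 256).
#' @param counts Named per-category instance counts.
#' @param palette Named list of RGB (0--1) colors per category.
#' @param background RGB background (mounting paper) color.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param margin Minimum gap in pixels between instance bounding boxes.
#' @param seed Integer seed; every derived fixture is byte-reproducible.
#' @return An object of class `sheet_recipe`.
#' @export
sheet_recipe <- function(width = 2048, height = 1024,
                         counts = c(bud = 13, flower = 17, immature_fruit = 9, mature_fruit = 10),
                         palette = list(
                           bud = c(0.80, 0.52, 0.20),
                           flower = c(0.58, 0.42, 0.72),
                           immature_fruit = c(0.38, 0.55, 0.25),
                           mature_fruit = c(0.45, 0.33, 0.18)
                         ),
                         background = c(0.93, 0.91, 0.86),
                         noise_sd = 0.015, margin = 8, seed = 1) {
  stopifnot(width >= 256, height >= 256, all(counts >= 0))
  counts_full <- stats::setNames(rep(0L, 4), CATEGORY_NAMES)
  counts_full[names(counts)] <- as.integer(counts)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    counts = counts_full, palette = palette, background = background,
    noise_sd = noise_sd, margin = margin, seed = as.integer(seed)
  ), class = "sheet_recipe")
}

# --- procedural organ polygons, centered at the origin ----------------------

ellipse_polygon <- function(a, b, angle, n = 28) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rotate_points(cbind(a / 2 * cos(th), b / 2 * sin(th)), angle)
}

lobed_disc_polygon <- function(diameter, n_petals = 5, depth = 0.3, phase = 0, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- diameter / 2 * (1 - depth + depth * sin(n_petals * th / 2 + phase)^2)
  cbind(r * cos(th), r * sin(th))
}

curved_capsule_polygon <- function(length, width, curvature, angle, n = 16) {
  t <- seq(-0.5, 0.5, length.out = n)
  cx <- t * length
  cy <- curvature * length * (4 * t^2 - 1) / 4
  dx <- c(diff(cx), cx[n] - cx[n - 1])
  dy <- c(diff(cy), cy[n] - cy[n - 1])
  nrm <- sqrt(dx^2 + dy^2)
  nx <- -dy / nrm
  ny <- dx / nrm
  top <- cbind(cx + width / 2 * nx, cy + width / 2 * ny)
  bottom <- cbind(cx - width / 2 * nx, cy - width / 2 * ny)
  rotate_points(rbind(top, bottom[n:1, ]), angle)
}

rotate_points <- function(pts, angle) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  pts %*% r
}

# Draw one organ polygon of a category with parameters sampled from the
# recipe's shape ranges (pixel units; consumes RNG).
sample_organ_polygon <- function(category) {
  switch(category,
    bud = {
      a <- stats::runif(1, 10, 40)
      b <- stats::runif(1, max(10, a / 1.8), a)
      ellipse_polygon(a, b, stats::runif(1, 0, pi))
    },
    flower = lobed_disc_polygon(
      stats::runif(1, 30, 90),
      n_petals = sample(4:6, 1), depth = stats::runif(1, 0.2, 0.35),
      phase = stats::runif(1, 0, pi)
    ),
    immature_fruit = curved_capsule_polygon(
      stats::runif(1, 60, 250), stats::runif(1, 6, 14),
      stats::runif(1, 0.05, 0.25), stats::runif(1, 0, pi)
    ),
    mature_fruit = curved_capsule_polygon(
      stats::runif(1, 120, 360), stats::runif(1, 8, 18),
      stats::runif(1, 0.02, 0.15), stats::runif(1, 0, pi)
    )
  )
}

#' Generate one synthetic sheet
#'
#' Renders a sheet image and its exact full-mask ground truth, byte
#' deterministic for a fixed recipe (including the seed). Instances are
#' placed by rejection sampling with margin-separated bounding boxes; if a
#' shape cannot be placed the packing is infeasible and a hard error names
#' the failing instance.
#'
#' @param recipe A [sheet_recipe()].
#' @param render If `FALSE`, skip the raster image (annotations only).
#' @param image_id Identifier for the sheet.
#' @return List with `image` (`height x width x 3` array in `[0, 1]`, or
#'   `NULL`) and `sheet` (a full-provenance [sheet_annotation()]).
#' @export
generate_sheet <- function(recipe, render = TRUE, image_id = "synthetic_sheet") {
  stopifnot(inherits(recipe, "sheet_recipe"))
  with_seed(recipe$seed, {
    placed_bbox <- matrix(numeric(0), ncol = 4)
    instances <- list()
    order_cats <- rep(CATEGORY_NAMES, recipe$counts)
    for (k in seq_along(order_cats)) {
      cat_k <- order_cats[k]
      ok <- FALSE
      for (try in seq_len(200L)) {
        poly <- sample_organ_polygon(cat_k)
        ext_x <- max(abs(poly[, 1])) + 1
        ext_y <- max(abs(poly[, 2])) + 1
        if (2 * ext_x >= recipe$width || 2 * ext_y >= recipe$height) next
        cx <- stats::runif(1, ext_x, recipe$width - ext_x)
        cy <- stats::runif(1, ext_y, recipe$height - ext_y)
        cand <- cbind(poly[, 1] + cx, poly[, 2] + cy)
        bb <- c(min(cand[, 1]), min(cand[, 2]), max(cand[, 1]), max(cand[, 2]))
        m <- recipe$margin
        if (nrow(placed_bbox) > 0 && any(
          bb[1] - m < placed_bbox[, 3] & bb[3] + m > placed_bbox[, 1] &
          bb[2] - m < placed_bbox[, 4] & bb[4] + m > placed_bbox[, 2]
        )) next
        mask <- mask_region(polygon = cand)
        if (mask_area(mask) == 0) next
        placed_bbox <- rbind(placed_bbox, bb)
        instances[[k]] <- organ_instance(cat_k, mask, id = k)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          "infeasible packing: could not place instance %d (%s) of %d on a %d x %d sheet",
          k, cat_k, length(order_cats), recipe$width, recipe$height
        ))
      }
    }
    sheet <- sheet_annotation(
      image_id, recipe$width, recipe$height, instances, provenance = "full"
    )
    image <- NULL
    if (render) {
      image <- render_sheet(recipe, sheet)
    }
    list(image = image, sheet = sheet)
  })
}

render_sheet <- function(recipe, sheet) {
  h <- recipe$height
  w <- recipe$width
  image <- array(0, c(h, w, 3))
  base_noise <- matrix(stats::rnorm(h * w, 0, recipe$noise_sd), h, w)
  for (ch in 1:3) image[, , ch] <- recipe$background[ch] + base_noise
  for (inst in sheet$instances) {
    ras <- mask_raster(inst$mask)
    col <- recipe$palette[[inst$category]]
    idx <- which(ras$mat, arr.ind = TRUE)
    rows <- ras$offset[2] + idx[, 1] # 0-based y + 1-based row index = 1-based image row
    cols <- ras$offset[1] + idx[, 2]
    shade <- stats::rnorm(nrow(idx), 0, 0.02)
    for (ch in 1:3) {
      image[cbind(rows, cols, ch)] <- col[ch] + shade
    }
  }
  image[image < 0] <- 0
  image[image > 1] <- 1
  image
}

#' Generate the Table-1-shaped annotation fixtures
#'
#' Builds a training fixture of 21 sheets holding exactly 279 buds, 349
#' flowers, 196 immature fruits and 212 mature fruits (1036 instances) and
#' a test fixture of 10 sheets holding 168/299/110/101 (678 instances),
#' with the per-sheet allocation random but fully determined by the seed.
#' Annotations only (no rendering).
#'
#' @param seed Integer master seed.
#' @param dir Optional directory; when given, writes
#'   `table1_training.json` and `table1_test.json` there.
#' @return List with `training` and `test`, each a list of
#'   [sheet_annotation()] objects.
#' @export
generate_fixture_table1 <- function(seed = 1, dir = NULL) {
  spec <- list(
    training = list(
      counts = c(bud = 279, flower = 349, immature_fruit = 196, mature_fruit = 212),
      n_sheets = 21L, prefix = "train"
    ),
    test = list(
      counts = c(bud = 168, flower = 299, immature_fruit = 110, mature_fruit = 101),
      n_sheets = 10L, prefix = "test"
    )
  )
  out <- list()
  for (part in names(spec)) {
    ps <- spec[[part]]
    alloc <- with_seed(derive_seed(seed, match(part, names(spec))), {
      sapply(CATEGORY_NAMES, function(cat) {
        tabulate(sample.int(ps$n_sheets, ps$counts[[cat]], replace = TRUE), ps$n_sheets)
      })
    })
    sheets <- lapply(seq_len(ps$n_sheets), function(i) {
      recipe <- sheet_recipe(
        counts = stats::setNames(alloc[i, ], CATEGORY_NAMES),
        seed = derive_seed(seed, 100L * match(part, names(spec)) + i)
      )
      generate_sheet(recipe, render = FALSE,
                     image_id = sprintf("%s_%02d", ps$prefix, i))$sheet
    })
    out[[part]] <- sheets
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_annotations(out$training, file.path(dir, "table1_training.json"))
    write_annotations(out$test, file.path(dir, "table1_test.json"))
  }
  out
}

#' Parametric perturbation model for synthetic predictions
#'
#' Describes how to corrupt ground truth into "predictions" with
#' analytically known metric expectations: independent per-category miss
#' probabilities, a Poisson false-alarm rate per sheet, a row-stochastic
#' label-swap matrix, mask jitter (dilation radius plus boundary noise),
#' and beta score models (high for detections, low for false alarms). With
#' the identity settings the perturbation is the identity map on
#' annotations (modulo the sampled scores).
#'
#' @param miss Per-category miss probability (length 1 or 4, in `[0, 1]`).
#' @param false_alarm_rate Expected false alarms per sheet (Poisson).
#' @param swap 4 x 4 row-stochastic label-swap matrix (rows = true label).
#' @param jitter_radius Dilation radius in pixels applied to each kept mask.
#' @param boundary_noise Probability of toggling each boundary pixel.
#' @param score_shape,fa_score_shape Beta shape pairs for detection and
#'   false-alarm scores.
#' @param seed Integer seed.
#' @return An object of class `perturbation_model`.
#' @export
perturbation_model <- function(miss = 0, false_alarm_rate = 0,
                               swap = diag(4), jitter_radius = 0,
                               boundary_noise = 0,
                               score_shape = c(12, 2), fa_score_shape = c(2, 12),
                               seed = 1) {
  if (length(miss) == 1L) miss <- rep(miss, 4)
  miss <- stats::setNames(miss, CATEGORY_NAMES)
  stopifnot(all(miss >= 0 & miss <= 1), false_alarm_rate >= 0, jitter_radius >= 0)
  swap <- as.matrix(swap)
  stopifnot(nrow(swap) == 4, ncol(swap) == 4, all(swap >= 0))
  if (any(abs(rowSums(swap) - 1) > 1e-9)) stop("swap matrix rows must sum to 1")
  dimnames(swap) <- list(CATEGORY_NAMES, CATEGORY_NAMES)
  structure(list(
    miss = miss, false_alarm_rate = false_alarm_rate, swap = swap,
    jitter_radius = jitter_radius, boundary_noise = boundary_noise,
    score_shape = score_shape, fa_score_shape = fa_score_shape,
    seed = as.integer(seed)
  ), class = "perturbation_model")
}

#' Perturb ground truth into synthetic predictions
#'
#' Each ground-truth instance is independently dropped with its category's
#' miss probability, otherwise copied with a jittered mask, relabeled
#' according to the swap matrix, and given a sampled confidence score.
#' False alarms (random organ shapes with low scores) are added at the
#' model's Poisson rate. Detection scores live in `[0.5, 1]`
#' (`0.5 + 0.5 * Beta(score_shape)`) and false-alarm scores in `[0, 0.5)`
#' (`0.5 * Beta(fa_score_shape)`), so the default counting cutoff of 0.5
#' separates them exactly.
#'
#' @param gt A ground-truth [sheet_annotation()] or list of them.
#' @param model A [perturbation_model()].
#' @return Predicted-provenance sheet(s), matching the input shape.
#' @export
perturb_predictions <- function(gt, model) {
  stopifnot(inherits(model, "perturbation_model"))
  if (inherits(gt, "sheet_annotation")) {
    return(perturb_one(gt, model, model$seed))
  }
  lapply(seq_along(gt), function(i) {
    perturb_one(gt[[i]], model, derive_seed(model$seed, i))
  })
}

perturb_one <- function(gt, model, seed) {
  with_seed(seed, {
    instances <- list()
    next_id <- 0L
    for (inst in gt$instances) {
      if (stats::runif(1) < model$miss[[inst$category]]) next
      mask <- inst$mask
      if (model$jitter_radius > 0 || model$boundary_noise > 0) {
        mask <- jitter_mask(mask, model$jitter_radius, model$boundary_noise,
                            gt$width, gt$height)
      }
      new_cat <- sample(CATEGORY_NAMES, 1, prob = model$swap[inst$category, ])
      next_id <- next_id + 1L
      instances[[next_id]] <- organ_instance(
        new_cat, mask,
        score = 0.5 + 0.5 * stats::rbeta(1, model$score_shape[1], model$score_shape[2]),
        id = next_id
      )
    }
    n_fa <- stats::rpois(1, model$false_alarm_rate)
    for (f in seq_len(n_fa)) {
      cat_f <- sample(CATEGORY_NAMES, 1)
      repeat {
        poly <- sample_organ_polygon(cat_f)
        ext_x <- max(abs(poly[, 1])) + 1
        ext_y <- max(abs(poly[, 2])) + 1
        if (2 * ext_x < gt$width && 2 * ext_y < gt$height) break
      }
      cx <- stats::runif(1, ext_x, gt$width - ext_x)
      cy <- stats::runif(1, ext_y, gt$height - ext_y)
      next_id <- next_id + 1L
      instances[[next_id]] <- organ_instance(
        cat_f, mask_region(polygon = cbind(poly[, 1] + cx, poly[, 2] + cy)),
        score = 0.5 * stats::rbeta(1, model$fa_score_shape[1], model$fa_score_shape[2]),
        id = next_id
      )
    }
    sheet_annotation(gt$image_id, gt$width, gt$height, instances,
                     provenance = "predicted")
  })
}

# Dilate a mask by a disc brush of the given radius (monotone: a larger
# radius never shrinks the mask, so matched IoU is non-increasing in the
# radius), optionally toggling boundary pixels, then clip to image bounds.
jitter_mask <- function(mask, radius, boundary_noise, width, height) {
  ras <- mask_raster(mask)
  r <- as.integer(ceiling(radius))
  mat <- ras$mat
  off <- ras$offset
  if (r > 0) {
    padded <- matrix(FALSE, nrow(mat) + 2 * r, ncol(mat) + 2 * r)
    padded[r + seq_len(nrow(mat)), r + seq_len(ncol(mat))] <- mat
    brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
    mat <- EBImage::dilate(padded, brush) > 0
    off <- off - r
  }
  if (boundary_noise > 0) {
    inner <- mat &
      rbind(FALSE, mat[-nrow(mat), ]) & rbind(mat[-1, ], FALSE) &
      cbind(FALSE, mat[, -ncol(mat)]) & cbind(mat[, -1], FALSE)
    boundary <- which(mat & !inner)
    flip <- boundary[stats::runif(length(boundary)) < boundary_noise]
    mat[flip] <- FALSE
  }
  # clip to image bounds
  rows <- which(off[2] + seq_len(nrow(mat)) - 1 >= 0 & off[2] + seq_len(nrow(mat)) - 1 < height)
  cols <- which(off[1] + seq_len(ncol(mat)) - 1 >= 0 & off[1] + seq_len(ncol(mat)) - 1 < width)
  mask_region(
    raster = mat[rows, cols, drop = FALSE],
    offset = c(off[1] + cols[1] - 1, off[2] + rows[1] - 1)
  )
}
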