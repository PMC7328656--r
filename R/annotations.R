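# Sheet-level annotation containers and COCO-dialect JSON I/O.
#
# File dialect (mirrors COCO Annotator exports): top-level arrays `images`
# (id, file_name, width, height), `annotations` (id, image_id, category_id,
# segmentation as a list of polygons, area, bbox [x, y, w, h], optional
# score) and `categories` (id, name). Category names are exactly "bud",
# "flower", "immature_fruit", "mature_fruit". An optional `info$provenance`
# field records which annotation regime produced the file.

#' Create an organ instance
#'
#' One reproductive structure on a sheet: a category, a mask and, for
#' predictions only, a confidence score. Ground-truth instances never carry
#' a score.
#'
#' @param category One of `"bud"`, `"flower"`, `"immature_fruit"`,
#'   `"mature_fruit"`.
#' @param mask A [mask_region()].
#' @param score Probability in `[0, 1]`, or `NULL` for ground truth.
#' @param id Optional integer instance id.
#' @return An object of class `organ_instance`.
#' @export
organ_instance <- function(category, mask, score = NULL, id = NULL) {
  category <- match.arg(category, CATEGORY_NAMES)
  stopifnot(inherits(mask, "mask_region"))
  if (!is.null(score)) {
    stopifnot(is.numeric(score), length(score) == 1L, score >= 0, score <= 1)
  }
  structure(
    list(category = category, mask = mask, score = score, id = id),
    class = "organ_instance"
  )
}

#' Create a sheet annotation
#'
#' All instances on one sheet image, with image dimensions and the
#' provenance of the annotation regime. Instances without ids are numbered
#' sequentially. Validates that every mask lies within the image bounds,
#' that score presence matches provenance (scores iff `predicted`), and
#' that `points` masks are at most 3 x 3 pixels (border clipping can shrink
#' a corner marker's square to 2 x 2).
#'
#' @param image_id Character image identifier.
#' @param width,height Image dimensions in pixels.
#' @param instances List of [organ_instance()] objects.
#' @param provenance One of `"points"`, `"partial"`, `"full"`, `"predicted"`.
#' @return An object of class `sheet_annotation`.
#' @export
sheet_annotation <- function(image_id, width, height, instances = list(),
                             provenance = c("full", "points", "partial", "predicted")) {
  provenance <- match.arg(provenance)
  stopifnot(width >= 1, height >= 1)
  for (k in seq_along(instances)) {
    inst <- instances[[k]]
    stopifnot(inherits(inst, "organ_instance"))
    bb <- mask_bbox(inst$mask)
    if (inst$mask$area > 0 &&
        (bb[1] < 0 || bb[2] < 0 || bb[1] + bb[3] > width || bb[2] + bb[4] > height)) {
      stop(sprintf(
        "instance %d mask bbox (%g, %g, %g, %g) exceeds image bounds %d x %d",
        k, bb[1], bb[2], bb[3], bb[4], width, height
      ))
    }
    if (provenance == "predicted" && is.null(inst$score)) {
      stop("predicted instances must carry a confidence score")
    }
    if (provenance != "predicted" && !is.null(inst$score)) {
      stop("ground-truth instances must not carry a score")
    }
    if (provenance == "points" && (bb[3] > 3 || bb[4] > 3)) {
      stop("points-provenance masks must be at most 3 x 3 pixels")
    }
    if (is.null(inst$id)) instances[[k]]$id <- k
  }
  structure(
    list(
      image_id = as.character(image_id), width = as.integer(width),
      height = as.integer(height), instances = instances,
      provenance = provenance
    ),
    class = "sheet_annotation"
  )
}

#' @export
print.sheet_annotation <- function(x, ...) {
  tab <- table(factor(
    vapply(x$instances, function(i) i$category, character(1)),
    levels = CATEGORY_NAMES
  ))
  cat(sprintf(
    "<sheet_annotation '%s' %dx%d, %s, %d instances (%s)>\n",
    x$image_id, x$width, x$height, x$provenance, length(x$instances),
    paste(sprintf("%s %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Per-category instance counts of one or more sheets
#'
#' @param sheets A [sheet_annotation()] or list of them.
#' @return Named integer vector over the four categories.
#' @export
count_instances <- function(sheets) {
  sheets <- as_sheet_list(sheets)
  cats <- unlist(lapply(sheets, function(s) {
    vapply(s$instances, function(i) i$category, character(1))
  }))
  table_out <- table(factor(cats, levels = CATEGORY_NAMES))
  stats::setNames(as.integer(table_out), CATEGORY_NAMES)
}

as_sheet_list <- function(sheets) {
  if (inherits(sheets, "sheet_annotation")) list(sheets) else sheets
}

# Decompose a mask into the polygon list written to file. Polygon masks are
# written verbatim. Raster masks are written exactly as one rectangle per
# maximal horizontal pixel run, so read(write(x)) reproduces the raster
# bit for bit.
mask_to_polygons <- function(mask) {
  if (mask$type == "polygon") {
    return(list(as.numeric(t(mask$polygon))))
  }
  ras <- mask$raster
  bb <- raster_bbox(ras)
  if (mask$area == bb[3] * bb[4]) {
    x <- bb[1]; y <- bb[2]; w <- bb[3]; h <- bb[4]
    return(list(c(x, y, x + w, y, x + w, y + h, x, y + h)))
  }
  polys <- list()
  for (r in seq_len(nrow(ras$mat))) {
    row <- ras$mat[r, ]
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1)
    ends <- which(d == -1) - 1L
    y <- ras$offset[2] + r - 1
    for (k in seq_along(starts)) {
      x0 <- ras$offset[1] + starts[k] - 1
      x1 <- ras$offset[1] + ends[k] # half-open right edge
      polys[[length(polys) + 1L]] <- c(x0, y, x1 + 1, y, x1 + 1, y + 1, x0, y + 1)
    }
  }
  polys
}

# Rebuild a mask from a COCO segmentation (list of flat polygon vectors).
# A single polygon stays a polygon mask; several are rasterized and merged.
polygons_to_mask <- function(seg) {
  polys <- lapply(seg, function(p) {
    matrix(as.numeric(p), ncol = 2, byrow = TRUE)
  })
  if (length(polys) == 1L) {
    return(mask_region(polygon = polys[[1]]))
  }
  rasters <- lapply(polys, function(p) rasterize_polygon(p[, 1], p[, 2]))
  x0 <- min(vapply(rasters, function(r) r$offset[1], numeric(1)))
  y0 <- min(vapply(rasters, function(r) r$offset[2], numeric(1)))
  x1 <- max(vapply(rasters, function(r) r$offset[1] + ncol(r$mat), numeric(1)))
  y1 <- max(vapply(rasters, function(r) r$offset[2] + nrow(r$mat), numeric(1)))
  mat <- matrix(FALSE, y1 - y0, x1 - x0)
  for (r in rasters) {
    if (!any(r$mat)) next
    ri <- (r$offset[2] - y0 + 1):(r$offset[2] - y0 + nrow(r$mat))
    ci <- (r$offset[1] - x0 + 1):(r$offset[1] - x0 + ncol(r$mat))
    mat[ri, ci] <- mat[ri, ci] | r$mat
  }
  mask_region(raster = mat, offset = c(x0, y0))
}

#' Read annotations from a COCO-dialect JSON file
#'
#' Every annotation is attached to its image; category ids are mapped onto
#' the four-category enumeration through the file's `categories` table. An
#' annotation whose category id is absent from that table is a hard error;
#' a polygon with fewer than 3 vertices is rejected with a warning and
#' reading continues.
#'
#' @param path Path to the JSON file.
#' @param provenance Override for the annotation regime; by default taken
#'   from the file's `info$provenance`, else `"predicted"` when scores are
#'   present, else `"full"`.
#' @return List of [sheet_annotation()] objects, one per image.
#' @export
read_annotations <- function(path, provenance = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cat_map <- new.env(parent = emptyenv())
  for (ct in doc$categories) {
    nm <- match.arg(ct$name, CATEGORY_NAMES)
    assign(as.character(ct$id), nm, envir = cat_map)
  }
  anns_by_image <- split(
    doc$annotations,
    vapply(doc$annotations, function(a) as.character(a$image_id), character(1))
  )
  has_score <- any(vapply(doc$annotations, function(a) !is.null(a$score), logical(1)))
  prov <- provenance %||% doc$info$provenance %||% (if (has_score) "predicted" else "full")
  sheets <- lapply(doc$images, function(img) {
    anns <- anns_by_image[[as.character(img$id)]] %||% list()
    instances <- list()
    for (a in anns) {
      cid <- as.character(a$category_id)
      if (!exists(cid, envir = cat_map)) {
        stop("unknown category id in annotation file: ", cid)
      }
      if (any(vapply(a$segmentation, length, integer(1)) < 6L)) {
        warning(sprintf(
          "dropping annotation %s on image %s: polygon with fewer than 3 vertices",
          a$id %||% "?", img$id
        ))
        next
      }
      mask <- polygons_to_mask(a$segmentation)
      instances[[length(instances) + 1L]] <- organ_instance(
        category = get(cid, envir = cat_map),
        mask = mask,
        score = a$score,
        id = a$id
      )
    }
    sheet_annotation(
      image_id = img$file_name %||% as.character(img$id),
      width = img$width, height = img$height,
      instances = instances, provenance = prov
    )
  })
  sheets
}

#' Write annotations to a COCO-dialect JSON file
#'
#' Inverse of [read_annotations()]: instance counts, categories and areas
#' round-trip exactly (polygon masks verbatim; raster masks as exact
#' rectangle decompositions).
#'
#' @param sheets A [sheet_annotation()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(sheets, path) {
  sheets <- as_sheet_list(sheets)
  images <- list()
  annotations <- list()
  ann_id <- 0L
  for (i in seq_along(sheets)) {
    s <- sheets[[i]]
    images[[i]] <- list(
      id = i, file_name = s$image_id,
      width = s$width, height = s$height
    )
    for (inst in s$instances) {
      ann_id <- ann_id + 1L
      bb <- mask_bbox(inst$mask)
      rec <- list(
        id = ann_id, image_id = i,
        category_id = category_id(inst$category),
        segmentation = mask_to_polygons(inst$mask),
        area = mask_area(inst$mask),
        bbox = bb
      )
      if (!is.null(inst$score)) rec$score <- inst$score
      annotations[[ann_id]] <- rec
    }
  }
  doc <- list(
    info = list(provenance = sheets[[1]]$provenance),
    images = images,
    annotations = annotations,
    categories = lapply(seq_len(4), function(i) {
      list(id = i, name = CATEGORY_NAMES[i])
    })
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch(
    {
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
      TRUE
    },
    error = function(e) stop("cannot write annotations to ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' Read predicted instances from a COCO results file
#'
#' Adapter for plugging an external detector into the evaluation pipeline:
#' any COCO-dialect file whose annotations carry `score` fields is read as
#' `predicted`-provenance sheets satisfying the segmenter contract.
#'
#' @param path Path to the results JSON.
#' @return List of [sheet_annotation()] objects with provenance `predicted`.
#' @export
read_predictions <- function(path) {
  read_annotations(path, provenance = "predicted")
}

#' Read an image file
#'
#' @param path PNG/JPEG/TIFF image path.
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3), c(dim(dat), 3))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  aperm(dat, c(2, 1, 3))
}

#' Write an image file
#'
#' @param image Numeric array `height x width x 3`, values in `[0, 1]`.
#' @param path Output path; format from the extension (PNG recommended).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image, path)
  invisible(path)
}

#' Resize a sheet image and its annotations
#'
#' Scales the image so its longest edge equals `target_long_edge`,
#' preserving aspect ratio, and applies the same scale factor to every mask.
#' Non-uniform scaling would corrupt downstream size measurement, so the
#' shorter edge is whatever the aspect ratio dictates (it equals half the
#' long edge only for 2:1 sheets).
#'
#' @param image Numeric `height x width x 3` array in `[0, 1]`, or `NULL`
#'   to rescale annotations only.
#' @param sheet A [sheet_annotation()] whose dimensions match the image.
#' @param target_long_edge Target size of the longest edge in pixels.
#' @return List with elements `image` and `sheet`.
#' @export
resize_image_and_annotations <- function(image, sheet, target_long_edge = 2048) {
  w <- sheet$width
  h <- sheet$height
  if (!is.null(image)) {
    if (length(dim(image)) != 3L || any(dim(image)[1:2] == 0L)) {
      stop("image must be a nonempty height x width x 3 array")
    }
    stopifnot(dim(image)[1] == h, dim(image)[2] == w)
  }
  s <- target_long_edge / max(w, h)
  new_w <- if (w >= h) as.integer(target_long_edge) else as.integer(round(w * s))
  new_h <- if (h > w) as.integer(target_long_edge) else as.integer(round(h * s))
  out_img <- NULL
  if (!is.null(image)) {
    if (s == 1) {
      out_img <- image
    } else {
      eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
      eb <- EBImage::resize(eb, w = new_w, h = new_h)
      out_img <- aperm(EBImage::imageData(eb), c(2, 1, 3))
      out_img[out_img < 0] <- 0
      out_img[out_img > 1] <- 1
    }
  }
  instances <- lapply(sheet$instances, function(inst) {
    m <- if (s == 1) inst$mask else scale_mask(inst$mask, s)
    organ_instance(inst$category, m, score = inst$score, id = inst$id)
  })
  out_sheet <- sheet_annotation(
    image_id = sheet$image_id, width = new_w, height = new_h,
    instances = instances, provenance = sheet$provenance
  )
  list(image = out_img, sheet = out_sheet)
}
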