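test_that("polygon rasterization follows the half-open pixel-center convention", {
  sq <- mask_region(polygon = cbind(c(3, 13, 13, 3), c(4, 4, 14, 14)))
  expect_equal(mask_area(sq), 100)
  expect_equal(mask_bbox(sq), c(3, 4, 10, 10))

  # discretization bound: raster area within the perimeter of the shoelace area
  tri <- mask_region(polygon = cbind(c(0, 20, 0), c(0, 0, 20)))
  perimeter <- 20 + 20 + sqrt(800)
  expect_lt(abs(mask_area(tri) - 200), perimeter)
})

test_that("rasterizing a polygon then re-extracting its bbox is idempotent", {
  set.seed(101)
  for (i in 1:50) {
    poly <- random_convex_polygon(runif(1, 50, 200), runif(1, 50, 200))
    m <- mask_region(polygon = poly)
    if (mask_area(m) == 0) next
    ras <- mask_raster(m)
    m2 <- mask_region(raster = ras$mat, offset = ras$offset)
    expect_equal(mask_bbox(m2), mask_bbox(m))
    expect_equal(mask_area(m2), mask_area(m))
    # raster area within the discretization bound of the shoelace area
    per <- sum(sqrt(rowSums((poly - poly[c(nrow(poly), 1:(nrow(poly) - 1)), ])^2)))
    expect_lt(abs(mask_area(m) - phenomask:::shoelace_area(poly)), per + 1)
  }
})

test_that("annotation files round-trip counts, categories, areas and provenance", {
  set.seed(7)
  sheets <- list(tiny_scene(2, seed = 1), tiny_scene(3, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(sheets, path)
  back <- read_annotations(path)
  expect_length(back, 2)
  expect_equal(count_instances(back), count_instances(sheets))
  expect_equal(back[[1]]$provenance, "full")
  for (k in seq_along(sheets[[1]]$instances)) {
    expect_equal(
      mask_area(back[[1]]$instances[[k]]$mask),
      mask_area(sheets[[1]]$instances[[k]]$mask)
    )
    expect_equal(
      back[[1]]$instances[[k]]$category,
      sheets[[1]]$instances[[k]]$category
    )
  }
})

test_that("random polygons survive the file round-trip with zero area drift", {
  set.seed(11)
  instances <- lapply(1:300, function(i) {
    gx <- 40 + ((i - 1) %% 20) * 90
    gy <- 40 + ((i - 1) %/% 20) * 90
    organ_instance(
      sample(categories()$name, 1),
      mask_region(polygon = random_convex_polygon(gx, gy, radius_max = 35))
    )
  })
  sheet <- sheet_annotation("grid", 1900, 1400, instances)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(sheet, path)
  back <- read_annotations(path)[[1]]
  drift <- vapply(seq_along(instances), function(k) {
    abs(mask_area(back$instances[[k]]$mask) - mask_area(instances[[k]]$mask))
  }, numeric(1))
  expect_lte(max(drift), 1)
})

test_that("points-provenance sheets keep their small square masks through I/O", {
  markers <- list(
    point_marker(0, 0, "bud"), point_marker(50, 0, "flower"),
    point_marker(120, 80, "immature_fruit"), point_marker(199, 99, "mature_fruit")
  )
  img <- array(0.5, c(100, 200, 3))
  sheet <- masks_from_markers(img, markers, mode = "points", image_id = "pts")
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(sheet, path)
  back <- read_annotations(path)[[1]]
  expect_equal(back$provenance, "points")
  for (inst in back$instances) {
    bb <- mask_bbox(inst$mask)
    expect_lte(bb[3], 3)
    expect_lte(bb[4], 3)
    expect_true(mask_area(inst$mask) %in% c(4, 6, 9))
  }
})

test_that("reader rejects unknown category ids and drops sub-3-vertex polygons", {
  doc <- list(
    info = list(provenance = "full"),
    images = list(list(id = 1, file_name = "a", width = 100, height = 100)),
    annotations = list(
      list(id = 1, image_id = 1, category_id = 9,
           segmentation = list(c(0, 0, 10, 0, 10, 10, 0, 10)),
           area = 100, bbox = c(0, 0, 10, 10))
    ),
    categories = lapply(1:4, function(i) list(id = i, name = categories()$name[i]))
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_annotations(path), "9")

  doc$annotations <- list(
    list(id = 1, image_id = 1, category_id = 1,
         segmentation = list(c(0, 0, 10, 10)), area = 0, bbox = c(0, 0, 10, 10)),
    list(id = 2, image_id = 1, category_id = 2,
         segmentation = list(c(0, 0, 10, 0, 10, 10, 0, 10)),
         area = 100, bbox = c(0, 0, 10, 10))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_warning(sheets <- read_annotations(path), "fewer than 3 vertices")
  expect_length(sheets[[1]]$instances, 1)
  expect_equal(mask_area(sheets[[1]]$instances[[1]]$mask), 100)
})

test_that("an empty annotations array yields a sheet with zero instances", {
  doc <- list(
    images = list(list(id = 1, file_name = "empty", width = 64, height = 64)),
    annotations = list(),
    categories = lapply(1:4, function(i) list(id = i, name = categories()$name[i]))
  )
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  sheets <- read_annotations(path)
  expect_length(sheets, 1)
  expect_length(sheets[[1]]$instances, 0)
})

test_that("resizing scales the image, bboxes and diagonals uniformly", {
  # 512x256 sheet halved to long edge 256: every bbox halves
  img <- array(runif(256 * 512 * 3), c(256, 512, 3))
  sheet <- sheet_annotation("rs", 512, 256, list(
    organ_instance("bud", square_mask(100, 60, 40)),
    organ_instance("flower", square_mask(300, 120, 60))
  ))
  out <- resize_image_and_annotations(img, sheet, target_long_edge = 256)
  expect_equal(dim(out$image)[1:2], c(128, 256))
  expect_equal(out$sheet$width, 256)
  expect_equal(mask_bbox(out$sheet$instances[[1]]$mask), c(50, 30, 20, 20))

  # already at target: identity
  same <- resize_image_and_annotations(img, sheet, target_long_edge = 512)
  expect_identical(same$image, img)
  expect_equal(mask_bbox(same$sheet$instances[[2]]$mask), c(300, 120, 60, 60))

  # 300x400 (w x h) sheet, 30x40 bbox: scaled within 1 px of direct arithmetic
  tall <- sheet_annotation("tall", 300, 400, list(
    organ_instance("bud", square_mask(50, 50, 30)),
    organ_instance("flower", mask_region(
      polygon = cbind(c(100, 130, 130, 100), c(200, 200, 240, 240))
    ))
  ))
  out2 <- resize_image_and_annotations(NULL, tall, target_long_edge = 2048)
  s <- 2048 / 400
  bb <- mask_bbox(out2$sheet$instances[[2]]$mask)
  expect_lt(abs(bb[3] - 30 * s), 1)
  expect_lt(abs(bb[4] - 40 * s), 1)
  # bbox diagonal scales by s within 1 px
  d0 <- sqrt(30^2 + 40^2)
  expect_lt(abs(sqrt(bb[3]^2 + bb[4]^2) - d0 * s), 1)
  expect_error(
    resize_image_and_annotations(array(0, c(0, 10, 3)), tall),
    "nonempty"
  )
})

test_that("sheet construction enforces score and bounds invariants", {
  m <- square_mask(10, 10, 20)
  expect_error(
    sheet_annotation("x", 25, 25, list(organ_instance("bud", m))),
    "bounds"
  )
  expect_error(
    sheet_annotation("x", 100, 100, list(organ_instance("bud", m, score = 0.5))),
    "score"
  )
  expect_error(
    sheet_annotation("x", 100, 100, list(organ_instance("bud", m)),
                     provenance = "predicted"),
    "score"
  )
})
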