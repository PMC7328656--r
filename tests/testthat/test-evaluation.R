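pred_sheet <- function(instances, width = 400, height = 400, id = "s") {
  sheet_annotation(id, width, height, instances, provenance = "predicted")
}
gt_sheet <- function(instances, width = 400, height = 400, id = "s") {
  sheet_annotation(id, width, height, instances, provenance = "full")
}

test_that("iou is exact pixel counting", {
  a <- square_mask(10, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, square_mask(100, 100, 10)), 0)
  # two 10x10 squares offset 5 px horizontally: 50 / 150
  b <- square_mask(15, 10, 10)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(iou(a, b), iou_pixels(a, b, 400, 400))
  line <- mask_region(polygon = cbind(c(0, 5, 5, 0), c(1, 1, 1, 1)))
  expect_error(iou(a, line), "zero-area")
  # random shapes match the whole-image pixel-counting oracle
  set.seed(3)
  for (i in 1:20) {
    pa <- mask_region(polygon = random_convex_polygon(60, 60, 40))
    pb <- mask_region(polygon = random_convex_polygon(75, 70, 40))
    if (mask_area(pa) == 0 || mask_area(pb) == 0) next
    expect_equal(iou(pa, pb), iou_pixels(pa, pb, 200, 200))
  }
})

test_that("matching is one-to-one, score-greedy and thresholded", {
  g1 <- organ_instance("bud", square_mask(10, 10, 10))
  g2 <- organ_instance("flower", square_mask(100, 100, 20))
  gt <- gt_sheet(list(g1, g2))

  # perfect predictions: all matched at IoU 1
  p <- pred_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), score = 1),
    organ_instance("flower", square_mask(100, 100, 20), score = 1)
  ))
  m <- match_instances(p, gt)
  expect_equal(nrow(m$matches), 2)
  expect_equal(m$matches$iou, c(1, 1))
  expect_equal(nrow(m$unmatched_pred), 0)
  expect_equal(nrow(m$unmatched_gt), 0)

  # two predictions over one object: the higher-score one wins
  p2 <- pred_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), score = 0.6, id = 1),
    organ_instance("bud", square_mask(11, 10, 10), score = 0.9, id = 2)
  ))
  m2 <- match_instances(p2, gt)
  expect_equal(m2$matches$pred_id, 2)
  expect_equal(m2$unmatched_pred$pred_id, 1)

  # IoU at or below the threshold does not match (1/3 and exactly 0.5)
  p3 <- pred_sheet(list(
    organ_instance("bud", square_mask(15, 10, 10), score = 0.9),
    organ_instance("flower", mask_region(
      polygon = cbind(c(100, 120, 120, 100), c(100, 100, 110, 110))
    ), score = 0.8)
  ))
  m3 <- match_instances(p3, gt)
  expect_equal(nrow(m3$matches), 0)
  expect_equal(nrow(m3$unmatched_gt), 2)

  expect_error(
    match_instances(pred_sheet(list(), id = "a"), gt_sheet(list(), id = "b")),
    "mismatch"
  )
})

test_that("greedy matching agrees with a step-by-step oracle on small scenes", {
  set.seed(17)
  for (rep in 1:20) {
    n_gt <- sample(1:5, 1)
    n_pr <- sample(1:5, 1)
    gt_inst <- lapply(seq_len(n_gt), function(k) {
      organ_instance(sample(categories()$name, 1),
                     square_mask(sample(0:60, 1), sample(0:60, 1), sample(8:20, 1)),
                     id = k)
    })
    pr_inst <- lapply(seq_len(n_pr), function(k) {
      organ_instance(sample(categories()$name, 1),
                     square_mask(sample(0:60, 1), sample(0:60, 1), sample(8:20, 1)),
                     score = round(runif(1), 3), id = k)
    })
    gt <- gt_sheet(gt_inst, 120, 120)
    pr <- pred_sheet(pr_inst, 120, 120)
    got <- match_instances(pr, gt)

    # oracle: full IoU matrix by pixel counting, then claim in score order
    iou_mat <- matrix(0, n_pr, n_gt)
    for (i in seq_len(n_pr)) {
      for (j in seq_len(n_gt)) {
        iou_mat[i, j] <- iou_pixels(pr_inst[[i]]$mask, gt_inst[[j]]$mask, 120, 120)
      }
    }
    scores <- vapply(pr_inst, function(x) x$score, numeric(1))
    claimed <- rep(FALSE, n_gt)
    pairs <- NULL
    for (i in order(-scores, seq_len(n_pr))) {
      cand <- which(!claimed & iou_mat[i, ] > 0.5)
      if (length(cand) == 0) next
      j <- cand[order(-iou_mat[i, cand], cand)][1]
      claimed[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
    expect_equal(nrow(got$matches), NROW(pairs))
    if (NROW(pairs) > 0) {
      got_pairs <- got$matches[order(got$matches$pred_id), c("pred_id", "gt_id")]
      oracle_pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
      expect_equal(unname(as.matrix(got_pairs)), unname(oracle_pairs))
    }
  }
})

test_that("matching is invariant to input order of equal-score predictions", {
  gt <- gt_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), id = 1),
    organ_instance("bud", square_mask(40, 40, 10), id = 2)
  ))
  insts <- list(
    organ_instance("bud", square_mask(10, 10, 10), score = 0.7, id = 1),
    organ_instance("bud", square_mask(40, 40, 10), score = 0.7, id = 2)
  )
  m_fwd <- match_instances(pred_sheet(insts), gt)
  m_rev <- match_instances(pred_sheet(rev(insts)), gt)
  ord <- function(m) m$matches[order(m$matches$pred_id), c("pred_id", "gt_id", "iou")]
  expect_equal(ord(m_fwd), ord(m_rev), ignore_attr = TRUE)
})

test_that("average precision follows the ranked cumulative-precision formula", {
  gt <- gt_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), id = 1),
    organ_instance("bud", square_mask(40, 40, 10), id = 2),
    organ_instance("bud", square_mask(70, 70, 10), id = 3)
  ))
  # ranks: correct, incorrect (false alarm), correct -> AP = (1 + 0 + 2/3)/3
  p <- pred_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), score = 0.9, id = 1),
    organ_instance("bud", square_mask(200, 200, 10), score = 0.8, id = 2),
    organ_instance("bud", square_mask(40, 40, 10), score = 0.7, id = 3)
  ))
  m <- match_instances(p, gt)
  expect_equal(average_precision(m, "bud"), 5 / 9)
  expect_equal(average_precision(m, "flower"), NA_real_)

  # all retrieved correctly, no extras -> AP 1; no predictions -> AP 0
  perfect <- pred_sheet(lapply(1:3, function(k) {
    organ_instance("bud", square_mask(10 + 30 * (k - 1), 10 + 30 * (k - 1), 10),
                   score = 0.9, id = k)
  }))
  expect_equal(average_precision(match_instances(perfect, gt), "bud"), 1)
  expect_equal(average_precision(match_instances(pred_sheet(list()), gt), "bud"), 0)

  # a geometric match with the wrong label is incorrect for both categories
  swapped <- pred_sheet(list(
    organ_instance("flower", square_mask(10, 10, 10), score = 0.9, id = 1)
  ))
  ms <- match_instances(swapped, gt)
  expect_equal(average_precision(ms, "bud"), 0)
})

test_that("average precision matches the brute-force loop on random suites", {
  set.seed(29)
  for (rep in 1:100) {
    n <- sample(1:20, 1)
    matched <- runif(n) < 0.6
    pred_cat <- sample(categories()$name, n, replace = TRUE)
    gt_cat <- ifelse(runif(n) < 0.8, pred_cat, sample(categories()$name, n, replace = TRUE))
    scores <- round(runif(n), 2) # duplicated scores exercise tie-breaking
    sides <- sample(20:200, n, replace = TRUE)
    n_extra_gt <- sample(0:5, 1)
    ms <- synthetic_match_set(
      matches = data.frame(
        image_id = rep("s", sum(matched)), pred_id = which(matched), gt_id = seq_len(sum(matched)),
        iou = runif(sum(matched), 0.5, 1), score = scores[matched],
        pred_category = pred_cat[matched], gt_category = gt_cat[matched],
        gt_max_side = sides[matched], stringsAsFactors = FALSE
      ),
      unmatched_pred = data.frame(
        image_id = rep("s", sum(!matched)), pred_id = which(!matched), score = scores[!matched],
        pred_category = pred_cat[!matched], pred_max_side = sides[!matched],
        stringsAsFactors = FALSE
      ),
      unmatched_gt = data.frame(
        image_id = rep("s", n_extra_gt), gt_id = 1000 + seq_len(n_extra_gt),
        gt_category = sample(categories()$name, n_extra_gt, replace = TRUE),
        gt_max_side = sample(20:200, n_extra_gt, replace = TRUE),
        stringsAsFactors = FALSE
      )
    )
    for (cat in categories()$name) {
      n_gt <- sum(gt_cat[matched] == cat) + sum(ms$unmatched_gt$gt_category == cat)
      got <- average_precision(ms, cat)
      if (n_gt == 0) {
        expect_true(is.na(got))
        next
      }
      sel_m <- pred_cat[matched] == cat
      sel_u <- pred_cat[!matched] == cat
      want <- ap_brute(
        c(scores[matched][sel_m], scores[!matched][sel_u]),
        c((gt_cat[matched] == cat)[sel_m], rep(FALSE, sum(sel_u))),
        sprintf("s %d", c(which(matched)[sel_m], which(!matched)[sel_u])),
        n_gt
      )
      expect_equal(got, want)
    }
  }
})

test_that("size-wise AP bins by max bbox side and matches subset recomputation", {
  # all ground truth 30 px and found -> small-bin AP 1, other bins absent
  gt <- gt_sheet(lapply(1:3, function(k) {
    organ_instance("bud", square_mask(10 + 40 * (k - 1), 10, 30), id = k)
  }), 200, 200)
  p <- pred_sheet(lapply(1:3, function(k) {
    organ_instance("bud", square_mask(10 + 40 * (k - 1), 10, 30), score = 0.9, id = k)
  }), 200, 200)
  sap <- sizewise_ap(match_instances(p, gt))
  expect_equal(unname(sap["small"]), 1)
  expect_true(is.na(sap["medium"]) && is.na(sap["large"]))

  # a 65-px instance is medium, not small; 64 px is small
  gt2 <- gt_sheet(list(
    organ_instance("flower", square_mask(10, 10, 65), id = 1),
    organ_instance("bud", square_mask(100, 100, 64), id = 2)
  ), 300, 300)
  p2 <- pred_sheet(list(
    organ_instance("flower", square_mask(10, 10, 65), score = 0.9, id = 1),
    organ_instance("bud", square_mask(100, 100, 64), score = 0.9, id = 2)
  ), 300, 300)
  sap2 <- sizewise_ap(match_instances(p2, gt2))
  expect_equal(unname(sap2["medium"]), 1)
  expect_equal(unname(sap2["small"]), 1)
  expect_true(is.na(sap2["large"]))

  # mixed perturbed suite: per-bin AP equals recomputation on the bin subset
  gt3 <- tiny_scene(3, seed = 8)
  pr3 <- perturb_predictions(gt3, perturbation_model(miss = 0.3, seed = 9))
  ms <- match_instances(pr3, gt3)
  sap3 <- sizewise_ap(ms)
  bins <- c(small = 64, medium = 128, large = Inf)
  lo <- c(small = 0, medium = 64, large = 128)
  for (b in names(bins)) {
    gt_sides <- c(ms$matches$gt_max_side, ms$unmatched_gt$gt_max_side)
    n_gt <- sum(gt_sides > lo[b] & gt_sides <= bins[b])
    if (n_gt == 0) {
      expect_true(is.na(sap3[b]))
      next
    }
    in_bin_m <- ms$matches$gt_max_side > lo[b] & ms$matches$gt_max_side <= bins[b]
    in_bin_u <- ms$unmatched_pred$pred_max_side > lo[b] &
      ms$unmatched_pred$pred_max_side <= bins[b]
    want <- ap_brute(
      c(ms$matches$score[in_bin_m], ms$unmatched_pred$score[in_bin_u]),
      c((ms$matches$gt_category == ms$matches$pred_category)[in_bin_m],
        rep(FALSE, sum(in_bin_u))),
      c(paste(ms$matches$image_id, ms$matches$pred_id)[in_bin_m],
        paste(ms$unmatched_pred$image_id, ms$unmatched_pred$pred_id)[in_bin_u]),
      n_gt
    )
    expect_equal(unname(sap3[b]), want)
  }
})

test_that("counting precision is detected over true, in percent", {
  expect_equal(counting_precision(10, 10), 100)
  expect_equal(counting_precision(12, 10), 120) # overestimate
  expect_equal(counting_precision(5, 10), 50)   # underestimate
  expect_true(is.na(counting_precision(3, 0)))
})

test_that("counting report covers categories, metacategories and score cutoff", {
  gt <- gt_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10)),
    organ_instance("flower", square_mask(40, 40, 10)),
    organ_instance("mature_fruit", square_mask(70, 70, 10))
  ))
  pr <- pred_sheet(list(
    organ_instance("bud", square_mask(10, 10, 10), score = 0.9),
    organ_instance("bud", square_mask(100, 100, 10), score = 0.8),
    organ_instance("flower", square_mask(40, 40, 10), score = 0.3) # below cutoff
  ))
  rep <- counting_report(list(pr), list(gt), score_threshold = 0.5)
  ps <- rep$per_sheet
  expect_equal(ps$cp[ps$category == "bud"], 200)
  expect_equal(ps$cp[ps$category == "flower"], 0)
  expect_true(is.na(ps$cp[ps$category == "immature_fruit"]))
  expect_equal(ps$cp[ps$category == "buds_flowers"], 100)
  expect_equal(ps$cp[ps$category == "fruits"], 0)
  expect_equal(ps$cp[ps$category == "all"], counting_precision(2, 3))
})

test_that("counting and measurement ratios are invariant under sheet duplication", {
  gt <- tiny_scene(2, seed = 14)
  pr <- perturb_predictions(gt, perturbation_model(miss = 0.25, seed = 15))
  one <- counting_report(list(pr), list(gt), score_threshold = 0)
  gt2 <- gt
  gt2$image_id <- "copy"
  pr2 <- pr
  pr2$image_id <- "copy"
  two <- counting_report(list(pr, pr2), list(gt, gt2), score_threshold = 0)
  expect_equal(two$pooled_cp, one$pooled_cp)
  m_one <- measurement_report(list(gt), list(pr), score_threshold = 0)
  m_two <- measurement_report(list(gt, gt2), list(pr, pr2), score_threshold = 0)
  expect_equal(m_two$mean_mp, m_one$mean_mp)
})

test_that("confusion matrix rows are detection probabilities with misdetection remainder", {
  gt <- gt_sheet(lapply(1:4, function(k) {
    organ_instance(categories()$name[k], square_mask(10 + 50 * (k - 1), 10, 20), id = k)
  }), 300, 300)
  perfect <- pred_sheet(lapply(1:4, function(k) {
    organ_instance(categories()$name[k], square_mask(10 + 50 * (k - 1), 10, 20),
                   score = 0.9, id = k)
  }), 300, 300)
  cm <- confusion_matrix(match_instances(perfect, gt))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_equal(unname(attr(cm, "misdetection")), rep(0, 4))

  # all flowers detected but labeled bud
  gt_f <- gt_sheet(list(organ_instance("flower", square_mask(10, 10, 20), id = 1)))
  pr_f <- pred_sheet(list(organ_instance("bud", square_mask(10, 10, 20),
                                         score = 0.9, id = 1)))
  cm_f <- confusion_matrix(match_instances(pr_f, gt_f))
  expect_equal(cm_f["flower", "bud"], 1)
  expect_equal(cm_f["flower", "flower"], 0)
  expect_true(all(is.na(cm_f["bud", ])))
  expect_lte(sum(cm_f["flower", ]), 1)
})

test_that("sizes are bounding-box diagonals in calibrated centimeters", {
  cal <- scale_calibration()
  expect_equal(round(sqrt(2) * 128 * cal$cm_per_pixel, 2), 1.52)
  expect_equal(round(sqrt(2) * 64 * cal$cm_per_pixel, 2), 0.76)
  # 3-4-5 triangle: bbox (0,0,30,40) at 0.01 cm/px -> 0.5 cm
  sheet <- gt_sheet(list(organ_instance(
    "bud", mask_region(polygon = cbind(c(0, 30, 30, 0), c(0, 0, 40, 40)))
  )), 100, 100)
  sz <- instance_sizes(sheet, scale_calibration(0.01))
  expect_equal(sz$size_cm, 0.5)

  stats <- measurement_statistics(list(sheet), list(pred_sheet(list(), 100, 100)))
  expect_equal(stats$n[stats$category == "bud" & stats$source == "truth"], 1)
  expect_equal(stats$n[stats$category == "bud" & stats$source == "prediction"], 0)
})

test_that("measurement precision is mean predicted over mean true", {
  expect_equal(measurement_precision(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(measurement_precision(c(1, 2), c(1.1, 2.2)), 110)
  expect_true(is.na(measurement_precision(numeric(0), c(1))))
  expect_true(is.na(measurement_precision(c(1), numeric(0))))
})
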