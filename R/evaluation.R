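# Evaluation of predicted instances against ground truth: IoU-thresholded
# one-to-one matching, average precision at IoU > 50%, size-wise AP,
# counting precision, detection/confusion probability matrix, and
# bounding-box-diagonal size measurement.

#' Match predicted to ground-truth instances on one sheet
#'
#' Predictions are processed in decreasing confidence order (ties broken by
#' lower instance id); each claims the still-unclaimed ground-truth
#' instance of highest IoU above the threshold (ties broken by lower
#' ground-truth id). The geometric claim is category-agnostic; label
#' correctness is judged later by [average_precision()] and
#' [confusion_matrix()], which is what allows cross-category confusions to
#' register at all. Leftover predictions are false alarms; leftover ground
#' truths are misses.
#'
#' @param pred A [sheet_annotation()] with provenance `predicted`.
#' @param gt The ground-truth [sheet_annotation()] for the same image.
#' @param iou_threshold Minimum IoU (exclusive) for a match; default 0.5.
#' @return An object of class `match_set`: data frames `matches`,
#'   `unmatched_pred`, `unmatched_gt`, plus `iou_threshold`.
#' @export
match_instances <- function(pred, gt, iou_threshold = 0.5) {
  if (pred$image_id != gt$image_id) {
    stop(sprintf(
      "image id mismatch: predictions are for '%s', ground truth for '%s'",
      pred$image_id, gt$image_id
    ))
  }
  np <- length(pred$instances)
  ng <- length(gt$instances)
  pred_info <- instance_table(pred)
  gt_info <- instance_table(gt)
  matches <- data.frame(
    image_id = character(0), pred_id = integer(0), gt_id = integer(0),
    iou = numeric(0), score = numeric(0),
    pred_category = character(0), gt_category = character(0),
    gt_max_side = numeric(0), stringsAsFactors = FALSE
  )
  claimed <- rep(FALSE, ng)
  matched_pred <- rep(FALSE, np)
  if (np > 0L && ng > 0L) {
    pred_rasters <- lapply(pred$instances, function(i) mask_raster(i$mask))
    gt_rasters <- lapply(gt$instances, function(i) mask_raster(i$mask))
    order_pred <- order(-pred_info$score, pred_info$id)
    for (p in order_pred) {
      bb <- pred_info[p, c("x", "y", "w", "h")]
      cand <- which(!claimed &
        gt_info$x < bb$x + bb$w & gt_info$x + gt_info$w > bb$x &
        gt_info$y < bb$y + bb$h & gt_info$y + gt_info$h > bb$y)
      if (length(cand) == 0L) next
      ious <- vapply(cand, function(g) iou_rasters(pred_rasters[[p]], gt_rasters[[g]]), numeric(1))
      ok <- ious > iou_threshold
      if (!any(ok)) next
      cand <- cand[ok]
      ious <- ious[ok]
      best <- cand[order(-ious, gt_info$id[cand])][1]
      claimed[best] <- TRUE
      matched_pred[p] <- TRUE
      matches <- rbind(matches, data.frame(
        image_id = pred$image_id,
        pred_id = pred_info$id[p], gt_id = gt_info$id[best],
        iou = ious[match(best, cand)], score = pred_info$score[p],
        pred_category = pred_info$category[p],
        gt_category = gt_info$category[best],
        gt_max_side = pmax(gt_info$w[best], gt_info$h[best]),
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(list(
    matches = matches,
    unmatched_pred = data.frame(
      image_id = rep(pred$image_id, sum(!matched_pred)),
      pred_id = pred_info$id[!matched_pred],
      score = pred_info$score[!matched_pred],
      pred_category = pred_info$category[!matched_pred],
      pred_max_side = pmax(pred_info$w[!matched_pred], pred_info$h[!matched_pred]),
      stringsAsFactors = FALSE
    ),
    unmatched_gt = data.frame(
      image_id = rep(gt$image_id, sum(!claimed)),
      gt_id = gt_info$id[!claimed],
      gt_category = gt_info$category[!claimed],
      gt_max_side = pmax(gt_info$w[!claimed], gt_info$h[!claimed]),
      stringsAsFactors = FALSE
    ),
    iou_threshold = iou_threshold
  ), class = "match_set")
}

instance_table <- function(sheet) {
  n <- length(sheet$instances)
  data.frame(
    id = vapply(sheet$instances, function(i) as.integer(i$id %||% NA_integer_), integer(1)),
    category = vapply(sheet$instances, function(i) i$category, character(1)),
    score = vapply(sheet$instances, function(i) i$score %||% NA_real_, numeric(1)),
    x = vapply(sheet$instances, function(i) mask_bbox(i$mask)[1], numeric(1)),
    y = vapply(sheet$instances, function(i) mask_bbox(i$mask)[2], numeric(1)),
    w = vapply(sheet$instances, function(i) mask_bbox(i$mask)[3], numeric(1)),
    h = vapply(sheet$instances, function(i) mask_bbox(i$mask)[4], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Match a whole set of sheets
#'
#' Runs [match_instances()] per sheet pair (paired by image id) and pools
#' the results into one `match_set`.
#'
#' @param preds,gts Lists of [sheet_annotation()] objects covering the same
#'   image ids.
#' @param iou_threshold Minimum IoU for a match.
#' @return A pooled `match_set`.
#' @export
match_sheets <- function(preds, gts, iou_threshold = 0.5) {
  preds <- as_sheet_list(preds)
  gts <- as_sheet_list(gts)
  gt_ids <- vapply(gts, function(s) s$image_id, character(1))
  sets <- lapply(preds, function(p) {
    g <- gts[[match(p$image_id, gt_ids)]]
    if (is.null(g)) stop("no ground truth for image ", p$image_id)
    match_instances(p, g, iou_threshold)
  })
  structure(list(
    matches = do.call(rbind, lapply(sets, `[[`, "matches")),
    unmatched_pred = do.call(rbind, lapply(sets, `[[`, "unmatched_pred")),
    unmatched_gt = do.call(rbind, lapply(sets, `[[`, "unmatched_gt")),
    iou_threshold = iou_threshold
  ), class = "match_set")
}

gt_category_counts <- function(matches) {
  cats <- c(matches$matches$gt_category, matches$unmatched_gt$gt_category)
  table(factor(cats, levels = CATEGORY_NAMES))
}

#' Average precision for one category at the match set's IoU threshold
#'
#' All predictions of the category (matched or not) are sorted by
#' decreasing confidence score; rank k is correct when the prediction
#' geometrically matched a ground-truth instance of the same category.
#' With P(k) the precision over the top-k ranks,
#' `AP = sum_k P(k) * correct_k / N_gt`, where `N_gt` is the number of
#' ground-truth instances of the category.
#'
#' @param matches A `match_set` from [match_instances()] or [match_sheets()].
#' @param category Category name.
#' @return AP in `[0, 1]`, or `NA` when the category has no ground truth.
#' @export
average_precision <- function(matches, category) {
  category <- match.arg(category, CATEGORY_NAMES)
  n_gt <- as.integer(gt_category_counts(matches)[category])
  if (n_gt == 0L) return(NA_real_)
  m <- matches$matches
  u <- matches$unmatched_pred
  score <- c(m$score[m$pred_category == category], u$score[u$pred_category == category])
  correct <- c(
    (m$gt_category == m$pred_category)[m$pred_category == category],
    rep(FALSE, sum(u$pred_category == category))
  )
  ids <- c(
    paste(m$image_id, m$pred_id)[m$pred_category == category],
    paste(u$image_id, u$pred_id)[u$pred_category == category]
  )
  ap_from_ranked(score, correct, ids, n_gt)
}

ap_from_ranked <- function(score, correct, ids, n_gt) {
  if (length(score) == 0L) return(0)
  o <- order(-score, ids)
  correct <- correct[o]
  p_k <- cumsum(correct) / seq_along(correct)
  sum(p_k * correct) / n_gt
}

#' Size-wise average precision
#'
#' Ground-truth instances are partitioned by the maximum side of their
#' bounding box into Small (1--64 px), Medium (65--128 px) and Large
#' (> 128 px) bins, and the AP is computed within each bin with all four
#' categories pooled (a rank is correct when geometrically matched with
#' the right label). Matched predictions inherit their ground truth's bin;
#' false alarms are binned by their own bounding box.
#'
#' @param matches A `match_set`.
#' @return Named numeric vector (`small`, `medium`, `large`); `NA` for an
#'   empty bin.
#' @export
sizewise_ap <- function(matches) {
  m <- matches$matches
  up <- matches$unmatched_pred
  ug <- matches$unmatched_gt
  bins <- c("small", "medium", "large")
  gt_bin <- table(factor(
    c(as.character(size_bin_of(m$gt_max_side)), as.character(size_bin_of(ug$gt_max_side))),
    levels = bins
  ))
  out <- stats::setNames(rep(NA_real_, 3), bins)
  pred_bin <- c(as.character(size_bin_of(m$gt_max_side)), as.character(size_bin_of(up$pred_max_side)))
  score <- c(m$score, up$score)
  correct <- c(m$gt_category == m$pred_category, rep(FALSE, nrow(up)))
  ids <- c(paste(m$image_id, m$pred_id), paste(up$image_id, up$pred_id))
  for (b in bins) {
    n_gt <- as.integer(gt_bin[b])
    if (n_gt == 0L) next
    sel <- pred_bin == b
    out[b] <- ap_from_ranked(score[sel], correct[sel], ids[sel], n_gt)
  }
  out
}

#' Counting precision
#'
#' Percent ratio of the automated count to the true (manually annotated)
#' count: `CP = 100 * pred_count / true_count`. A CP above 100% means the
#' automated count overestimates; below 100%, it underestimates. No IoU
#' matching is involved.
#'
#' @param pred_count Automatically detected instance count.
#' @param true_count Manually annotated instance count (>= 1).
#' @return CP in percent; `NA` when `true_count` is 0.
#' @examples
#' counting_precision(12, 10) # 120
#' @export
counting_precision <- function(pred_count, true_count) {
  ifelse(true_count >= 1, 100 * pred_count / true_count, NA_real_)
}

#' Counting-precision report over a sheet set
#'
#' Per sheet and per category (including the metacategories `buds_flowers`
#' and `fruits` and the pooled `all`), counts predictions whose score is at
#' least `score_threshold` and computes [counting_precision()]. Sheets with
#' no true instances of a category yield `NA` for it.
#'
#' @param preds,gts Lists of [sheet_annotation()] objects (paired by image
#'   id).
#' @param score_threshold Minimum prediction score to be counted.
#' @return List with `per_sheet` (long data frame: `image_id`, `category`,
#'   `true_count`, `pred_count`, `cp`), `mean_cp` (per-category mean of
#'   per-sheet CPs) and `pooled_cp` (CP of summed counts).
#' @export
counting_report <- function(preds, gts, score_threshold = 0.5) {
  preds <- as_sheet_list(preds)
  gts <- as_sheet_list(gts)
  gt_ids <- vapply(gts, function(s) s$image_id, character(1))
  groups <- c(
    as.list(stats::setNames(CATEGORY_NAMES, CATEGORY_NAMES)),
    list(
      buds_flowers = metacategory_members("buds_flowers"),
      fruits = metacategory_members("fruits"),
      all = CATEGORY_NAMES
    )
  )
  rows <- list()
  for (p in preds) {
    g <- gts[[match(p$image_id, gt_ids)]]
    pc <- count_instances(filter_by_score(p, score_threshold))
    gc <- count_instances(g)
    for (nm in names(groups)) {
      true_n <- sum(gc[groups[[nm]]])
      pred_n <- sum(pc[groups[[nm]]])
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = p$image_id, category = nm,
        true_count = true_n, pred_count = pred_n,
        cp = counting_precision(pred_n, true_n),
        stringsAsFactors = FALSE
      )
    }
  }
  per_sheet <- do.call(rbind, rows)
  agg <- function(f) {
    vapply(names(groups), function(nm) {
      d <- per_sheet[per_sheet$category == nm, ]
      f(d)
    }, numeric(1))
  }
  list(
    per_sheet = per_sheet,
    mean_cp = agg(function(d) mean(d$cp, na.rm = TRUE)),
    pooled_cp = agg(function(d) counting_precision(sum(d$pred_count), sum(d$true_count)))
  )
}

filter_by_score <- function(sheet, score_threshold) {
  if (sheet$provenance != "predicted" || score_threshold <= 0) return(sheet)
  keep <- vapply(sheet$instances, function(i) i$score >= score_threshold, logical(1))
  sheet$instances <- sheet$instances[keep]
  sheet
}

#' Detection and confusion probability matrix
#'
#' Entry (i, j) is the fraction of ground-truth instances of category i
#' whose matched prediction (the best match by prediction score, as
#' enforced by the greedy matching) carries category j. Rows need not sum
#' to 1: an organ may not be detected at all, and `1 - sum(row)` is its
#' misdetection probability, returned as the `misdetection` attribute /
#' column. Categories with no ground truth yield `NA` rows.
#'
#' @param matches A `match_set`.
#' @return 4 x 4 matrix (rows = ground truth, columns = predicted) with a
#'   `misdetection` attribute vector.
#' @export
confusion_matrix <- function(matches) {
  n_gt <- gt_category_counts(matches)
  if (sum(n_gt) == 0L) stop("confusion matrix requires nonempty ground truth")
  m <- matches$matches
  counts <- table(
    factor(m$gt_category, levels = CATEGORY_NAMES),
    factor(m$pred_category, levels = CATEGORY_NAMES)
  )
  probs <- matrix(NA_real_, 4, 4, dimnames = list(CATEGORY_NAMES, CATEGORY_NAMES))
  misdetect <- stats::setNames(rep(NA_real_, 4), CATEGORY_NAMES)
  for (i in seq_len(4)) {
    if (n_gt[i] > 0L) {
      probs[i, ] <- counts[i, ] / as.integer(n_gt[i])
      misdetect[i] <- 1 - sum(probs[i, ])
    }
  }
  attr(probs, "misdetection") <- misdetect
  probs
}

#' Instance sizes as bounding-box diagonals in centimeters
#'
#' The size of an instance is the diagonal length of the bounding box
#' surrounding its mask, `sqrt(w^2 + h^2)`, converted to cm.
#'
#' @param sheets A [sheet_annotation()] or list of them.
#' @param calibration A [scale_calibration()].
#' @param score_threshold Minimum score for predicted instances; ignored
#'   for ground truth.
#' @return Data frame `image_id`, `category`, `size_cm`, `score`.
#' @export
instance_sizes <- function(sheets, calibration = scale_calibration(),
                           score_threshold = 0) {
  sheets <- as_sheet_list(sheets)
  rows <- lapply(sheets, function(s) {
    s <- filter_by_score(s, score_threshold)
    if (length(s$instances) == 0L) return(NULL)
    info <- instance_table(s)
    data.frame(
      image_id = s$image_id, category = info$category,
      size_cm = px_to_cm(sqrt(info$w^2 + info$h^2), calibration),
      score = info$score, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      image_id = character(0), category = character(0),
      size_cm = numeric(0), score = numeric(0), stringsAsFactors = FALSE
    )
  }
  out
}

#' Measurement statistics: size distributions per category
#'
#' Quartile summaries (in cm) of the bounding-box-diagonal sizes of
#' ground-truth and predicted instances, per category and for the
#' metacategories.
#'
#' @param gt_sheets,pred_sheets Sheet lists.
#' @param calibration A [scale_calibration()].
#' @param score_threshold Minimum score for counted predictions.
#' @return Data frame with `category`, `source` (`truth` / `prediction`),
#'   `n`, `min`, `q1`, `median`, `mean`, `q3`, `max` (cm, 2 decimals).
#' @export
measurement_statistics <- function(gt_sheets, pred_sheets,
                                   calibration = scale_calibration(),
                                   score_threshold = 0.5) {
  gt <- instance_sizes(gt_sheets, calibration)
  pr <- instance_sizes(pred_sheets, calibration, score_threshold)
  groups <- c(
    as.list(stats::setNames(CATEGORY_NAMES, CATEGORY_NAMES)),
    list(
      buds_flowers = metacategory_members("buds_flowers"),
      fruits = metacategory_members("fruits")
    )
  )
  summarize <- function(sizes, category, source) {
    if (length(sizes) == 0L) {
      return(data.frame(
        category = category, source = source, n = 0L,
        min = NA_real_, q1 = NA_real_, median = NA_real_,
        mean = NA_real_, q3 = NA_real_, max = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    q <- stats::quantile(sizes, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(
      category = category, source = source, n = length(sizes),
      min = round_half_up(q[1], 2), q1 = round_half_up(q[2], 2),
      median = round_half_up(q[3], 2), mean = round_half_up(mean(sizes), 2),
      q3 = round_half_up(q[4], 2), max = round_half_up(q[5], 2),
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (nm in names(groups)) {
    out[[length(out) + 1L]] <- summarize(gt$size_cm[gt$category %in% groups[[nm]]], nm, "truth")
    out[[length(out) + 1L]] <- summarize(pr$size_cm[pr$category %in% groups[[nm]]], nm, "prediction")
  }
  do.call(rbind, out)
}

#' Measurement precision
#'
#' Percent ratio of the mean predicted size to the mean true size:
#' `MP = 100 * mean(pred_sizes) / mean(gt_sizes)`. Above 100% means the
#' true average size is overestimated.
#'
#' @param gt_sizes True sizes (cm), nonempty.
#' @param pred_sizes Predicted sizes (cm).
#' @return MP in percent; `NA` when either list is empty.
#' @export
measurement_precision <- function(gt_sizes, pred_sizes) {
  if (length(gt_sizes) == 0L || length(pred_sizes) == 0L) return(NA_real_)
  100 * mean(pred_sizes) / mean(gt_sizes)
}

#' Measurement-precision report over a sheet set
#'
#' Per sheet and per category (plus metacategories), the [measurement_precision()]
#' of predicted vs. true bounding-box diagonals.
#'
#' @inheritParams measurement_statistics
#' @return List with `per_sheet` (long data frame) and `mean_mp`
#'   (per-category mean across sheets).
#' @export
measurement_report <- function(gt_sheets, pred_sheets,
                               calibration = scale_calibration(),
                               score_threshold = 0.5) {
  gt <- instance_sizes(gt_sheets, calibration)
  pr <- instance_sizes(pred_sheets, calibration, score_threshold)
  groups <- c(
    as.list(stats::setNames(CATEGORY_NAMES, CATEGORY_NAMES)),
    list(
      buds_flowers = metacategory_members("buds_flowers"),
      fruits = metacategory_members("fruits"),
      all = CATEGORY_NAMES
    )
  )
  ids <- unique(c(gt$image_id, pr$image_id))
  rows <- list()
  for (id in ids) {
    for (nm in names(groups)) {
      g <- gt$size_cm[gt$image_id == id & gt$category %in% groups[[nm]]]
      p <- pr$size_cm[pr$image_id == id & pr$category %in% groups[[nm]]]
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, category = nm,
        n_true = length(g), n_pred = length(p),
        mp = measurement_precision(g, p), stringsAsFactors = FALSE
      )
    }
  }
  per_sheet <- do.call(rbind, rows)
  mean_mp <- vapply(names(groups), function(nm) {
    mean(per_sheet$mp[per_sheet$category == nm], na.rm = TRUE)
  }, numeric(1))
  list(per_sheet = per_sheet, mean_mp = mean_mp)
}

#' Full evaluation of predictions against ground truth
#'
#' Runs the whole metric suite on a sheet set: counting precision, AP per
#' category at the given IoU threshold, size-wise AP, the
#' detection/confusion probability matrix, measurement statistics and
#' measurement precision.
#'
#' @param preds,gts Lists of [sheet_annotation()] objects paired by image id.
#' @param iou_threshold IoU threshold for matching (default 0.5).
#' @param score_threshold Score cutoff for counting and measurement
#'   (default 0.5); AP always uses the full ranked prediction list.
#' @param calibration A [scale_calibration()].
#' @return An object of class `metrics_report`.
#' @export
evaluate_sheets <- function(preds, gts, iou_threshold = 0.5,
                            score_threshold = 0.5,
                            calibration = scale_calibration()) {
  preds <- as_sheet_list(preds)
  gts <- as_sheet_list(gts)
  matches <- match_sheets(preds, gts, iou_threshold)
  ap <- vapply(CATEGORY_NAMES, function(cat) average_precision(matches, cat), numeric(1))
  cm <- confusion_matrix(matches)
  structure(list(
    counting = counting_report(preds, gts, score_threshold),
    ap = ap,
    sizewise_ap = sizewise_ap(matches),
    confusion = cm,
    misdetection = attr(cm, "misdetection"),
    measurement = measurement_statistics(gts, preds, calibration, score_threshold),
    measurement_precision = measurement_report(gts, preds, calibration, score_threshold),
    matches = matches,
    params = list(
      iou_threshold = iou_threshold, score_threshold = score_threshold,
      cm_per_pixel = calibration$cm_per_pixel
    )
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation report (IoU >", x$params$iou_threshold,
      ", score >=", x$params$score_threshold, ")\n\n")
  cat("Mean counting precision (%):\n")
  print(round(x$counting$mean_cp, 1))
  cat("\nAverage precision per category:\n")
  print(round(x$ap, 3))
  cat("\nSize-wise AP:\n")
  print(round(x$sizewise_ap, 3))
  cat("\nConfusion matrix (rows = ground truth):\n")
  print(round(x$confusion, 3))
  cat("misdetection:", paste(round(x$misdetection, 3), collapse = " "), "\n")
  cat("\nMean measurement precision (%):\n")
  print(round(x$measurement_precision$mean_mp, 1))
  invisible(x)
}
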