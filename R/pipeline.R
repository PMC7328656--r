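# End-to-end pipeline: synthesize (or load) sheets, detect, evaluate,
# render reports. The command-line wrapper in inst/cli/phenomask.R is a
# thin shell over these functions.

#' Pipeline run configuration
#'
#' One flat document of every tunable the pipeline uses; a config file (YAML,
#' keys named exactly as below) round-trips unchanged and its hash is
#' recorded in the run manifest so runs are reproducible by reference.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer master seed for every random stage.
#' @param n_sheets Number of synthetic sheets to generate.
#' @param width,height Synthetic sheet dimensions in pixels.
#' @param iou_threshold IoU threshold for matching, in `(0, 1]`.
#' @param score_threshold Score cutoff for counting/measurement, in `(0, 1]`.
#' @param cm_per_pixel Scale calibration (cm per pixel).
#' @param window_size Partial-mask window side in pixels.
#' @param target_long_edge Resize target for the longest image edge.
#' @param detector `"baseline"` or `"perturbation"` (synthetic predictions
#'   from a [perturbation_model()]; useful for calibration studies).
#' @param miss,false_alarm_rate,jitter_radius Perturbation parameters used
#'   when `detector = "perturbation"`.
#' @param file Optional YAML file whose values seed the config; explicit
#'   arguments override file values.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = "phenomask_run", seed = 1, n_sheets = 4,
                       width = 2048, height = 1024,
                       iou_threshold = 0.5, score_threshold = 0.5,
                       cm_per_pixel = 0.0084, window_size = 100,
                       target_long_edge = 2048, detector = "baseline",
                       miss = 0, false_alarm_rate = 0, jitter_radius = 0,
                       file = NULL) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), n_sheets = as.integer(n_sheets),
    width = as.integer(width), height = as.integer(height),
    iou_threshold = iou_threshold, score_threshold = score_threshold,
    cm_per_pixel = cm_per_pixel, window_size = window_size,
    target_long_edge = target_long_edge, detector = detector,
    miss = miss, false_alarm_rate = false_alarm_rate,
    jitter_radius = jitter_radius
  )
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    explicit <- names(as.list(match.call()))[-1]
    for (nm in setdiff(names(from_file), explicit)) cfg[[nm]] <- from_file[[nm]]
  }
  stopifnot(
    cfg$iou_threshold > 0, cfg$iou_threshold <= 1,
    cfg$score_threshold > 0, cfg$score_threshold <= 1,
    cfg$cm_per_pixel > 0, cfg$window_size > 0, cfg$target_long_edge > 0,
    cfg$n_sheets >= 1
  )
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Generates `n_sheets` synthetic sheets with ground truth, produces
#' predictions (baseline detector on the rendered images, or the
#' perturbation model on the annotations), evaluates them, and writes the
#' artifacts under `config$out_dir`: ground-truth and prediction JSON,
#' report JSON and CSV tables, a plain-text summary, and a manifest
#' (package version, seed, config and its hash). Deterministic for a fixed
#' config. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param write_images Also write the rendered sheet PNGs (off by default;
#'   they are large).
#' @return The [evaluate_sheets()] `metrics_report`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), write_images = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  render <- config$detector == "baseline" || write_images
  sim <- stage("synth", {
    lapply(seq_len(config$n_sheets), function(i) {
      generate_sheet(
        sheet_recipe(
          width = config$width, height = config$height,
          counts = default_counts_for(config$width, config$height),
          seed = derive_seed(config$seed, i)
        ),
        render = render, image_id = sprintf("sheet_%02d", i)
      )
    })
  })
  gts <- lapply(sim, `[[`, "sheet")
  preds <- stage("detect", {
    if (config$detector == "baseline") {
      lapply(sim, function(s) {
        baseline_segment(s$image, image_id = s$sheet$image_id)
      })
    } else {
      perturb_predictions(gts, perturbation_model(
        miss = config$miss, false_alarm_rate = config$false_alarm_rate,
        jitter_radius = config$jitter_radius,
        seed = derive_seed(config$seed, 9999L)
      ))
    }
  })
  report <- stage("evaluate", {
    evaluate_sheets(
      preds, gts,
      iou_threshold = config$iou_threshold,
      score_threshold = config$score_threshold,
      calibration = scale_calibration(config$cm_per_pixel)
    )
  })
  stage("report", write_report(report, gts, preds, config, sim, write_images))
  invisible(report)
}

write_report <- function(report, gts, preds, config, sim, write_images) {
  out <- config$out_dir
  write_annotations(gts, file.path(out, "ground_truth.json"))
  write_annotations(preds, file.path(out, "predictions.json"))
  if (write_images) {
    for (s in sim) {
      if (!is.null(s$image)) {
        write_image(s$image, file.path(out, paste0(s$sheet$image_id, ".png")))
      }
    }
  }
  json <- list(
    counting_mean_cp = as.list(report$counting$mean_cp),
    counting_pooled_cp = as.list(report$counting$pooled_cp),
    ap = as.list(report$ap),
    sizewise_ap = as.list(report$sizewise_ap),
    confusion = apply(report$confusion, 1, as.list, simplify = FALSE),
    misdetection = as.list(report$misdetection),
    measurement_precision_mean = as.list(report$measurement_precision$mean_mp),
    params = report$params
  )
  jsonlite::write_json(json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$counting$per_sheet,
                   file.path(out, "counting_precision.csv"), row.names = FALSE)
  utils::write.csv(report$measurement,
                   file.path(out, "measurement_statistics.csv"), row.names = FALSE)
  utils::write.csv(report$measurement_precision$per_sheet,
                   file.path(out, "measurement_precision.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(category = CATEGORY_NAMES, ap = unname(report$ap)),
    file.path(out, "average_precision.csv"), row.names = FALSE
  )
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(out, "confusion_matrix.csv"))
  summary_path <- file.path(out, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  cfg_plain <- unclass(config)
  manifest <- list(
    package = "phenomask",
    version = as.character(utils::packageVersion("phenomask")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = config_hash(cfg_plain),
    n_sheets = length(gts)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

# Scale the default per-sheet instance counts with sheet area so small
# sheets stay packable.
default_counts_for <- function(width, height) {
  f <- min(1, (as.double(width) * height) / (2048 * 1024))
  base <- c(bud = 13, flower = 17, immature_fruit = 9, mature_fruit = 10)
  stats::setNames(pmax(1L, as.integer(round(base * f))), names(base))
}

# Order-independent hash of the flat config document (no external digest
# dependency: sum of a rolling polynomial over the serialized key=value
# pairs, printed as hex).
config_hash <- function(cfg) {
  s <- paste(sort(sprintf("%s=%s", names(cfg), vapply(cfg, function(v) {
    paste(format(v, digits = 15), collapse = ",")
  }, character(1)))), collapse = ";")
  bytes <- utf8ToInt(s)
  acc <- 0
  for (b in bytes) acc <- (acc * 131 + b) %% 2^31
  sprintf("%08x", acc)
}
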