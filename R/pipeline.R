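#' Pipeline configuration
#'
#' One flat configuration for the whole two-stage workflow: cohort
#' simulation, patient-level split, U-net training, prediction-mask
#' refinement, metric evaluation and component clustering. All stage seeds
#' are derived from the single `seed`, so one value determines every random
#' draw in a run.
#'
#' @param out_dir Output directory for all artifacts.
#' @param n_masses Cohort size for simulation.
#' @param canvas_size Phantom canvas side (pixels).
#' @param input_size,depth,base_filters,learning_rate,max_epochs,minibatch_size
#'   U-net settings (see [unet_config()]).
#' @param goal_train_fraction Stratified split goal.
#' @param smoothing_window,threshold Refinement settings (see
#'   [refinement_params()]).
#' @param fcm_m,fcm_tol,fcm_max_iter Fuzzy c-means settings.
#' @param component_mask Which mask defines in-mass pixels for component
#'   clustering: the refined `"predicted"` mask or the `"expert"` outline.
#' @param n_boot Bootstrap replicates for cohort summaries.
#' @param two_mass_fraction Passed to [generate_cohort()].
#' @param test_profile Use the reduced CPU profile (128 px, depth 2, base
#'   8 filters, 3 epochs, 60 masses)?
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "adnexseg_run",
                            n_masses = 54, canvas_size = 256,
                            input_size = 256, depth = 4, base_filters = 32,
                            learning_rate = 0.001, max_epochs = 120,
                            minibatch_size = 12,
                            goal_train_fraction = 0.65,
                            smoothing_window = 15, threshold = 0.5,
                            fcm_m = 2, fcm_tol = 1e-5, fcm_max_iter = 300,
                            component_mask = c("predicted", "expert"),
                            n_boot = 2000, two_mass_fraction = 1 / 54,
                            test_profile = FALSE, seed = 1L) {
  cfg <- list(out_dir = out_dir, n_masses = n_masses,
              canvas_size = canvas_size, input_size = input_size,
              depth = depth, base_filters = base_filters,
              learning_rate = learning_rate, max_epochs = max_epochs,
              minibatch_size = minibatch_size,
              goal_train_fraction = goal_train_fraction,
              smoothing_window = smoothing_window, threshold = threshold,
              fcm_m = fcm_m, fcm_tol = fcm_tol, fcm_max_iter = fcm_max_iter,
              component_mask = match.arg(component_mask),
              n_boot = n_boot, two_mass_fraction = two_mass_fraction,
              seed = as.integer(seed))
  if (isTRUE(test_profile)) {
    cfg$canvas_size <- 128; cfg$input_size <- 128
    cfg$depth <- 2; cfg$base_filters <- 8
    cfg$max_epochs <- 3; cfg$n_masses <- min(cfg$n_masses, 60)
    cfg$n_boot <- 500
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

stage_paths <- function(cfg) {
  root <- cfg$out_dir
  list(root = root,
       cohort = file.path(root, "cohort"),
       split = file.path(root, "split.csv"),
       model = file.path(root, "unet.rds"),
       history = file.path(root, "training_log.csv"),
       predictions = file.path(root, "predictions"),
       components = file.path(root, "components"),
       metrics = file.path(root, "metrics.csv"),
       summary = file.path(root, "summary.json"),
       log = file.path(root, "pipeline.log.jsonl"))
}

stage_config_json <- function(cfg, keys) {
  jsonlite::toJSON(cfg[keys], auto_unbox = TRUE, digits = NA)
}

stage_done_path <- function(cfg, stage) {
  file.path(cfg$out_dir, sprintf(".done_%s.json", stage))
}

stage_is_done <- function(cfg, stage, keys, outputs) {
  dp <- stage_done_path(cfg, stage)
  file.exists(dp) && all(file.exists(outputs)) &&
    identical(readChar(dp, file.info(dp)$size),
              as.character(stage_config_json(cfg, keys)))
}

stage_mark_done <- function(cfg, stage, keys) {
  writeLines(as.character(stage_config_json(cfg, keys)),
             stage_done_path(cfg, stage), sep = "")
}

log_stage <- function(cfg, stage, seed, t0, skipped = FALSE) {
  line <- jsonlite::toJSON(list(
    stage = stage, seed = seed, skipped = skipped,
    wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), auto_unbox = TRUE)
  cat(line, "\n", file = stage_paths(cfg)$log, append = TRUE, sep = "")
}

with_mass <- function(mass_id, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for mass %s: %s",
                 stage, mass_id, conditionMessage(e)), call. = FALSE))
}

sim_keys <- c("n_masses", "canvas_size", "two_mass_fraction", "seed")

#' Simulate a phantom cohort to disk
#'
#' @param cfg A [pipeline_config()].
#' @param force Overwrite an existing cohort directory?
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(cfg, force = FALSE) {
  if (cfg$n_masses < 1)
    stop("usage: n_masses must be >= 1 to simulate a cohort")
  p <- stage_paths(cfg)
  dir.create(p$root, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  if (!force && stage_is_done(cfg, "simulate", sim_keys,
                              file.path(p$cohort, "manifest.csv"))) {
    log_stage(cfg, "simulate", cfg$seed, t0, skipped = TRUE)
    return(invisible(load_manifest(file.path(p$cohort, "manifest.csv"))))
  }
  if (dir.exists(p$cohort) && !force)
    stop(sprintf("cohort directory %s exists and was built with different settings; use force = TRUE to overwrite",
                 p$cohort))
  unlink(p$cohort, recursive = TRUE)
  records <- generate_cohort(cfg$n_masses, seed = cfg$seed,
                             canvas_size = cfg$canvas_size,
                             two_mass_fraction = cfg$two_mass_fraction)
  manifest <- save_cohort(records, p$cohort)
  stage_mark_done(cfg, "simulate", sim_keys)
  log_stage(cfg, "simulate", cfg$seed, t0)
  invisible(manifest)
}

split_keys <- c(sim_keys, "goal_train_fraction")

#' Patient-level stratified split stage
#'
#' @inheritParams cmd_simulate
#' @export
cmd_split <- function(cfg, force = FALSE) {
  p <- stage_paths(cfg)
  t0 <- Sys.time()
  if (!force && stage_is_done(cfg, "split", split_keys, p$split)) {
    log_stage(cfg, "split", cfg$seed + 1L, t0, skipped = TRUE)
    return(invisible(read.csv(p$split, stringsAsFactors = FALSE)))
  }
  manifest <- load_manifest(file.path(p$cohort, "manifest.csv"))
  split <- stratified_split(manifest, cfg$goal_train_fraction,
                            seed = cfg$seed + 1L)
  write.csv(split, p$split, row.names = FALSE)
  stage_mark_done(cfg, "split", split_keys)
  log_stage(cfg, "split", cfg$seed + 1L, t0)
  invisible(split)
}

train_keys <- c(split_keys, "input_size", "depth", "base_filters",
                "learning_rate", "max_epochs", "minibatch_size")

#' U-net training stage
#'
#' Standardises every training ROI to the network input size, applies the
#' 12-fold flip/rotation augmentation, and trains the U-net.
#'
#' @inheritParams cmd_simulate
#' @export
cmd_train <- function(cfg, force = FALSE) {
  p <- stage_paths(cfg)
  t0 <- Sys.time()
  if (!force && stage_is_done(cfg, "train", train_keys, p$model)) {
    log_stage(cfg, "train", cfg$seed + 2L, t0, skipped = TRUE)
    return(invisible(load_unet(p$model)))
  }
  records <- load_cohort(p$cohort)
  split <- read.csv(p$split, stringsAsFactors = FALSE)
  train_ids <- split$mass_id[split$partition == "train"]
  samples <- list()
  for (r in records) {
    if (!r$mass_id %in% train_ids) next
    with_mass(r$mass_id, "train", {
      roi <- standardize_roi(r$image, r$bbox, cfg$input_size)
      msk <- standardize_roi(r$expert_mask, r$bbox, cfg$input_size)
      samples <- c(samples, augment_pair(roi, msk))
    })
  }
  model <- build_unet(unet_config(
    input_size = cfg$input_size, depth = cfg$depth,
    base_filters = cfg$base_filters, learning_rate = cfg$learning_rate,
    max_epochs = cfg$max_epochs, minibatch_size = cfg$minibatch_size,
    seed = cfg$seed + 2L))
  model <- unet_train(model, samples)
  save_unet(model, p$model)
  write.csv(model$history, p$history, row.names = FALSE)
  stage_mark_done(cfg, "train", train_keys)
  log_stage(cfg, "train", cfg$seed + 2L, t0)
  invisible(model)
}

seg_keys <- c(train_keys, "smoothing_window", "threshold")

#' Prediction and refinement stage for the test partition
#'
#' @inheritParams cmd_simulate
#' @export
cmd_segment <- function(cfg, force = FALSE) {
  p <- stage_paths(cfg)
  t0 <- Sys.time()
  done_flag <- file.path(p$predictions, ".complete")
  if (!force && stage_is_done(cfg, "segment", seg_keys, done_flag)) {
    log_stage(cfg, "segment", cfg$seed + 2L, t0, skipped = TRUE)
    return(invisible(NULL))
  }
  dir.create(p$predictions, recursive = TRUE, showWarnings = FALSE)
  model <- load_unet(p$model)
  params <- refinement_params(cfg$smoothing_window, cfg$threshold)
  records <- load_cohort(p$cohort)
  split <- read.csv(p$split, stringsAsFactors = FALSE)
  test_ids <- split$mass_id[split$partition == "test"]
  for (r in records) {
    if (!r$mass_id %in% test_ids) next
    with_mass(r$mass_id, "segment", {
      roi <- standardize_roi(r$image, r$bbox, cfg$input_size)
      pred <- unet_predict(model, roi)
      ref <- refine_mask(pred$mask, r$bbox, params)
      save_mask(ref$mask, file.path(p$predictions,
                                    paste0(r$mass_id, "_mask.png")))
      save_contour(ref$contour, file.path(p$predictions,
                                          paste0(r$mass_id, "_contour.csv")))
    })
  }
  writeLines("ok", done_flag)
  stage_mark_done(cfg, "segment", seg_keys)
  log_stage(cfg, "segment", cfg$seed + 2L, t0)
  invisible(NULL)
}

comp_keys <- c(seg_keys, "fcm_m", "fcm_tol", "fcm_max_iter", "component_mask")

#' Component clustering stage for the test partition
#'
#' @inheritParams cmd_simulate
#' @export
cmd_components <- function(cfg, force = FALSE) {
  p <- stage_paths(cfg)
  t0 <- Sys.time()
  done_flag <- file.path(p$components, ".complete")
  if (!force && stage_is_done(cfg, "components", comp_keys, done_flag)) {
    log_stage(cfg, "components", cfg$seed + 3L, t0, skipped = TRUE)
    return(invisible(NULL))
  }
  dir.create(p$components, recursive = TRUE, showWarnings = FALSE)
  records <- load_cohort(p$cohort)
  split <- read.csv(p$split, stringsAsFactors = FALSE)
  test_ids <- split$mass_id[split$partition == "test"]
  for (r in records) {
    if (!r$mass_id %in% test_ids) next
    with_mass(r$mass_id, "components", {
      roi <- crop(r$image, r$bbox)
      mask <- if (cfg$component_mask == "predicted") {
        load_mask(file.path(p$predictions,
                            paste0(r$mass_id, "_mask.png"))) > 0
      } else {
        crop(r$expert_mask, r$bbox)
      }
      lab <- segment_components(roi, mask, m = cfg$fcm_m, tol = cfg$fcm_tol,
                                max_iter = cfg$fcm_max_iter,
                                seed = cfg$seed + 3L)
      save_mask(lab$labels, file.path(p$components,
                                      paste0(r$mass_id, "_components.png")))
      stats <- list(mass_id = r$mass_id,
                    pixel_counts = lab$pixel_counts,
                    cluster_gray_means = lab$cluster_gray_means,
                    hypo_cluster = lab$hypo_cluster,
                    iterations = lab$fcm$iterations,
                    final_objective = tail(lab$fcm$objective_trace, 1),
                    seed = cfg$seed + 3L)
      jsonlite::write_json(stats, file.path(
        p$components, paste0(r$mass_id, "_stats.json")), auto_unbox = TRUE)
    })
  }
  writeLines("ok", done_flag)
  stage_mark_done(cfg, "components", comp_keys)
  log_stage(cfg, "components", cfg$seed + 3L, t0)
  invisible(NULL)
}

eval_keys <- c(seg_keys, "n_boot")

#' Evaluation stage: per-mass metrics and cohort summary
#'
#' @inheritParams cmd_simulate
#' @export
cmd_evaluate <- function(cfg, force = FALSE) {
  p <- stage_paths(cfg)
  t0 <- Sys.time()
  if (!force && stage_is_done(cfg, "evaluate", eval_keys,
                              c(p$metrics, p$summary))) {
    log_stage(cfg, "evaluate", cfg$seed + 4L, t0, skipped = TRUE)
    return(invisible(read.csv(p$metrics, stringsAsFactors = FALSE)))
  }
  records <- load_cohort(p$cohort)
  split <- read.csv(p$split, stringsAsFactors = FALSE)
  test_ids <- split$mass_id[split$partition == "test"]
  rows <- list()
  for (r in records) {
    if (!r$mass_id %in% test_ids) next
    with_mass(r$mass_id, "evaluate", {
      pred <- load_mask(file.path(p$predictions,
                                  paste0(r$mass_id, "_mask.png"))) > 0
      ref <- crop(r$expert_mask, r$bbox)
      rows <- c(rows, list(evaluate_mass(pred, ref, r$mass_id)))
    })
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, p$metrics, row.names = FALSE)
  summ <- summarize_cohort(metrics, n_boot = cfg$n_boot,
                           seed = cfg$seed + 4L)
  jsonlite::write_json(summ, p$summary, auto_unbox = TRUE, digits = NA)
  stage_mark_done(cfg, "evaluate", eval_keys)
  log_stage(cfg, "evaluate", cfg$seed + 4L, t0)
  invisible(metrics)
}

#' Run the full pipeline
#'
#' Simulate, split, train, segment, evaluate, and cluster components, in
#' order. Completed stages whose configuration is unchanged are skipped, so
#' an interrupted run resumes where it stopped.
#'
#' @inheritParams cmd_simulate
#' @return The per-mass metrics data frame, invisibly.
#' @export
cmd_run_all <- function(cfg, force = FALSE) {
  cmd_simulate(cfg, force)
  cmd_split(cfg, force)
  cmd_train(cfg, force)
  cmd_segment(cfg, force)
  metrics <- cmd_evaluate(cfg, force)
  cmd_components(cfg, force)
  invisible(metrics)
}
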