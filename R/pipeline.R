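#' Pipeline configuration
#'
#' One nested configuration for the full experiment: phantom generation,
#' preprocessing geometry/intensity, model, training, lesion processing and
#' evaluation. All randomness flows from `seed` via named substreams. The
#' config round-trips losslessly through YAML.
#'
#' @param seed Global seed.
#' @param n_train,n_test Phantom cohort sizes (training and held-out).
#' @param target_in_plane_mm Preprocessing target in-plane spacing.
#' @param input_size_px In-plane crop / network input size.
#' @param model,training Overrides passed to [model_config()] / [train_config()].
#' @param phantom Overrides passed to [phantom_params()].
#' @param closing_radius_mm,min_volume_mm3 Lesion-outline parameters.
#' @param significance_rule "1pct" or "5pct".
#' @param benign_threshold,percentile Evaluation parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_train = 20L, n_test = 12L,
                            target_in_plane_mm = 0.6, input_size_px = 96L,
                            model = list(), training = list(), phantom = list(),
                            closing_radius_mm = c(3, 3), min_volume_mm3 = 250,
                            significance_rule = "1pct",
                            benign_threshold = 0.95, percentile = 90) {
  model <- utils::modifyList(list(n_scales = 5L, branch_depth = 2L, base_width = 8L,
                                  input_size_px = as.integer(input_size_px)), model)
  training <- utils::modifyList(list(epochs = 5L, batch_size = 2L, n_folds = 2L,
                                     seed = as.integer(seed)), training)
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 target_in_plane_mm = target_in_plane_mm,
                 input_size_px = as.integer(input_size_px),
                 model = model, training = training, phantom = phantom,
                 closing_radius_mm = closing_radius_mm,
                 min_volume_mm3 = min_volume_mm3,
                 significance_rule = significance_rule,
                 benign_threshold = benign_threshold, percentile = percentile),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[setdiff(names(x), character(0))])
}

# Geometric preprocessing of one case: in-plane resampling (bilinear for
# intensities, nearest for masks/labels), prostate-centred crop, label
# fusion.
preprocess_geometry <- function(case, target_in_plane_mm, input_size_px) {
  res <- function(v) resample_to_grid(v, target_in_plane_mm)
  t2w <- res(case$t2w); adc <- res(case$adc)
  pm <- res(case$prostate_mask)
  gm <- resample_to_grid(case$grade_map, target_in_plane_mm, method = "nearest")
  pa <- res(case$pathologist_mask)
  ro <- res(case$radiologist_outline)
  crop <- function(v) crop_around_prostate(v, pm, input_size_px)
  out <- case
  out$t2w <- crop(t2w); out$adc <- crop(adc)
  out$grade_map <- crop(gm); out$pathologist_mask <- crop(pa)
  out$radiologist_outline <- crop(ro)
  out$prostate_mask <- crop(pm)
  out$labels <- fuse_labels(out$grade_map, out$pathologist_mask, out$prostate_mask)
  out
}

# Intensity preprocessing: frozen-landmark standardization + in-gland
# z-scoring per sequence.
preprocess_intensity <- function(case, lm_t2w, lm_adc) {
  case$t2w <- zscore_in_gland(apply_standardization(case$t2w, case$prostate_mask, lm_t2w),
                              case$prostate_mask)
  case$adc <- zscore_in_gland(apply_standardization(case$adc, case$prostate_mask, lm_adc),
                              case$prostate_mask)
  case
}

#' Preprocess a cohort
#'
#' Applies the geometric chain to every case; when `landmarks` is `NULL`
#' they are learned from this cohort (the training split), otherwise the
#' frozen artifact is applied unchanged (test splits).
#'
#' @param cases List of `study_case`s.
#' @param config A `pipeline_config`.
#' @param landmarks `NULL` or list with `t2w`, `adc` `histogram_landmarks`.
#' @return List with `cases` (preprocessed) and `landmarks`.
#' @export
preprocess_cohort <- function(cases, config, landmarks = NULL) {
  geo <- lapply(cases, preprocess_geometry,
                target_in_plane_mm = config$target_in_plane_mm,
                input_size_px = config$input_size_px)
  if (is.null(landmarks)) {
    masks <- lapply(geo, function(cs) cs$prostate_mask)
    landmarks <- list(
      t2w = learn_landmarks(lapply(geo, function(cs) cs$t2w), masks, "T2w"),
      adc = learn_landmarks(lapply(geo, function(cs) cs$adc), masks, "ADC"))
  }
  list(cases = lapply(geo, preprocess_intensity, lm_t2w = landmarks$t2w,
                      lm_adc = landmarks$adc),
       landmarks = landmarks)
}

#' Predict a cohort with a fold ensemble
#'
#' @param models List of `spcnet_model`s (fold checkpoints).
#' @param cases Preprocessed cases.
#' @return List of `probability_volume`s.
#' @export
predict_cohort <- function(models, cases) {
  lapply(cases, function(cs) predict_case(models, cs))
}

#' Evaluate a cohort at pixel, lesion and patient level
#'
#' @param cases Preprocessed cases with `labels`.
#' @param predictions Matching `probability_volume`s.
#' @param thresholds A `threshold_artifact`.
#' @param config A `pipeline_config`.
#' @return List `pixel`, `lesion_all`, `lesion_cs`, `patient`.
#' @export
evaluate_cohort <- function(cases, predictions, thresholds, config = pipeline_config()) {
  th <- thresholds$thresholds
  list(
    pixel = per_pixel_eval(cases, predictions, th),
    lesion_all = per_lesion_eval(cases, predictions, threshold = th[["cancer"]],
                                 mode = "all",
                                 closing_radius_mm = config$closing_radius_mm,
                                 min_volume_mm3 = config$min_volume_mm3,
                                 benign_threshold = config$benign_threshold,
                                 percentile = config$percentile),
    lesion_cs = per_lesion_eval(cases, predictions, threshold = th[["aggressive"]],
                                mode = "cs", significance_rule = config$significance_rule,
                                closing_radius_mm = config$closing_radius_mm,
                                min_volume_mm3 = config$min_volume_mm3,
                                benign_threshold = config$benign_threshold,
                                percentile = config$percentile),
    patient = per_patient_eval(cases, predictions, threshold = th[["aggressive"]],
                               significance_rule = config$significance_rule,
                               closing_radius_mm = config$closing_radius_mm,
                               min_volume_mm3 = config$min_volume_mm3,
                               percentile = config$percentile))
}

#' Run the end-to-end phantom experiment
#'
#' Generates seeded training and held-out phantom cohorts, preprocesses them
#' (landmarks frozen from the training cohort), trains the fold models,
#' calibrates thresholds on the pooled held-out-fold validation predictions,
#' predicts the test cohort with the fold ensemble and evaluates at pixel,
#' lesion and patient level.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print progress.
#' @return List with `evaluation`, `thresholds`, `cv` (fold models etc.),
#'   `test_cases`, `test_predictions`, `landmarks`.
#' @export
run_phantom_experiment <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating %d training + %d test phantoms", config$n_train, config$n_test)
  pp_train <- do.call(phantom_params, utils::modifyList(
    list(seed = derive_seed(config$seed, "train-cohort"), n_cases = config$n_train),
    config$phantom))
  pp_test <- do.call(phantom_params, utils::modifyList(
    list(seed = derive_seed(config$seed, "test-cohort"), n_cases = config$n_test),
    config$phantom))
  train_raw <- generate_cohort(pp_train)$cases
  test_raw <- generate_cohort(pp_test)$cases
  say("preprocessing")
  tr <- preprocess_cohort(train_raw, config)
  te <- preprocess_cohort(test_raw, config, landmarks = tr$landmarks)
  model_cfg <- do.call(model_config, config$model)
  train_cfg <- do.call(train_config, config$training)
  say("training %d folds x %d epochs", train_cfg$n_folds, train_cfg$epochs)
  cv <- train_crossval(tr$cases, model_cfg, train_cfg, verbose = verbose)
  say("calibrating thresholds on validation folds")
  ids <- vapply(tr$cases, function(cs) cs$case_id, "")
  val_cases <- list(); val_preds <- list()
  for (k in seq_len(train_cfg$n_folds)) {
    hold <- cv$folds$case_id[cv$folds$fold == k]
    held <- tr$cases[ids %in% hold]
    val_cases <- c(val_cases, held)
    val_preds <- c(val_preds, predict_cohort(list(cv$models[[k]]), held))
  }
  thresholds <- pick_thresholds(val_cases, val_preds)
  say("predicting test cohort with the %d-fold ensemble", length(cv$models))
  test_preds <- predict_cohort(cv$models, te$cases)
  evaluation <- evaluate_cohort(te$cases, test_preds, thresholds, config)
  list(evaluation = evaluation, thresholds = thresholds, cv = cv,
       test_cases = te$cases, test_predictions = test_preds,
       landmarks = tr$landmarks, config = config)
}

#' Run the staged pipeline with resumable artifacts
#'
#' Executes phantom -> preprocess -> train -> predict -> evaluate, writing
#' versioned artifacts per stage under `out_dir` (NIfTI volumes + manifest,
#' landmark and threshold YAML, checkpoints, per-epoch history, evaluation
#' CSV/JSON, and an md5 checksum log). With `resume = TRUE` a stage whose
#' artifact exists is loaded instead of recomputed, so deleting one stage's
#' artifact regenerates only that stage and those downstream.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Artifact directory.
#' @param resume Reuse existing stage artifacts.
#' @param verbose Print progress.
#' @return The evaluation list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = TRUE,
                         verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  logf("run at %s, seed %d", format(Sys.time()), config$seed)
  stage <- function(name, fun) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (resume && file.exists(path)) {
      logf("stage %s: resumed from artifact", name)
      return(readRDS(path))
    }
    if (verbose) message("stage: ", name)
    val <- fun()
    saveRDS(val, path)
    logf("stage %s: computed, md5 %s", name, unname(tools::md5sum(path)))
    val
  }
  phantom <- stage("phantom", function() {
    pp_train <- do.call(phantom_params, utils::modifyList(
      list(seed = derive_seed(config$seed, "train-cohort"), n_cases = config$n_train),
      config$phantom))
    pp_test <- do.call(phantom_params, utils::modifyList(
      list(seed = derive_seed(config$seed, "test-cohort"), n_cases = config$n_test),
      config$phantom))
    tr <- generate_cohort(pp_train, dir = file.path(out_dir, "phantom", "train"))
    te <- generate_cohort(pp_test, dir = file.path(out_dir, "phantom", "test"))
    list(train = tr$cases, test = te$cases)
  })
  prep <- stage("preprocess", function() {
    tr <- preprocess_cohort(phantom$train, config)
    te <- preprocess_cohort(phantom$test, config, landmarks = tr$landmarks)
    write_landmarks(tr$landmarks$t2w, file.path(out_dir, "landmarks_t2w.yaml"))
    write_landmarks(tr$landmarks$adc, file.path(out_dir, "landmarks_adc.yaml"))
    list(train = tr$cases, test = te$cases, landmarks = tr$landmarks)
  })
  trained <- stage("train", function() {
    model_cfg <- do.call(model_config, config$model)
    train_cfg <- do.call(train_config, config$training)
    cv <- train_crossval(prep$train, model_cfg, train_cfg, verbose = verbose)
    for (k in seq_along(cv$models))
      save_checkpoint(cv$models[[k]], file.path(out_dir, "checkpoints",
                                                sprintf("fold%d.rds", k)))
    utils::write.csv(do.call(rbind, Map(function(h, k) cbind(fold = k, h),
                                        cv$histories, seq_along(cv$histories))),
                     file.path(out_dir, "history.csv"), row.names = FALSE)
    utils::write.csv(cv$folds, file.path(out_dir, "folds.csv"), row.names = FALSE)
    cv
  })
  preds <- stage("predict", function() {
    train_cfg <- do.call(train_config, config$training)
    ids <- vapply(prep$train, function(cs) cs$case_id, "")
    val_cases_idx <- list(); val_preds <- list()
    for (k in seq_len(train_cfg$n_folds)) {
      hold <- trained$folds$case_id[trained$folds$fold == k]
      held <- prep$train[ids %in% hold]
      val_cases_idx <- c(val_cases_idx, held)
      val_preds <- c(val_preds, predict_cohort(list(trained$models[[k]]), held))
    }
    thresholds <- pick_thresholds(val_cases_idx, val_preds)
    write_thresholds(thresholds, file.path(out_dir, "thresholds.yaml"))
    list(test = predict_cohort(trained$models, prep$test), thresholds = thresholds)
  })
  ev <- stage("evaluate", function() {
    res <- evaluate_cohort(prep$test, preds$test, preds$thresholds, config)
    rep <- rbind(res$pixel, res$lesion_all, res$lesion_cs)
    utils::write.csv(rep, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    jsonlite::write_json(list(pixel = res$pixel, lesion_all = res$lesion_all,
                              lesion_cs = res$lesion_cs,
                              patient = unclass(res$patient)),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    res
  })
  invisible(ev)
}
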