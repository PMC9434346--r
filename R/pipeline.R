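# Orchestration: one YAML config drives synth -> train/detect ->
# train/segment -> quantify -> evaluate -> predict, with per-stage seeds
# derived from the top-level seed and a JSON run manifest.  Re-running the
# same config reproduces every CSV bit-exactly.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "retquant_run",
    profile = list(image_height = 128L, image_width = 256L),
    synth = list(n_train = 6L, n_test = 3L, speckle_sigma = 0),
    detector = list(epochs = 4L, channels = c(8L, 16L, 32L, 64L),
                    lr = 0.05, batch_size = 32L, threshold = 0.5),
    segmenter = list(epochs = 6L, channels = c(8L, 16L, 32L), lr = 0.05),
    evaluate = list(n_boot = 200L),
    predict = list(n_eyes = 40L, n_trees = 150L, cv_folds = 5L,
                   variant = "six_metric", horizon = "month3",
                   signal = "lesions"),
    stages = c("synth", "detect", "segment", "quantify", "evaluate",
               "predict"))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(path, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or a list; unknown
#'   keys are rejected by name
#' @return validated config list
#' @export
load_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
    else if (is.character(config)) {
      if (!nzchar(config) || !file.exists(config))
        stop("config file not found: '", config, "'", call. = FALSE)
      yaml::read_yaml(config)
    }
    else if (is.list(config)) config
    else stop("config must be a path or a list", call. = FALSE)
  cfg <- merge_config(default_config(), user)
  if (!all(cfg$stages %in% default_config()$stages))
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, default_config()$stages), collapse = ", "),
         call. = FALSE)
  cfg
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # the run location is not part of the run identity
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

scene_paths <- function(dir, id) {
  list(scan = file.path(dir, sprintf("%s_scan.png", id)),
       mask = file.path(dir, sprintf("%s_mask.png", id)),
       traces = file.path(dir, sprintf("%s_traces.csv", id)))
}

#' Run the SD-OCT quantification pipeline
#'
#' Executes the configured stages and writes all outputs under
#' `cfg$out_dir`.  Every stochastic stage is seeded from the top-level seed,
#' so an identical config reproduces identical CSV outputs.
#'
#' @param config `NULL`, YAML path, or list (see [load_config()])
#' @param out_dir overrides `cfg$out_dir`
#' @param seed overrides `cfg$seed`
#' @param stages overrides `cfg$stages` (subset of synth, detect, segment,
#'   quantify, evaluate, predict; later stages need the earlier ones in the
#'   same call or their outputs on disk)
#' @param verbose log stage progress
#' @return the run manifest (also written as `manifest.json`)
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         stages = NULL, verbose = FALSE) {
  cfg <- load_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(stages)) cfg$stages <- stages
  cfg <- load_config(cfg)  # re-validate overrides
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("retquant")),
                   config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  outputs <- function(stage, files) {
    manifest$stages[[stage]] <<- list(outputs = unname(files),
                                      seed = child_seed(cfg$seed,
                                                        match(stage, default_config()$stages)))
  }
  ph <- cfg$profile$image_height; pw <- cfg$profile$image_width
  scenes <- NULL; models <- list(); preds <- NULL

  run_stage <- function(stage, fn) {
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    invisible(ok)
  }

  if ("synth" %in% cfg$stages) run_stage("synth", function() {
    say("stage synth")
    sseed <- child_seed(cfg$seed, 1L)
    n <- cfg$synth$n_train + cfg$synth$n_test
    scenes <<- lapply(seq_len(n), function(i) {
      sp <- scene_spec(image_height = ph, image_width = pw,
                       speckle_sigma = cfg$synth$speckle_sigma)
      generate_scene(sp, seed = child_seed(sseed, i))
    })
    files <- character(0)
    for (i in seq_len(n)) {
      id <- sprintf("scene%03d", i)
      p <- scene_paths(cfg$out_dir, id)
      write_scan_png(scenes[[i]]$image, p$scan)
      write_mask_png(scenes[[i]]$annotation$lesion_mask, p$mask)
      write_traces_csv(scenes[[i]]$annotation, p$traces)
      files <- c(files, unlist(p))
    }
    gt <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(scene = sprintf("scene%03d", i),
                 t(scenes[[i]]$features), check.names = FALSE)))
    gt_path <- file.path(cfg$out_dir, "ground_truth_features.csv")
    write_feature_table(gt, gt_path)
    outputs("synth", c(files, gt_path))
  })

  train_idx <- seq_len(cfg$synth$n_train)
  test_idx <- setdiff(seq_along(scenes), train_idx)

  if ("detect" %in% cfg$stages) run_stage("detect", function() {
    say("stage detect")
    dseed <- child_seed(cfg$seed, 2L)
    files <- character(0)
    for (layer in c("ez", "elm")) {
      clips <- list(); labs <- logical(0)
      for (i in train_idx) {
        g <- slice_clips(scenes[[i]]$image)
        for (k in seq_len(g$n_clips)) clips[[length(clips) + 1L]] <- g$clips[, , k]
        labs <- c(labs, clip_labels(scenes[[i]]$annotation, layer))
      }
      cc <- clip_cnn_config(channels = cfg$detector$channels,
                            lr = cfg$detector$lr,
                            epochs = cfg$detector$epochs,
                            batch_size = cfg$detector$batch_size,
                            threshold = cfg$detector$threshold,
                            seed = child_seed(dseed, match(layer, c("ez", "elm"))))
      models[[layer]] <<- train_clip_cnn(clips, labs, cc)
      f <- file.path(cfg$out_dir, sprintf("detector_%s.rds", layer))
      save_model(models[[layer]], f)
      files <- c(files, f)
    }
    outputs("detect", files)
  })

  if ("segment" %in% cfg$stages) run_stage("segment", function() {
    say("stage segment")
    sc <- fcn_config(channels = cfg$segmenter$channels, lr = cfg$segmenter$lr,
                     epochs = cfg$segmenter$epochs,
                     seed = child_seed(cfg$seed, 3L))
    models$fcn <<- train_fcn(lapply(scenes[train_idx], `[[`, "image"),
                             lapply(scenes[train_idx],
                                    function(s) s$annotation$lesion_mask), sc)
    f <- file.path(cfg$out_dir, "segmenter.rds")
    save_model(models$fcn, f)
    outputs("segment", f)
  })

  if ("quantify" %in% cfg$stages) run_stage("quantify", function() {
    say("stage quantify")
    preds <<- lapply(test_idx, function(i) {
      img <- scenes[[i]]$image
      list(seg = segment(models$fcn, img),
           ez = detect_layers(models$ez, img),
           elm = detect_layers(models$elm, img))
    })
    feat <- do.call(rbind, lapply(seq_along(test_idx), function(j) {
      i <- test_idx[j]
      f <- extract_biomarkers(scenes[[i]]$image, preds[[j]]$seg,
                              preds[[j]]$ez, preds[[j]]$elm)
      data.frame(scene = sprintf("scene%03d", i), t(f), check.names = FALSE)
    }))
    f <- file.path(cfg$out_dir, "predicted_features.csv")
    write_feature_table(feat, f)
    mfiles <- vapply(seq_along(test_idx), function(j) {
      p <- file.path(cfg$out_dir,
                     sprintf("scene%03d_predmask.png", test_idx[j]))
      write_mask_png(preds[[j]]$seg$labels, p)
      p
    }, character(1))
    outputs("quantify", c(f, mfiles))
  })

  if ("evaluate" %in% cfg$stages) run_stage("evaluate", function() {
    say("stage evaluate")
    rep <- segmentation_report(
      lapply(preds, function(p) p$seg$labels),
      lapply(test_idx, function(i) scenes[[i]]$annotation$lesion_mask),
      pred_layers = list(ez = lapply(preds, function(p) p$ez$presence),
                         elm = lapply(preds, function(p) p$elm$presence)),
      true_layers = list(
        ez = lapply(test_idx, function(i) clip_labels(scenes[[i]]$annotation, "ez")),
        elm = lapply(test_idx, function(i) clip_labels(scenes[[i]]$annotation, "elm"))),
      n_boot = cfg$evaluate$n_boot, seed = child_seed(cfg$seed, 5L))
    f1 <- file.path(cfg$out_dir, "metrics_table.csv")
    f2 <- file.path(cfg$out_dir, "metrics.json")
    write_segmentation_report(rep, f1, f2)
    outputs("evaluate", c(f1, f2))
  })

  if ("predict" %in% cfg$stages) run_stage("predict", function() {
    say("stage predict")
    pseed <- child_seed(cfg$seed, 6L)
    cohort <- generate_cohort(cfg$predict$n_eyes, seed = pseed,
                              image_height = ph, image_width = pw,
                              signal = cfg$predict$signal, render = FALSE)
    ft <- cohort_feature_table(cohort)
    f0 <- file.path(cfg$out_dir, "cohort_features.csv")
    write_feature_table(ft, f0)
    fm <- build_feature_matrix(ft, cfg$predict$variant, cfg$predict$horizon)
    rep <- fit_predict_cv(fm$x, fm$y,
                          forest_config(n_trees = cfg$predict$n_trees,
                                        cv_folds = cfg$predict$cv_folds,
                                        seed = child_seed(pseed, 1L)),
                          fm$columns)
    f1 <- file.path(cfg$out_dir, "prediction_metrics.csv")
    write.csv(data.frame(metric = c("auc_macro", "accuracy",
                                    "sensitivity_macro", "specificity_macro"),
                         value = c(rep$auc_macro, rep$accuracy,
                                   rep$sensitivity_macro,
                                   rep$specificity_macro)),
              f1, row.names = FALSE)
    f2 <- file.path(cfg$out_dir, "feature_importance.csv")
    write.csv(rank_feature_importance(rep, top_k = length(rep$importance)),
              f2, row.names = FALSE)
    outputs("predict", c(f0, f1, f2))
  })

  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
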