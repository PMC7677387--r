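# End-to-end pipeline: phantom generation -> preprocessing -> augmentation
# -> training / cross-validation -> segmentation -> quantification ->
# population statistics, with file artifacts and provenance sidecars so
# any stage can be re-run reproducibly.

PIPELINE_STAGES <- c("generate-phantoms", "preprocess", "augment",
                     "cross-validate", "train", "segment", "quantify",
                     "stats")

#' Pipeline configuration
#'
#' @param out_dir artifact root directory
#' @param seed global seed; every stage derives its own sub-seed from it
#' @param n_subjects phantom subjects to simulate (default 12)
#' @param grid_shape phantom grid (default desk scale `c(48, 48, 64)`)
#' @param crop_shape model crop shape (default desk scale `c(32, 32, 32)`)
#' @param width_multiplier network width scale (default 0.125, desk scale)
#' @param epochs training epochs (default 12, desk scale)
#' @param k cross-validation folds (default 3)
#' @param n_random_transforms augmentation draws per reflection state
#'   (default 0 at desk scale)
#' @param muscle_length_mm,target_scale phantom geometry: muscle length and
#'   a scale factor applied to cohort volume targets so muscles fit small
#'   grids (defaults 60 mm and 0.12)
#' @param ... overrides stored verbatim in the config
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 12L,
                            grid_shape = c(48L, 48L, 64L),
                            crop_shape = c(32L, 32L, 32L),
                            width_multiplier = 0.125,
                            epochs = 12L, k = 3L,
                            n_random_transforms = 0L,
                            muscle_length_mm = 60,
                            target_scale = 0.12, ...) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 crop_shape = as.integer(crop_shape),
                 width_multiplier = width_multiplier,
                 epochs = as.integer(epochs), k = as.integer(k),
                 n_random_transforms = as.integer(n_random_transforms),
                 muscle_length_mm = muscle_length_mm,
                 target_scale = target_scale, extra = list(...)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path config file; keys as in [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[setdiff(names(config), "extra")], tmp,
                       auto_unbox = TRUE, digits = 10)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(cfg, stage, dir) {
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         stage_seed = derive_seed(cfg$seed, stage),
         config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("psoasvol")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
}

plog <- function(cfg, stage, ...) {
  message(sprintf("[%s seed=%d] %s", stage, cfg$seed, sprintf(...)))
}

need_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 path, stage_needed), call. = FALSE)
  path
}

pipeline_paths <- function(cfg) {
  root <- cfg$out_dir
  list(root = root,
       phantoms = file.path(root, "phantoms"),
       cohort_csv = file.path(root, "phantoms", "cohort.csv"),
       landmarks_csv = file.path(root, "phantoms", "landmarks.csv"),
       crops = file.path(root, "crops"),
       crops_csv = file.path(root, "crops", "index.csv"),
       augment_csv = file.path(root, "augment", "samples.csv"),
       model = file.path(root, "model"),
       weights = file.path(root, "model", "weights.rds"),
       model_spec = file.path(root, "model", "network_spec.json"),
       cv_dir = file.path(root, "cv"),
       cv_csv = file.path(root, "cv", "per_subject.csv"),
       cv_json = file.path(root, "cv", "summary.json"),
       pred = file.path(root, "predicted_masks"),
       records_csv = file.path(root, "records.csv"),
       stats_dir = file.path(root, "stats"))
}

phantom_spec_from_config <- function(cfg) {
  phantom_spec(grid_shape = cfg$grid_shape,
               muscle_length_mm = cfg$muscle_length_mm,
               lateral_offset_mm = cfg$grid_shape[1] * 2.232 / 4,
               curvature_mm = 4, seed = derive_seed(cfg$seed, "phantom"))
}

stage_generate_phantoms <- function(cfg, paths) {
  dir.create(paths$phantoms, recursive = TRUE, showWarnings = FALSE)
  n <- cfg$n_subjects
  cohort <- generate_cohort(cohort_params(), n_female = ceiling(n / 2),
                            n_male = floor(n / 2),
                            seed = derive_seed(cfg$seed, "cohort"))
  write.csv(cohort, paths$cohort_csv, row.names = FALSE)
  lm_rows <- NULL
  for (i in seq_len(n)) {
    spec <- phantom_spec_from_config(cfg)
    ph <- generate_phantom(spec,
                           cohort$target_left_ml[i] * cfg$target_scale,
                           cohort$target_right_ml[i] * cfg$target_scale,
                           subject_id = cohort$subject_id[i],
                           seed = derive_seed(cfg$seed, paste0("subj", i)))
    id <- cohort$subject_id[i]
    write_volume(ph$volume, file.path(paths$phantoms, paste0(id, "_water.nii")))
    write_mask(ph$left_mask, file.path(paths$phantoms, paste0(id, "_mask_left.nii")))
    write_mask(ph$right_mask, file.path(paths$phantoms, paste0(id, "_mask_right.nii")))
    lm_rows <- rbind(lm_rows, data.frame(
      subject_id = id,
      lx = ph$landmarks$left_hip[1], ly = ph$landmarks$left_hip[2],
      lz = ph$landmarks$left_hip[3],
      rx = ph$landmarks$right_hip[1], ry = ph$landmarks$right_hip[2],
      rz = ph$landmarks$right_hip[3]))
    plog(cfg, "generate-phantoms", "subject %s: %.1f / %.1f ml", id,
         ph$true_left_ml, ph$true_right_ml)
  }
  write.csv(lm_rows, paths$landmarks_csv, row.names = FALSE)
  write_sidecar(cfg, "generate-phantoms", paths$phantoms)
}

load_prepared_subjects <- function(cfg, paths) {
  need_artifact(paths$landmarks_csv, "generate-phantoms")
  lms <- read.csv(paths$landmarks_csv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lms)), function(i) {
    id <- lms$subject_id[i]
    vol <- read_volume(need_artifact(
      file.path(paths$phantoms, paste0(id, "_water.nii")), "generate-phantoms"))
    masks <- list(
      left = read_mask(file.path(paths$phantoms, paste0(id, "_mask_left.nii"))),
      right = read_mask(file.path(paths$phantoms, paste0(id, "_mask_right.nii"))))
    pair <- prepare_subject(vol,
                            list(left_hip = c(lms$lx[i], lms$ly[i], lms$lz[i]),
                                 right_hip = c(lms$rx[i], lms$ry[i], lms$rz[i])),
                            masks = masks, crop_shape = cfg$crop_shape)
    list(id = id, pair = pair, parent_shape = dim(vol$data),
         voxel_mm = vol$voxel_mm)
  })
}

stage_preprocess <- function(cfg, paths) {
  subjects <- load_prepared_subjects(cfg, paths)
  dir.create(paths$crops, recursive = TRUE, showWarnings = FALSE)
  idx <- NULL
  for (s in subjects) {
    for (m in c("left", "right")) {
      crop <- s$pair[[m]]
      f <- paste0(s$id, "_", m, "_crop.nii")
      write_nifti(crop$intensities, file.path(paths$crops, f), crop$voxel_mm)
      fm <- paste0(s$id, "_", m, "_cropmask.nii")
      write_nifti(crop$mask, file.path(paths$crops, fm), crop$voxel_mm, 2L)
      idx <- rbind(idx, data.frame(
        subject_id = s$id, muscle = m, file = f, mask_file = fm,
        reflected = crop$reflected,
        off1 = crop$source_offset[1], off2 = crop$source_offset[2],
        off3 = crop$source_offset[3]))
    }
  }
  write.csv(idx, paths$crops_csv, row.names = FALSE)
  write_sidecar(cfg, "preprocess", paths$crops)
  invisible(subjects)
}

stage_augment <- function(cfg, paths) {
  subjects <- load_prepared_subjects(cfg, paths)
  aug <- augmentation_spec(n_random_transforms = cfg$n_random_transforms,
                           seed = derive_seed(cfg$seed, "augment"))
  ts <- build_training_set(lapply(subjects, `[[`, "pair"), aug)
  dir.create(dirname(paths$augment_csv), recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(ts$samples, function(s) data.frame(
    subject = s$subject, muscle = s$muscle, reflected = s$reflected,
    shift1 = s$transform$shift[1] %||% 0L,
    shift2 = s$transform$shift[2] %||% 0L,
    shift3 = s$transform$shift[3] %||% 0L,
    scale_inplane = s$transform$scale[1] %||% 1,
    scale_outplane = s$transform$scale[3] %||% 1)))
  write.csv(rows, paths$augment_csv, row.names = FALSE)
  write_sidecar(cfg, "augment", dirname(paths$augment_csv))
  plog(cfg, "augment", "%d samples from %d subjects", ts$n_samples,
       length(subjects))
  invisible(ts)
}

desk_specs <- function(cfg) {
  list(net = network_spec(width_multiplier = cfg$width_multiplier),
       train = train_config(learning_rate = 1e-3, epochs = cfg$epochs,
                            seed = derive_seed(cfg$seed, "train")),
       augment = augmentation_spec(
         n_random_transforms = cfg$n_random_transforms,
         max_shift_inplane = 2L, max_shift_outplane = 4L,
         seed = derive_seed(cfg$seed, "augment")))
}

stage_cross_validate <- function(cfg, paths) {
  subjects <- load_prepared_subjects(cfg, paths)
  sp <- desk_specs(cfg)
  rep <- cross_validate(subjects, k = cfg$k, config = sp$train,
                        spec = sp$net, augment = sp$augment)
  dir.create(paths$cv_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(rep$per_subject, paths$cv_csv, row.names = FALSE)
  ba <- bland_altman(rep$per_subject$auto_total_ml,
                     rep$per_subject$manual_total_ml)
  jsonlite::write_json(
    list(pooled_mean_dsc = rep$pooled_mean, pooled_sd_dsc = rep$pooled_sd,
         per_fold = rep$per_fold,
         bland_altman = list(bias_pct = ba$bias, loa_lower = ba$loa_lower,
                             loa_upper = ba$loa_upper, n = ba$n)),
    paths$cv_json, auto_unbox = TRUE, digits = 8, dataframe = "rows")
  write_sidecar(cfg, "cross-validate", paths$cv_dir)
  plog(cfg, "cross-validate", "pooled DSC %.4f +/- %.4f", rep$pooled_mean,
       rep$pooled_sd)
  invisible(rep)
}

stage_train <- function(cfg, paths) {
  subjects <- load_prepared_subjects(cfg, paths)
  sp <- desk_specs(cfg)
  ts <- build_training_set(lapply(subjects, `[[`, "pair"), sp$augment)
  samples <- lapply(seq_len(ts$n_samples), function(i) materialize_sample(ts, i))
  fit <- train_model(samples, sp$train, sp$net)
  dir.create(paths$model, recursive = TRUE, showWarnings = FALSE)
  saveRDS(get_weights(fit$network), paths$weights)
  jsonlite::write_json(
    list(width_multiplier = cfg$width_multiplier,
         loss_history = fit$loss_history, best_epoch = fit$best_epoch),
    paths$model_spec, auto_unbox = TRUE, digits = 8)
  write_sidecar(cfg, "train", paths$model)
  plog(cfg, "train", "final loss %.4f (best epoch %d)",
       fit$loss_history[length(fit$loss_history)], fit$best_epoch)
  invisible(fit)
}

load_trained_network <- function(cfg, paths) {
  need_artifact(paths$weights, "train")
  net <- build_network(network_spec(width_multiplier = cfg$width_multiplier))
  set_weights(net, readRDS(paths$weights))
}

stage_segment <- function(cfg, paths) {
  subjects <- load_prepared_subjects(cfg, paths)
  net <- load_trained_network(cfg, paths)
  dir.create(paths$pred, recursive = TRUE, showWarnings = FALSE)
  for (s in subjects) {
    for (m in c("left", "right")) {
      crop <- s$pair[[m]]
      pred <- predict_mask(net, crop)
      mask_crop <- pred$mask
      if (crop$reflected)   # undo the left-crop reflection before re-embedding
        mask_crop <- mask_crop[dim(mask_crop)[1]:1, , , drop = FALSE]
      full <- embed_crop(mask_crop, crop$source_offset, s$parent_shape)
      write_mask(muscle_mask(full, s$voxel_mm),
                 file.path(paths$pred, paste0(s$id, "_pred_", m, ".nii")))
    }
  }
  write_sidecar(cfg, "segment", paths$pred)
}

stage_quantify <- function(cfg, paths) {
  need_artifact(paths$cohort_csv, "generate-phantoms")
  cohort <- read.csv(paths$cohort_csv, stringsAsFactors = FALSE)
  records <- NULL
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    lp <- need_artifact(file.path(paths$pred, paste0(id, "_pred_left.nii")),
                        "segment")
    rp <- file.path(paths$pred, paste0(id, "_pred_right.nii"))
    records <- rbind(records,
                     quantify_subject(read_mask(lp), read_mask(rp),
                                      cohort[i, ]))
  }
  records <- qc_screen(records, qc_config(
    min_ml = 100 * cfg$target_scale, max_ml = 800 * cfg$target_scale))
  write.csv(records, paths$records_csv, row.names = FALSE)
  write_sidecar(cfg, "quantify", dirname(paths$records_csv))
  invisible(records)
}

stage_stats <- function(cfg, paths) {
  need_artifact(paths$records_csv, "quantify")
  records <- read.csv(paths$records_csv, stringsAsFactors = FALSE)
  dir.create(paths$stats_dir, recursive = TRUE, showWarnings = FALSE)
  small <- nrow(records) < 40
  res <- list(
    n = nrow(records),
    by_gender = lapply(split(records, records$gender), function(d)
      list(n = nrow(d), mean_total_ml = mean(d$total_ml),
           mean_lr_diff_ml = mean(d$lr_diff_ml),
           mean_imi = mean(d$imi, na.rm = TRUE))),
    asymmetry_p = tryCatch(
      signed_rank_test(records$left_ml, records$right_ml)$p_value,
      error = function(e) NA_real_))
  if (!small) {
    an <- analyze_cohort(records)
    res$spearman <- list(
      volume_height = lapply(an$volume_height, function(s) s$effect$rho),
      imi_bmi = lapply(an$imi_bmi, function(s) s$effect$rho),
      imi_age = lapply(an$imi_age, function(s) s$effect$rho))
    plot_cohort_figures(records, paths$stats_dir)
  }
  jsonlite::write_json(res, file.path(paths$stats_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8)
  write_sidecar(cfg, "stats", paths$stats_dir)
  invisible(res)
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order
#' (`generate-phantoms`, `preprocess`, `augment`, `cross-validate`,
#' `train`, `segment`, `quantify`, `stats`), writing artifacts and a
#' provenance sidecar (config hash, seed, package version) per stage.
#' A missing upstream artifact raises an error naming the stage to run
#' first.
#'
#' @param config a [pipeline_config()]
#' @param stages subset of stage names (default: all except
#'   `cross-validate`, which is opt-in because it trains `k` models)
#' @return invisibly, the pipeline paths
#' @export
run_pipeline <- function(config,
                         stages = setdiff(PIPELINE_STAGES, "cross-validate")) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  paths <- pipeline_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(
    `generate-phantoms` = stage_generate_phantoms,
    preprocess = stage_preprocess, augment = stage_augment,
    `cross-validate` = stage_cross_validate, train = stage_train,
    segment = stage_segment, quantify = stage_quantify, stats = stage_stats)
  for (stage in PIPELINE_STAGES)
    if (stage %in% stages) runners[[stage]](config, paths)
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: every pipeline stage plus `run-all`.  Options:
#' `--config FILE` (JSON/YAML), `--out-dir DIR`, `--seed N`, `--n N`
#' (subjects), `--stages a,b,c` (run-all only).
#'
#' @param args character vector (default: the command line)
#' @return exit status, invisibly
#' @export
psoasvol_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: psoasvol <", paste(c(PIPELINE_STAGES, "run-all"),
                                       collapse = "|"),
            "> [--config FILE] [--out-dir DIR] [--seed N] [--n N]")
    return(invisible(1L))
  }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(); i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args))
      stop("malformed option: ", args[i])
    opt[[key]] <- args[i + 1L]; i <- i + 2L
  }
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
         else pipeline_config(out_dir = opt[["out-dir"]] %||% "psoasvol_out")
  if (!is.null(opt[["out-dir"]])) cfg$out_dir <- opt[["out-dir"]]
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$n)) cfg$n_subjects <- as.integer(opt$n)

  stages <- if (cmd == "run-all") {
    if (!is.null(opt$stages)) strsplit(opt$stages, ",")[[1]]
    else setdiff(PIPELINE_STAGES, "cross-validate")
  } else if (cmd %in% PIPELINE_STAGES) cmd
  else stop("unknown subcommand: ", cmd)
  run_pipeline(cfg, stages)
  invisible(0L)
}
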