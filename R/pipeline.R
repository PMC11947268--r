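#' Default end-to-end run configuration
#'
#' Collects every knob of the pipeline with the study's constants as
#' defaults: 26 subjects (13 per condition), 20-minute recordings at 250 Hz,
#' 1-45 Hz band-pass, RANSAC-style bad-channel handling, the 600-720 s crop,
#' 1-s epochs, grouped stratified 6-fold cross-validation, and the
#' per-family learning rates.
#'
#' @param n_subjects,balance,base_seed,duration_s Cohort settings.
#' @param alpha_gain,theta_gain,beta_gain,noise_scale Generator gains.
#' @param subset `"COGN-26"` or `"FULL-256"`.
#' @param family Architecture family.
#' @param cv `"kfold6"` or `"loso"`.
#' @param k Folds for the grouped scheme.
#' @param detect_bad_channels Run the detector during preprocessing. When
#'   FALSE, only the channels in `subset` are simulated, which is much
#'   lighter and statistically identical for clean synthetic cohorts.
#' @param explain Compute subject-averaged Grad-CAM maps for the first test
#'   subject of the first fold (convolutional families only).
#' @param train A [train_config()]; its learning rate defaults to the
#'   family's published value.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
default_run_config <- function(n_subjects = 26, balance = c(13, 13),
                               base_seed = 1, duration_s = 1200,
                               alpha_gain = 1.6, theta_gain = 1.5,
                               beta_gain = 1.4, noise_scale = 10,
                               subset = "COGN-26", family = "cnn1d",
                               cv = c("kfold6", "loso"), k = 6,
                               detect_bad_channels = TRUE,
                               explain = FALSE,
                               train = NULL, out_dir = tempfile("eegdecode_run_")) {
  cv <- match.arg(cv)
  if (is.null(train)) {
    train <- train_config(learning_rate = default_learning_rate(family),
                          seed = base_seed)
  }
  structure(list(n_subjects = n_subjects, balance = balance,
                 base_seed = base_seed, duration_s = duration_s,
                 alpha_gain = alpha_gain, theta_gain = theta_gain,
                 beta_gain = beta_gain, noise_scale = noise_scale,
                 subset = subset, family = family, cv = cv, k = k,
                 detect_bad_channels = detect_bad_channels, explain = explain,
                 train = train, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate (subject by subject, so full-montage recordings never accumulate
#' in memory) -> band-pass -> bad-channel detection and interpolation ->
#' crop 600-720 s -> 1-s epochs -> channel subset -> fold plan -> train and
#' evaluate -> optional Grad-CAM. Writes a JSON manifest, the fold plan, and
#' the metrics table under `config$out_dir`. Re-running with the same
#' configuration reproduces the metrics bit-for-bit.
#'
#' @param config A [default_run_config()].
#' @return The manifest, invisibly (with `$report` attached).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$k > config$n_subjects) {
    stop("folds stage: k = ", config$k, " exceeds n_subjects = ",
         config$n_subjects)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- build_montage()
  conditions <- rep(c("GI", "MT"), times = config$balance)
  gen_channels <- if (config$detect_bad_channels) NULL else
    if (identical(config$subset, "COGN-26")) cognitive_channels else NULL

  message("stage simulate+preprocess: ", config$n_subjects, " subjects")
  sets <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sp <- subject_spec(subject_id = sprintf("S%02d", i),
                       condition = conditions[i],
                       seed = derive_seed(config$base_seed, i),
                       duration_s = config$duration_s,
                       alpha_gain = config$alpha_gain,
                       theta_gain = config$theta_gain,
                       beta_gain = config$beta_gain,
                       noise_scale = config$noise_scale)
    rec <- simulate_recording(sp, montage, channels = gen_channels)
    rec <- preprocess_recording(rec, montage,
                                detect = config$detect_bad_channels,
                                max_windows = 24)
    sets[[i]] <- select_channels(segment_epochs(rec), config$subset)
  }
  epochs <- bind_epoch_sets(sets)
  rm(sets)

  message("stage folds: ", config$cv)
  subj <- unique(epochs$subject_ids)
  subj_lab <- epochs$labels[match(subj, epochs$subject_ids)]
  plan <- if (config$cv == "kfold6") {
    make_grouped_stratified_folds(subj, subj_lab, k = config$k,
                                  seed = config$base_seed)
  } else {
    make_loso_folds(subj)
  }
  write_fold_plan(plan, file.path(config$out_dir, "folds.json"))

  message("stage train+evaluate: ", config$family)
  spec <- architecture_spec(config$family)
  report <- run_cv(epochs, plan, spec, config$train, subset = "FULL-256",
                   keep_models = config$explain)
  write_metrics_report(report,
                       file.path(config$out_dir,
                                 sprintf("metrics_%s_%s.csv", config$family,
                                         config$subset)))

  cam_file <- NULL
  if (config$explain && config$family %in% c("cnn1d", "cnn1d_lstm")) {
    message("stage explain: Grad-CAM")
    f1 <- plan$folds[[1]]
    te <- subset_epochs(epochs, epochs$subject_ids == f1$test[1])
    model <- report$models[[1]]
    if (config$train$standardize) {
      tr <- subset_epochs(epochs, epochs$subject_ids %in% f1$train)
      te <- standardize_epochs(tr, list(te))$others[[1]]
    }
    avg <- subject_average(gradcam(model, te))
    cam_file <- file.path(config$out_dir,
                          paste0("gradcam_", f1$test[1], ".csv"))
    utils::write.csv(avg$intensities, cam_file)
  }

  n_params <- build_model(spec,
                          if (identical(config$subset, "COGN-26")) 26 else 256)
  manifest <- list(
    config = unclass(config[setdiff(names(config), "train")]),
    train = unclass(config$train),
    n_epochs = dim(epochs$epochs)[1],
    n_channels = dim(epochs$epochs)[2],
    parameter_count = n_params$parameter_count,
    files = c(list.files(config$out_dir)),
    avg_accuracy = report$table$accuracy[report$table$fold == "Avg."]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$report <- report
  invisible(manifest)
}
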