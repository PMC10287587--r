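# Config-driven orchestration of the full ensemble pipeline: split ->
# cross-validated base-learner training -> tune-split prediction ->
# Super Learner weight optimization -> test-split evaluation.

#' The six canonical preprocessing/architecture variants
#'
#' Z-score without bias correction (U-Net); z-score, volume min-max, slice
#' min-max and Nyul standardization each after bias correction (U-Net); and
#' z-score after bias correction with the attention U-Net.
#'
#' @param levels,root_features Architecture size shared by all variants
#'   (desk-scale defaults 3 and 4; the full-scale networks use 5 and 32).
#' @return List of variants for [train_cv()] / [pipeline_config()].
#' @export
default_variants <- function(levels = 3L, root_features = 4L) {
  u <- unet_config(levels, root_features, attention = FALSE)
  a <- unet_config(levels, root_features, attention = TRUE)
  list(
    list(name = "zscore_raw", config = u,
         preprocess = preprocess_spec("zscore", bias_correct = FALSE)),
    list(name = "zscore_n4", config = u,
         preprocess = preprocess_spec("zscore", bias_correct = TRUE)),
    list(name = "minmax_volume_n4", config = u,
         preprocess = preprocess_spec("minmax_volume", bias_correct = TRUE)),
    list(name = "minmax_slice_n4", config = u,
         preprocess = preprocess_spec("minmax_slice", bias_correct = TRUE)),
    list(name = "nyul_n4", config = u,
         preprocess = preprocess_spec("nyul", bias_correct = TRUE)),
    list(name = "zscore_n4_attention", config = a,
         preprocess = preprocess_spec("zscore", bias_correct = TRUE))
  )
}

#' Pipeline configuration
#'
#' @param cohort Either a list of [exam()] objects or a [phantom_config()]
#'   (the phantom cohort is generated on the fly).
#' @param fractions Train/tune/test fractions for [split_cohort()].
#' @param k Cross-validation folds.
#' @param variants Variant list, see [default_variants()].
#' @param epochs,batch_size,lr,augmentation,stop_val_dsc Training settings,
#'   see [train_learner()].
#' @param sl_epochs,sl_lr Super Learner fit settings, see [fit_weights()].
#' @param threshold Final binarization threshold.
#' @param seed One master seed, expanded deterministically into per-stage
#'   seeds (split, folds, per-learner initialization/augmentation, SL fit).
#' @param out_dir Run directory; artifacts are written beneath it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, fractions = c(0.80, 0.09, 0.11), k = 5L,
                            variants = default_variants(),
                            epochs = 8L, batch_size = 16L, lr = 1e-2,
                            augmentation = augmentation_spec(),
                            stop_val_dsc = 0.92,
                            sl_epochs = 200L, sl_lr = 0.2,
                            threshold = 0.5, seed = 0L,
                            out_dir = tempfile("slseg_run")) {
  if (length(variants) < 1) stop("variant list must be nonempty", call. = FALSE)
  structure(list(cohort = cohort, fractions = fractions, k = as.integer(k),
                 variants = variants, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 augmentation = augmentation, stop_val_dsc = stop_val_dsc,
                 sl_epochs = as.integer(sl_epochs), sl_lr = sl_lr,
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

log_line <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste(..., collapse = " "))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full ensemble pipeline
#'
#' Executes split -> per-variant cross-validated training -> base-learner
#' prediction on the tune split -> Super Learner weight optimization ->
#' prediction, combination and thresholding on the test split -> per-learner
#' and ensemble metric reports. An equal-weights ensemble is evaluated
#' alongside the optimized one. All artifacts (splits, learners, weights,
#' per-exam reports, per-location summary, config echo, log) are persisted
#' under `config$out_dir`; re-running with the same config and seed
#' reproduces the splits and weights. Test-split exams never enter any
#' learner's training pool nor the weight fit (asserted at run time).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory and in-memory results
#'   (split, learners, sl_fit, reports, summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))

  cohort <- if (inherits(config$cohort, "phantom_config"))
    generate_cohort(config$cohort) else config$cohort
  ids <- vapply(cohort, function(e) e$image$exam_id, character(1))
  names(cohort) <- ids
  log_line(logf, "cohort", length(cohort), "exams")

  split <- split_cohort(ids, config$fractions, seed = derive_seed(config$seed, "split"))
  jsonlite::write_json(unclass(split), file.path(config$out_dir, "splits.json"),
                       auto_unbox = FALSE, digits = NA)
  log_line(logf, "split", sprintf("train=%d tune=%d test=%d",
                                  length(split$train_ids), length(split$tune_ids),
                                  length(split$test_ids)))

  train_exams <- cohort[split$train_ids]
  tune_exams <- cohort[split$tune_ids]
  test_exams <- cohort[split$test_ids]

  learners <- train_cv(train_exams, k = config$k, variants = config$variants,
                       epochs = config$epochs, batch_size = config$batch_size,
                       seed = derive_seed(config$seed, "train"), lr = config$lr,
                       augmentation = config$augmentation,
                       stop_val_dsc = config$stop_val_dsc)
  ldir <- file.path(config$out_dir, "learners")
  for (nm in names(learners)) save_learner(learners[[nm]], file.path(ldir, nm))
  log_line(logf, "train_cv", length(learners), "base learners trained")

  # leakage guard: no test exam in any training pool
  for (nm in names(learners))
    if (any(learners[[nm]]$train_ids %in% split$test_ids))
      stop("leakage: test exam in training pool of ", nm, call. = FALSE)

  # base-learner predictions on the tune split, cached to disk
  tune_maps <- lapply(learners, function(lr_)
    lapply(tune_exams, function(e) predict_slices(lr_, e)))
  saveRDS(tune_maps, file.path(config$out_dir, "tune_predictions.rds"))
  stack <- probability_stack(learners, tune_exams, prob_maps = tune_maps)
  truth <- stack_truth(tune_exams)
  fit <- fit_weights(stack, truth, epochs = config$sl_epochs, lr = config$sl_lr,
                     seed = derive_seed(config$seed, "sl"))
  write_weights(fit, file.path(config$out_dir, "weights.json"),
                learner_ids = names(learners))
  log_line(logf, "fit_weights", sprintf("epochs_run=%d final_loss=%.4f",
                                        fit$epochs_run,
                                        utils::tail(fit$loss_trajectory, 1)))

  # test-split evaluation
  m <- length(learners)
  reports <- list()
  for (ei in seq_along(test_exams)) {
    e <- test_exams[[ei]]
    eid <- e$image$exam_id
    maps <- lapply(learners, function(lr_) predict_slices(lr_, e))
    for (j in seq_len(m)) {
      pm <- maps[[j]]
      pred <- binarize(pm, config$threshold, e$mask$spacing, eid)
      reports[[length(reports) + 1]] <-
        evaluate_exam(pred, e$mask, pm, exam_id = eid, model = names(learners)[j])
    }
    sl_map <- combine_maps(maps, fit$weights)
    eq_map <- combine_maps(maps, ensemble_weights(rep(1 / m, m)))
    reports[[length(reports) + 1]] <-
      evaluate_exam(binarize(sl_map, config$threshold, e$mask$spacing, eid),
                    e$mask, sl_map, exam_id = eid, model = "super_learner")
    reports[[length(reports) + 1]] <-
      evaluate_exam(binarize(eq_map, config$threshold, e$mask$spacing, eid),
                    e$mask, eq_map, exam_id = eid, model = "equal_weights")
    log_line(logf, "evaluate", eid)
  }
  reports <- do.call(rbind, reports)
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  write.table(reports, file.path(rep_dir, "per_exam.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  labels <- vapply(cohort, function(e) e$location_label, character(1))
  summary_tbl <- summarize_by_location(reports, labels,
                                       sl_model = "super_learner",
                                       exclude_models = "equal_weights")
  write.table(summary_tbl, file.path(rep_dir, "summary_by_location.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  cfg_echo <- list(fractions = config$fractions, k = config$k,
                   variants = vapply(config$variants, `[[`, character(1), "name"),
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$lr, sl_epochs = config$sl_epochs,
                   sl_lr = config$sl_lr, threshold = config$threshold,
                   seed = config$seed)
  jsonlite::write_json(cfg_echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  sl_rows <- reports[reports$model == "super_learner", ]
  base_rows <- reports[!reports$model %in% c("super_learner", "equal_weights"), ]
  log_line(logf, "summary",
           sprintf("SL mean DSC=%.3f base mean DSC=%.3f",
                   mean(sl_rows$dsc), mean(base_rows$dsc)))

  invisible(list(out_dir = config$out_dir, split = split, learners = learners,
                 sl_fit = fit, reports = reports, summary = summary_tbl))
}
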