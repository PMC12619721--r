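# End-to-end pipelines mirroring the study's experiment shapes, plus the
# command-line entry point. Every run is reproducible from its config + seed;
# stability selection, scaling and component choice see training data only.

#' Pipeline configuration
#'
#' Collects the study's analysis settings with their published defaults:
#' 5-fold CV repeated 20x (regression) / 10x (classification), 1000 response
#' permutations, stability selection over 200 Binary-Matrix-Sampling subsets
#' at inclusion probability 0.7 and significance 0.05, training extraction at
#' fraction 0.70 over 4 PMI segments, age as the orthogonal constraint, and a
#' low/high class boundary at 48 h (inclusive for "low").
#'
#' @param pmi_window PMI window in hours, both bounds inclusive.
#' @param constraint_columns metadata columns used as orthogonal constraints.
#' @param cv_folds,cv_repeats_regression,cv_repeats_classification CV shape.
#' @param n_permutations randomisation-test size.
#' @param stability_subsets,stability_p,stability_alpha,stability_max_a
#'   stability-selection settings.
#' @param split_segments,split_fraction,training_size training extraction;
#'   `training_size` forces an exact total.
#' @param class_threshold_hours low/high boundary (low = PMI <= threshold).
#' @param class_train_per_class balanced training size per class.
#' @param max_a largest component count tried by [select_components()].
#' @param perm_cv_repeats CV repeats inside each permutation evaluation.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pmi_window = c(16, 199),
                            constraint_columns = "age_years",
                            cv_folds = 5L,
                            cv_repeats_regression = 20L,
                            cv_repeats_classification = 10L,
                            n_permutations = 1000L,
                            stability_subsets = 200L,
                            stability_p = 0.7,
                            stability_alpha = 0.05,
                            stability_max_a = 2L,
                            split_segments = 4L,
                            split_fraction = 0.70,
                            training_size = NULL,
                            class_threshold_hours = 48,
                            class_train_per_class = 14L,
                            max_a = 3L,
                            perm_cv_repeats = 1L,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (diff(cfg$pmi_window) < 0) stop("invalid pmi_window")
  counts <- c(cfg$cv_folds, cfg$cv_repeats_regression,
              cfg$cv_repeats_classification, cfg$n_permutations,
              cfg$stability_subsets, cfg$split_segments, cfg$max_a)
  if (any(counts < 1)) stop("all counts in the config must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_log <- function(stage, ...) {
  message(sprintf("[pmipf] %s: %s", stage, paste0(...)))
}

.write_report <- function(report, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drop_models <- function(x) {
    x$diagnostics$model <- NULL
    x
  }
  jsonlite::write_json(drop_models(report),
                       file.path(out_dir, paste0(stem, ".json")),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       na = "null")
  invisible(NULL)
}

#' Run the full regression pipeline
#'
#' Filter to the PMI window, extract a training set by cluster
#' representatives, stability-select predictors on the training samples only,
#' choose the component count by repeated CV under the randomisation test,
#' refit on the selected panel, and report R2, Q2, SDEC, SDECV, SDEP and
#' permutation p-values plus the test-set predictions.
#'
#' @param ds a `pmi_dataset`.
#' @param config a [pipeline_config()].
#' @param split optional `split_result` to replay (e.g. from [read_split()]);
#'   computed from the filtered data when `NULL`.
#' @param out_dir optional directory for JSON/CSV reports.
#' @return report list: `config`, `split`, `selection`, `component_choice`,
#'   `diagnostics`, `test_predictions`.
#' @export
run_regression <- function(ds, config = pipeline_config(), split = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(ds, "pmi_dataset"), inherits(config, "pipeline_config"))
  seed <- config$seed
  .stage_log("filter", "window [", config$pmi_window[1L], ", ",
             config$pmi_window[2L], "] h")
  ds <- filter_by_pmi(ds, config$pmi_window[1L], config$pmi_window[2L])

  .stage_log("split", nrow(ds$concentrations), " samples, ",
             config$split_segments, " segments (seed ", seed, ")")
  if (is.null(split)) {
    split <- select_training(ds, fraction = config$split_fraction,
                             training_size = config$training_size,
                             n_segments = config$split_segments)
  }
  train <- subset_dataset(ds, split$training_ids)
  test <- subset_dataset(ds, split$test_ids)

  .stage_log("stabsel", "training-only, ", config$stability_subsets,
             " subsets (seed ", seed + 1L, ")")
  selection <- stability_select(train,
                                constraints = config$constraint_columns,
                                alpha = config$stability_alpha,
                                n_subsets = config$stability_subsets,
                                sampling_p = config$stability_p,
                                max_a = config$stability_max_a,
                                folds = config$cv_folds,
                                seed = seed + 1L)
  panel <- selected_metabolites(selection)
  if (length(panel) == 0L) {
    .stage_log("stabsel", "nothing selected; falling back to the full panel")
    panel <- colnames(train$concentrations)
  }

  .stage_log("components", "A = 1..", config$max_a, " (seed ", seed + 2L, ")")
  choice <- select_components(train, max_a = config$max_a,
                              constraints = config$constraint_columns,
                              selected = panel, folds = config$cv_folds,
                              repeats = config$cv_repeats_regression,
                              n_perm = config$n_permutations,
                              cv_repeats = config$perm_cv_repeats,
                              seed = seed + 2L)
  a_use <- if (is.na(choice$n_components)) 1L else choice$n_components

  .stage_log("diagnostics", "refit on ", length(panel),
             " predictors, A = ", a_use)
  diagnostics <- fit_diagnostics(train, n_components = a_use,
                                 constraints = config$constraint_columns,
                                 selected = panel, test_ds = test,
                                 folds = config$cv_folds,
                                 repeats = config$cv_repeats_regression,
                                 n_perm = config$n_permutations,
                                 cv_repeats = config$perm_cv_repeats,
                                 seed = seed + 3L)
  test_pred <- predict(diagnostics$model,
                       test$concentrations[, panel, drop = FALSE])
  report <- list(kind = "regression",
                 config = unclass(config),
                 split = list(training_ids = split$training_ids,
                              test_ids = split$test_ids),
                 selection = as.data.frame(selection),
                 selected = panel,
                 component_choice = choice[c("n_components", "passed", "table")],
                 diagnostics = diagnostics,
                 test_predictions = data.frame(
                   sample_id = test$samples$sample_id,
                   pmi_hours = test$samples$pmi_hours,
                   predicted = unname(test_pred)))
  .write_report(report, out_dir, "regression")
  report
}

#' Run the classification pipeline
#'
#' Dichotomises PMI at the class threshold, extracts a balanced training set
#' per class by the cluster-representative rule, fits oCPLS2C with the
#' component count maximising cross-validated MCC under the randomisation
#' test, and reports MCC in calculation / cross-validation / prediction with
#' both confusion matrices.
#'
#' @inheritParams run_regression
#' @return report list with `mcc`, `confusion`, `selection`, `split`.
#' @export
run_classification <- function(ds, config = pipeline_config(pmi_window = c(16, 100)),
                               out_dir = NULL) {
  stopifnot(inherits(ds, "pmi_dataset"), inherits(config, "pipeline_config"))
  seed <- config$seed
  ds <- filter_by_pmi(ds, config$pmi_window[1L], config$pmi_window[2L])
  cls <- classify_pmi(ds$samples$pmi_hours, config$class_threshold_hours)
  .stage_log("classify", "low n = ", sum(cls == "low"),
             ", high n = ", sum(cls == "high"))

  # balanced training set: cluster representatives within each class
  train_ids <- character(0L)
  per_class <- config$class_train_per_class
  for (lev in levels(cls)) {
    sub <- subset_dataset(ds, ds$samples$sample_id[cls == lev])
    n_sub <- nrow(sub$concentrations)
    segs <- max(1L, min(2L, n_sub %/% 4L))
    target <- min(per_class, n_sub - 1L)
    sp <- select_training(sub, fraction = min(0.9, target / n_sub + 0.01),
                          training_size = target, n_segments = segs)
    train_ids <- c(train_ids, sp$training_ids)
  }
  test_ids <- setdiff(ds$samples$sample_id, train_ids)
  train <- subset_dataset(ds, train_ids)
  test <- subset_dataset(ds, test_ids)
  cls_train <- classify_pmi(train$samples$pmi_hours, config$class_threshold_hours)
  cls_test <- classify_pmi(test$samples$pmi_hours, config$class_threshold_hours)

  .stage_log("stabsel", "training-only, class response (seed ", seed + 1L, ")")
  selection <- stability_select(train,
                                constraints = config$constraint_columns,
                                classes = cls_train,
                                alpha = config$stability_alpha,
                                n_subsets = config$stability_subsets,
                                sampling_p = config$stability_p,
                                max_a = config$stability_max_a,
                                folds = config$cv_folds,
                                seed = seed + 1L)
  panel <- selected_metabolites(selection)
  if (length(panel) == 0L) panel <- colnames(train$concentrations)

  choice <- select_components(train, max_a = config$max_a,
                              constraints = config$constraint_columns,
                              selected = panel, classes = cls_train,
                              folds = config$cv_folds,
                              repeats = config$cv_repeats_classification,
                              n_perm = config$n_permutations,
                              cv_repeats = config$perm_cv_repeats,
                              seed = seed + 2L)
  a_use <- if (is.na(choice$n_components)) 1L else choice$n_components

  model <- ocpls_train(train$concentrations[, panel, drop = FALSE],
                       cls_train,
                       as.matrix(train$samples[config$constraint_columns]),
                       a_use)
  cm_train <- confusion_matrix(cls_train, predict(model, train$concentrations[, panel, drop = FALSE]))
  cm_test <- confusion_matrix(cls_test, predict(model, test$concentrations[, panel, drop = FALSE]))
  cv <- repeated_cv(train, n_components = a_use,
                    constraints = config$constraint_columns,
                    selected = panel, classes = cls_train,
                    folds = config$cv_folds,
                    repeats = config$cv_repeats_classification,
                    seed = seed + 3L)
  perm <- permutation_test(train, statistic = "MCC", n_components = a_use,
                           constraints = config$constraint_columns,
                           selected = panel, classes = cls_train,
                           n_perm = config$n_permutations,
                           folds = config$cv_folds, seed = seed + 4L)
  report <- list(kind = "classification",
                 config = unclass(config),
                 split = list(training_ids = train_ids, test_ids = test_ids),
                 class_sizes = table(cls),
                 selection = as.data.frame(selection),
                 selected = panel,
                 component_choice = choice[c("n_components", "passed", "table")],
                 mcc = list(calculation = mcc(cm_train),
                            cross_validation = cv$mcc,
                            prediction = mcc(cm_test),
                            p_value = perm$p_value),
                 confusion = list(training = cm_train, test = cm_test))
  .write_report(report, out_dir, "classification")
  report
}

#' Two-batch reproducibility assessment
#'
#' Per-metabolite cosine similarity between two batches of the same samples,
#' flagged at the similarity threshold; optionally re-runs the regression
#' pipeline on each batch with the identical split and predictor panel to
#' compare SDEPs.
#'
#' @param batch1,batch2 aligned `pmi_dataset`s.
#' @param config a [pipeline_config()].
#' @param threshold strong-similarity flag level (default 0.90).
#' @param refit if `TRUE`, fit the window's regression model on both batches
#'   with the same split and report per-batch SDEP.
#' @param out_dir optional output directory.
#' @return report list with `similarity` table and optional `sdep` pair.
#' @export
run_reproducibility <- function(batch1, batch2, config = pipeline_config(),
                                threshold = 0.90, refit = FALSE,
                                out_dir = NULL) {
  sim <- cosine_batch_similarity(batch1, batch2, threshold)
  .stage_log("similarity", sum(sim$strong), " of ", nrow(sim),
             " metabolites above ", threshold)
  report <- list(kind = "reproducibility", config = unclass(config),
                 threshold = threshold, similarity = sim)
  if (refit) {
    b1 <- filter_by_pmi(batch1, config$pmi_window[1L], config$pmi_window[2L])
    b2 <- filter_by_pmi(batch2, config$pmi_window[1L], config$pmi_window[2L])
    split <- select_training(b1, fraction = config$split_fraction,
                             training_size = config$training_size,
                             n_segments = config$split_segments)
    sdep_for <- function(b) {
      tr <- subset_dataset(b, split$training_ids)
      te <- subset_dataset(b, split$test_ids)
      model <- ocpls_train(tr$concentrations, tr$samples$pmi_hours,
                           as.matrix(tr$samples[config$constraint_columns]), 1L)
      error_metrics(te$samples$pmi_hours, predict(model, te$concentrations),
                    "SDEP")
    }
    report$split <- split[c("training_ids", "test_ids")]
    report$sdep <- c(batch1 = sdep_for(b1), batch2 = sdep_for(b2))
  }
  .write_report(report, out_dir, "reproducibility")
  report
}

#' Subset a dataset by sample IDs
#'
#' @param ds a `pmi_dataset`.
#' @param ids sample IDs to keep (order as given).
#' @return a `pmi_dataset`.
#' @export
subset_dataset <- function(ds, ids) {
  stopifnot(inherits(ds, "pmi_dataset"))
  missing <- setdiff(ids, ds$samples$sample_id)
  if (length(missing)) stop("unknown sample IDs: ", paste(missing, collapse = ", "))
  samples <- ds$samples[match(ids, ds$samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  pmi_dataset(ds$concentrations[ids, , drop = FALSE], samples)
}

# ---- command line -----------------------------------------------------------

#' Command-line entry point
#'
#' Drives the pipelines from the shell:
#' `pmi-ocpls.R regress|classify|reproduce|simulate [options]`. Installed at
#' `system.file("cli", "pmi-ocpls.R", package = "pmipf")`.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the report of the executed pipeline.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || !args[1L] %in%
      c("regress", "classify", "reproduce", "simulate")) {
    stop("usage: pmi-ocpls.R regress|classify|reproduce|simulate [options]")
  }
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--concentrations", type = "character", default = NULL),
    optparse::make_option("--metadata", type = "character", default = NULL),
    optparse::make_option("--concentrations2", type = "character", default = NULL),
    optparse::make_option("--synthetic", action = "store_true", default = FALSE),
    optparse::make_option("--n-samples", type = "integer", default = 65L),
    optparse::make_option("--window", type = "character", default = "16,199"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--permutations", type = "integer", default = 1000L),
    optparse::make_option("--subsets", type = "integer", default = 200L),
    optparse::make_option("--out", type = "character", default = ".")))
  opt <- optparse::parse_args(parser, args = args[-1L])
  window <- as.numeric(strsplit(opt$window, ",")[[1L]])
  cfg <- pipeline_config(pmi_window = window, seed = opt$seed,
                         n_permutations = opt$permutations,
                         stability_subsets = opt$subsets)
  load_input <- function() {
    if (opt$synthetic) {
      simulate_dataset(synthetic_spec(opt[["n-samples"]], seed = opt$seed))
    } else {
      if (is.null(opt$concentrations) || is.null(opt$metadata)) {
        stop("provide --concentrations and --metadata, or --synthetic")
      }
      read_dataset(opt$concentrations, opt$metadata)
    }
  }
  report <- switch(cmd,
    regress = run_regression(load_input(), cfg, out_dir = opt$out),
    classify = run_classification(load_input(), cfg, out_dir = opt$out),
    reproduce = {
      if (opt$synthetic) {
        both <- simulate_dataset(synthetic_spec(opt[["n-samples"]],
                                                seed = opt$seed), batches = 2L)
        run_reproducibility(both$batch1, both$batch2, cfg, out_dir = opt$out)
      } else {
        b1 <- read_dataset(opt$concentrations, opt$metadata)
        b2 <- read_dataset(opt$concentrations2, opt$metadata)
        run_reproducibility(b1, b2, cfg, out_dir = opt$out)
      }
    },
    simulate = {
      ds <- simulate_dataset(synthetic_spec(opt[["n-samples"]], seed = opt$seed))
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_dataset(ds, file.path(opt$out, "concentrations.csv"),
                    file.path(opt$out, "metadata.csv"))
      list(kind = "simulate", n = nrow(ds$concentrations))
    })
  invisible(report)
}
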