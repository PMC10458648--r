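#' Configuration for a full pipeline run
#'
#' Gathers every stage's parameters: field generation, segmentation, GLCM
#' extraction, optional feature selection, the resampling methods and model
#' families to cross, and the train/test split. `lodging_config()` builds the
#' object in code; [read_lodging_config()] loads the same structure from a
#' YAML or JSON file.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_plots Synthetic field size (default 130).
#' @param field Extra arguments for [field_config()].
#' @param segmentation Arguments for [segment_canopy()] (e.g. `mu`,
#'   `iterations`, `min_area`).
#' @param glcm List with `levels`, `d`, `angles`.
#' @param roi_margin Background margin around each plot bbox, pixels.
#' @param select Run RF-RFE feature selection (default TRUE).
#' @param rfe List with `cv_folds`, `ntree` for the selection stage.
#' @param methods Resampling methods to apply (default all five).
#' @param models Model families to fit (default all four).
#' @param tune Tune hyperparameters per model (default FALSE: protocol
#'   defaults are used; tuning multiplies runtime).
#' @param tune_budget TPE/grid budget when `tune = TRUE`.
#' @param split List with `prop` and `stratified`.
#' @param out_dir Output (run) directory.
#' @return A list of class `lodging_config`.
#' @export
lodging_config <- function(seed = 1L,
                           n_plots = 130,
                           field = list(),
                           segmentation = list(),
                           glcm = list(levels = 16, d = 1,
                                       angles = c(0, 45, 90, 135)),
                           roi_margin = 6,
                           select = TRUE,
                           rfe = list(cv_folds = 10, ntree = 200),
                           methods = resample_methods(),
                           models = model_types(),
                           tune = FALSE,
                           tune_budget = 10,
                           split = list(prop = 0.8, stratified = TRUE),
                           out_dir = tempfile("soylodge_run_")) {
  bad_m <- setdiff(methods, resample_methods())
  if (length(bad_m) > 0) abort(sprintf("Unknown method(s): %s", paste(bad_m, collapse = ", ")))
  bad_mod <- setdiff(models, model_types())
  if (length(bad_mod) > 0) abort(sprintf("Unknown model(s): %s", paste(bad_mod, collapse = ", ")))
  structure(
    list(seed = as.integer(seed), n_plots = as.integer(n_plots),
         field = field, segmentation = segmentation, glcm = glcm,
         roi_margin = roi_margin, select = select, rfe = rfe,
         methods = methods, models = models,
         tune = isTRUE(tune), tune_budget = tune_budget,
         split = split, out_dir = out_dir),
    class = "lodging_config"
  )
}

#' @rdname lodging_config
#' @param path YAML (.yml/.yaml) or JSON configuration file.
#' @export
read_lodging_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(lodging_config, raw)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full lodging-classification pipeline
#'
#' Executes, in order: synthetic field generation, per-plot segmentation and
#' texture extraction, optional RF-RFE feature selection, a stratified 80/20
#' split, resampling of the training partition per method, model fitting
#' (optionally tuned) and evaluation on the untouched test partition for every
#' method x model pair. Each stage's artifact is written into the run
#' directory; a manifest lists every file with an md5 checksum and records
#' stage seeds and timings. With `resume = TRUE`, stages whose artifacts
#' already exist are reloaded instead of recomputed.
#'
#' @param config A [lodging_config()] (or path to a YAML/JSON config).
#' @param resume Reuse existing stage artifacts in `config$out_dir`.
#' @return Invisibly, a list of class `lodging_run`: `dir`, `features`,
#'   `selection`, `reports` (named list of `lodging_evaluation` objects, one
#'   per `method_model`), and `summary` (tibble of OA/kappa per pair).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- read_lodging_config(config)
  stopifnot(inherits(config, "lodging_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "reports"), showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "log.txt"), open = "a")
  on.exit(close(logf), add = TRUE)
  timings <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "soylodge_stage_error")
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_line(logf, "stage %-10s done in %.1fs", name, timings[[name]])
    out
  }

  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   file.path(config$out_dir, "config.yaml"))

  # --- simulate -------------------------------------------------------------
  features_path <- file.path(config$out_dir, "features.csv")
  if (resume && file.exists(features_path)) {
    log_line(logf, "resume: loading features.csv")
    features <- as_tibble(read.csv(features_path))
    features$class <- as_lodging_factor(features$class)
  } else {
    field <- stage("simulate", {
      fc <- do.call(field_config,
                    c(list(n_plots = config$n_plots, seed = config$seed),
                      config$field))
      generate_field(fc)
    })
    stage("write_field", write_field(field,
                                     file.path(config$out_dir, "field.png"),
                                     file.path(config$out_dir, "plots.csv")))
    # --- segment + features -------------------------------------------------
    features <- stage("features", {
      extract_field_features(
        field, roi_margin = config$roi_margin, segment = TRUE,
        levels = config$glcm$levels, d = config$glcm$d,
        angles = config$glcm$angles, segment_args = config$segmentation
      )
    })
    write.csv(features[, setdiff(names(features), "canopy_truth")],
              features_path, row.names = FALSE)
  }

  # --- select ---------------------------------------------------------------
  selection <- NULL
  if (isTRUE(config$select)) {
    selection <- stage("select", {
      rf_rfe(features[, c(feature_columns(features)[
               feature_columns(features) %in% texture_feature_names()],
               "class")],
             cv_folds = config$rfe$cv_folds, ntree = config$rfe$ntree,
             seed = derive_seed(config$seed, 2))
    })
    write_rfe_json(selection, file.path(config$out_dir, "selection.json"))
    keep <- c("plot_id", selection$chosen_features, "score", "class", "provenance")
    features_used <- features[, intersect(keep, names(features))]
  } else {
    keep <- c("plot_id", texture_feature_names(), "score", "class", "provenance")
    features_used <- features[, intersect(keep, names(features))]
  }

  # --- split ----------------------------------------------------------------
  parts <- stage("split", split_train_test(
    features_used, prop = config$split$prop,
    stratified = isTRUE(config$split$stratified),
    seed = derive_seed(config$seed, 3)))

  # --- resample x model -----------------------------------------------------
  reports <- list()
  rows <- list()
  for (mi in seq_along(config$methods)) {
    method <- config$methods[mi]
    plan <- resample_plan(method, seed = derive_seed(config$seed, 10 + mi))
    train_m <- stage(paste0("resample_", method),
                     apply_resample(parts$train, plan))
    write.csv(train_m, file.path(config$out_dir,
                                 sprintf("train_%s.csv", method)),
              row.names = FALSE)
    for (mod in config$models) {
      hp <- NULL
      if (isTRUE(config$tune)) {
        hp <- stage(paste0("tune_", method, "_", mod),
                    tune_lodging(train_m, mod, budget = config$tune_budget,
                                 seed = derive_seed(config$seed, 20 + mi)))
      }
      key <- paste(method, mod, sep = "_")
      rep <- stage(paste0("eval_", key), {
        m <- fit_lodging(train_m, mod, hp, seed = derive_seed(config$seed, 30 + mi))
        prob <- predict(m, parts$test, type = "prob")
        evaluate_predictions(parts$test$class, prob = prob)
      })
      write_evaluation_json(rep, file.path(config$out_dir, "reports",
                                           paste0(key, ".json")))
      reports[[key]] <- rep
      rows[[key]] <- tibble(method = method, model = mod,
                            oa = rep$oa, kappa = rep$kappa,
                            misclassification_rate = rep$misclassification_rate)
    }
  }
  summary <- bind_rows(rows)
  write.csv(summary, file.path(config$out_dir, "summary.csv"), row.names = FALSE)

  # --- manifest -------------------------------------------------------------
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   c("manifest.json", "log.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("soylodge")),
    seed = config$seed,
    timings = timings,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(dir = config$out_dir, features = features, selection = selection,
         reports = reports, summary = summary, config = config),
    class = "lodging_run"
  ))
}

#' @export
print.lodging_run <- function(x, ...) {
  cat(sprintf("<lodging_run: %d plots, %d reports in %s>\n",
              nrow(x$features), length(x$reports), x$dir))
  print(x$summary)
  invisible(x)
}

#' Evaluate a confusion-matrix fixture file
#'
#' Reads a 4 x 4 confusion-matrix CSV (header `actual,NL,ML,HL,SL`; rows
#' actual, columns predicted) and computes the full metric set with
#' [evaluate_confusion()]. The packaged reference matrices can be addressed
#' by name: `"xgboost"`, `"rf"`, `"knn"`, `"ann"`.
#'
#' @param path CSV path, or one of the packaged fixture names.
#' @return A `lodging_evaluation`.
#' @examples
#' glance(evaluate_fixture("xgboost"))
#' @export
evaluate_fixture <- function(path) {
  if (path %in% c("xgboost", "rf", "knn", "ann")) {
    path <- system.file("extdata", "table2",
                        paste0(path, "_confusion.csv"),
                        package = "soylodge", mustWork = TRUE)
  }
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("actual", lodging_classes())) ||
      nrow(df) != 4) {
    abort("Fixture must be a 4x4 matrix CSV with header actual,NL,ML,HL,SL.",
          class = "soylodge_fixture_error")
  }
  C <- as.matrix(df[, lodging_classes()])
  if (any(C != round(C)) || any(C < 0)) {
    abort("Fixture counts must be non-negative integers.",
          class = "soylodge_fixture_error")
  }
  evaluate_confusion(C)
}
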