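# End-to-end orchestration: screening -> selection -> compensation ->
# segmentation -> features -> (optional) classification, with per-stage
# logging and a machine-readable report.

#' Pipeline configuration
#'
#' @param input frame directory (PNG/JPEG, sorted lexicographically) or an
#'   in-memory list of RGB arrays.
#' @param output_dir optional directory for masks, features and the JSON
#'   report; NULL keeps everything in memory.
#' @param target_luma compensation target (default 125).
#' @param red_threshold screening red-fraction cutoff (default 0.4).
#' @param selection_method focus score for frame selection (default "smd").
#' @param min_iter,max_iter,cord_gamma,scan_range vocal-cord snake options
#'   (see [segment_vocal_cords()]).
#' @param glcm_levels,glcm_distance GLCM settings.
#' @param cohort optional training cohort for the classification stage: a
#'   list with `features` (36 columns), `labels` and optionally `rsi`.
#' @param seed RNG seed used by every stochastic stage.
#' @return object of class `lq_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = NULL,
                            target_luma = 125, red_threshold = 0.4,
                            selection_method = "smd",
                            min_iter = 13L, max_iter = 41L,
                            cord_gamma = -40, scan_range = 60L,
                            glcm_levels = 8L, glcm_distance = 1L,
                            cohort = NULL, seed = 1) {
  structure(list(input = input, output_dir = output_dir,
                 target_luma = target_luma, red_threshold = red_threshold,
                 selection_method = selection_method,
                 min_iter = min_iter, max_iter = max_iter,
                 cord_gamma = cord_gamma, scan_range = scan_range,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 cohort = cohort, seed = seed),
            class = "lq_config")
}

#' Write / read a plain-text key-value config file
#'
#' Scalar fields only (`input`, `output_dir` and numeric settings); the
#' cohort cannot be serialized this way and is dropped with a note.
#'
#' @param config `lq_config`.
#' @param path file path.
#' @return `path` (write) or `lq_config` (read).
#' @export
write_config <- function(config, path) {
  scalars <- config[!vapply(config, is.null, logical(1))]
  scalars$cohort <- NULL
  lines <- vapply(names(scalars), function(k)
    sprintf("%s: %s", k, as.character(scalars[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  cfg <- pipeline_config()
  for (p in kv) {
    k <- trimws(p[1]); v <- trimws(paste(p[-1], collapse = ":"))
    if (!k %in% names(cfg)) next
    num <- suppressWarnings(as.numeric(v))
    cfg[[k]] <- if (!is.na(num)) num else v
  }
  cfg
}

run_stage <- function(report, name, fun) {
  if (!is.null(report$failure)) {
    report$stages[[name]] <- list(status = "skipped")
    return(report)
  }
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(value = fun(), error = NULL),
                  lq_error = function(e) list(value = NULL, error = conditionMessage(e)),
                  error = function(e) list(value = NULL, error = conditionMessage(e)))
  elapsed <- proc.time()[["elapsed"]] - t0
  if (is.null(res$error)) {
    report$stages[[name]] <- list(status = "ok", seconds = round(elapsed, 3))
    report$value <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", seconds = round(elapsed, 3),
                                  error = res$error)
    report$failure <- list(stage = name, error = res$error)
    message(sprintf("[laryngoquant] stage '%s' failed: %s", name, res$error))
  }
  report
}

#' Run the full pipeline
#'
#' Executes screening, sharp-frame selection, brightness compensation,
#' four-region segmentation, 36-feature extraction and, when a training
#' cohort is configured, LPR classification (SVM on the five selected
#' features) plus severity grading (BPNN on cohort RSI bins). A stage
#' failure aborts downstream stages but still yields a partial report
#' naming the failed stage.
#'
#' @param config `lq_config` from [pipeline_config()].
#' @return object of class `lq_report`: list with `stages`, `selected_frame`,
#'   `scores`, `compensation_shift`, `regions`, `features`,
#'   `classification`, `failure` (NULL on success).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "lq_config")) lq_stop("expected an lq_config")
  rep <- list(stages = list(), failure = NULL)
  frames <- NULL
  rep <- run_stage(rep, "input", function() {
    if (is.list(config$input)) {
      config$input
    } else if (is.character(config$input)) {
      paths <- list_frames(config$input)
      if (!length(paths)) lq_stop("no frames found in input directory", "lq_io_error")
      lapply(paths, read_frame)
    } else lq_stop("config$input must be a directory or a list of frames", "lq_io_error")
  })
  frames <- rep$value
  rep <- run_stage(rep, "screening", function() {
    idx <- screen(frames, red_threshold = config$red_threshold)
    if (!length(idx)) lq_stop("no frame survived screening", "lq_not_found")
    idx
  })
  surviving <- rep$value
  rep <- run_stage(rep, "selection", function()
    select_sharpest(frames, surviving, method = config$selection_method))
  sel <- rep$value
  rep$selected_frame <- sel
  if (is.null(rep$failure)) rep$scores <- sharpness_report(frames)
  rep <- run_stage(rep, "compensation", function()
    histogram_shift(frames[[sel]], target = config$target_luma))
  comp <- rep$value
  if (!is.null(comp)) rep$compensation_shift <- attr(comp, "shift")
  rep <- run_stage(rep, "segmentation", function()
    segment_regions(comp, min_iter = config$min_iter, max_iter = config$max_iter,
                    gamma = config$cord_gamma, scan_range = config$scan_range))
  regions <- rep$value
  rep$regions <- regions
  rep <- run_stage(rep, "features", function()
    extract_features(comp, regions, distance = config$glcm_distance,
                     levels = config$glcm_levels))
  rep$features <- rep$value
  if (!is.null(config$cohort)) {
    rep <- run_stage(rep, "classification", function() {
      co <- config$cohort
      bal <- balanced_subsample(co$features, co$labels, seed = config$seed)
      sel5 <- lq_selected_features()
      fit <- svm_train(bal$features[, sel5, drop = FALSE], bal$labels)
      label <- unname(predict(fit, t(rep$features[sel5])))
      cv <- svm_cv(bal$features[, sel5, drop = FALSE], bal$labels,
                   seed = config$seed)
      out <- list(label = label, cv = cv[c("accuracy", "sensitivity",
                                           "false_positive_rate")])
      if (!is.null(co$rsi) && label == "LPR") {
        lpr_rows <- co$labels == "LPR"
        sev <- rsi_to_severity(co$rsi[lpr_rows])
        cfg <- severity_config(seed = config$seed)
        net <- bpnn_train(co$features[lpr_rows, sel5, drop = FALSE], sev, cfg)
        out$severity <- as.character(predict(net, t(rep$features[sel5])))
      }
      out
    })
    rep$classification <- rep$value
  }
  rep$value <- NULL
  class(rep) <- "lq_report"
  if (!is.null(config$output_dir)) write_report(rep, config$output_dir)
  rep
}

#' @export
print.lq_report <- function(x, ...) {
  for (nm in names(x$stages))
    cat(sprintf("  %-14s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$failure))
    cat(sprintf("failed at '%s': %s\n", x$failure$stage, x$failure$error))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Masks as 0/255 PNG, the feature vector as a one-row CSV and the rest of
#' the report as JSON.
#'
#' @param report `lq_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$regions)) {
    for (nm in names(report$regions))
      write_mask(report$regions[[nm]], file.path(dir, paste0("mask_", nm, ".png")))
  }
  if (!is.null(report$features)) {
    df <- as.data.frame(as.list(report$features), check.names = FALSE)
    utils::write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  }
  json <- report
  json$regions <- if (!is.null(report$regions))
    lapply(report$regions, function(m) sum(m)) else NULL
  class(json) <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}

#' Write / read a feature cohort CSV
#'
#' Header row: the 36 canonical feature names plus `label` and `rsi`.
#'
#' @param cohort list with `features`, `labels`, `rsi`.
#' @param path CSV path.
#' @return `path` (write) or cohort list (read).
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$features
  df$label <- as.character(cohort$labels)
  df$rsi <- cohort$rsi
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c(lq_feature_names(), "label") %in% colnames(df)))
    lq_stop("cohort CSV lacks the canonical feature columns", "lq_io_error")
  list(features = df[, lq_feature_names(), drop = FALSE],
       labels = factor(df$label, levels = c("LPR", "non-LPR")),
       rsi = if ("rsi" %in% colnames(df)) as.integer(df$rsi) else NULL)
}
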