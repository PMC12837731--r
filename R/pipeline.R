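# Pipeline orchestration: simulate/load -> detect -> extract -> cluster ->
# stats, with reproducibility bookkeeping.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a synthetic scene spec, an EDF
#' file (with annotation CSVs), or a bare feature table CSV (in which case
#' the detection and feature stages are skipped).
#'
#' @param scene a [scene_spec()], or `NULL`.
#' @param edf_path path to an EDF recording, or `NULL`.
#' @param feature_table path to a feature CSV (columns `avg_frequency`,
#'   `duration`, `amplitude`, `n_cycles`, `epoch`, optionally `age`), or
#'   `NULL`.
#' @param spikes_path,epochs_path annotation CSVs accompanying `edf_path`.
#' @param detector a [detector_config()].
#' @param k cluster count or `"auto"`.
#' @param n_restarts k-means restarts.
#' @param seed master seed; per-stage seeds derive from it.
#' @param age_adjust fit age-adjusted regressions (needs an `age` column).
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene = NULL, edf_path = NULL,
                            feature_table = NULL,
                            spikes_path = NULL, epochs_path = NULL,
                            detector = detector_config(), k = "auto",
                            n_restarts = 300, seed = 1, age_adjust = FALSE,
                            out_dir = tempfile("hfo_run_")) {
  n_src <- sum(!vapply(list(scene, edf_path, feature_table), is.null, TRUE))
  if (n_src != 1)
    stop("exactly one input source (scene, edf_path or feature_table) is required",
         call. = FALSE)
  structure(list(scene = scene, edf_path = edf_path,
                 feature_table = feature_table, spikes_path = spikes_path,
                 epochs_path = epochs_path, detector = detector, k = k,
                 n_restarts = n_restarts, seed = as.integer(seed),
                 age_adjust = age_adjust, out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks the recording sampling rate (>= 1000 Hz, the inclusion criterion
#' for scalp HFO analysis), channel labels against the 10-20 set, and
#' annotation consistency (non-overlapping epochs, ictal intervals >= 3 s).
#'
#' @param rec an [eeg_recording()] (or `NULL` to skip signal checks).
#' @param epochs,spikes annotation data frames (or `NULL`).
#' @return data frame of failures with columns `code` and `message`; zero
#'   rows when everything passes.
#' @export
validate_inputs <- function(rec = NULL, epochs = NULL, spikes = NULL) {
  fail <- list()
  add <- function(code, msg)
    fail[[length(fail) + 1]] <<- data.frame(code = code, message = msg,
                                            stringsAsFactors = FALSE)
  if (!is.null(rec)) {
    if (rec$sampling_rate < 1000)
      add("sampling_rate", sprintf(
        "sampling rate %g Hz is below the 1000 Hz required for scalp HFO analysis",
        rec$sampling_rate))
    unknown <- setdiff(rec$channels, ten_twenty_channels())
    if (length(unknown))
      add("channel_labels", paste("labels outside the 10-20 analysis set:",
                                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(epochs)) {
    ok <- tryCatch({ check_epochs(epochs); TRUE }, error = function(e) e$message)
    if (!isTRUE(ok)) add("epochs", ok)
    else {
      ict <- epochs$label == "ictal_active"
      if (any(ict) && any(epochs$offset_s[ict] - epochs$onset_s[ict] < 3))
        add("ictal_duration", "ictal epoch shorter than the 3 s minimum")
    }
  }
  if (!is.null(spikes) && nrow(spikes) > 0 && any(spikes$time_s < 0))
    add("spikes", "negative spike times")
  if (length(fail)) do.call(rbind, fail) else
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate or load, detect, extract features,
#' cluster, epoch statistics), writes every intermediate table plus report
#' files to the output directory, and returns a manifest with per-stage row
#' counts and the derived seeds. With a feature-table input the detection
#' and feature stages are skipped and recorded as such.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   stage_seeds = list(
                     synth = derive_seed(config$seed, "synth"),
                     cluster = derive_seed(config$seed, "cluster")),
                   stages = list())

  feats <- NULL
  if (!is.null(config$feature_table)) {
    feats <- read.csv(config$feature_table, stringsAsFactors = FALSE)
    manifest$stages$detect <- "skipped"
    manifest$stages$features <- "skipped"
    manifest$input <- config$feature_table
  } else {
    if (!is.null(config$scene)) {
      scene <- config$scene
      scene$seed <- manifest$stage_seeds$synth
      sim <- simulate_scene(scene)
      rec <- sim$recording
      spikes <- sim$truth$spikes
      epochs <- sim$truth$epochs
      manifest$input <- "synthetic scene"
      manifest$stages$synth <- list(
        n_truth_bursts = if (is.null(sim$truth$bursts)) 0L else nrow(sim$truth$bursts))
    } else {
      rec <- read_edf(config$edf_path)
      spikes <- if (!is.null(config$spikes_path)) read_spikes(config$spikes_path)
      epochs <- if (!is.null(config$epochs_path)) read_epochs(config$epochs_path)
      manifest$input <- config$edf_path
    }
    v <- validate_inputs(rec, epochs, spikes)
    if (nrow(v) > 0)
      stop("input validation failed: ",
           paste(v$code, v$message, sep = ": ", collapse = "; "), call. = FALSE)
    events <- detect_hfo(rec, config$detector, spikes = spikes, epochs = epochs)
    filtered <- attr(events, "filtered")
    write.csv(events, file.path(config$out_dir, "events.csv"), row.names = FALSE)
    manifest$stages$detect <- list(n_events = nrow(events),
                                   n_spike_ripples = sum(events$kind == "spike_ripple"))
    analysed <- events[events$kind == "spike_ripple", , drop = FALSE]
    attr(analysed, "thresholds") <- attr(events, "thresholds")
    feats <- extract_features(filtered, analysed, config$detector)
    write.csv(feats, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    manifest$stages$features <- list(n_events = nrow(feats))
  }

  model <- cluster_hfo(feats, k = config$k, n_restarts = config$n_restarts,
                       seed = manifest$stage_seeds$cluster)
  clusters_out <- model$features
  write.csv(clusters_out, file.path(config$out_dir, "clusters.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(k = model$k, total_wss = model$total_wss,
         wss_curve = model$wss_curve, seed = model$seed,
         centroids_standardized = model$centroids,
         centroids_raw = model$centroids_raw),
    file.path(config$out_dir, "model.json"), digits = 10, auto_unbox = TRUE,
    pretty = TRUE)
  manifest$stages$cluster <- list(k = model$k, n_excluded = length(model$excluded),
                                  n_clustered = nrow(clusters_out),
                                  total_wss = model$total_wss)

  keep <- clusters_out$epoch != "unassigned"
  stats_files <- NULL
  if (any(keep) && length(unique(clusters_out$epoch[keep])) >= 2) {
    sub <- clusters_out[keep, , drop = FALSE]
    tab <- build_contingency(sub$cluster, sub$epoch)
    chi <- chi_square_test(tab)
    mfit <- tryCatch(multinomial_logit(sub$epoch, sub$cluster),
                     error = function(e) NULL)
    age <- if (config$age_adjust && "age" %in% names(sub)) sub$age else NULL
    ols_fits <- list()
    for (feat in c("avg_frequency", "duration")) {
      ols_fits[[paste0(feat, "_crude")]] <-
        ols_regression(sub[[feat]], sub$epoch)
      if (!is.null(age))
        ols_fits[[paste0(feat, "_adjusted")]] <-
          ols_regression(sub[[feat]], sub$epoch, age = age)
    }
    for (feat in c("amplitude", "n_cycles")) {
      ols_fits[[paste0("log_", feat, "_crude")]] <-
        ols_regression(log(sub[[feat]]), sub$epoch)
      if (!is.null(age))
        ols_fits[[paste0("log_", feat, "_adjusted")]] <-
          ols_regression(log(sub[[feat]]), sub$epoch, age = age)
    }
    stats_files <- make_reports(tab, chi, mfit, ols_fits, dir = config$out_dir)
    manifest$stages$stats <- list(chi_square = chi$statistic, df = chi$df,
                                  p_value = chi$p_value)
  } else {
    manifest$stages$stats <- "skipped (fewer than 2 epochs observed)"
  }
  manifest$row_counts <- list(features = nrow(feats),
                              clustered = nrow(clusters_out))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
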