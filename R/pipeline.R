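#' Write a synthetic cohort to delimiter-separated text
#'
#' Writes one signal file per subject (`signals/<subject_id>.csv`: a time
#' column plus one column per electrode), a `participants.csv` table
#' (`subject_id`, `psq_score`, `true_class`) and a plain-text `manifest.txt`
#' recording the simulation parameters.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sig_dir <- file.path(dir, "signals")
  dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    df <- data.frame(time_s = seq_len(ncol(rec$samples)) / rec$fs)
    for (ch in rec$channel_names) df[[ch]] <- rec$samples[ch, ]
    utils::write.csv(df,
      file.path(sig_dir, paste0(rec$subject_id, ".csv")),
      row.names = FALSE
    )
  }
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
    row.names = FALSE
  )
  p <- cohort$params
  manifest <- c(
    paste0("n_subjects: ", p$n_subjects),
    paste0("channels: ", paste(p$channels, collapse = ",")),
    paste0("fs: ", p$fs),
    paste0("duration_s: ", p$duration_s),
    paste0("stress_prevalence: ", p$stress_prevalence),
    paste0("psq_mean_by_class: ", paste(p$psq_mean_by_class, collapse = ",")),
    paste0("psq_sd: ", p$psq_sd),
    paste0("effect_size: ", p$effect_size),
    paste0("planted_features: ", paste(p$planted_features, collapse = ",")),
    paste0("seed: ", p$seed),
    paste0(
      "noise_spectrum: ",
      paste(names(p$noise_spectrum), unlist(p$noise_spectrum),
        sep = "=", collapse = ","
      )
    )
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read per-subject signal files
#'
#' Reads every `*.csv` in a directory as one subject's recording (columns:
#' optional time column plus one column per electrode). Subjects missing a
#' required electrode or containing non-finite samples are skipped with a
#' warning and listed in the `skipped` attribute; recordings shorter than
#' `min_duration_s` are likewise dropped (mirroring a minimum-length
#' inclusion criterion).
#'
#' @param dir Directory of signal files.
#' @param montage Required electrode column names.
#' @param fs Sampling rate in Hz of the stored signals.
#' @param min_duration_s Optional minimum recording length in seconds.
#' @return Named list of [eeg_recording()] objects with attribute `skipped`
#'   (tibble `subject_id`, `reason`).
#' @export
read_signals <- function(dir, montage = c("AF7", "AF8", "TP7", "TP8"),
                         fs = 250, min_duration_s = NULL) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop_input("no signal files found in ", dir)
  recs <- list()
  skipped <- list()
  for (f in files) {
    sid <- sub("\\.csv$", "", basename(f))
    df <- utils::read.csv(f, check.names = FALSE)
    if (!all(montage %in% names(df))) {
      miss <- setdiff(montage, names(df))
      warning("subject ", sid, " skipped: missing electrode(s) ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
      skipped[[sid]] <- paste("missing electrode:", paste(miss, collapse = ","))
      next
    }
    mat <- t(as.matrix(df[, montage, drop = FALSE]))
    if (anyNA(mat) || any(!is.finite(mat))) {
      warning("subject ", sid, " skipped: non-finite samples", call. = FALSE)
      skipped[[sid]] <- "non-finite samples"
      next
    }
    if (!is.null(min_duration_s) && ncol(mat) / fs < min_duration_s) {
      warning("subject ", sid, " skipped: recording shorter than ",
        min_duration_s, " s",
        call. = FALSE
      )
      skipped[[sid]] <- paste0("duration < ", min_duration_s, " s")
      next
    }
    recs[[sid]] <- eeg_recording(sid, mat, fs)
  }
  attr(recs, "skipped") <- tibble::tibble(
    subject_id = names(skipped),
    reason = unlist(skipped, use.names = FALSE) %||% character(0)
  )
  recs
}

#' Pipeline configuration
#'
#' Bundles and validates every tunable of the end-to-end analysis. Supply
#' either a [sim_params()] object (`simulate`) or a signals directory plus
#' participants table (`signals_dir`, `participants`).
#'
#' @param simulate Optional [sim_params()] for a synthetic run.
#' @param signals_dir,participants Optional on-disk inputs: a directory for
#'   [read_signals()] and a data frame (or CSV path) with `subject_id` and
#'   `psq_score`.
#' @param montage Electrode names. Default AF7, AF8, TP7, TP8.
#' @param fs Sampling rate of on-disk signals.
#' @param schemes List of [segmentation_scheme()] objects to compare.
#'   Default: non-overlapping 10 s and overlapping 20 s / step 10 s.
#' @param classifiers Character vector of classifier names to run.
#' @param aggregation Instance granularity for [build_feature_table()].
#' @param entropy_bins,entropy_as_printed Feature options.
#' @param k Number of features to select. Default 10.
#' @param disc A [discretization_spec()].
#' @param n_folds CV folds. Default 10.
#' @param stratified Stratified folds. Default FALSE.
#' @param min_duration_s Minimum recording length for on-disk inputs.
#' @param seed Global seed governing fold assignment (and simulation when
#'   `simulate` carries no own seed override).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, signals_dir = NULL,
                            participants = NULL,
                            montage = c("AF7", "AF8", "TP7", "TP8"),
                            fs = 250,
                            schemes = list(
                              segmentation_scheme("non_overlapping", window_s = 10),
                              segmentation_scheme("overlapping", window_s = 20, step_s = 10)
                            ),
                            classifiers = c("RF", "J48", "KNN", "MLP", "ABM"),
                            aggregation = c("per_subject_mean", "per_segment"),
                            entropy_bins = 64L, entropy_as_printed = FALSE,
                            k = 10L, disc = discretization_spec(),
                            n_folds = 10L, stratified = FALSE,
                            min_duration_s = NULL, seed = 1L) {
  aggregation <- match.arg(aggregation)
  if (is.null(simulate) && (is.null(signals_dir) || is.null(participants))) {
    stop_input("supply either simulate = sim_params(...) or signals_dir + participants")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_params"))
  for (s in schemes) stopifnot(inherits(s, "segmentation_scheme"))
  classifiers <- match.arg(classifiers,
    c("RF", "J48", "KNN", "MLP", "ABM"),
    several.ok = TRUE
  )
  structure(
    list(
      simulate = simulate, signals_dir = signals_dir,
      participants = participants, montage = montage, fs = fs,
      schemes = schemes, classifiers = classifiers, aggregation = aggregation,
      entropy_bins = entropy_bins, entropy_as_printed = entropy_as_printed,
      k = k, disc = disc, n_folds = n_folds, stratified = stratified,
      min_duration_s = min_duration_s, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the end-to-end stress-classification pipeline
#'
#' Executes segment -> extract -> label -> select -> evaluate for every
#' configured (scheme, classifier) pair: recordings are windowed, the 20
#' time-domain features are computed per electrode and aggregated to
#' instances, PSQ thresholds are computed from the analyzed cohort and
#' subjects in the intermediate band are excluded, the top-k features by
#' information gain are selected per scheme, and each classifier is evaluated
#' by pooled k-fold cross-validation. All randomness flows from the
#' configuration seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `results` (the [compare_report()] tibble), `reports`
#'   (named list of `metrics_report`), `rankings` (per-scheme
#'   [rank_and_select()] tables), `rule` (the [compute_thresholds()] rule),
#'   `labels`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    recordings <- cohort$recordings
    participants <- cohort$participants
  } else {
    recordings <- read_signals(
      config$signals_dir, config$montage, config$fs,
      min_duration_s = config$min_duration_s
    )
    participants <- config$participants
    if (is.character(participants)) {
      participants <- utils::read.csv(participants)
    }
  }
  participants <- participants[
    participants$subject_id %in% names(recordings),
  ]
  rule <- compute_thresholds(participants$psq_score)
  labels <- assign_labels(participants, rule)

  reports <- list()
  rankings <- list()
  for (scheme in config$schemes) {
    segs <- dplyr::bind_rows(lapply(recordings, segment_recording, scheme = scheme))
    tab <- build_feature_table(segs,
      aggregation = config$aggregation, channels = config$montage,
      entropy_bins = config$entropy_bins,
      entropy_as_printed = config$entropy_as_printed
    )
    labeled <- suppressMessages(attach_labels(tab, labels))
    ranking <- rank_and_select(labeled, k = config$k, disc = config$disc)
    rankings[[scheme$mode]] <- ranking
    sel <- attr(ranking, "selected")
    for (cl in config$classifiers) {
      spec <- classifier_spec(cl, scheme = scheme$mode)
      rep <- cross_validate(labeled, spec,
        n_folds = config$n_folds, seed = config$seed,
        stratified = config$stratified, features = sel
      )
      reports[[paste(cl, scheme$mode, sep = "_")]] <- rep
    }
  }
  list(
    results = compare_report(reports),
    reports = reports,
    rankings = rankings,
    rule = rule,
    labels = labels,
    config = config
  )
}

#' Flatten a segment table to long format
#'
#' Debug serialization of segments as one row per sample:
#' `subject_id`, `channel`, `start_s`, `sample_index` (1-based within the
#' window), `value`.
#'
#' @param segments Output of [segment_recording()].
#' @return A long-format tibble.
#' @export
segments_to_long <- function(segments) {
  segments |>
    dplyr::mutate(sample_index = lapply(.data$samples, seq_along)) |>
    tidyr::unnest(c("sample_index", "samples")) |>
    dplyr::rename(value = "samples") |>
    dplyr::select("subject_id", "channel", "start_s", "sample_index", "value")
}
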