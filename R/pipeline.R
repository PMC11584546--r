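#' Pipeline configuration
#'
#' All thresholds of the study protocol are configuration defaults here,
#' never hard-coded in the stages: the 0.8-1.2 s duration gate, the 15%
#' repeat-variability threshold, the 800 Hz spectral band edge, and the
#' phenotype cutoffs (4.5 kg / 5% weight loss, 28/18 kg grip, 1.0 m/s gait).
#'
#' @param audio_dir directory of input WAV files named
#'   `<subject_id>_rep<k>.wav`.
#' @param assessment_csv path to the assessment table CSV.
#' @param output_dir directory the pipeline writes its outputs to.
#' @param sample_rate_hz synthesis sampling rate.
#' @param duration_min_s,duration_max_s duration-gate bounds (seconds).
#' @param variability_threshold_pct repeat-CV acceptance threshold.
#' @param endpoint endpoint-detector settings, an [endpoint_config()].
#' @param frame_time [frame_config()] for A1/A2.
#' @param frame_lp [frame_config()] for A3.
#' @param lp_order linear-prediction order for A3.
#' @param end_frequency_hz A4 band edge (must be below Nyquist).
#' @param a2_relative A2 normalization variant (see [compute_a2()]).
#' @param standardize_exposure per-SD exposure scaling in the models.
#' @param covariates optional adjustment covariates (crude models if `NULL`).
#' @param n_subjects cohort size for [run_synth()].
#' @param seed integer seed governing all randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(audio_dir = NULL, assessment_csv = NULL,
                            output_dir = NULL, sample_rate_hz = 44100,
                            duration_min_s = 0.8, duration_max_s = 1.2,
                            variability_threshold_pct = 15,
                            endpoint = endpoint_config(),
                            frame_time = frame_config(),
                            frame_lp = frame_config(0.025, 0.010, "hamming"),
                            lp_order = 12, end_frequency_hz = 800,
                            a2_relative = TRUE, standardize_exposure = FALSE,
                            covariates = NULL, n_subjects = 60, seed = 1L) {
  if (duration_min_s <= 0 || duration_min_s >= duration_max_s)
    stop("pipeline_config: need 0 < duration_min_s < duration_max_s")
  if (variability_threshold_pct <= 0)
    stop("pipeline_config: variability_threshold_pct must be > 0")
  if (end_frequency_hz <= 0 || end_frequency_hz >= sample_rate_hz / 2)
    stop("pipeline_config: end_frequency_hz must be below Nyquist")
  structure(list(audio_dir = audio_dir, assessment_csv = assessment_csv,
                 output_dir = output_dir, sample_rate_hz = sample_rate_hz,
                 duration_min_s = duration_min_s,
                 duration_max_s = duration_max_s,
                 variability_threshold_pct = variability_threshold_pct,
                 endpoint = endpoint, frame_time = frame_time,
                 frame_lp = frame_lp, lp_order = lp_order,
                 end_frequency_hz = end_frequency_hz,
                 a2_relative = a2_relative,
                 standardize_exposure = standardize_exposure,
                 covariates = covariates, n_subjects = n_subjects,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-subject vowel-synthesis parameters for run_synth: baseline values with
# between-subject variation, shifted by the subject's true phenotype in the
# directions the feature-phenotype model encodes (sarcopenia-based frailty
# -> more shimmer and formant drift; energy-based frailty -> steeper
# spectral tilt and less aspiration noise).
subject_voice_params <- function(ebf_frail, sbf_frail) {
  list(
    f0 = runif(1, 100, 180),
    jitter_pct = runif(1, 0.2, 0.8),
    shimmer_pct = runif(1, 1.5, 3.5) + 3.5 * sbf_frail,
    open_quotient = min(0.9, runif(1, 0.50, 0.62) + 0.15 * ebf_frail),
    noise_snr_db = runif(1, 22, 28) + 8 * ebf_frail,
    drift_amplitude = runif(1, 4, 10) + 10 * sbf_frail,
    drift_rate = runif(1, 2, 4)
  )
}

#' Generate a synthetic study on disk
#'
#' Writes one WAV per subject and repeat (3 repeats each, about 1 s of
#' sustained /a/ with leading and trailing silence), the assessment CSV, the
#' true feature and outcome tables, and a truth manifest (JSON) holding the
#' per-subject synthesis parameters. Deterministic under the config seed.
#'
#' @param config a [pipeline_config()]; `output_dir` must be set.
#' @return (invisibly) a list with the table paths and the cohort object.
#' @export
run_synth <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (is.null(out)) stop("run_synth: output_dir is not set")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("run_synth: cannot create output_dir ", out)
  audio_dir <- file.path(out, "audio")
  dir.create(audio_dir, showWarnings = FALSE)
  cohort <- generate_cohort(cohort_spec(config$n_subjects, seed = config$seed))
  n <- nrow(cohort$assessments)
  truth <- vector("list", n)
  if (n > 0) {
    phen <- cohort$outcomes
    for (i in seq_len(n)) {
      sid <- cohort$assessments$subject_id[i]
      vp <- subject_voice_params(
        ebf_frail = as.integer(isTRUE(phen$ebf_status[i] == "frail")),
        sbf_frail = as.integer(isTRUE(phen$sbf_status[i] == "frail")))
      truth[[i]] <- c(list(subject_id = sid), vp)
      for (rep_k in 1:3) {
        sp <- vowel_spec(
          source = glottal_source_params(vp$f0, vp$jitter_pct, vp$shimmer_pct,
                                         vp$open_quotient, vp$noise_snr_db),
          tract = vocal_tract_params(drift_amplitude = vp$drift_amplitude,
                                     drift_rate = vp$drift_rate),
          duration_s = runif(1, 0.9, 1.1),
          sample_rate_hz = config$sample_rate_hz,
          seed = NULL)  # RNG stream already seeded; keep one stream
        w <- synthesize_vowel(sp)
        pad <- function(sec) numeric(round(sec * config$sample_rate_hz))
        padded <- waveform(c(pad(runif(1, 0.15, 0.25)),
                             0.7 * w$samples,
                             pad(runif(1, 0.15, 0.25))),
                           config$sample_rate_hz)
        write_wav(padded, file.path(audio_dir,
                                    sprintf("%s_rep%d.wav", sid, rep_k)))
      }
    }
  } else {
    warning("run_synth: n_subjects = 0; writing empty tables")
  }
  paths <- list(
    audio_dir = audio_dir,
    assessments = file.path(out, "assessments.csv"),
    features_true = file.path(out, "features_true.csv"),
    outcomes_true = file.path(out, "outcomes_true.csv"),
    truth_manifest = file.path(out, "truth_manifest.json")
  )
  write.csv(cohort$assessments, paths$assessments, row.names = FALSE)
  write.csv(cohort$features, paths$features_true, row.names = FALSE)
  write.csv(cohort$outcomes, paths$outcomes_true, row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed, n_subjects = n,
                            sample_rate_hz = config$sample_rate_hz,
                            subjects = truth),
                       paths$truth_manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(cohort = cohort)))
}

assessment_schema <- c("subject_id", "sex", "weight_loss_kg",
                       "weight_loss_pct", "exhaustion", "chair_rise_unable",
                       "grip_kg", "gait_speed_mps", "non_ambulatory",
                       "adl_deterioration")

read_assessments <- function(path) {
  if (!file.exists(path)) stop("run_pipeline: assessment CSV not found: ", path)
  a <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(assessment_schema, names(a))
  if (length(missing_cols))
    stop("run_pipeline: assessment CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in c("exhaustion", "chair_rise_unable", "non_ambulatory",
               "adl_deterioration")) {
    v <- a[[nm]]
    if (!is.logical(v)) {
      parsed <- v %in% c("TRUE", "true", "yes", "1", 1)
      bad <- !(v %in% c("TRUE", "true", "yes", "1", "FALSE", "false", "no",
                        "0", 0, 1) | is.na(v))
      if (any(bad))
        stop("run_pipeline: assessment CSV column '", nm,
             "' not yes/no at row(s) ", paste(which(bad), collapse = ", "))
      parsed[is.na(v)] <- NA
      a[[nm]] <- parsed
    }
  }
  a
}

# QC one subject's recordings; returns list(qc_rows, feature_row_or_NULL)
qc_subject <- function(sid, files, config) {
  rows <- list()
  note <- function(rep_idx, code, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sid, repeat_index = rep_idx, reason = code,
      detail = detail, stringsAsFactors = FALSE)
  }
  feats <- list()
  for (k in seq_along(files)) {
    res <- tryCatch({
      w <- read_wav(files[k], subject_id = sid, repeat_index = k)
      trimmed <- detect_endpoints(w, config$endpoint)
      if (!validate_duration(trimmed, config$duration_min_s,
                             config$duration_max_s)) {
        note(k, "duration_fail",
             sprintf("%.3f s", wave_duration(trimmed)))
        NULL
      } else {
        compute_features(trimmed, cfg_time = config$frame_time,
                         cfg_lp = config$frame_lp,
                         end_frequency_hz = config$end_frequency_hz,
                         a2_relative = config$a2_relative)
      }
    }, error = function(e) {
      note(k, "read_or_trim_error", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) feats[[length(feats) + 1L]] <- res
  }
  if (length(feats) < 3L) {
    note(NA_integer_, "too_few_valid_repeats", sprintf("%d of 3", length(feats)))
    return(list(qc = do.call(rbind, rows), feature_row = NULL))
  }
  rep_mat <- do.call(rbind, feats[1:3])
  qc <- select_repeats(rep_mat, config$variability_threshold_pct)
  for (nm in names(qc$variability_pass)) {
    if (!qc$variability_pass[nm])
      note(NA_integer_, "cv_fail",
           sprintf("%s CV %.1f%%", nm, qc$per_parameter_cv_pct[nm]))
  }
  fr <- as.data.frame(as.list(qc$accepted_values))
  fr <- cbind(data.frame(subject_id = sid), fr)
  list(qc = if (length(rows)) do.call(rbind, rows) else NULL, feature_row = fr)
}

#' Run the full analysis pipeline
#'
#' Record QC (endpoint trimming, duration gate, repeat-variability
#' screening), feature extraction, phenotype scoring, and the per-feature
#' association models, from WAV files plus an assessment CSV to a results
#' bundle on disk: `qc_report.csv`, `features.csv`, `phenotypes.csv`,
#' `associations.csv`, and `manifest.json`. Unreadable recordings flag their
#' subject and the pipeline continues; every excluded subject or parameter
#' appears in the QC report with a reason code.
#'
#' @param config a [pipeline_config()] with `audio_dir`, `assessment_csv`
#'   and `output_dir` set.
#' @return (invisibly) a list with the tables (`qc`, `features`,
#'   `phenotypes`, `associations`) and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$audio_dir) || is.null(config$assessment_csv) ||
      is.null(config$output_dir))
    stop("run_pipeline: audio_dir, assessment_csv and output_dir must be set")
  assessments <- read_assessments(config$assessment_csv)
  wavs <- list.files(config$audio_dir, pattern = "_rep[0-9]+\\.wav$",
                     full.names = TRUE)
  if (length(wavs) == 0L) stop("run_pipeline: no WAV files in ", config$audio_dir)
  sids <- sub("_rep[0-9]+\\.wav$", "", basename(wavs))

  qc_rows <- list(); feat_rows <- list()
  for (sid in unique(sids)) {
    res <- qc_subject(sid, sort(wavs[sids == sid]), config)
    if (!is.null(res$qc)) qc_rows[[length(qc_rows) + 1L]] <- res$qc
    if (!is.null(res$feature_row))
      feat_rows[[length(feat_rows) + 1L]] <- res$feature_row
  }
  if (length(feat_rows) == 0L)
    stop("run_pipeline: no subject survived quality control")
  features <- do.call(rbind, feat_rows)
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(subject_id = character(), repeat_index = integer(),
               reason = character(), detail = character())
  phenotypes <- score_phenotypes(assessments)
  d <- analysis_table(features, phenotypes)

  results <- list()
  for (exposure in c("A1", "A2", "A3", "A4")) {
    for (outcome in c("ebf_frail", "sbf_frail", "hbf_e", "hbf_s")) {
      r <- tryCatch(
        suppressMessages(fit_binomial(
          d, outcome, exposure, covariates = config$covariates,
          standardize_exposure = config$standardize_exposure)),
        error = function(e) data.frame(
          effect_type = "OR", outcome = outcome, exposure = exposure,
          term = exposure, estimate = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, se_log = NA_real_, p_value = NA_real_,
          n_used = NA_integer_, baseline_category = NA_character_,
          note = conditionMessage(e)))
      if (is.null(r$note)) r$note <- NA_character_
      if (is.null(r$category)) r$category <- NA_character_
      results[[length(results) + 1L]] <- r
    }
    rm <- tryCatch(
      suppressMessages(suppressWarnings(fit_multinomial(
        d, "four_category", exposure, covariates = config$covariates,
        standardize_exposure = config$standardize_exposure))),
      error = function(e) data.frame(
        effect_type = "RRR", outcome = "four_category", exposure = exposure,
        category = NA_character_, term = exposure, estimate = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, se_log = NA_real_,
        p_value = NA_real_, n_used = NA_integer_,
        baseline_category = "nonfrail", note = conditionMessage(e)))
    if (is.null(rm$note)) rm$note <- NA_character_
    results[[length(results) + 1L]] <- rm
  }
  col_order <- c("effect_type", "outcome", "exposure", "category", "term",
                 "estimate", "ci_low", "ci_high", "se_log", "p_value",
                 "n_used", "baseline_category", "note")
  associations <- do.call(rbind, lapply(results, function(r) r[, col_order]))

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list(qc = file.path(out, "qc_report.csv"),
                features = file.path(out, "features.csv"),
                phenotypes = file.path(out, "phenotypes.csv"),
                associations = file.path(out, "associations.csv"),
                manifest = file.path(out, "manifest.json"))
  write.csv(qc, paths$qc, row.names = FALSE)
  write.csv(features, paths$features, row.names = FALSE)
  write.csv(phenotypes, paths$phenotypes, row.names = FALSE)
  write.csv(associations, paths$associations, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         package_version = as.character(utils::packageVersion("voxfrail")),
         n_recordings = length(wavs),
         n_subjects_assessed = nrow(assessments),
         n_subjects_with_features = nrow(features),
         n_models = length(results),
         thresholds = list(
           duration_s = c(config$duration_min_s, config$duration_max_s),
           variability_pct = config$variability_threshold_pct,
           end_frequency_hz = config$end_frequency_hz)),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, features = features, phenotypes = phenotypes,
                 associations = associations, paths = paths))
}
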