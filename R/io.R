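#' Write a session waveform as CSV with a JSON sidecar
#'
#' The CSV holds the uniformly sampled trace (`time_s,pressure_mmhg`); the
#' sidecar records the subject id, sampling rate, decompensation step,
#' per-step sample boundaries and CRM labels, so the pair fully describes
#' the session.
#'
#' @param session A `crm_session`.
#' @param dir Output directory (created if needed).
#' @return Invisible list with the two file paths.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$subject$subject_id
  csv <- file.path(dir, paste0(id, ".csv"))
  js <- file.path(dir, paste0(id, ".json"))
  fs <- session$waveform$fs
  x <- session$waveform$samples
  utils::write.csv(data.frame(time_s = (seq_along(x) - 1) / fs,
                              pressure_mmhg = x),
                   csv, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = id, fs = fs, hdd_step = session$subject$hdd_step,
         steps = session$steps),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, json = js))
}

#' Read a waveform CSV written by [write_session()]
#'
#' @param csv Path to the `time_s,pressure_mmhg` CSV.
#' @return Waveform list with `fs` (inferred from the time column) and
#'   `samples`.
#' @export
read_waveform_csv <- function(csv) {
  d <- utils::read.csv(csv)
  if (!all(c("time_s", "pressure_mmhg") %in% names(d)))
    stop("expected columns time_s,pressure_mmhg")
  fs <- round(1 / stats::median(diff(d$time_s)))
  list(fs = fs, samples = d$pressure_mmhg)
}

#' Reassemble a session from a waveform CSV + JSON sidecar pair
#'
#' Inverse of [write_session()] up to the generator internals: the
#' waveform, step boundaries, CRM labels and subject identity are
#' restored, which is everything downstream processing needs.
#'
#' @param dir Directory holding the file pair.
#' @param subject_id Basename of the pair.
#' @return A `crm_session` (without per-beat ground-truth annotations).
#' @export
read_session <- function(dir, subject_id) {
  w <- read_waveform_csv(file.path(dir, paste0(subject_id, ".csv")))
  side <- jsonlite::read_json(file.path(dir, paste0(subject_id, ".json")),
                              simplifyVector = TRUE)
  w$fs <- side$fs
  structure(list(waveform = w, beats = NULL,
                 steps = as.data.frame(side$steps),
                 subject = list(subject_id = side$subject_id,
                                hdd_step = side$hdd_step)),
            class = "crm_session")
}

#' Write a cohort manifest as JSON
#'
#' @param subjects List of `crm_subject`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(subjects, path) {
  jsonlite::write_json(lapply(subjects, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Manifest path from [write_manifest()].
#' @return List of `crm_subject`.
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(r)
    subject_params(r$subject_id, r$hdd_step, r$baseline_sys, r$baseline_dia,
                   r$baseline_hr, r$hrip_base, r$noise_sd, r$wander_amp,
                   r$seed))
}

#' Write a feature table as CSV
#'
#' @param table Feature table from [build_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path Path from [write_feature_csv()].
#' @return data.frame in feature-table layout.
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", "group", "step", "crm", feature_registry()$name)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("feature CSV missing columns: ", paste(missing, collapse = ", "))
  d
}

#' Write an MRMR ranking as JSON
#'
#' @param ranking A `crm_ranking`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranking_json <- function(ranking, path) {
  jsonlite::write_json(as.data.frame(ranking), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the feature registry as JSON
#'
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
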