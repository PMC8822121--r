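# Recording bundle: plain-text serialization of a subject recording
# (manifest JSON + CSV streams + JSON-lines detections), with a lossless
# numeric roundtrip.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a subject recording as a bundle directory
#'
#' Layout: `manifest.json` (sampling spec, subject metadata, file list),
#' `emg.csv` (ch1..ch12 + per-sample label), `gaze.csv`, `trials.csv`,
#' `detections.jsonl` (one frame per line). Floating-point values are
#' written with 17 significant digits so `read_bundle(write_bundle(r))`
#' reproduces every stream bit-exactly.
#'
#' @param recording A `subject_recording`.
#' @param path Output directory (created if needed).
#' @param subject Subject identifier stored in the manifest.
#' @return The manifest (invisibly).
#' @export
write_bundle <- function(recording, path, subject = "S1") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- recording$sampling

  emg_dt <- data.table::as.data.table(
    matrix(fmt17(recording$emg), nrow = nrow(recording$emg)))
  data.table::setnames(emg_dt, paste0("ch", seq_len(ncol(recording$emg))))
  emg_dt[, label := recording$emg_labels]
  data.table::fwrite(emg_dt, file.path(path, "emg.csv"))

  if (!is.null(recording$gaze)) {
    g <- data.table::data.table(t = fmt17(recording$gaze$t),
                                x = fmt17(recording$gaze$x),
                                y = fmt17(recording$gaze$y),
                                valid = recording$gaze$valid)
    data.table::fwrite(g, file.path(path, "gaze.csv"))
  }

  tr <- recording$trials
  num_cols <- names(tr)[vapply(tr, is.double, TRUE)]
  trc <- tr
  for (cc in num_cols) trc[[cc]] <- fmt17(tr[[cc]])
  data.table::fwrite(trc, file.path(path, "trials.csv"))

  if (!is.null(recording$detections)) {
    det <- recording$detections
    con <- file(file.path(path, "detections.jsonl"), open = "wt")
    on.exit(close(con), add = TRUE)
    for (f in unique(det$frame_index)) {
      rows <- which(det$frame_index == f)
      inst <- lapply(rows, function(r) {
        poly <- det$polygon[[r]]
        list(label = det$label[r], score = fmt17(det$score[r]),
             polygon = lapply(seq_len(nrow(poly)),
                              function(v) c(fmt17(poly[v, 1]), fmt17(poly[v, 2]))))
      })
      line <- jsonlite::toJSON(
        list(frame_index = f, timestamp = fmt17(det$timestamp[rows[1]]),
             instances = inst),
        auto_unbox = TRUE)
      writeLines(line, con)
    }
  }

  manifest <- list(
    format_version = 1L,
    subject = subject,
    population = recording$population,
    seed = recording$config$seed %||% NA,
    sampling = sp,
    n_emg_samples = nrow(recording$emg),
    n_trials = nrow(recording$trials),
    files = list(emg = "emg.csv", gaze = "gaze.csv", trials = "trials.csv",
                 detections = "detections.jsonl")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a recording bundle
#'
#' Validates the manifest against the stored streams: missing files,
#' missing columns and a manifest sampling rate inconsistent with the
#' stream cadences are descriptive errors.
#'
#' @param path Bundle directory.
#' @return A `subject_recording`.
#' @export
read_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("manifest not found: %s", mf_path)
  manifest <- jsonlite::fromJSON(mf_path)
  need <- function(fname) {
    fp <- file.path(path, fname)
    if (!file.exists(fp)) stopf("bundle file missing: %s", fp)
    fp
  }

  emg_dt <- data.table::fread(need(manifest$files$emg))
  ch_cols <- grep("^ch", names(emg_dt), value = TRUE)
  if (length(ch_cols) != manifest$sampling$n_electrodes ||
      !"label" %in% names(emg_dt)) {
    stopf("schema error in %s: expected %d channel columns + label",
          manifest$files$emg, manifest$sampling$n_electrodes)
  }
  emg <- as.matrix(emg_dt[, ch_cols, with = FALSE])
  dimnames(emg) <- NULL
  labels <- as.integer(emg_dt$label)

  gaze <- NULL
  if (!is.null(manifest$files$gaze) && file.exists(file.path(path, manifest$files$gaze))) {
    gaze <- data.table::fread(file.path(path, manifest$files$gaze))
    if (!all(c("t", "x", "y", "valid") %in% names(gaze))) {
      stopf("schema error in %s: columns t, x, y, valid required",
            manifest$files$gaze)
    }
    gaze <- data.table::data.table(t = as.numeric(gaze$t),
                                   x = as.numeric(gaze$x),
                                   y = as.numeric(gaze$y),
                                   valid = as.logical(gaze$valid))
    # cadence check against the manifest gaze rate
    if (nrow(gaze) > 10) {
      dt <- stats::median(diff(gaze$t))
      if (abs(dt - 1 / manifest$sampling$gaze_rate) > 0.5 / manifest$sampling$gaze_rate) {
        stopf("rate mismatch: manifest gaze_rate %s Hz but stream cadence %.4f s",
              manifest$sampling$gaze_rate, dt)
      }
      dur_gaze <- max(gaze$t) - min(gaze$t) + dt
      dur_emg <- nrow(emg) / manifest$sampling$emg_rate
      if (abs(dur_gaze - dur_emg) > 0.5) {
        stopf("rate mismatch: emg duration %.2f s at manifest emg_rate %s Hz vs gaze span %.2f s",
              dur_emg, manifest$sampling$emg_rate, dur_gaze)
      }
    }
  }

  trials <- as.data.frame(data.table::fread(need(manifest$files$trials)))
  if (!all(c("trial_id", "grasp_id", "object", "condition") %in% names(trials))) {
    stopf("schema error in %s: trial metadata columns missing", manifest$files$trials)
  }

  detections <- NULL
  det_path <- file.path(path, manifest$files$detections %||% "detections.jsonl")
  if (file.exists(det_path)) {
    lines <- readLines(det_path)
    rows <- vector("list", length(lines))
    for (li in seq_along(lines)) {
      fr <- jsonlite::fromJSON(lines[li], simplifyVector = FALSE)
      inst <- fr$instances
      if (length(inst)) {
        rows[[li]] <- data.table::data.table(
          frame_index = as.integer(fr$frame_index),
          timestamp = as.numeric(fr$timestamp),
          inst_id = seq_along(inst),
          label = vapply(inst, `[[`, "", "label"),
          score = vapply(inst, function(z) as.numeric(z$score), 1),
          polygon = lapply(inst, function(z) {
            do.call(rbind, lapply(z$polygon, function(v) as.numeric(unlist(v))))
          })
        )
      }
    }
    detections <- data.table::rbindlist(Filter(Negate(is.null), rows))
  }

  sampling <- list(emg_rate = manifest$sampling$emg_rate,
                   gaze_rate = manifest$sampling$gaze_rate,
                   video_rate = manifest$sampling$video_rate,
                   n_electrodes = as.integer(manifest$sampling$n_electrodes))
  structure(list(emg = emg, emg_labels = labels, gaze = gaze,
                 detections = detections, trials = trials,
                 population = manifest$population,
                 config = list(seed = manifest$seed),
                 sampling = sampling),
            class = "subject_recording")
}
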