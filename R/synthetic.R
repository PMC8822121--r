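# Protocol-faithful synthetic multimodal recordings: sEMG with per-sample
# labels, gaze, and per-frame object detections, standing in for real
# eye-tracker + EMG acquisitions.

#' Sampling specification of the acquisition setup
#'
#' @return list with emg_rate (1926 Hz), gaze_rate (100 Hz), video_rate
#'   (25 FPS) and n_electrodes (12).
#' @export
sampling_spec <- function() {
  list(emg_rate = 1926, gaze_rate = 100, video_rate = 25, n_electrodes = 12L)
}

#' Default per-grasp muscle-activation signatures
#'
#' A 10 x 12 nonnegative matrix: each grasp activates a smooth bump of
#' forearm channels centred at a grasp-specific location, with a secondary
#' bump and a small per-grasp amplitude offset so the rows are pairwise
#' distinct. Amplitudes are in the same arbitrary mV-scale units as the
#' generated rest noise.
#'
#' @return numeric matrix 10 x 12, rownames = grasp names.
#' @export
default_signatures <- function() {
  map <- grasp_object_pairs()
  n_ch <- 12L
  sig <- matrix(0, nrow = 10L, ncol = n_ch)
  ch <- seq_len(n_ch)
  for (g in 1:10) {
    mu1 <- 1 + (g - 1) * (n_ch - 1) / 9
    mu2 <- ((mu1 + 5.5 - 1) %% n_ch) + 1
    amp <- 0.9 + 0.05 * g
    sig[g, ] <- amp * exp(-0.5 * ((ch - mu1) / 1.4)^2) +
      0.45 * amp * exp(-0.5 * ((ch - mu2) / 1.8)^2)
  }
  rownames(sig) <- map$grasps$name
  sig
}

#' Synthetic recording configuration
#'
#' Bundles every tunable of the generator. Defaults reproduce the
#' acquisition protocol's structure: rest-grasp-rest trials with at least
#' 1 s of rest, 10 grasps x 32 repetitions across static-seated /
#' static-standing / dynamic conditions, at least five objects per scene,
#' pre-movement target fixations and noisy detections.
#'
#' @param seed Integer seed; the whole recording is reproducible under it.
#' @param population `"amputee"` or `"able_bodied"`; populations differ
#'   only by a noise multiplier (no claim of physiological realism).
#' @param grasps Optional subset of grasp ids for a miniature protocol.
#' @param rest_range Uniform range (s) of each rest period; minimum 1 s.
#' @param grasp_range Uniform range (s) of the grasp hold.
#' @param signatures 10 x 12 nonnegative per-grasp activation matrix.
#' @param noise_sd Rest-noise standard deviation (arbitrary units).
#' @param population_noise_mult Named multipliers applied to `noise_sd`.
#' @param amp_jitter_sd Lognormal sd of the per-repetition amplitude jitter.
#' @param ramp_s Raised-cosine on/off envelope ramp (s).
#' @param fixation_lead Time (s) gaze lands on the target before grasp onset.
#' @param fixation_hold Time (s) gaze stays on the target after onset.
#' @param gaze_jitter_px Fixation jitter sd (px).
#' @param saccade_dwell_s Dwell per scanned distractor outside fixations (s).
#' @param gaze_invalid_rate Fraction of gaze samples flagged invalid.
#' @param distractor_count Distractor objects per scene (>= 4, so scenes
#'   hold at least five objects).
#' @param person_rate Probability a scene also contains a person instance.
#' @param score_mean,score_sd Detection score distribution (clipped to
#'   `[0, 1]`).
#' @param miss_prob Per-frame, per-instance detection miss probability.
#' @param target_miss_prob Optional override of `miss_prob` for the target
#'   object only (1.0 forces sEMG-only fallback).
#' @param contour_jitter_px Per-vertex detection contour jitter sd (px).
#' @param spurious_rate Per-frame probability of one spurious instance.
#' @param frame_px Scene size in pixels (width, height), origin top-left,
#'   y down.
#' @param pre_window,post_window Extraction window around grasp onset (s)
#'   within which detections are stored.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         population = c("amputee", "able_bodied"),
                         grasps = NULL,
                         rest_range = c(1.0, 3.0),
                         grasp_range = c(1.5, 2.5),
                         signatures = default_signatures(),
                         noise_sd = 0.2,
                         population_noise_mult = c(amputee = 1.5, able_bodied = 1.0),
                         amp_jitter_sd = 0.08,
                         ramp_s = 0.15,
                         fixation_lead = 1.0,
                         fixation_hold = 0.5,
                         gaze_jitter_px = 3,
                         saccade_dwell_s = 0.3,
                         gaze_invalid_rate = 0.02,
                         distractor_count = 4L,
                         person_rate = 0.3,
                         score_mean = 0.95,
                         score_sd = 0.03,
                         miss_prob = 0.05,
                         target_miss_prob = NULL,
                         contour_jitter_px = 1.5,
                         spurious_rate = 0.02,
                         frame_px = c(1920L, 1080L),
                         pre_window = 2.0,
                         post_window = 3.5) {
  population <- match.arg(population)
  if (rest_range[1] < 1.0) stopf("rest_range minimum must be >= 1 s")
  if (diff(rest_range) < 0 || diff(grasp_range) < 0) stopf("malformed duration range")
  if (distractor_count < 4L) stopf("distractor_count must be >= 4 (scenes hold at least five objects)")
  if (!is.matrix(signatures) || ncol(signatures) != 12L) {
    stopf("signatures must be a matrix with 12 channel columns")
  }
  if (any(signatures < 0)) stopf("signatures must be nonnegative")
  if (anyDuplicated(signatures)) stopf("signatures must be pairwise distinct")
  spec <- sampling_spec()
  if (grasp_range[1] < 200 / spec$emg_rate) {
    stopf("grasp_range minimum (%.3f s) shorter than one classification window", grasp_range[1])
  }
  structure(list(
    seed = as.integer(seed), population = population, grasps = grasps,
    rest_range = rest_range, grasp_range = grasp_range,
    signatures = signatures, noise_sd = noise_sd,
    population_noise_mult = population_noise_mult,
    amp_jitter_sd = amp_jitter_sd, ramp_s = ramp_s,
    fixation_lead = fixation_lead, fixation_hold = fixation_hold,
    gaze_jitter_px = gaze_jitter_px, saccade_dwell_s = saccade_dwell_s,
    gaze_invalid_rate = gaze_invalid_rate,
    distractor_count = as.integer(distractor_count), person_rate = person_rate,
    score_mean = score_mean, score_sd = score_sd,
    miss_prob = miss_prob, target_miss_prob = target_miss_prob,
    contour_jitter_px = contour_jitter_px, spurious_rate = spurious_rate,
    frame_px = as.integer(frame_px),
    pre_window = pre_window, post_window = post_window,
    sampling = spec
  ), class = "synth_config")
}

effective_noise_sd <- function(config) {
  config$noise_sd * config$population_noise_mult[[config$population]]
}

raised_cosine_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  ramp_n <- min(ramp_n, floor(n / 2))
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[n - ramp_n + seq_len(ramp_n)] <- rev(up)
  }
  env
}

#' Synthesize one rest-grasp-rest sEMG segment
#'
#' Rest portions are zero-mean Gaussian noise; the grasp portion adds the
#' grasp's 12-channel activation signature under a raised-cosine on/off
#' envelope. Draws from the current RNG state; seed externally for
#' reproducibility.
#'
#' @param grasp_id Grasp id (1-10).
#' @param durations list(rest1, grasp, rest2) in seconds.
#' @param config A [synth_config()].
#' @return list(signal = samples x 12 matrix, labels = integer vector
#'   (0 = rest), onset = first grasp-labelled sample (1-based),
#'   grasp_end = last grasp-labelled sample).
#' @export
synthesize_emg_segment <- function(grasp_id, durations, config) {
  rate <- config$sampling$emg_rate
  n1 <- max(1L, round(durations$rest1 * rate))
  ng <- round(durations$grasp * rate)
  n2 <- max(1L, round(durations$rest2 * rate))
  if (ng < 200L) stopf("grasp duration %.3f s shorter than one 200-sample window", durations$grasp)
  n <- n1 + ng + n2
  sd_eff <- effective_noise_sd(config)
  signal <- matrix(if (sd_eff > 0) stats::rnorm(n * 12L, sd = sd_eff) else 0,
                   nrow = n, ncol = 12L)
  env <- raised_cosine_envelope(ng, round(config$ramp_s * rate))
  amp <- if (config$amp_jitter_sd > 0) exp(stats::rnorm(1, 0, config$amp_jitter_sd)) else 1
  sig_row <- config$signatures[grasp_id, ]
  signal[n1 + seq_len(ng), ] <- signal[n1 + seq_len(ng), ] +
    (amp * env) %o% sig_row
  labels <- rep(REST_ID, n)
  labels[n1 + seq_len(ng)] <- as.integer(grasp_id)
  list(signal = signal, labels = labels, onset = n1 + 1L, grasp_end = n1 + ng)
}

# Star-shaped simple polygon of 8-16 vertices around a centre.
random_polygon <- function(cx, cy, radius, n_min = 8L, n_max = 16L) {
  n <- sample(n_min:n_max, 1L)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * stats::runif(n, 0.65, 1)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Non-overlapping scene layout on a jittered grid; returns centres/radii.
scene_layout <- function(n_objects, frame_px) {
  margin <- 80
  n_col <- 5L; n_row <- 3L
  if (n_objects > n_col * n_row) {
    stopf("scene placement failure: %d objects exceed %d grid cells",
          n_objects, n_col * n_row)
  }
  cw <- (frame_px[1] - 2 * margin) / n_col
  chg <- (frame_px[2] - 2 * margin) / n_row
  cells <- sample.int(n_col * n_row, n_objects)
  col <- (cells - 1L) %% n_col
  row <- (cells - 1L) %/% n_col
  radius <- stats::runif(n_objects, 60, min(cw, chg) / 2 - 15)
  cx <- margin + col * cw + cw / 2 + stats::runif(n_objects, -10, 10)
  cy <- margin + row * chg + chg / 2 + stats::runif(n_objects, -10, 10)
  data.frame(cx = cx, cy = cy, radius = radius)
}

clip_score <- function(s) pmin(1, pmax(0, s))

#' Generate the scene and gaze stream for one trial
#'
#' The scene contains the trial's target object plus at least four
#' distractors as non-overlapping simple polygons. Gaze fixates the target
#' from `fixation_lead` seconds before grasp onset until `fixation_hold`
#' after it, and scans distractors otherwise; invalid samples are injected
#' at `gaze_invalid_rate`. Detections (with score jitter, misses, contour
#' jitter and occasional spurious instances) are emitted only within the
#' extraction window `[onset - pre_window, onset + post_window]`, mirroring
#' how detector output is stored offline. Draws from the current RNG state.
#'
#' @param trial One-row trial record with `object`, `condition`,
#'   `seg_start_s`, `seg_end_s` and `onset_s` (absolute seconds).
#' @param config A [synth_config()].
#' @param fixate_object Object class gaze fixates before onset; defaults to
#'   the trial's target. Setting a class not paired with the trial's grasp
#'   yields an adversarial scene.
#' @return list(detections = data.table(frame_index, timestamp, inst_id,
#'   label, score, polygon), gaze = data.table(t, x, y, valid)).
#' @export
generate_scene_and_gaze <- function(trial, config, fixate_object = NULL) {
  spec <- config$sampling
  fixate_object <- tolower(fixate_object %||% trial$object)
  all_objects <- grasp_object_pairs()$objects

  scene_labels <- unique(c(trial$object, fixate_object))
  pool <- setdiff(all_objects, scene_labels)
  n_extra <- max(0L, config$distractor_count + 1L - length(scene_labels))
  scene_labels <- c(scene_labels, sample(pool, n_extra))
  has_person <- stats::runif(1) < config$person_rate
  if (has_person) scene_labels <- c(scene_labels, "person")

  layout <- scene_layout(length(scene_labels), config$frame_px)
  base_polys <- lapply(seq_along(scene_labels), function(i) {
    random_polygon(layout$cx[i], layout$cy[i], layout$radius[i])
  })
  centres <- cbind(layout$cx, layout$cy)
  fix_idx <- match(fixate_object, scene_labels)
  distract_idx <- setdiff(which(scene_labels != "person"), fix_idx)

  ## ---- gaze over the whole segment ----
  g_rate <- spec$gaze_rate
  k0 <- ceiling(trial$seg_start_s * g_rate)
  k1 <- ceiling(trial$seg_end_s * g_rate) - 1L
  t_gaze <- (k0:k1) / g_rate
  n_g <- length(t_gaze)
  fix_a <- trial$onset_s - config$fixation_lead
  fix_b <- trial$onset_s + config$fixation_hold
  in_fix <- t_gaze >= fix_a & t_gaze <= fix_b

  x <- numeric(n_g); y <- numeric(n_g)
  # scanning behaviour: dwell on a random non-target object per chunk
  chunk <- pmax(1L, floor((t_gaze - t_gaze[1]) / config$saccade_dwell_s) + 1L)
  n_chunk <- max(chunk)
  pick_from <- if (length(distract_idx)) distract_idx else fix_idx
  chunk_obj <- sample(pick_from, n_chunk, replace = TRUE)
  obj_of_sample <- chunk_obj[chunk]
  x <- centres[obj_of_sample, 1] + stats::rnorm(n_g, 0, 25)
  y <- centres[obj_of_sample, 2] + stats::rnorm(n_g, 0, 25)
  x[in_fix] <- centres[fix_idx, 1] + stats::rnorm(sum(in_fix), 0, config$gaze_jitter_px)
  y[in_fix] <- centres[fix_idx, 2] + stats::rnorm(sum(in_fix), 0, config$gaze_jitter_px)
  x <- pmin(pmax(x, 0), config$frame_px[1] - 1)
  y <- pmin(pmax(y, 0), config$frame_px[2] - 1)
  valid <- stats::runif(n_g) >= config$gaze_invalid_rate
  gaze <- data.table::data.table(t = t_gaze, x = x, y = y, valid = valid)

  ## ---- detections within the extraction window ----
  v_rate <- spec$video_rate
  f0 <- max(ceiling(trial$seg_start_s * v_rate),
            ceiling((trial$onset_s - config$pre_window) * v_rate))
  f1 <- min(ceiling(trial$seg_end_s * v_rate) - 1L,
            floor((trial$onset_s + config$post_window) * v_rate))
  target_idx <- match(trial$object, scene_labels)
  miss_target <- config$target_miss_prob %||% config$miss_prob
  rows <- vector("list", max(0L, f1 - f0 + 1L))
  ri <- 0L
  if (f1 >= f0) {
    for (f in f0:f1) {
      labs <- character(0); scores <- numeric(0); polys <- list()
      for (i in seq_along(scene_labels)) {
        p_miss <- if (i == target_idx) miss_target else config$miss_prob
        if (stats::runif(1) < p_miss) next
        poly <- base_polys[[i]]
        if (config$contour_jitter_px > 0) {
          poly <- poly + matrix(stats::rnorm(length(poly), 0, config$contour_jitter_px),
                                ncol = 2)
        }
        labs <- c(labs, scene_labels[i])
        scores <- c(scores, clip_score(stats::rnorm(1, config$score_mean, config$score_sd)))
        polys[[length(polys) + 1L]] <- poly
      }
      if (stats::runif(1) < config$spurious_rate) {
        labs <- c(labs, sample(all_objects, 1L))
        scores <- c(scores, stats::runif(1, 0.5, 1))
        polys[[length(polys) + 1L]] <- random_polygon(
          stats::runif(1, 100, config$frame_px[1] - 100),
          stats::runif(1, 100, config$frame_px[2] - 100), 40)
      }
      if (length(labs)) {
        ri <- ri + 1L
        rows[[ri]] <- data.table::data.table(
          frame_index = f, timestamp = f / v_rate,
          inst_id = seq_along(labs), label = labs, score = scores,
          polygon = polys
        )
      }
    }
  }
  detections <- if (ri) data.table::rbindlist(rows[seq_len(ri)]) else
    data.table::data.table(frame_index = integer(0), timestamp = numeric(0),
                           inst_id = integer(0), label = character(0),
                           score = numeric(0), polygon = list())
  list(detections = detections, gaze = gaze)
}

#' Generate a full synthetic subject recording
#'
#' Realizes the complete acquisition protocol for one subject: every grasp
#' is repeated 32 times (12 static-seated, 12 static-standing, 8 dynamic)
#' in rest-grasp-rest trials, yielding 320 segments for the full ten-grasp
#' protocol. sEMG, gaze and detections share one time origin; ground-truth
#' onsets and fold assignments are recorded in the trial table.
#'
#' @param config A [synth_config()].
#' @param map A `grasp_object_map` (defaults to the protocol pairing).
#' @param streams Which streams to materialize; trial structure and labels
#'   are always produced.
#' @param adversarial_fixation If `TRUE`, gaze fixates an object *not*
#'   paired with the trial's grasp (when one exists in the catalog),
#'   producing scenes that drive fused decisions to the guaranteed failure
#'   mode.
#' @return An object of class `subject_recording`: list(emg, emg_labels,
#'   gaze, detections, trials, population, config, sampling).
#' @export
generate_subject <- function(config = synth_config(),
                             map = grasp_object_pairs(),
                             streams = c("emg", "gaze", "detections"),
                             adversarial_fixation = FALSE) {
  streams <- match.arg(streams, several.ok = TRUE)
  trials <- build_fold_partition(protocol_trials(map, config$grasps))
  rate <- config$sampling$emg_rate

  with_seed(config$seed, {
    n_t <- nrow(trials)
    trials$rest1_s <- stats::runif(n_t, config$rest_range[1], config$rest_range[2])
    trials$grasp_s <- stats::runif(n_t, config$grasp_range[1], config$grasp_range[2])
    trials$rest2_s <- stats::runif(n_t, config$rest_range[1], config$rest_range[2])

    seg_n <- integer(n_t); seg_list <- vector("list", n_t)
    labels_list <- vector("list", n_t)
    onset_in_seg <- integer(n_t); grasp_end_in_seg <- integer(n_t)
    for (i in seq_len(n_t)) {
      seg <- synthesize_emg_segment(
        trials$grasp_id[i],
        list(rest1 = trials$rest1_s[i], grasp = trials$grasp_s[i],
             rest2 = trials$rest2_s[i]),
        config
      )
      seg_n[i] <- nrow(seg$signal)
      seg_list[[i]] <- seg$signal
      labels_list[[i]] <- seg$labels
      onset_in_seg[i] <- seg$onset
      grasp_end_in_seg[i] <- seg$grasp_end
    }
    seg_start <- cumsum(c(0L, seg_n[-n_t])) + 1L
    trials$seg_start_sample <- seg_start
    trials$seg_end_sample <- seg_start + seg_n - 1L
    trials$onset_sample <- seg_start + onset_in_seg - 1L
    trials$grasp_end_sample <- seg_start + grasp_end_in_seg - 1L
    trials$seg_start_s <- (seg_start - 1L) / rate
    trials$seg_end_s <- trials$seg_end_sample / rate
    trials$onset_s <- (trials$onset_sample - 1L) / rate

    emg <- do.call(rbind, seg_list)
    emg_labels <- unlist(labels_list, use.names = FALSE)

    gaze <- NULL; detections <- NULL
    if (any(c("gaze", "detections") %in% streams)) {
      gaze_list <- vector("list", n_t)
      det_list <- vector("list", n_t)
      for (i in seq_len(n_t)) {
        fixate <- NULL
        if (adversarial_fixation) {
          unpaired <- setdiff(map$objects, objects_for_grasp(map, trials$grasp_id[i]))
          if (length(unpaired)) fixate <- unpaired[1 + (i %% length(unpaired))]
        }
        sg <- generate_scene_and_gaze(trials[i, ], config, fixate_object = fixate)
        gaze_list[[i]] <- sg$gaze
        det_list[[i]] <- sg$detections
      }
      if ("gaze" %in% streams) gaze <- data.table::rbindlist(gaze_list)
      if ("detections" %in% streams) detections <- data.table::rbindlist(det_list)
    }
  })

  structure(list(
    emg = emg, emg_labels = emg_labels,
    gaze = gaze, detections = detections,
    trials = as.data.frame(trials),
    population = config$population,
    config = config, sampling = config$sampling
  ), class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf(
    "subject_recording (%s): %d trials, %.1f s sEMG (%d x %d), %s gaze samples, %s detection instances\n",
    x$population, nrow(x$trials), nrow(x$emg) / x$sampling$emg_rate,
    nrow(x$emg), ncol(x$emg),
    if (is.null(x$gaze)) "no" else format(nrow(x$gaze)),
    if (is.null(x$detections)) "no" else format(nrow(x$detections))
  ))
  invisible(x)
}

#' Extract per-trial sEMG segments
#'
#' @param recording A `subject_recording`.
#' @param trials Subset of the recording's trial table (default all).
#' @return list of list(signal, labels, trial) per trial.
#' @export
trial_segments <- function(recording, trials = recording$trials) {
  lapply(seq_len(nrow(trials)), function(i) {
    a <- trials$seg_start_sample[i]; b <- trials$seg_end_sample[i]
    list(signal = recording$emg[a:b, , drop = FALSE],
         labels = recording$emg_labels[a:b],
         trial = trials[i, ])
  })
}
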