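# Shared fixtures. The miniature protocol (grasps 8 and 10: index finger
# extension and prismatic four finger, whose paired objects span exactly
# four classes: remote, knife, fork, wrench) is generated once and the
# classifier trained once; both are cached across test files.

.fixtures <- new.env(parent = emptyenv())

MINI_GRASPS <- c(8L, 10L)
MINI_SEED <- 11L

mini_config <- function(variant = c("clean", "miss", "noisy"), ...) {
  variant <- match.arg(variant)
  base <- list(
    seed = MINI_SEED, grasps = MINI_GRASPS,
    rest_range = c(1, 1.6), grasp_range = c(1.5, 1.9),
    miss_prob = 0, gaze_invalid_rate = 0, contour_jitter_px = 0.5,
    spurious_rate = 0
  )
  if (variant == "miss") {
    base$target_miss_prob <- 1.0
    base$fixation_hold <- 1.0   # forward search stays inside the fixation
  }
  if (variant == "noisy") {
    base$miss_prob <- 0.05
    base$gaze_invalid_rate <- 0.02
    base$spurious_rate <- 0.02
    base$contour_jitter_px <- 1.5
  }
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(synth_config, base)
}

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

get_mini_recording <- function(variant = "clean", ...) {
  key <- paste0("rec_", variant)
  if (variant == "adversarial") {
    memo(key, generate_subject(mini_config("clean"), adversarial_fixation = TRUE))
  } else {
    memo(key, generate_subject(mini_config(variant)))
  }
}

# One trained classifier (folds 1-3 of the clean miniature recording,
# 210-style split scaled to two grasps) reused everywhere.
get_mini_fit <- function() {
  memo("fit", {
    rec <- get_mini_recording("clean")
    trials <- rec$trials
    sp <- split_train_validation(trials[trials$fold != 4L, , drop = FALSE], 7L)
    scaler <- fit_scaler(lapply(trial_segments(rec, sp$train), `[[`, "signal"))
    wspec <- window_spec()
    build_set <- function(tt) {
      ws <- lapply(trial_segments(rec, tt), function(s) {
        window_segment(transform_emg(s$signal, scaler), s$labels, wspec)
      })
      list(tensor = tensorize(do.call(bind_windows, lapply(ws, `[[`, "windows")), wspec),
           labels = unlist(lapply(ws, `[[`, "labels")))
    }
    train_set <- build_set(sp$train)
    val_set <- build_set(sp$validation)
    model <- build_model(model_spec(filters = 16L), seed = 3L)
    fit <- train_model(model, train_set, val_set,
                       train_config(epochs = 8L, seed = 5L),
                       class_weights = compute_class_weights(train_set$labels))
    test_set <- build_set(trials[trials$fold == 4L, , drop = FALSE])
    list(rec = rec, split = sp, scaler = scaler, wspec = wspec,
         fit = fit, train_set = train_set, val_set = val_set,
         test_set = test_set, build_set = build_set)
  })
}

bind_windows <- function(...) {
  ws <- Filter(function(w) dim(w)[1] > 0L, list(...))
  d <- dim(ws[[1]])
  out <- array(0, c(sum(vapply(ws, function(w) dim(w)[1], 1L)), d[2], d[3]))
  at <- 0L
  for (w in ws) {
    k <- dim(w)[1]
    out[at + seq_len(k), , ] <- w
    at <- at + k
  }
  out
}

# Run streaming prediction + fusion over the held-out fold of a recording,
# with the cached clean-trained model.
eval_mini_fold <- function(variant = "clean", fold = 4L) {
  key <- paste0("eval_", variant, "_", fold)
  memo(key, {
    mf <- get_mini_fit()
    rec <- get_mini_recording(variant)
    gcfg <- gaze_config(); fcfg <- fusion_config()
    rate <- rec$sampling$emg_rate
    test_trials <- rec$trials[rec$trials$fold == fold, , drop = FALSE]
    timelines <- annotate_stream(rec$gaze, rec$detections, test_trials, gcfg,
                                 video_rate = rec$sampling$video_rate)
    traces <- list(); labels <- list(); meta <- list()
    for (i in seq_len(nrow(test_trials))) {
      tr <- test_trials[i, ]
      a <- max(1L, tr$onset_sample - round(gcfg$pre_window * rate))
      b <- min(nrow(rec$emg), tr$onset_sample + round(gcfg$post_window * rate))
      ps <- predict_stream(mf$fit$model,
                           transform_emg(rec$emg[a:b, , drop = FALSE], mf$scaler),
                           mf$wspec)
      tl <- align_timeline(timelines[[as.character(tr$trial_id)]], rate, a)
      id <- as.character(tr$trial_id)
      traces[[id]] <- run_fusion(ps, tl, grasp_object_pairs(), fcfg)
      labels[[id]] <- stream_labels(rec$emg_labels[a:b], mf$wspec)
      meta[[id]] <- data.frame(trial_id = tr$trial_id, subject = "S1",
                               condition = tr$condition, object = tr$object,
                               grasp_id = tr$grasp_id,
                               onset_local = tr$onset_sample - a + 1L,
                               stringsAsFactors = FALSE)
    }
    list(traces = traces, labels = labels,
         trials = do.call(rbind, meta), timelines = timelines)
  })
}
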