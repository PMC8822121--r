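test_that("generated recordings follow the rest-grasp-rest protocol structure", {
  rec <- get_mini_recording("clean")
  trials <- rec$trials
  # 2 grasps x 32 repetitions
  expect_equal(nrow(trials), 64L)
  expect_equal(unname(table(trials$fold)), rep(16L, 4L), ignore_attr = TRUE)

  # label stream: one non-rest run per repetition, flanked by rest
  runs <- rle(rec$emg_labels != 0L)
  expect_equal(sum(runs$values), nrow(trials))
  expect_false(runs$values[1])
  expect_false(runs$values[length(runs$values)])

  # onset samples carry a non-rest label and are preceded by >= 1 s rest
  rate <- rec$sampling$emg_rate
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_sample[i]
    expect_gt(rec$emg_labels[on], 0L)
    expect_equal(rec$emg_labels[on], trials$grasp_id[i])
    pre <- rec$emg_labels[(on - rate):(on - 1L)]
    expect_true(all(pre == 0L))
  }

  # streams share the time origin and durations agree within one frame
  dur_emg <- nrow(rec$emg) / rate
  expect_lt(abs(max(rec$gaze$t) + 1 / rec$sampling$gaze_rate - dur_emg), 0.05)

  # generated trials pass the fold partitioner without error
  expect_no_error(build_fold_partition(trials))
})

test_that("same seed reproduces the recording bit-exactly, different seed does not", {
  cfg <- mini_config("noisy", grasps = 8L, rest_range = c(1, 1.2),
                     grasp_range = c(1.5, 1.6))
  r1 <- generate_subject(cfg)
  r2 <- generate_subject(cfg)
  expect_identical(r1$emg, r2$emg)
  expect_identical(r1$emg_labels, r2$emg_labels)
  expect_identical(r1$gaze, r2$gaze)
  expect_identical(r1$detections$score, r2$detections$score)
  expect_identical(r1$detections$polygon[[5]], r2$detections$polygon[[5]])

  cfg3 <- mini_config("noisy", seed = 99L, grasps = 8L, rest_range = c(1, 1.2),
                      grasp_range = c(1.5, 1.6))
  r3 <- generate_subject(cfg3, streams = "emg")
  expect_false(identical(r1$emg, r3$emg))
})

test_that("noise-free segments reproduce the activation signature exactly", {
  cfg <- mini_config("clean", noise_sd = 0, amp_jitter_sd = 0)
  set.seed(1)
  seg <- synthesize_emg_segment(8L, list(rest1 = 1, grasp = 2, rest2 = 1), cfg)
  # rest portions are exactly zero
  expect_true(all(seg$signal[seq_len(seg$onset - 1L), ] == 0))
  expect_true(all(seg$signal[(seg$grasp_end + 1L):nrow(seg$signal), ] == 0))
  # plateau (between the ramps) equals the signature row
  rate <- cfg$sampling$emg_rate
  ramp <- round(cfg$ramp_s * rate)
  plateau <- seg$signal[(seg$onset + ramp + 1L):(seg$grasp_end - ramp - 1L), ]
  expect_equal(colMeans(plateau), unname(cfg$signatures[8L, ]), tolerance = 1e-12)
  # labels mark exactly the grasp portion
  expect_equal(which(seg$labels != 0L), seg$onset:seg$grasp_end)
})

test_that("active channels are louder during grasp than rest at the default noise", {
  cfg <- synth_config(seed = 2L, grasps = 5L)
  set.seed(7)
  seg <- synthesize_emg_segment(5L, list(rest1 = 1.5, grasp = 2, rest2 = 1.5), cfg)
  active <- which(cfg$signatures[5L, ] > 0.3)
  grasp_amp <- colMeans(abs(seg$signal[seg$onset:seg$grasp_end, active, drop = FALSE]))
  rest_amp <- colMeans(abs(seg$signal[seq_len(seg$onset - 1L), active, drop = FALSE]))
  expect_true(all(grasp_amp > rest_amp))
})

test_that("scenes hold at least five objects and clean fixations hit the target", {
  rec <- get_mini_recording("clean")
  det <- rec$detections
  inst_per_frame <- table(det$frame_index)
  expect_gte(min(inst_per_frame), 5L)

  # noise-free fixation window: every gaze sample maps to the target
  tr <- rec$trials[1, ]
  gcfg <- gaze_config()
  idx <- which(rec$gaze$t >= tr$onset_s - rec$config$fixation_lead + 0.05 &
               rec$gaze$t <= tr$onset_s)
  fidx <- floor(rec$gaze$t[idx] * rec$sampling$video_rate)
  hits <- vapply(seq_along(idx), function(k) {
    frame <- det[det$frame_index == fidx[k], ]
    if (!nrow(frame)) return(NA_character_)
    looked_at_object(list(x = rec$gaze$x[idx[k]], y = rec$gaze$y[idx[k]],
                          valid = rec$gaze$valid[idx[k]]), frame, gcfg)$label
  }, character(1))
  hits <- hits[!is.na(hits)]
  expect_gt(length(hits), 0L)
  expect_true(all(hits == tr$object))
})

test_that("a target miss probability of 1 removes the target from all detections", {
  rec <- get_mini_recording("miss")
  for (i in c(1L, 20L, 40L)) {
    tr <- rec$trials[i, ]
    win <- rec$detections[rec$detections$timestamp >= tr$seg_start_s &
                            rec$detections$timestamp <= tr$seg_end_s, ]
    expect_false(any(win$label == tr$object))
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(rest_range = c(0.5, 2)), "must be >= 1 s")
  expect_error(synth_config(grasp_range = c(0.05, 0.1)), "shorter than one")
  expect_error(synth_config(distractor_count = 2L), "distractor_count")
  expect_error(synth_config(signatures = matrix(1, 10, 12)), "pairwise distinct")
})
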