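tl_at <- function(samples, labels) {
  data.table::data.table(sample = as.integer(samples), looked_at = labels)
}

test_that("intent events fire on rest-to-grasp transitions, including at stream start", {
  ps <- make_prob_stream(c(0L, 0L, 8L, 8L, 0L, 10L))
  expect_equal(detect_intent(ps), c(3L, 6L))
  expect_equal(detect_intent(make_prob_stream(rep(0L, 5))), integer(0))
  expect_equal(detect_intent(make_prob_stream(c(8L, 8L, 0L))), 1L)
})

test_that("target-object search honours the 480-sample lookback and 500 ms forward window", {
  cfg <- fusion_config()
  expect_equal(cfg$timeout_samples, 963L)  # ceil(0.5 s x 1926 Hz)

  # looked at 100 samples before intent -> found instantly
  hit <- find_target_object(tl_at(c(8000, 9900), c("mug", "remote")), 10000L, cfg)
  expect_equal(hit$object, "remote")
  expect_equal(hit$found_at, 10000L)

  # the most recent look wins within the window
  hit2 <- find_target_object(tl_at(c(9700, 9900), c("mug", "remote")), 10000L, cfg)
  expect_equal(hit2$object, "remote")

  # last look 600 samples before intent, nothing after -> none
  hit3 <- find_target_object(tl_at(9400, "mug"), 10000L, cfg)
  expect_true(is.na(hit3$object))

  # first look ~200 ms after intent -> found late at that sample
  hit4 <- find_target_object(tl_at(10385, "jar"), 10000L, cfg)
  expect_equal(hit4$object, "jar")
  expect_equal(hit4$found_at, 10385L)

  # beyond the 500 ms timeout -> none
  expect_true(is.na(find_target_object(tl_at(11000, "jar"), 10000L, cfg)$object))
})

test_that("restricted argmax picks the best admissible grasp", {
  map <- grasp_object_pairs()
  classes <- 0:10
  p <- rep(0.01, 11); names(p) <- classes
  p["2"] <- 0.40   # lateral: not admissible for a bottle
  p["1"] <- 0.35   # medium wrap
  p["4"] <- 0.10   # tripod grasp
  allowed <- grasp_ids_for_object(map, "bottle")
  expect_setequal(allowed, c(1L, 4L))
  expect_equal(fuse_decision(p, allowed), 1L)

  # restriction is a no-op when the global argmax is already admissible
  p2 <- p; p2["1"] <- 0.9
  expect_equal(fuse_decision(p2, allowed), 1L)
  expect_equal(unname(which.max(p2)), which(names(p2) == "1"))

  # singleton allowed set wins regardless of the posterior
  expect_equal(fuse_decision(p, 7L), 7L)

  expect_error(fuse_decision(p, integer(0)), "empty allowed")
  expect_error(fuse_decision(p, c(0L, 1L)), "rest cannot")
})

test_that("fusion trace follows the state machine and resets on rest", {
  # episode: rest, grasp steps with remote identified, long rest, then a
  # second grasp far enough that the stale look is outside the lookback
  ids <- c(0L, 0L, 8L, 8L, 8L, rep(0L, 25L), 10L, 10L)
  ps <- make_prob_stream(ids)
  tl <- tl_at(ps$t[3] - 50L, "remote")
  tr <- run_fusion(ps, tl)

  expect_s3_class(tr, "fusion_trace")
  expect_equal(tr$state, c("REST", "REST", "FUSED", "FUSED", "FUSED",
                           rep("REST", 25L), "SEARCHING", "SEARCHING"))
  # restriction soundness: fused decisions lie in the identified object's set
  allowed <- grasp_ids_for_object(grasp_object_pairs(), "remote")
  expect_true(all(tr$fused[tr$state == "FUSED"] %in% allowed))
  # rest reset clears the object
  expect_true(is.na(tr$object[6]))
  expect_equal(tr$fused[6], 0L)
  # no FUSED state spans a rest-classified step
  expect_true(all(tr$state[tr$unimodal == 0L] == "REST"))

  # all-none timeline: trace equals the unimodal argmax everywhere
  tr0 <- run_fusion(ps, tl_at(integer(0), character(0)))
  expect_equal(tr0$fused, tr0$unimodal)
  expect_true(all(tr0$state %in% c("REST", "SEARCHING", "EMG_ONLY")))
  tr_null <- run_fusion(ps, NULL)
  expect_equal(tr_null$fused, tr_null$unimodal)
})

test_that("late identification switches from searching to fused mid-episode", {
  ids <- c(0L, rep(8L, 60L))
  ps <- make_prob_stream(ids)
  intent_t <- ps$t[2]
  found_t <- intent_t + 385L   # ~200 ms after intent
  tr <- run_fusion(ps, tl_at(found_t, "remote"))
  pre <- tr$t > intent_t - 1 & tr$t < found_t & tr$unimodal != 0L
  post <- tr$t >= found_t & tr$unimodal != 0L
  expect_true(all(tr$state[pre] == "SEARCHING"))
  expect_true(all(tr$state[post] == "FUSED"))
  # unimodal output during the search, restricted afterwards
  expect_equal(tr$fused[pre], tr$unimodal[pre])

  # timeout: no object within 500 ms -> sEMG-only continuation
  tr2 <- run_fusion(ps, tl_at(intent_t + 2000L, "remote"))
  deadline <- intent_t + fusion_config()$timeout_samples
  expect_true(all(tr2$state[tr2$t >= deadline] == "EMG_ONLY"))
  expect_equal(tr2$fused, tr2$unimodal)
})

test_that("dominance: with the correct object, fusion never demotes a correct decision", {
  ev <- eval_mini_fold("clean")
  for (id in names(ev$traces)) {
    tr <- ev$traces[[id]]
    labs <- ev$labels[[id]]
    true_obj <- ev$trials$object[ev$trials$trial_id == as.integer(id)]
    at <- which(tr$state == "FUSED" & !is.na(tr$object) & tr$object == true_obj &
                  tr$unimodal == labs & labs != 0L)
    expect_true(all(tr$fused[at] == labs[at]))
  }
})

test_that("fusion corrects unimodal errors that fall outside the allowed set", {
  # true grasp 8 (index finger extension) on a remote; the classifier
  # mistakes it for grasp 10 (prismatic four finger), which a remote cannot
  # take -- the restricted argmax recovers the true grasp.
  n <- 12L
  probs <- matrix(0.02, n, 11); colnames(probs) <- 0:10
  probs[1:2, "0"] <- 0.8
  for (k in 3:n) { probs[k, "10"] <- 0.45; probs[k, "8"] <- 0.35 }
  probs <- probs / rowSums(probs)
  ps <- make_prob_stream(rep(0L, n), prob_rows = probs)
  tl <- tl_at(ps$t[3] - 10L, "remote")
  tr <- run_fusion(ps, tl)
  labs <- c(0L, 0L, rep(8L, n - 2L))
  expect_gt(accuracy(tr$fused, labs), accuracy(tr$unimodal, labs))
  expect_true(all(tr$fused[tr$state == "FUSED"] == 8L))
})

test_that("an identified object unpaired with the true grasp forces wrong fused decisions", {
  # gaze says mug, but the subject performs prismatic four finger (10):
  # the allowed set {lateral, tripod} excludes the truth.
  ids <- c(0L, rep(10L, 20L))
  ps <- make_prob_stream(ids)
  tr <- run_fusion(ps, tl_at(ps$t[2] - 10L, "mug"))
  labs <- c(0L, rep(10L, 20L))
  fused_steps <- tr$state == "FUSED"
  expect_true(any(fused_steps))
  expect_true(all(tr$fused[fused_steps] != labs[fused_steps]))
})

test_that("streamed and replayed fusion drivers produce identical traces", {
  # handcrafted sequences covering all states
  seqs <- list(
    list(ids = c(0L, 0L, 8L, 8L, 0L, 10L, 10L, 0L),
         tl = tl_at(c(230L, 700L), c("remote", "knife"))),
    list(ids = c(8L, 8L, 0L, 0L, 5L, 5L, 5L),
         tl = tl_at(c(1000L), c("ball"))),
    list(ids = rep(c(0L, 9L), 10),
         tl = tl_at(integer(0), character(0)))
  )
  for (sq in seqs) {
    ps <- make_prob_stream(sq$ids)
    expect_identical(run_fusion(ps, sq$tl), run_fusion_stream(ps, sq$tl))
  }

  # and on real traces from the miniature recording
  ev <- eval_mini_fold("clean")
  mf <- get_mini_fit()
  rec <- mf$rec
  gcfg <- gaze_config()
  rate <- rec$sampling$emg_rate
  for (id in names(ev$traces)[1:4]) {
    tr_row <- rec$trials[rec$trials$trial_id == as.integer(id), ]
    a <- max(1L, tr_row$onset_sample - round(gcfg$pre_window * rate))
    b <- min(nrow(rec$emg), tr_row$onset_sample + round(gcfg$post_window * rate))
    ps <- predict_stream(mf$fit$model,
                         transform_emg(rec$emg[a:b, , drop = FALSE], mf$scaler))
    tl <- align_timeline(ev$timelines[[id]], rate, a)
    expect_identical(run_fusion(ps, tl), run_fusion_stream(ps, tl))
  }
})

test_that("a rest debounce greater than one survives isolated rest blips", {
  ids <- c(0L, 8L, 8L, 0L, 8L, 8L)
  ps <- make_prob_stream(ids)
  tl <- tl_at(ps$t[2] - 10L, "remote")
  # default: single rest sample resets, second episode re-identifies
  tr1 <- run_fusion(ps, tl)
  expect_equal(tr1$state[4], "REST")
  # debounced: the blip does not clear the fused state
  tr2 <- run_fusion(ps, tl, config = fusion_config(rest_debounce = 2L))
  expect_equal(tr2$state[5], "FUSED")
  expect_identical(run_fusion_stream(ps, tl, config = fusion_config(rest_debounce = 2L)),
                   tr2)
})
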