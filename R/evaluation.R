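# Metrics and statistics: per-fold accuracies, correct-object-identification
# rates, confusion matrices, Wilcoxon signed-rank / Mann-Whitney tests with
# rank-biserial effect sizes, and the 4-fold cross-validation driver.

#' Per-step classification accuracy
#'
#' Fraction of steps whose decision equals the ground-truth label, over all
#' 11 classes (ten grasps and rest), as a percentage.
#'
#' @param decisions Integer class ids (or a `fusion_trace`, scored on its
#'   `fused` column).
#' @param labels Integer ground-truth class ids of the same length.
#' @return Accuracy in percent.
#' @export
accuracy <- function(decisions, labels) {
  if (inherits(decisions, "fusion_trace")) decisions <- decisions$fused
  if (length(decisions) != length(labels)) {
    stopf("decisions (%d) and labels (%d) differ in length",
          length(decisions), length(labels))
  }
  100 * mean(decisions == labels)
}

#' Confusion matrix over the 11 classes
#'
#' @param decisions,labels Integer class ids.
#' @param classes Class ids spanning the matrix (default 0:10).
#' @return Square matrix, rows = true class (rows sum to class support),
#'   columns = decision.
#' @export
confusion_matrix <- function(decisions, labels, classes = 0:10) {
  if (inherits(decisions, "fusion_trace")) decisions <- decisions$fused
  cm <- table(factor(labels, levels = classes),
              factor(decisions, levels = classes))
  m <- unclass(as.matrix(cm))
  dimnames(m) <- list(true = as.character(classes),
                      decision = as.character(classes))
  m
}

#' Majority labels of the trailing classification windows
#'
#' Ground-truth label stream matched to [predict_stream()]: for each step
#' emitting at sample t, the majority per-sample label of the trailing
#' window ending at t (ties toward rest).
#'
#' @param labels Per-sample integer labels.
#' @param spec A [window_spec()].
#' @return Integer vector, one label per streaming step.
#' @export
stream_labels <- function(labels, spec = window_spec()) {
  L <- length(labels)
  wl <- spec$window_len; st <- spec$stride_inference
  if (L < wl) return(integer(0))
  ends <- seq.int(wl, L, by = st)
  vapply(ends, function(e) majority_label(labels[(e - wl + 1L):e]), integer(1))
}

#' Identified object of the grasp episode at onset
#'
#' Walks a fusion trace to the first non-rest step at or after the
#' ground-truth onset and reports the object its episode identified
#' (`NA` when the episode never reached the FUSED state, or no episode
#' covers the onset).
#'
#' @param trace A `fusion_trace`.
#' @param onset_sample Ground-truth onset on the trace's sample clock.
#' @return Object label or `NA`.
#' @export
identified_object_at_onset <- function(trace, onset_sample) {
  k <- which(trace$t >= onset_sample & trace$state != "REST")
  if (!length(k)) return(NA_character_)
  k <- k[1]
  # episode start: walk back over contiguous non-REST steps
  while (k > 1L && trace$state[k - 1L] != "REST") k <- k - 1L
  while (k <= nrow(trace) && trace$state[k] != "REST") {
    if (trace$state[k] == "FUSED") return(trace$object[k])
    k <- k + 1L
  }
  NA_character_
}

#' Correct-object-identification rates
#'
#' An identification is correct when the object recognized by the
#' multimodal approach at the beginning of the grasp corresponds to the
#' target one; trials with no identified object count as incorrect. Rates
#' are aggregated per subject and condition (static / dynamic).
#'
#' @param traces Named list (by trial_id) of `fusion_trace`s.
#' @param trials Trial table with trial_id, object, condition and
#'   `onset_local` (onset on each trace's sample clock); optional `subject`.
#' @return data.frame(subject, condition, rate, n_trials) plus a
#'   `per_trial` attribute with the per-trial outcomes.
#' @export
object_id_rate <- function(traces, trials) {
  subj <- trials$subject %||% rep("S1", nrow(trials))
  cond <- ifelse(trials$condition == "dynamic", "dynamic", "static")
  correct <- logical(nrow(trials))
  identified <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- traces[[as.character(trials$trial_id[i])]]
    obj <- identified_object_at_onset(tr, trials$onset_local[i])
    identified[i] <- obj
    correct[i] <- !is.na(obj) && obj == trials$object[i]
  }
  agg <- stats::aggregate(correct, by = list(subject = subj, condition = cond),
                          FUN = function(z) 100 * mean(z))
  names(agg)[3] <- "rate"
  n <- stats::aggregate(correct, by = list(subject = subj, condition = cond),
                        FUN = length)
  agg$n_trials <- n$x
  attr(agg, "per_trial") <- data.frame(trial_id = trials$trial_id,
                                       identified = identified,
                                       correct = correct,
                                       stringsAsFactors = FALSE)
  agg
}

rank_signed <- function(d) {
  r <- rank(abs(d))
  list(w_pos = sum(r[d > 0]), w_neg = sum(r[d < 0]))
}

#' Wilcoxon signed-rank test with matched rank-biserial effect size
#'
#' Paired one-sided or two-sided test on `a - b`; zero differences are
#' dropped. Exact null distribution for n <= 25 without ties, normal
#' approximation with continuity correction otherwise. The matched
#' rank-biserial correlation is `(W+ - W-) / (W+ + W-)`; its magnitude is
#' reported as the effect size.
#'
#' @param a,b Paired samples (e.g. per-subject multimodal and unimodal
#'   accuracies).
#' @param alternative `"greater"` (a > b), `"two.sided"` or `"less"`.
#' @return list of class `gf_test_result`: test, p_value, effect_size
#'   (magnitude), effect_sign, statistic, alternative, n.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stopf("paired samples differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("all paired differences are zero; effect size undefined")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = TRUE))
  w <- rank_signed(d)
  es <- (w$w_pos - w$w_neg) / (w$w_pos + w$w_neg)
  structure(list(test = "wilcoxon_signed_rank",
                 p_value = unname(ht$p.value),
                 effect_size = abs(es), effect_sign = sign(es),
                 statistic = unname(ht$statistic),
                 alternative = alternative, n = n, exact = exact),
            class = "gf_test_result")
}

#' Mann-Whitney test with rank-biserial effect size
#'
#' Independent two-sample rank test; exact null for small samples without
#' ties, normal approximation with continuity and tie correction otherwise.
#' The rank-biserial correlation is `1 - 2U / (n_a n_b)`; its magnitude is
#' reported.
#'
#' @param group_a,group_b Independent samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list of class `gf_test_result`.
#' @export
mann_whitney <- function(group_a, group_b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b)) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- (length(group_a) + length(group_b)) <= 50L && !ties
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  U <- unname(ht$statistic)
  es <- 1 - 2 * U / (length(group_a) * length(group_b))
  structure(list(test = "mann_whitney",
                 p_value = unname(ht$p.value),
                 effect_size = abs(es), effect_sign = sign(es),
                 statistic = U, alternative = alternative,
                 n = c(n_a = length(group_a), n_b = length(group_b)),
                 exact = exact),
            class = "gf_test_result")
}

#' @export
print.gf_test_result <- function(x, ...) {
  cat(sprintf("%s (%s): p = %.4g, effect size = %.3f (sign %+d), n = %s\n",
              x$test, x$alternative, x$p_value, x$effect_size,
              x$effect_sign, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Four-fold cross-validation of the unimodal and multimodal pipelines
#'
#' For each fold: trains the ConvLSTM on the other three folds (with the
#' one-repetition-per-condition-per-grasp validation split), then evaluates
#' both approaches on the held-out fold's extraction windows
#' (`[onset - 2 s, onset + 3.5 s]`). The scaler and class weights are fit
#' on training data only; an audit log records the trial ids used on each
#' side so leakage is checkable.
#'
#' @param recording A `subject_recording` with gaze and detections.
#' @param mspec A [model_spec()].
#' @param tcfg A [train_config()].
#' @param gcfg A [gaze_config()].
#' @param fcfg A [fusion_config()].
#' @param wspec A [window_spec()].
#' @param seed Base seed for splits and model init.
#' @param folds Folds to run (default all four).
#' @param subject Subject label carried into the results.
#' @param verbose Print fold progress.
#' @return list of class `crossval_result`: fold_results (data.frame with
#'   unimodal/multimodal accuracy per fold), confusions, object_id
#'   (per subject x condition), per_trial traces, audit.
#' @export
crossval_driver <- function(recording, mspec = model_spec(),
                            tcfg = train_config(), gcfg = gaze_config(),
                            fcfg = fusion_config(), wspec = window_spec(),
                            seed = 1L, folds = 1:4, subject = "S1",
                            verbose = FALSE) {
  trials <- recording$trials
  trials$subject <- subject
  rate <- recording$sampling$emg_rate
  pairing <- grasp_object_pairs()
  n_total <- nrow(recording$emg)

  eval_trials <- trials[trials$fold %in% folds, , drop = FALSE]
  timelines <- annotate_stream(recording$gaze, recording$detections, eval_trials,
                               gcfg, video_rate = recording$sampling$video_rate)

  fold_rows <- list(); confusions <- list(); audit <- list()
  all_traces <- list(); trial_rows <- list()

  for (f in folds) {
    train_pool <- trials[trials$fold != f, , drop = FALSE]
    test_trials <- trials[trials$fold == f, , drop = FALSE]
    sp <- split_train_validation(train_pool, derive_seed(seed, paste0("split", f)))
    audit[[as.character(f)]] <- list(
      train = sp$train$trial_id, validation = sp$validation$trial_id,
      test = test_trials$trial_id
    )
    stopifnot(length(intersect(c(sp$train$trial_id, sp$validation$trial_id),
                               test_trials$trial_id)) == 0L)

    scaler <- fit_scaler(lapply(trial_segments(recording, sp$train), `[[`, "signal"))
    build_set <- function(tt) {
      segs <- trial_segments(recording, tt)
      ws <- lapply(segs, function(s) {
        window_segment(transform_emg(s$signal, scaler), s$labels, wspec)
      })
      list(tensor = tensorize(abind_windows(lapply(ws, `[[`, "windows")), wspec),
           labels = unlist(lapply(ws, `[[`, "labels")))
    }
    train_set <- build_set(sp$train)
    val_set <- build_set(sp$validation)
    cw <- compute_class_weights(train_set$labels)
    model <- build_model(mspec, seed = derive_seed(seed, paste0("init", f)))
    fit <- train_model(model, train_set, val_set,
                       config = tcfg_with_seed(tcfg, derive_seed(seed, paste0("train", f))),
                       class_weights = cw, verbose = verbose)
    if (verbose) {
      message(sprintf("fold %d: best val acc %.3f (epoch %d)",
                      f, fit$best_val_accuracy, fit$best_epoch))
    }

    uni_dec <- integer(0); multi_dec <- integer(0); step_lab <- integer(0)
    for (i in seq_len(nrow(test_trials))) {
      tr <- test_trials[i, ]
      a <- max(1L, tr$onset_sample - round(gcfg$pre_window * rate))
      b <- min(n_total, tr$onset_sample + round(gcfg$post_window * rate))
      emg_std <- transform_emg(recording$emg[a:b, , drop = FALSE], scaler)
      ps <- predict_stream(fit$model, emg_std, wspec)
      labs <- stream_labels(recording$emg_labels[a:b], wspec)
      tl <- align_timeline(timelines[[as.character(tr$trial_id)]],
                           emg_rate = rate, start_sample = a)
      trace <- run_fusion(ps, tl, pairing, fcfg)
      uni_dec <- c(uni_dec, trace$unimodal)
      multi_dec <- c(multi_dec, trace$fused)
      step_lab <- c(step_lab, labs)
      all_traces[[as.character(tr$trial_id)]] <- trace
      trial_rows[[as.character(tr$trial_id)]] <- data.frame(
        trial_id = tr$trial_id, subject = subject, fold = f,
        condition = tr$condition, object = tr$object, grasp_id = tr$grasp_id,
        onset_local = tr$onset_sample - a + 1L,
        unimodal_accuracy = accuracy(trace$unimodal, labs),
        multimodal_accuracy = accuracy(trace$fused, labs),
        stringsAsFactors = FALSE
      )
    }
    fold_rows[[as.character(f)]] <- data.frame(
      fold = f,
      unimodal_accuracy = accuracy(uni_dec, step_lab),
      multimodal_accuracy = accuracy(multi_dec, step_lab),
      best_val_accuracy = fit$best_val_accuracy,
      stringsAsFactors = FALSE
    )
    confusions[[as.character(f)]] <- list(
      unimodal = confusion_matrix(uni_dec, step_lab),
      multimodal = confusion_matrix(multi_dec, step_lab)
    )
  }

  per_trial <- do.call(rbind, trial_rows)
  rownames(per_trial) <- NULL
  oid <- object_id_rate(all_traces, per_trial_merge(per_trial))
  structure(list(
    fold_results = do.call(rbind, fold_rows),
    confusions = confusions,
    object_id = oid,
    per_trial = per_trial,
    traces = all_traces,
    audit = audit
  ), class = "crossval_result")
}

per_trial_merge <- function(per_trial) {
  data.frame(trial_id = per_trial$trial_id, subject = per_trial$subject,
             condition = per_trial$condition, object = per_trial$object,
             onset_local = per_trial$onset_local, stringsAsFactors = FALSE)
}

tcfg_with_seed <- function(tcfg, seed) {
  tcfg$seed <- as.integer(seed)
  tcfg
}

abind_windows <- function(window_list) {
  window_list <- Filter(function(w) dim(w)[1] > 0L, window_list)
  if (!length(window_list)) stopf("no windows to bind")
  d <- dim(window_list[[1]])
  n <- sum(vapply(window_list, function(w) dim(w)[1], 1L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (w in window_list) {
    k <- dim(w)[1]
    out[at + seq_len(k), , ] <- w
    at <- at + k
  }
  out
}

#' Compare approaches across a cohort of per-subject results
#'
#' Applies the one-sided Wilcoxon signed-rank test (multimodal better than
#' unimodal) to per-subject mean accuracies, mirroring per-subject
#' averaging of fold results.
#'
#' @param subject_summary data.frame(subject, unimodal, multimodal).
#' @return A `gf_test_result`.
#' @export
cohort_multimodal_test <- function(subject_summary) {
  wilcoxon_signed_rank(subject_summary$multimodal, subject_summary$unimodal,
                       alternative = "greater")
}
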