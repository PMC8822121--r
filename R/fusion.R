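# Multimodal fusion: sEMG-driven intent detection, target-object search on
# the gaze timeline, restricted-argmax grasp selection, rest-triggered reset.

#' Fusion timing configuration
#'
#' @param lookback Lookback for the target-object search, in sEMG samples
#'   (480 samples, about 250 ms at 1926 Hz).
#' @param forward_timeout Forward search timeout after intent detection (s).
#' @param stride Classification stride in sEMG samples.
#' @param emg_rate sEMG sampling rate (Hz).
#' @param rest_debounce Consecutive rest-classified steps required to reset
#'   the state machine; the default 1 resets as soon as a sample is
#'   classified as rest.
#' @return list of class `fusion_config`. `timeout_samples` is the forward
#'   timeout on the sample clock (963 samples = ceil(0.5 s x 1926 Hz)).
#' @export
fusion_config <- function(lookback = 480L, forward_timeout = 0.5,
                          stride = 20L, emg_rate = 1926,
                          rest_debounce = 1L) {
  stopifnot(lookback > 0, forward_timeout > 0, stride > 0, emg_rate > 0,
            rest_debounce >= 1)
  structure(list(lookback = as.integer(lookback),
                 forward_timeout = forward_timeout,
                 stride = as.integer(stride), emg_rate = emg_rate,
                 timeout_samples = as.integer(ceiling(forward_timeout * emg_rate)),
                 rest_debounce = as.integer(rest_debounce)),
            class = "fusion_config")
}

#' Read a fusion configuration from YAML
#'
#' All timing constants are overridable; absent keys keep their defaults.
#' @param path YAML file.
#' @return A [fusion_config()].
#' @export
fusion_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(fusion_config))
  do.call(fusion_config, vals[intersect(names(vals), known)])
}

#' Align a looked-at timeline to a local sEMG sample clock
#'
#' Converts the timeline's absolute timestamps (s) to 1-based sample
#' indices of an sEMG stream starting at absolute sample `start_sample`.
#'
#' @param timeline A `looked_at_timeline` (columns t, looked_at, ...).
#' @param emg_rate sEMG rate (Hz).
#' @param start_sample Absolute 1-based sample index of the stream start.
#' @return data.table with columns `sample` and `looked_at`, time-ordered.
#' @export
align_timeline <- function(timeline, emg_rate = 1926, start_sample = 1L) {
  s <- as.integer(round(timeline$t * emg_rate)) + 1L - (start_sample - 1L)
  data.table::data.table(sample = s, looked_at = timeline$looked_at)[order(sample)]
}

classes_of <- function(prob_seq) as.integer(colnames(prob_seq$probs))

#' Detect grasp-intent events in a posterior sequence
#'
#' An intent event fires at the first step whose argmax is non-rest
#' following a rest-classified step (or the stream start); later non-rest
#' steps of the same episode emit no new event.
#'
#' @param prob_seq A `prob_stream` (probs + emitting sample indices `t`).
#' @return Integer vector of step indices at which intent events occur.
#' @export
detect_intent <- function(prob_seq) {
  if (!nrow(prob_seq$probs)) return(integer(0))
  cls <- classes_of(prob_seq)[row_argmax(prob_seq$probs)]
  nonrest <- cls != REST_ID
  which(nonrest & !c(FALSE, nonrest[-length(nonrest)]))
}

#' Search the gaze timeline for the target object
#'
#' Returns the most recent looked-at object within the `lookback` window
#' `(intent_sample - 480, intent_sample]`; if none, the first looked-at
#' object in the forward window `(intent_sample, intent_sample + 500 ms]`;
#' otherwise none.
#'
#' @param timeline Aligned timeline ([align_timeline()]: columns sample,
#'   looked_at).
#' @param intent_sample sEMG sample index of the intent event.
#' @param config A [fusion_config()].
#' @return list(object = label or NA, found_at = sample at which the
#'   identification becomes available, or NA).
#' @export
find_target_object <- function(timeline, intent_sample, config = fusion_config()) {
  ok <- !is.na(timeline$looked_at)
  back <- ok & timeline$sample > intent_sample - config$lookback &
    timeline$sample <= intent_sample
  if (any(back)) {
    i <- max(which(back))
    return(list(object = timeline$looked_at[i], found_at = intent_sample))
  }
  fwd <- ok & timeline$sample > intent_sample &
    timeline$sample <= intent_sample + config$timeout_samples
  if (any(fwd)) {
    i <- min(which(fwd))
    return(list(object = timeline$looked_at[i],
                found_at = timeline$sample[i]))
  }
  list(object = NA_character_, found_at = NA_integer_)
}

#' Restricted-argmax grasp selection
#'
#' Picks the grasp with the highest classifier probability among only the
#' grasp types paired with the identified object.
#'
#' @param p Named posterior vector (names = class ids, 0 = rest).
#' @param allowed Integer vector of admissible grasp ids (non-empty, rest
#'   excluded).
#' @return The selected grasp id.
#' @export
fuse_decision <- function(p, allowed) {
  allowed <- as.integer(allowed)
  if (!length(allowed)) stopf("empty allowed grasp set")
  if (REST_ID %in% allowed) stopf("rest cannot be in the allowed grasp set")
  sub <- p[as.character(allowed)]
  if (anyNA(sub)) stopf("posterior lacks entries for some allowed grasps")
  allowed[which.max(sub)]
}

#' Run the multimodal fusion state machine
#'
#' Replays a posterior sequence against a looked-at timeline. States:
#' `REST` (output rest), `SEARCHING` (intent detected, object not yet
#' identified; unimodal output), `FUSED` (object identified; restricted
#' argmax), `EMG_ONLY` (no object within the timeout; unimodal output).
#' The machine restarts as soon as a step is classified as rest.
#'
#' @param prob_seq A `prob_stream` over the analyzed sEMG stream.
#' @param timeline Aligned timeline ([align_timeline()]); `NULL` means no
#'   visual information (pure sEMG fallback).
#' @param pairing A `grasp_object_map`.
#' @param config A [fusion_config()].
#' @return `fusion_trace` data.frame: t (sample), unimodal (class id),
#'   fused (class id), state, object (label or NA).
#' @export
run_fusion <- function(prob_seq, timeline, pairing = grasp_object_pairs(),
                       config = fusion_config()) {
  n <- nrow(prob_seq$probs)
  classes <- classes_of(prob_seq)
  cls_u <- classes[row_argmax(prob_seq$probs)]
  tt <- prob_seq$t
  state <- character(n); fused <- integer(n); object <- rep(NA_character_, n)
  if (is.null(timeline)) {
    timeline <- data.table::data.table(sample = integer(0),
                                       looked_at = character(0))
  }
  i <- 1L
  while (i <= n) {
    if (cls_u[i] == REST_ID) {
      state[i] <- "REST"; fused[i] <- REST_ID
      i <- i + 1L
      next
    }
    # episode: maximal run of steps not interrupted by a debounced rest reset
    j <- i
    rest_run <- 0L
    while (j <= n) {
      if (cls_u[j] == REST_ID) {
        rest_run <- rest_run + 1L
        if (rest_run >= config$rest_debounce) {
          j <- j - rest_run
          break
        }
      } else {
        rest_run <- 0L
      }
      j <- j + 1L
    }
    if (j > n) j <- n
    intent_sample <- tt[i]
    hit <- find_target_object(timeline, intent_sample, config)
    allowed <- if (!is.na(hit$object)) {
      grasp_ids_for_object(pairing, hit$object)
    } else {
      integer(0)
    }
    deadline <- intent_sample + config$timeout_samples
    for (k in i:j) {
      if (cls_u[k] == REST_ID) {
        state[k] <- "REST"; fused[k] <- REST_ID
        next
      }
      if (!is.na(hit$object) && tt[k] >= hit$found_at) {
        state[k] <- "FUSED"
        object[k] <- hit$object
        fused[k] <- fuse_decision(prob_seq$probs[k, ], allowed)
      } else if (is.na(hit$object) && tt[k] >= deadline) {
        state[k] <- "EMG_ONLY"
        fused[k] <- cls_u[k]
      } else {
        state[k] <- "SEARCHING"
        fused[k] <- cls_u[k]
      }
    }
    i <- j + 1L
  }
  structure(data.frame(t = tt, unimodal = cls_u, fused = fused,
                       state = state, object = object,
                       stringsAsFactors = FALSE),
            class = c("fusion_trace", "data.frame"))
}

#' Streamed (step-incremental) fusion driver
#'
#' Processes the posterior sequence one step at a time, consuming timeline
#' entries causally. Produces a trace identical to [run_fusion()]; the two
#' drivers cross-check each other.
#'
#' @inheritParams run_fusion
#' @return A `fusion_trace`.
#' @export
run_fusion_stream <- function(prob_seq, timeline,
                              pairing = grasp_object_pairs(),
                              config = fusion_config()) {
  n <- nrow(prob_seq$probs)
  classes <- classes_of(prob_seq)
  tt <- prob_seq$t
  if (is.null(timeline)) {
    timeline <- data.table::data.table(sample = integer(0),
                                       looked_at = character(0))
  }
  state <- "REST"; cur_obj <- NA_character_; allowed <- integer(0)
  intent_sample <- NA_integer_; deadline <- NA_integer_
  rest_run <- 0L
  out_state <- character(n); fused <- integer(n); unimodal <- integer(n)
  object <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    p <- prob_seq$probs[k, ]
    cls <- classes[which.max(p)]
    unimodal[k] <- cls
    if (cls == REST_ID) {
      rest_run <- rest_run + 1L
      if (rest_run >= config$rest_debounce) {
        state <- "REST"; cur_obj <- NA_character_; allowed <- integer(0)
        intent_sample <- NA_integer_
      }
      out_state[k] <- "REST"; fused[k] <- REST_ID
      next
    }
    rest_run <- 0L
    if (state == "REST") {
      intent_sample <- tt[k]
      deadline <- intent_sample + config$timeout_samples
      back <- !is.na(timeline$looked_at) &
        timeline$sample > intent_sample - config$lookback &
        timeline$sample <= intent_sample
      if (any(back)) {
        cur_obj <- timeline$looked_at[max(which(back))]
        allowed <- grasp_ids_for_object(pairing, cur_obj)
        state <- "FUSED"
      } else {
        state <- "SEARCHING"
      }
    }
    if (state == "SEARCHING") {
      cand <- !is.na(timeline$looked_at) &
        timeline$sample > intent_sample &
        timeline$sample <= min(tt[k], deadline)
      if (any(cand)) {
        cur_obj <- timeline$looked_at[min(which(cand))]
        allowed <- grasp_ids_for_object(pairing, cur_obj)
        state <- "FUSED"
      } else if (tt[k] >= deadline) {
        state <- "EMG_ONLY"
      }
    }
    out_state[k] <- state
    object[k] <- if (state == "FUSED") cur_obj else NA_character_
    fused[k] <- if (state == "FUSED") fuse_decision(p, allowed) else cls
  }
  structure(data.frame(t = tt, unimodal = unimodal, fused = fused,
                       state = out_state, object = object,
                       stringsAsFactors = FALSE),
            class = c("fusion_trace", "data.frame"))
}

#' Write a fusion trace as CSV
#' @param trace A `fusion_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace), path)
  invisible(path)
}
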