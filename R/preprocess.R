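# Deterministic sEMG preprocessing: train-set standardization, rectification,
# non-overlapping 200-sample windowing, and subsequence tensorization.

#' Window specification for the classifier input
#'
#' 200-sample non-overlapping windows (slightly more than 100 ms at
#' 1926 Hz), split into 10 subsequences of 1 x 20 x 12, classified every
#' 20 samples (about 10 ms) at inference time.
#'
#' @param window_len Window length in samples.
#' @param n_subseq Number of subsequences per window.
#' @param subseq_cols Columns per subsequence.
#' @param stride_inference Streaming-inference stride in samples.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(window_len = 200L, n_subseq = 10L, subseq_cols = 20L,
                        stride_inference = 20L) {
  if (window_len != n_subseq * subseq_cols) {
    stopf("window_len (%d) must equal n_subseq * subseq_cols (%d)",
          window_len, n_subseq * subseq_cols)
  }
  if (window_len %% stride_inference != 0) {
    stopf("stride_inference must divide window_len")
  }
  structure(list(window_len = as.integer(window_len),
                 n_subseq = as.integer(n_subseq),
                 subseq_cols = as.integer(subseq_cols),
                 stride_inference = as.integer(stride_inference),
                 overlap = 0L),
            class = "window_spec")
}

#' Fit a per-channel standardization scaler on training data
#'
#' Pools all training samples and stores per-channel mean and standard
#' deviation. Applying the scaler removes the mean, makes the variance
#' unitary, and rectifies (absolute value) — fit only on training data so
#' held-out folds never leak into the statistics.
#'
#' @param train_segments A samples x 12 matrix, or a list of such matrices
#'   (or of `list(signal = ...)` segments) that are pooled.
#' @return Object of class `emg_scaler` with `mean` and `sd` 12-vectors.
#' @export
fit_scaler <- function(train_segments) {
  x <- pool_segments(train_segments)
  if (!nrow(x)) stopf("no training samples to fit scaler on")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    stopf("constant channel(s) in training data: %s", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv, n = nrow(x), fitted = TRUE),
            class = "emg_scaler")
}

pool_segments <- function(segments) {
  if (is.matrix(segments)) return(segments)
  mats <- lapply(segments, function(s) if (is.list(s)) s$signal else s)
  do.call(rbind, mats)
}

#' Standardize and rectify an sEMG segment
#'
#' Elementwise `|(x - mean) / sd|` with the scaler's training statistics;
#' all outputs are nonnegative.
#'
#' @param segment samples x 12 matrix.
#' @param scaler A fitted [fit_scaler()] object.
#' @return Matrix of the same shape.
#' @export
transform_emg <- function(segment, scaler) {
  if (!inherits(scaler, "emg_scaler") || !isTRUE(scaler$fitted)) {
    stopf("scaler is not fitted")
  }
  if (ncol(segment) != length(scaler$mean)) {
    stopf("segment has %d channels; scaler was fit on %d",
          ncol(segment), length(scaler$mean))
  }
  abs(sweep(sweep(segment, 2, scaler$mean, "-"), 2, scaler$sd, "/"))
}

#' Cut a labelled segment into non-overlapping windows
#'
#' Produces `floor(L / window_len)` windows; the trailing remainder is
#' dropped. Each window's label is the majority per-sample label within it,
#' with ties broken toward rest (conservative for intent detection).
#'
#' @param segment samples x 12 matrix (already transformed or raw).
#' @param labels Integer per-sample labels (0 = rest); `NULL` for unlabelled.
#' @param spec A [window_spec()].
#' @return list(windows = N x window_len x 12 array, labels = integer N,
#'   end_sample = integer N of 1-based window end indices).
#' @export
window_segment <- function(segment, labels = NULL, spec = window_spec()) {
  L <- nrow(segment)
  wl <- spec$window_len
  n_win <- L %/% wl
  if (n_win == 0L) {
    warning(sprintf("segment of %d samples shorter than one %d-sample window", L, wl))
    return(list(windows = array(0, c(0L, wl, ncol(segment))),
                labels = integer(0), end_sample = integer(0)))
  }
  used <- segment[seq_len(n_win * wl), , drop = FALSE]
  # N x wl x 12; sample index fastest within window
  windows <- aperm(array(used, c(wl, n_win, ncol(segment))), c(2, 1, 3))
  win_labels <- integer(0)
  if (!is.null(labels)) {
    win_labels <- vapply(seq_len(n_win), function(w) {
      majority_label(labels[((w - 1L) * wl + 1L):(w * wl)])
    }, integer(1))
  }
  list(windows = windows, labels = win_labels,
       end_sample = seq_len(n_win) * wl)
}

majority_label <- function(lab) {
  tab <- table(lab)
  top <- max(tab)
  winners <- as.integer(names(tab)[tab == top])
  if (length(winners) > 1L && REST_ID %in% winners) return(REST_ID)
  winners[1L]
}

#' Tensorize windows into the classifier input layout
#'
#' Each 200 x 12 window is divided into 10 subsequences of 1 row x 20
#' columns x 12 channels: output shape N x 10 x 1 x 20 x 12, where element
#' (n, s, 1, c, e) holds window sample (20 (s-1) + c, e).
#'
#' @param windows N x 200 x 12 array (from [window_segment()]).
#' @param spec A [window_spec()].
#' @return 5-d array N x n_subseq x 1 x subseq_cols x 12.
#' @export
tensorize <- function(windows, spec = window_spec()) {
  d <- dim(windows)
  if (length(d) != 3L || d[2] != spec$window_len) {
    stopf("windows must be N x %d x channels", spec$window_len)
  }
  n <- d[1]; ch <- d[3]
  # window axis order: (n, sample, e) with sample = 20 (s-1) + c
  # -> (n, c, s, e) then reorder to (n, s, 1, c, e)
  x <- array(windows, c(n, spec$subseq_cols, spec$n_subseq, ch))
  out <- aperm(x, c(1, 3, 2, 4))
  dim(out) <- c(n, spec$n_subseq, 1L, spec$subseq_cols, ch)
  out
}

#' Invert [tensorize()]
#'
#' @param tensor N x 10 x 1 x 20 x 12 array.
#' @param spec A [window_spec()].
#' @return N x 200 x 12 array of the original windows.
#' @export
untensorize <- function(tensor, spec = window_spec()) {
  d <- dim(tensor)
  if (length(d) != 5L || d[3] != 1L) stopf("malformed tensor")
  x <- tensor
  dim(x) <- c(d[1], d[2], d[4], d[5])      # (n, s, c, e)
  x <- aperm(x, c(1, 3, 2, 4))             # (n, c, s, e)
  dim(x) <- c(d[1], d[2] * d[4], d[5])
  x
}
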