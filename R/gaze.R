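# Gaze-to-object association: detection filtering, point-to-contour
# distance, looked-at labelling, and extraction-window annotation.

#' Gaze association configuration
#'
#' @param score_min Detection score threshold; instances scoring strictly
#'   below it are discarded (a score of exactly `score_min` is kept).
#' @param distance_max Gaze-to-contour threshold in px; an object is looked
#'   at when the distance is strictly below it.
#' @param pre_window,post_window Extraction window around grasp onset (s).
#' @param inside_zero If `TRUE` (default), a gaze point inside a contour has
#'   distance 0; if `FALSE`, distance to the boundary polyline is used even
#'   from inside.
#' @return list of class `gaze_config`.
#' @export
gaze_config <- function(score_min = 0.8, distance_max = 20,
                        pre_window = 2.0, post_window = 3.5,
                        inside_zero = TRUE) {
  stopifnot(score_min > 0, distance_max > 0, pre_window > 0, post_window > 0)
  structure(list(score_min = score_min, distance_max = distance_max,
                 pre_window = pre_window, post_window = post_window,
                 inside_zero = isTRUE(inside_zero)),
            class = "gaze_config")
}

#' Filter detection instances
#'
#' Keeps instances with score >= `score_min` whose label is neither
#' `"person"` nor `"background"`.
#'
#' @param frame data.table/data.frame of instances with columns `label`,
#'   `score` (and typically `frame_index`, `polygon`); one frame or many.
#' @param config A [gaze_config()].
#' @return The filtered table.
#' @export
filter_instances <- function(frame, config = gaze_config()) {
  if (!nrow(frame)) return(frame)
  keep <- frame$score >= config$score_min &
    !(tolower(frame$label) %in% non_graspable_classes())
  frame[keep, , drop = FALSE]
}

#' Euclidean distance from a point to a polygon contour
#'
#' Minimal distance from `(x, y)` to the polygon boundary (closed
#' polyline). Under the default inside-is-zero rule, points inside the
#' polygon return 0.
#'
#' @param x,y Point coordinates (px, origin top-left, y down).
#' @param contour V x 2 matrix of vertices (V >= 3), implicitly closed.
#' @param inside_zero Treat interior points as distance 0.
#' @return Distance in px.
#' @export
point_contour_distance <- function(x, y, contour, inside_zero = TRUE) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L || !all(is.finite(contour))) {
    stopf("degenerate polygon: need >= 3 finite vertices")
  }
  if (inside_zero && point_in_polygon(x, y, contour)) return(0)
  x1 <- contour[, 1]; y1 <- contour[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- ((x - x1) * dx + (y - y1) * dy) / pmax(len2, .Machine$double.eps)
  tt <- pmin(pmax(tt, 0), 1)
  px <- x1 + tt * dx; py <- y1 + tt * dy
  sqrt(min((x - px)^2 + (y - py)^2))
}

# Even-odd ray casting; boundary points may land either way but the
# segment-distance term is 0 there anyway.
point_in_polygon <- function(x, y, contour) {
  xv <- contour[, 1]; yv <- contour[, 2]
  n <- length(xv)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((yv > y) != (yv[j] > y)) &
    (x < (xv[j] - xv) * (y - yv) / (yv[j] - yv) + xv)
  sum(crosses) %% 2L == 1L
}

#' Identify the object a gaze sample is looking at
#'
#' Among the score-filtered, non-person/background instances of the frame,
#' returns the label whose contour is nearest to the gaze point if that
#' distance is strictly below `distance_max`; `NA` otherwise, for invalid
#' gaze samples, and when the frame has no accepted instance. Equidistant
#' instances are broken deterministically by lower instance index.
#'
#' @param sample list or one-row data.frame with `x`, `y`, `valid`.
#' @param frame Instance table of one frame (columns label, score, polygon).
#' @param config A [gaze_config()].
#' @return list(label = character or NA, distance = px or NA).
#' @export
looked_at_object <- function(sample, frame, config = gaze_config()) {
  none <- list(label = NA_character_, distance = NA_real_)
  if (!isTRUE(as.logical(sample$valid))) return(none)
  inst <- filter_instances(frame, config)
  if (!nrow(inst)) return(none)
  d <- vapply(seq_len(nrow(inst)), function(i) {
    point_contour_distance(sample$x, sample$y, inst$polygon[[i]],
                           inside_zero = config$inside_zero)
  }, numeric(1))
  best <- which.min(d)  # first minimum = lowest instance index
  if (d[best] < config$distance_max) {
    list(label = inst$label[best], distance = d[best])
  } else {
    none
  }
}

#' Annotate gaze with looked-at objects over each trial's extraction window
#'
#' For every trial, gaze samples at their native rate within
#' `[onset - pre_window, onset + post_window]` are mapped to the video
#' frame whose interval contains their timestamp (floor to the last started
#' frame) and labelled with the looked-at object.
#'
#' @param gaze data.table with columns `t`, `x`, `y`, `valid`.
#' @param detections Instance table (frame_index, timestamp, inst_id,
#'   label, score, polygon).
#' @param trials Trial table with `onset_s` (and `trial_id`).
#' @param config A [gaze_config()].
#' @param video_rate Video frame rate (FPS).
#' @return Named list (by trial_id) of `looked_at_timeline` data.tables:
#'   columns t, looked_at (NA = none), distance_px, frame_index,
#'   valid_instance.
#' @export
annotate_stream <- function(gaze, detections, trials, config = gaze_config(),
                            video_rate = 25) {
  frame_split <- if (nrow(detections)) {
    split(seq_len(nrow(detections)), detections$frame_index)
  } else {
    list()
  }
  out <- vector("list", nrow(trials))
  names(out) <- as.character(trials$trial_id)
  for (i in seq_len(nrow(trials))) {
    a <- trials$onset_s[i] - config$pre_window
    b <- trials$onset_s[i] + config$post_window
    idx <- which(gaze$t >= a & gaze$t <= b)
    if (!length(idx)) {
      warning(sprintf("trial %s: extraction window outside recording",
                      names(out)[i]))
    }
    g <- gaze[idx, ]
    n <- nrow(g)
    looked <- rep(NA_character_, n)
    dist <- rep(NA_real_, n)
    fidx <- as.integer(floor(g$t * video_rate))
    valid_inst <- rep(FALSE, n)
    for (k in seq_len(n)) {
      rows <- frame_split[[as.character(fidx[k])]]
      if (is.null(rows)) next
      frame <- detections[rows, ]
      res <- looked_at_object(list(x = g$x[k], y = g$y[k], valid = g$valid[k]),
                              frame, config)
      valid_inst[k] <- isTRUE(as.logical(g$valid[k])) &&
        nrow(filter_instances(frame, config)) > 0L
      looked[k] <- res$label
      dist[k] <- res$distance
    }
    tl <- data.table::data.table(t = g$t, looked_at = looked,
                                 distance_px = dist, frame_index = fidx,
                                 valid_instance = valid_inst)
    data.table::setattr(tl, "class", c("looked_at_timeline", class(tl)))
    out[[i]] <- tl
  }
  out
}
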