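# Acquisition-protocol structure: grasp taxonomy, object catalog,
# grasp-object pairing, fold partitioning and train/validation splitting.

#' Grasp taxonomy
#'
#' The ten canonical grasp types of the grasping protocol plus the rest
#' class. The rest class has id 0 and is distinct from every grasp.
#'
#' @return A data.frame with columns `id` (integer, 0 for rest, 1-10 for
#'   grasps) and `name` (lowercase canonical label).
#' @export
#' @examples
#' grasp_taxonomy()
grasp_taxonomy <- function() {
  map <- grasp_object_pairs()
  data.frame(
    id = c(REST_ID, map$grasps$id),
    name = c(REST_NAME, map$grasps$name),
    stringsAsFactors = FALSE
  )
}

#' Object catalog
#'
#' The 18 graspable household object classes of the protocol. The detector
#' additionally emits the reserved non-graspable labels `"person"` and
#' `"background"`, which never enter the grasp-object pairing.
#'
#' @return Character vector of 18 lowercase object class names.
#' @export
object_classes <- function() {
  grasp_object_pairs()$objects
}

#' Reserved non-graspable detector labels
#' @return Character vector `c("person", "background")`.
#' @export
non_graspable_classes <- function() {
  c("person", "background")
}

#' Grasp-object pairing table
#'
#' Loads the protocol's pairing between grasp types and household objects.
#' Every grasp is paired with exactly three objects and every object with at
#' least one grasp, so a lookup by object always returns a non-empty set of
#' admissible grasps.
#'
#' @return An object of class `grasp_object_map` with elements
#'   `grasps` (data.frame: id, name, and a list-column `objects`),
#'   `pairs` (data.frame: grasp_id, grasp, object) and
#'   `objects` (character vector of the 18 graspable classes).
#' @export
#' @examples
#' map <- grasp_object_pairs()
#' grasps_for_object(map, "bottle")
grasp_object_pairs <- function() {
  cached <- .pairing_cache$map
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "grasp_object_pairs.json",
                      package = "graspfusion", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  grasps <- data.frame(
    id = as.integer(raw$grasps$id),
    name = tolower(raw$grasps$name),
    stringsAsFactors = FALSE
  )
  grasps$objects <- lapply(raw$grasps$objects, tolower)
  pairs <- do.call(rbind, lapply(seq_len(nrow(grasps)), function(i) {
    data.frame(
      grasp_id = grasps$id[i],
      grasp = grasps$name[i],
      object = grasps$objects[[i]],
      stringsAsFactors = FALSE
    )
  }))
  stopifnot(
    nrow(grasps) == 10L,
    !anyDuplicated(grasps$id),
    all(vapply(grasps$objects, length, 1L) == 3L)
  )
  objects <- sort(unique(pairs$object))
  if (any(objects %in% non_graspable_classes())) {
    stopf("pairing table contains a non-graspable class")
  }
  map <- structure(
    list(grasps = grasps, pairs = pairs, objects = objects,
         non_graspable = tolower(raw$non_graspable)),
    class = "grasp_object_map"
  )
  .pairing_cache$map <- map
  map
}

.pairing_cache <- new.env(parent = emptyenv())

#' @export
print.grasp_object_map <- function(x, ...) {
  cat(sprintf("grasp_object_map: %d grasp types, %d objects, %d pairs\n",
              nrow(x$grasps), length(x$objects), nrow(x$pairs)))
  invisible(x)
}

#' Admissible grasps for an object
#'
#' @param map A `grasp_object_map`.
#' @param object Object class name (lowercase).
#' @return Character vector of grasp names paired with `object` (non-empty
#'   for every graspable class), in taxonomy order.
#' @export
grasps_for_object <- function(map, object) {
  stopifnot(inherits(map, "grasp_object_map"))
  object <- tolower(object)
  if (object %in% map$non_graspable) {
    stopf("'%s' is a non-graspable class and has no paired grasps", object)
  }
  if (!object %in% map$objects) {
    stopf("unknown object class '%s'", object)
  }
  map$pairs$grasp[map$pairs$object == object]
}

#' Grasp ids admissible for an object
#' @inheritParams grasps_for_object
#' @return Integer vector of grasp ids.
#' @export
grasp_ids_for_object <- function(map, object) {
  object <- tolower(object)
  map$pairs$grasp_id[map$pairs$object == object]
}

#' Objects paired with a grasp
#'
#' @param map A `grasp_object_map`.
#' @param grasp Grasp name or id.
#' @return Character vector of the three paired object classes.
#' @export
objects_for_grasp <- function(map, grasp) {
  stopifnot(inherits(map, "grasp_object_map"))
  if (is.numeric(grasp)) {
    idx <- match(as.integer(grasp), map$grasps$id)
  } else {
    idx <- match(tolower(grasp), map$grasps$name)
  }
  if (is.na(idx)) stopf("unknown grasp '%s'", as.character(grasp))
  map$grasps$objects[[idx]]
}

PROTOCOL_CONDITIONS <- c("static_seated", "static_standing", "dynamic")

# Repetitions per (grasp, condition) over the whole protocol and per fold.
REPS_PER_CONDITION <- c(static_seated = 12L, static_standing = 12L, dynamic = 8L)
REPS_PER_FOLD <- c(static_seated = 3L, static_standing = 3L, dynamic = 2L)
N_FOLDS <- 4L

#' Enumerate the trials of the grasping protocol
#'
#' Builds the full trial table: per grasp, 12 static-seated and 12
#' static-standing repetitions cycling through the grasp's three paired
#' objects, and 8 dynamic repetitions cycling through the first two paired
#' objects. 32 repetitions per grasp in total (320 trials for the full
#' ten-grasp protocol).
#'
#' @param map A `grasp_object_map`.
#' @param grasps Optional integer vector of grasp ids to restrict the
#'   protocol to (a miniature protocol keeps the full per-grasp repetition
#'   structure); default all ten.
#' @return data.frame with columns trial_id, grasp_id, grasp, object,
#'   condition, repetition (1-based within grasp x condition).
#' @export
protocol_trials <- function(map = grasp_object_pairs(), grasps = NULL) {
  ids <- grasps %||% map$grasps$id
  ids <- as.integer(ids)
  if (!all(ids %in% map$grasps$id)) stopf("unknown grasp id in 'grasps'")
  rows <- list()
  for (g in ids) {
    objs <- objects_for_grasp(map, g)
    for (cond in PROTOCOL_CONDITIONS) {
      n_rep <- REPS_PER_CONDITION[[cond]]
      n_obj <- if (cond == "dynamic") 2L else 3L
      rep_idx <- seq_len(n_rep)
      rows[[length(rows) + 1L]] <- data.frame(
        grasp_id = g,
        grasp = map$grasps$name[match(g, map$grasps$id)],
        object = objs[((rep_idx - 1L) %% n_obj) + 1L],
        condition = cond,
        repetition = rep_idx,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Partition protocol trials into four folds
#'
#' Assigns every repetition to one of four disjoint folds so that each fold
#' holds, per grasp, 3 static-seated, 3 static-standing and 2 dynamic
#' repetitions performed on distinct objects. The assignment is
#' deterministic: within each (grasp, condition, object) cell, repetitions
#' ordered by repetition index go to folds 1, 2, 3, 4 in turn.
#'
#' @param trials Trial table as produced by [protocol_trials()] (extra
#'   columns are carried through).
#' @return The trial table with an integer `fold` column, of class
#'   `fold_partition`.
#' @export
build_fold_partition <- function(trials) {
  required <- c("grasp_id", "object", "condition", "repetition")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stopf("trials table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  # Structural completeness: every (grasp, condition) cell at full count.
  for (g in unique(trials$grasp_id)) {
    for (cond in PROTOCOL_CONDITIONS) {
      n <- sum(trials$grasp_id == g & trials$condition == cond)
      if (n != REPS_PER_CONDITION[[cond]]) {
        stopf("incomplete protocol: grasp %d, condition '%s' has %d repetitions (expected %d)",
              g, cond, n, REPS_PER_CONDITION[[cond]])
      }
    }
  }
  trials$fold <- NA_integer_
  key <- interaction(trials$grasp_id, trials$condition, trials$object, drop = TRUE)
  for (cell in levels(key)) {
    idx <- which(key == cell)
    idx <- idx[order(trials$repetition[idx])]
    if (length(idx) != N_FOLDS) {
      stopf("cell %s has %d repetitions; expected one per fold", cell, length(idx))
    }
    trials$fold[idx] <- seq_len(N_FOLDS)
  }
  class(trials) <- c("fold_partition", class(trials))
  trials
}

#' Split a training pool into training and validation repetitions
#'
#' From a three-fold training pool, draws uniformly at random one repetition
#' per (condition x grasp) cell into the validation set; the remainder is
#' the training set. For the full protocol this yields the 210/30 split.
#'
#' @param training_trials Trial table (three folds of a partition).
#' @param seed Integer seed; the split is reproducible under it.
#' @return list(train = ..., validation = ...) of trial tables.
#' @export
split_train_validation <- function(training_trials, seed) {
  grasps <- unique(training_trials$grasp_id)
  val_rows <- integer(0)
  with_seed(seed, {
    for (g in sort(grasps)) {
      for (cond in PROTOCOL_CONDITIONS) {
        idx <- which(training_trials$grasp_id == g & training_trials$condition == cond)
        if (!length(idx)) {
          stopf("no repetitions for grasp %d, condition '%s' in training pool", g, cond)
        }
        val_rows <- c(val_rows, idx[sample.int(length(idx), 1L)])
      }
    }
  })
  list(
    train = training_trials[-val_rows, , drop = FALSE],
    validation = training_trials[val_rows, , drop = FALSE]
  )
}

#' Write / read a trial metadata table
#'
#' CSV interface with columns subject, grasp, object, condition, repetition,
#' fold, onset_sample (plus any extra columns present).
#'
#' @param trials Trial table.
#' @param path CSV file path.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(as.data.frame(trials), path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("trials file not found: %s", path)
  as.data.frame(data.table::fread(path))
}
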