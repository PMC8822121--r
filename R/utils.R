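# Internal helpers shared across modules.

.datatable.aware <- TRUE

REST_ID <- 0L
REST_NAME <- "rest"

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stream label; keeps every
# stream independent while staying inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483562
  as.integer(h + 1L)
}

row_argmax <- function(p) {
  max.col(p, ties.method = "first")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
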