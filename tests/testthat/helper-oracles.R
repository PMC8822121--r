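# Independent oracles used to cross-check the implementation.

# Brute-force point-to-contour distance by dense boundary sampling.
oracle_contour_distance <- function(x, y, poly, step = 0.05) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = k)
    px <- a[1] + tt * (b[1] - a[1]); py <- a[2] + tt * (b[2] - a[2])
    dmin <- min(dmin, sqrt(min((x - px)^2 + (y - py)^2)))
  }
  dmin
}

# Exhaustive sign-flip null for the Wilcoxon signed-rank statistic,
# reproducing the exact two-sided/one-sided p-value conventions of the
# signed-rank distribution (no zeros, no ties assumed).
oracle_wilcoxon_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  p_le <- mean(w <= obs); p_ge <- mean(w >= obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, if (obs > n * (n + 1) / 4) 2 * p_ge else 2 * p_le)
  )
}

# Exhaustive relabeling null for the Mann-Whitney U statistic (no ties).
oracle_mann_whitney_p <- function(a, b, alternative) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_stat <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    sum(outer(av, bv, ">"))
  }
  obs <- u_stat(seq_len(m))
  combs <- utils::combn(m + n, m)
  u <- apply(combs, 2, u_stat)
  p_le <- mean(u <= obs); p_ge <- mean(u >= obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, if (obs > m * n / 2) 2 * p_ge else 2 * p_le)
  )
}

# Build a posterior stream with a prescribed argmax sequence.
make_prob_stream <- function(argmax_ids, classes = 0:10, peak = 0.6,
                             t = NULL, prob_rows = NULL) {
  n <- length(argmax_ids)
  if (is.null(prob_rows)) {
    probs <- matrix((1 - peak) / (length(classes) - 1), n, length(classes))
    probs[cbind(seq_len(n), match(argmax_ids, classes))] <- peak
  } else {
    probs <- prob_rows
  }
  colnames(probs) <- classes
  structure(list(probs = probs,
                 t = t %||% (200L + 20L * (seq_len(n) - 1L))),
            class = "prob_stream")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
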