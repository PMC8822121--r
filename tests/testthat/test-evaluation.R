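test_that("accuracy and confusion matrices are consistent", {
  expect_equal(accuracy(c(1L, 2L, 3L), c(1L, 2L, 3L)), 100)
  expect_equal(accuracy(c(rep(1L, 7), rep(2L, 3)), rep(1L, 10)), 70)
  expect_error(accuracy(1:3, 1:4), "differ in length")

  set.seed(8)
  dec <- sample(0:10, 500, replace = TRUE)
  lab <- sample(0:10, 500, replace = TRUE)
  cm <- confusion_matrix(dec, lab)
  expect_equal(dim(cm), c(11L, 11L))
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(lab, levels = 0:10)))))
  expect_equal(100 * sum(diag(cm)) / sum(cm), accuracy(dec, lab))
})

test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    a <- rnorm(n); b <- a + rnorm(n, mean = 0.3)
    for (alt in c("greater", "less", "two.sided")) {
      got <- wilcoxon_signed_rank(b, a, alternative = alt)
      ref <- oracle_wilcoxon_p(b - a, alt)
      expect_lt(abs(got$p_value - ref), 1e-9)
      expect_lte(abs(got$effect_size), 1)
    }
  }

  # one-signed differences -> effect size magnitude 1, tiny one-sided p
  a <- c(1, 2, 3, 4, 5, 6)
  shift <- seq(0.5, 1.0, by = 0.1)   # distinct, so the null stays exact
  res <- wilcoxon_signed_rank(a + shift, a, alternative = "greater")
  expect_equal(res$effect_size, 1)
  expect_equal(res$p_value, 1 / 2^6, tolerance = 1e-12)

  # reversed direction under the greater alternative
  rev <- wilcoxon_signed_rank(a, a + shift, alternative = "greater")
  expect_gte(rev$p_value, 0.5)

  # zero differences are dropped; all-zero is an error
  mixed <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6.5), c(1, 2, 3, 4, 5, 6),
                                alternative = "greater")
  expect_equal(mixed$n, 1L)
  expect_error(wilcoxon_signed_rank(a, a), "all paired differences")
})

test_that("Mann-Whitney matches exhaustive relabeling enumeration", {
  set.seed(99)
  for (rep in 1:6) {
    a <- rnorm(4); b <- rnorm(4, mean = 1)
    for (alt in c("two.sided", "greater", "less")) {
      got <- mann_whitney(a, b, alternative = alt)
      ref <- oracle_mann_whitney_p(a, b, alt)
      expect_lt(abs(got$p_value - ref), 1e-9)
    }
  }

  # identical groups -> effect size 0; fully separated -> magnitude 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$effect_size, 0)
  sep <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$effect_size, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("object identification rate matches a hand-counted oracle", {
  # three trials: correct, wrong object, never fused
  mk_trace <- function(states, objects, t0 = 200L) {
    structure(data.frame(t = t0 + 20L * (seq_along(states) - 1L),
                         unimodal = ifelse(states == "REST", 0L, 8L),
                         fused = ifelse(states == "REST", 0L, 8L),
                         state = states, object = objects,
                         stringsAsFactors = FALSE),
              class = c("fusion_trace", "data.frame"))
  }
  traces <- list(
    "1" = mk_trace(c("REST", "FUSED", "FUSED"), c(NA, "remote", "remote")),
    "2" = mk_trace(c("REST", "FUSED", "FUSED"), c(NA, "knife", "knife")),
    "3" = mk_trace(c("REST", "SEARCHING", "EMG_ONLY"), c(NA, NA, NA))
  )
  trials <- data.frame(trial_id = 1:3, subject = "S1",
                       condition = c("static_seated", "static_standing", "dynamic"),
                       object = c("remote", "remote", "remote"),
                       onset_local = c(210L, 210L, 210L),
                       stringsAsFactors = FALSE)
  oid <- object_id_rate(traces, trials)
  static <- oid$rate[oid$condition == "static"]
  dynamic <- oid$rate[oid$condition == "dynamic"]
  expect_equal(static, 50)   # 1 of 2 static trials correct
  expect_equal(dynamic, 0)   # never fused counts as incorrect
  per_trial <- attr(oid, "per_trial")
  expect_equal(per_trial$correct, c(TRUE, FALSE, FALSE))
})

test_that("cohort comparison favours the multimodal approach when it dominates", {
  summary <- data.frame(subject = paste0("S", 1:6),
                        unimodal = c(60, 62, 59, 65, 63, 61),
                        multimodal = c(71, 70, 68, 74, 72, 70))
  res <- cohort_multimodal_test(summary)
  expect_equal(res$effect_size, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("the four-fold driver runs end to end on a miniature protocol without leakage", {
  cfg <- mini_config("clean", rest_range = c(1, 1.2), grasp_range = c(1.5, 1.7),
                     seed = 23L)
  rec <- generate_subject(cfg)
  cv <- crossval_driver(rec, mspec = model_spec(filters = 6L),
                        tcfg = train_config(epochs = 2L), seed = 9L)

  # four train/evaluate cycles
  expect_equal(cv$fold_results$fold, 1:4)
  expect_true(all(cv$fold_results$unimodal_accuracy >= 0 &
                    cv$fold_results$unimodal_accuracy <= 100))

  # audit: held-out trials never appear in training or validation
  for (f in 1:4) {
    au <- cv$audit[[as.character(f)]]
    expect_length(intersect(c(au$train, au$validation), au$test), 0L)
    expect_length(intersect(au$train, au$validation), 0L)
    expect_setequal(au$test, rec$trials$trial_id[rec$trials$fold == f])
  }

  # per-subject mean equals the mean of the four fold accuracies
  expect_equal(mean(cv$fold_results$multimodal_accuracy),
               sum(cv$fold_results$multimodal_accuracy) / 4)

  # every trial of the protocol was evaluated exactly once
  expect_setequal(cv$per_trial$trial_id, rec$trials$trial_id)

  # fused decisions in FUSED states respect the pairing (restriction soundness)
  map <- grasp_object_pairs()
  for (id in names(cv$traces)) {
    tr <- cv$traces[[id]]
    at <- which(tr$state == "FUSED")
    if (length(at)) {
      ok <- vapply(at, function(k) {
        tr$fused[k] %in% grasp_ids_for_object(map, tr$object[k])
      }, logical(1))
      expect_true(all(ok))
    }
  }
})
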