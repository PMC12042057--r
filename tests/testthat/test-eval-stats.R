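test_that("confusion metrics match hand arithmetic and flag undefined ratios", {
  expect_equal(confusion_metrics(confusion_counts(3, 0, 0, 1))[["sensitivity"]],
               75)
  m <- confusion_metrics(confusion_counts(5, 0, 5, 0))
  expect_true(all(m == 100))
  m2 <- confusion_metrics(confusion_counts(TP = 14, FN = 1, TN = 16, FP = 13))
  expect_equal(round(m2[["sensitivity"]], 1), 93.3)
  expect_equal(round(m2[["specificity"]], 1), 55.2)
  expect_equal(round(m2[["accuracy"]], 1), 68.2)
  no_pos <- confusion_metrics(confusion_counts(0, 0, 10, 0))
  expect_true(is.na(no_pos[["sensitivity"]]))
  expect_true(is.na(no_pos[["precision"]]))
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  set.seed(3)
  for (i in 1:20) {
    cts <- confusion_counts(sample(0:30, 1) + 1, sample(0:30, 1),
                            sample(0:30, 1) + 1, sample(0:30, 1))
    m <- confusion_metrics(cts)
    P <- cts$TP + cts$FN; N <- cts$TN + cts$FP
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("Wald intervals reproduce hand arithmetic and cap to [0, 100]", {
  ci <- normal_ci(0.9333, 50)
  expect_equal(round_ref(ci$lower), 86.4)
  expect_equal(ci$upper, 100)

  ci2 <- normal_ci(0.714, 148)
  expect_equal(round_ref(ci2$lower), 64.1)
  expect_equal(round_ref(ci2$upper), 78.7)

  ci3 <- normal_ci(0.5, 100)
  expect_equal(round_ref(ci3$lower), 40.2)
  expect_equal(round_ref(ci3$upper), 59.8)

  expect_equal(normal_ci(0, 5)$lower, 0)
  expect_equal(normal_ci(1, 5)$upper, 100)
  expect_error(normal_ci(1.5, 10), "p_hat")
  expect_error(normal_ci(0.5, 0), "n must")
})

test_that("CI width shrinks monotonically with n and vanishes asymptotically", {
  widths <- vapply(c(10, 50, 200, 1000, 1e5), function(n) {
    ci <- normal_ci(0.3, n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[length(widths)], 0.6)
})

test_that("AUROC equals all-pairs concordance including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auroc(scores, labels), pairwise_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("selection precision counts valid selected frames with its CI", {
  truth <- data.frame(video_id = rep("V1", 10), frame_index = 0:9,
                      validity = c(rep("valid", 9), "invalid"))
  sel <- data.frame(video_id = rep("V1", 10), frame_index = 0:9)
  ci <- selection_precision(sel, truth)
  expect_equal(ci$estimate, 90)
  expect_identical(ci$n, 10L)

  all_valid <- selection_precision(sel[1:9, ], truth)
  expect_equal(all_valid$estimate, 100)
  expect_equal(all_valid$upper, 100)

  none <- selection_precision(sel[10, , drop = FALSE], truth)
  expect_equal(none$estimate, 0)
  expect_equal(none$lower, 0)

  expect_error(selection_precision(sel[0, ], truth), "non-empty")
  bad <- data.frame(video_id = "V2", frame_index = 0L)
  expect_error(selection_precision(bad, truth), "truth row")
})

test_that("stratified splits reproduce the rounding convention and stay disjoint", {
  ids <- seq_len(2227)
  sp <- stratified_split(ids, rep("all", 2227), c(0.747, 0.122, 0.131),
                         seed = 1)
  expect_identical(as.integer(table(sp$split)), c(1664L, 272L, 291L))

  all_train <- stratified_split(1:50, rep("s", 50), c(1, 0, 0))
  expect_true(all(all_train$split == "train"))

  two <- stratified_split(1:200, rep(c("a", "b"), each = 100),
                          c(0.8, 0.1, 0.1), seed = 2)
  tab <- table(two$stratum, two$split)
  expect_true(all(tab == 10 | tab == 80))

  # partition property
  expect_identical(sort(two$id), 1:200)
  expect_false(anyNA(two$split))
  # deterministic per seed
  expect_identical(stratified_split(1:200, rep(c("a", "b"), each = 100),
                                    c(0.8, 0.1, 0.1), seed = 2), two)

  expect_warning(tiny <- stratified_split(1:2, c("s", "s"), c(0.5, 0.25, 0.25)),
                 "fewer")
  expect_true(all(tiny$split == "train"))
  expect_error(stratified_split(1:4, rep("s", 4), c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("patient-grouped splits never split a patient", {
  pid <- rep(sprintf("P%02d", 1:30), each = 4)
  strata <- rep(rep(c("pos", "neg"), 15), each = 4)
  sp <- stratified_split(seq_along(pid), strata, c(0.6, 0.2, 0.2), seed = 4,
                         group = pid)
  per_patient <- tapply(as.character(sp$split), pid,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("decision evaluation excludes indeterminates and reports CIs", {
  dec <- data.frame(patient_id = sprintf("P%d", 1:6),
                    decision = c("ROP-positive", "ROP-negative",
                                 "indeterminate", "ROP-positive",
                                 "ROP-negative", "ROP-positive"))
  gold <- data.frame(patient_id = sprintf("P%d", 1:6),
                     rop_status = c(1, 0, 1, 0, 1, 1))
  ev <- evaluate_decisions(dec, gold)
  expect_identical(ev$n_indeterminate, 1L)
  expect_identical(ev$counts$TP, 2L)
  expect_identical(ev$counts$FP, 1L)
  expect_identical(ev$counts$FN, 1L)
  expect_identical(ev$ci$sensitivity$n, 5L)
  ev2 <- evaluate_decisions(dec, gold, ci_n_mode = "denominator")
  expect_identical(ev2$ci$sensitivity$n, 3L)
})
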