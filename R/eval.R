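#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative counts, total >= 1.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != floor(v))) stopf("counts must be non-negative integers")
  if (sum(v) < 1) stopf("need at least one case")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion metrics as percentages
#'
#' accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP); all on the 0-100
#' scale. A metric whose denominator is zero is returned as NA (undefined)
#' rather than silently zero.
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector: accuracy, sensitivity, specificity,
#'   precision (percent).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    n <- TP + FP + TN + FN
    ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    c(accuracy = ratio(TP + TN, n),
      sensitivity = ratio(TP, TP + FN),
      specificity = ratio(TN, TN + FP),
      precision = ratio(TP, TP + FP))
  })
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' `100 * (p_hat +/- z * sqrt(p_hat * (1 - p_hat) / n))`, capped into
#' [0, 100]. z defaults to 1.96 for a 95% interval. Note the `n` is the
#' interval's sample size, which in the reader-study convention mirrored
#' here is the full evaluation-set size (e.g. all 148 test frames or all 50
#' patients) even for subgroup metrics such as sensitivity; pass the
#' subgroup denominator instead for the per-denominator convention.
#'
#' @param p_hat proportion in [0,1].
#' @param n sample size (>= 1).
#' @param z normal quantile (default 1.96).
#' @return object of class `proportion_ci` with fields `p_hat`, `n`, `z`,
#'   `estimate` (percent), `lower`, `upper` (capped percents, unrounded;
#'   the print method reports one decimal, half-up).
#' @export
normal_ci <- function(p_hat, n, z = 1.96) {
  if (!is_fraction(p_hat)) stopf("p_hat must lie in [0,1]")
  if (!is_count(n) || n < 1) stopf("n must be a count >= 1")
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  structure(list(p_hat = p_hat, n = as.integer(n), z = z,
                 estimate = 100 * p_hat,
                 lower = max(0, 100 * (p_hat - half)),
                 upper = min(100, 100 * (p_hat + half))),
            class = "proportion_ci")
}

#' @export
format.proportion_ci <- function(x, ...) {
  sprintf("%.1f%% (95%% CI, %.1f%%-%.1f%%)",
          round_half_up(x$estimate, 1), round_half_up(x$lower, 1),
          round_half_up(x$upper, 1))
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(format(x), sprintf("[n = %d]\n", x$n))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The all-pairs concordance statistic: the probability that a randomly
#' chosen positive scores above a randomly chosen negative, ties counted
#' one half. Computed from midranks (Mann-Whitney form).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes required.
#' @return AUROC in [0,1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("auroc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Frame-selection precision with confidence interval
#'
#' The proportion of selected frames whose ground truth marks them as
#' clear (valid) retinal images, with a normal-approximation interval at
#' n = number of selected frames.
#'
#' @param selected data.frame with `video_id` and `frame_index` of selected
#'   crops.
#' @param truth frame-truth data.frame (columns `video_id`, `frame_index`,
#'   `validity`); every selected crop must have a truth row.
#' @param z normal quantile.
#' @return a [normal_ci()] object.
#' @export
selection_precision <- function(selected, truth, z = 1.96) {
  if (is.null(selected) || nrow(selected) == 0) {
    stopf("selection_precision needs a non-empty selection")
  }
  key <- paste(truth$video_id, truth$frame_index)
  idx <- match(paste(selected$video_id, selected$frame_index), key)
  if (anyNA(idx)) stopf("selected crops without a truth row")
  valid <- truth$validity[idx] == "valid"
  normal_ci(mean(valid), nrow(selected), z)
}

#' Stratified train/validation/test split
#'
#' Within each stratum, the training and validation counts are the
#' half-up-rounded products of the stratum size with the requested
#' fractions, and the remainder goes to test; items are then assigned at
#' random within the stratum (deterministic per seed). With
#' `group = patient_id`, whole groups are assigned to one split (grouped by
#' stratum of the group).
#'
#' @param ids item identifiers.
#' @param strata stratum label per item.
#' @param fractions length-3 numeric (train, validation, test), summing
#'   to 1.
#' @param seed integer seed.
#' @param group optional grouping vector (e.g. patient id); all items of a
#'   group land in the same split.
#' @return data.frame with columns `id`, `stratum`, `split` (factor
#'   train/validation/test).
#' @export
stratified_split <- function(ids, strata, fractions, seed = 1, group = NULL) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be length 3 and sum to 1")
  }
  if (length(ids) != length(strata)) stopf("ids and strata lengths differ")
  if (!is.null(group)) {
    gkey <- !duplicated(group)
    gsplit <- stratified_split(group[gkey], strata[gkey], fractions, seed)
    split <- gsplit$split[match(group, gsplit$id)]
    return(data.frame(id = ids, stratum = strata, split = split))
  }
  split <- rep(NA_character_, length(ids))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    if (n < 3) {
      warnf("stratum '%s' has %d item(s), fewer than the number of splits; all to train",
            s, n)
      split[idx] <- "train"
      next
    }
    n_train <- as.integer(round_half_up(n * fractions[1]))
    n_val <- as.integer(round_half_up(n * fractions[2]))
    n_test <- n - n_train - n_val
    if (n_test < 0) { n_val <- n_val + n_test; n_test <- 0L }
    perm <- with_seed(child_seed(seed, 71L, match(s, unique(strata))),
                      sample(idx))
    split[perm] <- rep(c("train", "validation", "test"),
                       c(n_train, n_val, n_test))
  }
  data.frame(id = ids, stratum = strata,
             split = factor(split, levels = c("train", "validation", "test")))
}

#' Evaluate screening decisions against gold labels
#'
#' Indeterminate decisions are excluded from the confusion matrix and
#' reported separately.
#'
#' @param decisions data.frame with `patient_id` and `decision`
#'   ("ROP-positive", "ROP-negative", "indeterminate").
#' @param gold data.frame with `patient_id` and `rop_status` (1 = ROP).
#' @param ci_n_mode "evaluation-set" uses the number of determinate
#'   patients as the CI n for every metric (the reader-study convention);
#'   "denominator" uses each metric's own denominator.
#' @return list with `counts` ([confusion_counts()]), `metrics`,
#'   `ci` (list of [normal_ci()] per metric), `n_indeterminate`.
#' @export
evaluate_decisions <- function(decisions, gold,
                               ci_n_mode = c("evaluation-set", "denominator")) {
  ci_n_mode <- match.arg(ci_n_mode)
  m <- merge(decisions, gold, by = "patient_id")
  det <- m[m$decision != "indeterminate", ]
  pred <- det$decision == "ROP-positive"
  truth <- det$rop_status == 1
  counts <- confusion_counts(TP = sum(pred & truth), FP = sum(pred & !truth),
                             TN = sum(!pred & !truth), FN = sum(!pred & truth))
  metrics <- confusion_metrics(counts)
  n_all <- nrow(det)
  dens <- c(accuracy = n_all,
            sensitivity = counts$TP + counts$FN,
            specificity = counts$TN + counts$FP,
            precision = counts$TP + counts$FP)
  cis <- lapply(names(metrics), function(nm) {
    if (is.na(metrics[[nm]])) return(NULL)
    n_ci <- if (ci_n_mode == "evaluation-set") n_all else dens[[nm]]
    normal_ci(metrics[[nm]] / 100, n_ci)
  })
  names(cis) <- names(metrics)
  list(counts = counts, metrics = metrics, ci = cis,
       n_indeterminate = sum(m$decision == "indeterminate"))
}
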