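#' Top-k frame selection policy
#'
#' @param k number of top-quality crops kept per video (default 3, matching
#'   the screening protocol of taking the three highest-ranked retinal
#'   images; videos with fewer scored crops contribute all of them).
#' @param min_frames minimum usable crops for a video to be screenable.
#' @return object of class `selection_policy`.
#' @export
selection_policy <- function(k = 3, min_frames = 1) {
  if (!is_count(k) || k < 1) stopf("k must be a count >= 1")
  structure(list(k = as.integer(k), min_frames = as.integer(min_frames)),
            class = "selection_policy")
}

#' Build a labeled quality dataset from a synthetic cohort
#'
#' Crops every frame at its ground-truth circle (empty frames are cropped
#' at the frame center with the spec radius, yielding background crops) and
#' labels each crop valid/invalid from the frame truth. This mirrors how a
#' frame-selection dataset is assembled from expert-reviewed frames.
#'
#' @param cohort a [generate_cohort()] result.
#' @param spec the [cohort_spec()] used to generate it.
#' @param input_size side length crops are downscaled to (keeps the
#'   dataset light); use 256 for full resolution.
#' @return list with `crops` (list of `fundus_crop`), `labels` (1 = valid),
#'   and `meta` (the frame-truth rows, same order).
#' @export
make_quality_dataset <- function(cohort, spec, input_size = 64) {
  ft <- cohort$frame_truth
  crops <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    vid <- cohort$videos[[ft$video_id[i]]]
    frame <- extract_frames(vid, stride = 1)[[ft$frame_index[i] + 1L]]
    circ <- if (is.finite(ft$radius[i])) {
      list(a = ft$center_x[i], b = ft$center_y[i], R = ft$radius[i])
    } else {
      list(a = (spec$width - 1) / 2, b = (spec$height - 1) / 2,
           R = spec$radius)
    }
    crops[[i]] <- downscale_crop(crop_fundus(frame, circ), input_size)
  }
  list(crops = crops, labels = as.integer(ft$validity == "valid"), meta = ft)
}

#' Build a labeled ROP dataset from a synthetic cohort
#'
#' Crops the valid frames at their ground-truth circles and labels each
#' crop with the patient's ROP status; patient ids are carried for the
#' split-integrity check of [train_rop_classifier()].
#'
#' @inheritParams make_quality_dataset
#' @return list with `crops`, `labels` (1 = ROP), `patient_id`, `meta`.
#' @export
make_rop_dataset <- function(cohort, spec, input_size = 64) {
  ft <- cohort$frame_truth[cohort$frame_truth$validity == "valid", ]
  crops <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    vid <- cohort$videos[[ft$video_id[i]]]
    frame <- extract_frames(vid, stride = 1)[[ft$frame_index[i] + 1L]]
    circ <- list(a = ft$center_x[i], b = ft$center_y[i], R = ft$radius[i])
    crops[[i]] <- downscale_crop(crop_fundus(frame, circ), input_size)
  }
  list(crops = crops, labels = ft$rop_status, patient_id = ft$patient_id,
       meta = ft)
}

#' Train the valid/invalid fundus-frame classifier
#'
#' Fits a [fundus_net()] on crop descriptors to separate clear fundus
#' views from artifact frames (blur, glare, partial, empty). The returned
#' model's quality score is its positive-class probability.
#'
#' @param train,val lists with elements `crops` (list of crops) and
#'   `labels` (1 = valid, 0 = invalid); both classes must be present in
#'   `train`.
#' @param input_size classifier input side length (crops are downscaled).
#' @param hidden,learning_rate,max_epochs,patience,seed passed to
#'   [fundus_net()].
#' @return object of class `quality_model`.
#' @export
train_quality_classifier <- function(train, val, input_size = 64,
                                     hidden = 8, learning_rate = 0.01,
                                     max_epochs = 2000, patience = 100,
                                     seed = 1) {
  if (length(unique(train$labels)) < 2) {
    stopf("quality training set must contain valid and invalid examples")
  }
  xtr <- featurize_crops(lapply(train$crops, downscale_crop, size = input_size))
  xva <- featurize_crops(lapply(val$crops, downscale_crop, size = input_size))
  net <- fundus_net(xtr, train$labels, xva, val$labels, hidden = hidden,
                    learning_rate = learning_rate, w_pos = 1,
                    max_epochs = max_epochs, patience = patience, seed = seed)
  structure(list(net = net, input_size = input_size,
                 val_auroc = net$val_auroc),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("Fundus frame quality classifier (input %dx%d), val AUROC %.3f\n",
              x$input_size, x$input_size, x$val_auroc))
  invisible(x)
}

#' Score crop quality
#'
#' @param model a [train_quality_classifier()] model.
#' @param crops one `fundus_crop` (256x256, or already at the model's input
#'   size) or a list of them.
#' @return numeric vector of scores in [0,1]; higher = clearer fundus view.
#' @export
score_quality <- function(model, crops) {
  stopifnot(inherits(model, "quality_model"))
  if (inherits(crops, "fundus_crop") || (is.array(crops) && !is.list(crops))) {
    crops <- list(crops)
  }
  for (cr in crops) {
    img <- if (inherits(cr, "fundus_crop")) cr$image else cr
    if (!dim(img)[1] %in% c(model$input_size, 256) || dim(img)[1] != dim(img)[2]) {
      stopf("crops must be square, 256x256 or %dx%d",
            model$input_size, model$input_size)
    }
  }
  x <- featurize_crops(lapply(crops, downscale_crop, size = model$input_size))
  unname(predict(model$net, x, type = "prob"))
}

#' Rank per-video crops by quality and select the top k
#'
#' @param scores data.frame with columns `frame_index` and `score` (one
#'   video's scored crops).
#' @param policy a [selection_policy()].
#' @return data.frame sorted by descending score (ties broken by lower
#'   frame index), with `rank` and logical `selected` columns; zero rows in
#'   means zero rows out (video flagged as having no usable frames by the
#'   caller).
#' @export
rank_and_select <- function(scores, policy = selection_policy()) {
  if (is.null(scores) || nrow(scores) == 0) {
    return(data.frame(frame_index = integer(0), score = numeric(0),
                      rank = integer(0), selected = logical(0)))
  }
  ord <- order(-scores$score, scores$frame_index)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= policy$k
  rownames(out) <- NULL
  out
}

#' Mine hard negatives: confident false positives of the quality model
#'
#' Scores unlabeled crops and returns the `top_m` highest-scoring crops
#' whose ground truth (or reviewer) marks them invalid and whose score
#' clears the confidence threshold -- the cases an expert would be asked to
#' confirm and add to the training set.
#'
#' @param model a quality model.
#' @param crops list of crops.
#' @param invalid logical vector: TRUE where the truth marks the frame
#'   invalid.
#' @param top_m maximum number of candidates (fewer are returned when fewer
#'   qualify).
#' @param threshold minimum score for a "confident" false positive.
#' @return data.frame with `index` (into `crops`) and `score`, ordered by
#'   score descending.
#' @export
mine_hard_negatives <- function(model, crops, invalid, top_m,
                                threshold = 0.5) {
  stopifnot(length(crops) == length(invalid))
  if (top_m == 0 || length(crops) == 0) {
    return(data.frame(index = integer(0), score = numeric(0)))
  }
  sc <- score_quality(model, crops)
  cand <- which(invalid & sc >= threshold)
  cand <- cand[order(-sc[cand])]
  cand <- cand[seq_len(min(top_m, length(cand)))]
  data.frame(index = cand, score = sc[cand])
}
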