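#' Screen one video for ROP
#'
#' Runs the full per-video pipeline: extract frames at the stride, convert
#' to grayscale, find the magnifier circle (Hough search + closest-
#' dimension selection; frames without an acceptable circle are
#' disregarded), crop and resize the fundus field, score crop quality and
#' keep the top-k, classify each kept crop with the calibrated ROP model,
#' and decide by the any-positive rule: the patient's video is called
#' ROP-positive iff at least one selected frame is called positive. A video
#' with no usable frames is `indeterminate` (the capture protocol's cue to
#' take another video).
#'
#' @param video a [video_record()].
#' @param mag_spec a [magnifier_spec()].
#' @param quality_model a [train_quality_classifier()] model.
#' @param rop_model a calibrated [train_rop_classifier()] model.
#' @param threshold probability threshold for a positive frame call.
#' @param policy a [selection_policy()].
#' @param stride frame sampling stride.
#' @param ... passed to [hough_circle_search()].
#' @return object of class `screening_decision`: fields `patient_id`,
#'   `video_id`, `decision` ("ROP-positive"/"ROP-negative"/"indeterminate"),
#'   `frame_calls` (data.frame frame_index, quality, probability, call),
#'   `n_frames`, `n_circles`.
#' @export
screen_video <- function(video, mag_spec, quality_model, rop_model,
                         threshold = 0.5, policy = selection_policy(),
                         stride = 5, ...) {
  frames <- extract_frames(video, stride)
  crops <- list()
  meta <- data.frame(frame_index = integer(0), score = numeric(0))
  for (fr in frames) {
    gray <- to_grayscale(fr)
    cand <- hough_circle_search(gray, mag_spec, ...)
    circ <- select_magnifier_circle(cand, mag_spec)
    if (is.null(circ)) next
    crops[[length(crops) + 1L]] <- crop_fundus(fr, circ)
    meta <- rbind(meta, data.frame(frame_index = fr$frame_index,
                                   score = NA_real_))
  }
  if (length(crops) == 0) {
    return(structure(list(patient_id = video$patient_id,
                          video_id = video$video_id,
                          decision = "indeterminate",
                          frame_calls = data.frame(),
                          n_frames = length(frames), n_circles = 0L),
                     class = "screening_decision"))
  }
  meta$score <- score_quality(quality_model, crops)
  ranked <- rank_and_select(meta, policy)
  sel <- ranked[ranked$selected, , drop = FALSE]
  sel_crops <- crops[match(sel$frame_index, meta$frame_index)]
  prob <- predict(rop_model, sel_crops, type = "prob")
  calls <- data.frame(frame_index = sel$frame_index, quality = sel$score,
                      probability = prob, call = prob >= threshold)
  decision <- if (any(calls$call)) "ROP-positive" else "ROP-negative"
  structure(list(patient_id = video$patient_id, video_id = video$video_id,
                 decision = decision, frame_calls = calls,
                 n_frames = length(frames), n_circles = length(crops)),
            class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf("Screening decision for %s (%s): %s\n",
              x$patient_id, x$video_id, x$decision))
  cat(sprintf("  %d frames extracted, %d circles found, %d frames called\n",
              x$n_frames, x$n_circles,
              if (is.null(x$frame_calls)) 0L else nrow(x$frame_calls)))
  invisible(x)
}

#' Screen a cohort of patients
#'
#' One decision per patient; a patient with several videos is called
#' ROP-positive iff any video decision is positive, indeterminate iff all
#' video decisions are indeterminate.
#'
#' @param videos named list of [video_record()]s (patient ids taken from
#'   the records).
#' @inheritParams screen_video
#' @return data.frame of class `screening_cohort`: `patient_id`,
#'   `decision`, `n_videos`, `n_positive_frames`.
#' @export
screen_cohort <- function(videos, mag_spec, quality_model, rop_model,
                          threshold = 0.5, policy = selection_policy(),
                          stride = 5, ...) {
  if (length(videos) == 0) {
    out <- data.frame(patient_id = character(0), decision = character(0),
                      n_videos = integer(0), n_positive_frames = integer(0))
    class(out) <- c("screening_cohort", class(out))
    return(out)
  }
  pid <- vapply(videos, function(v) v$patient_id, character(1))
  vid <- vapply(videos, function(v) v$video_id, character(1))
  if (anyDuplicated(vid)) stopf("duplicate video ids in cohort")
  decisions <- lapply(videos, function(v) {
    screen_video(v, mag_spec, quality_model, rop_model,
                 threshold = threshold, policy = policy, stride = stride, ...)
  })
  rows <- lapply(unique(pid), function(p) {
    ds <- decisions[pid == p]
    labels <- vapply(ds, function(d) d$decision, character(1))
    dec <- if (any(labels == "ROP-positive")) "ROP-positive"
           else if (any(labels == "ROP-negative")) "ROP-negative"
           else "indeterminate"
    npos <- sum(vapply(ds, function(d) {
      if (nrow(d$frame_calls) == 0) 0L else sum(d$frame_calls$call)
    }, integer(1)))
    data.frame(patient_id = p, decision = dec, n_videos = length(ds),
               n_positive_frames = npos)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_cohort", class(out))
  out
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat(sprintf("Cohort screening: %d patients (%d positive, %d negative, %d indeterminate)\n",
              nrow(x), sum(x$decision == "ROP-positive"),
              sum(x$decision == "ROP-negative"),
              sum(x$decision == "indeterminate")))
  NextMethod()
}
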