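#' Describe a video source
#'
#' A video is either an in-memory list of frames (height x width x 3 arrays),
#' or a directory containing a `frame_%06d.png` stack. MP4/MOV paths are
#' recognized but raise an explicit decode error at extraction time, since
#' no video decoder is bundled; frame stacks are the supported on-disk
#' container (one PNG per frame, lossless).
#'
#' @param source list of frame arrays, or a path to a frame-stack directory.
#' @param video_id,patient_id identifiers carried through the pipeline.
#' @return object of class `video_record` with fields `source`, `container`
#'   ("memory", "frame-stack", "mp4" or "mov") and `n_frames`.
#' @export
video_record <- function(source, video_id = "V1", patient_id = NA_character_) {
  if (is.list(source)) {
    if (length(source) < 1) stopf("a video needs at least one frame")
    container <- "memory"
    n_frames <- length(source)
  } else if (is.character(source) && length(source) == 1) {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("mp4", "mov")) {
      container <- ext
      n_frames <- NA_integer_
    } else if (dir.exists(source)) {
      container <- "frame-stack"
      n_frames <- length(list.files(source, pattern = "^frame_\\d{6}\\.png$"))
      if (n_frames < 1) stopf("no frame_%%06d.png frames found in '%s'", source)
    } else {
      stopf("video source '%s' is neither a directory nor an mp4/mov path", source)
    }
  } else {
    stopf("source must be a list of frames or a path")
  }
  structure(list(source = source, video_id = video_id,
                 patient_id = patient_id, container = container,
                 n_frames = n_frames),
            class = "video_record")
}

#' @export
print.video_record <- function(x, ...) {
  cat(sprintf("Video %s (%s, %s frames)\n", x$video_id, x$container,
              ifelse(is.na(x$n_frames), "?", x$n_frames)))
  invisible(x)
}

new_frame_image <- function(pixels, video_id, frame_index) {
  d <- dim(pixels)
  structure(list(video_id = video_id, frame_index = as.integer(frame_index),
                 pixels = pixels, width = d[2], height = d[1]),
            class = "frame_image")
}

#' Extract frames from a video at a sampling stride
#'
#' Keeps the frames whose 0-based index is divisible by `stride`, in order,
#' so a `n`-frame video yields `ceiling(n / stride)` frames. The default
#' stride used by the screening pipeline is 5 (every fifth frame).
#'
#' @param video a [video_record()].
#' @param stride sampling stride, integer >= 1.
#' @return list of `frame_image` objects (fields `video_id`, `frame_index`,
#'   `pixels`, `width`, `height`).
#' @export
extract_frames <- function(video, stride = 5) {
  stopifnot(inherits(video, "video_record"))
  if (!is_count(stride) || stride < 1) stopf("stride must be an integer >= 1")
  if (video$container %in% c("mp4", "mov")) {
    stopf(paste0("cannot decode '%s' container: no video decoder is bundled; ",
                 "export the video as a frame_%%06d.png stack directory"),
          video$container)
  }
  keep <- seq(0L, video$n_frames - 1L, by = stride)
  if (video$container == "memory") {
    frames <- lapply(keep, function(i) {
      new_frame_image(video$source[[i + 1L]], video$video_id, i)
    })
  } else {
    frames <- lapply(keep, function(i) {
      path <- file.path(video$source, sprintf("frame_%06d.png", i))
      if (!file.exists(path)) stopf("frame file missing: %s", path)
      new_frame_image(png::readPNG(path), video$video_id, i)
    })
  }
  frames
}

#' Convert a frame to grayscale
#'
#' Single-plane input is returned unchanged; color input is converted with
#' fixed ITU-R BT.601 luma weights (0.299, 0.587, 0.114). Accepts either a
#' `frame_image` or a bare array/matrix, returning the same kind of object.
#'
#' @param frame a `frame_image`, a height x width x 3 array, or a matrix.
#' @return grayscale frame of the same kind (pixel matrix).
#' @export
to_grayscale <- function(frame) {
  if (inherits(frame, "frame_image")) {
    out <- frame
    out$pixels <- to_grayscale(frame$pixels)
    return(out)
  }
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3 && d[3] == 3) return(luma(frame))
  if (length(d) == 3 && d[3] == 1) return(frame[, , 1])
  stopf("expected a matrix or an array with 1 or 3 planes")
}
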