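#' Specify the expected magnifier geometry
#'
#' The condensing lens held over the eye appears in each frame as a bright
#' circle whose on-image radius depends on the lens power and capture
#' distance. The Hough search is restricted to a radius window around the
#' expected radius; frames in which no circle of the expected dimensions is
#' found are disregarded.
#'
#' @param lens_power condensing lens power in diopters: 20, 28 or 40.
#' @param expected_radius expected circle radius in pixels. Defaults by
#'   lens (higher power gives a smaller aerial image): 96 px for +20 D,
#'   80 px for +28 D, 64 px for +40 D, at the package's 256 px frame scale.
#' @param radius_tolerance half-width of the radius search window, px.
#' @param max_candidates maximum number of circle candidates returned.
#' @return object of class `magnifier_spec`.
#' @export
magnifier_spec <- function(lens_power = 28, expected_radius = NULL,
                           radius_tolerance = 10, max_candidates = 5) {
  if (!lens_power %in% c(20, 28, 40)) stopf("lens_power must be 20, 28 or 40")
  if (is.null(expected_radius)) {
    expected_radius <- c(`20` = 96, `28` = 80, `40` = 64)[[as.character(lens_power)]]
  }
  if (expected_radius <= 0) stopf("expected_radius must be positive")
  if (radius_tolerance < 0) stopf("radius_tolerance must be >= 0")
  structure(list(lens_power = lens_power, expected_radius = expected_radius,
                 radius_tolerance = radius_tolerance,
                 max_candidates = as.integer(max_candidates)),
            class = "magnifier_spec")
}

# Gradient-magnitude edge map by central differences; returns 0-based
# (x, y) coordinates of pixels whose magnitude exceeds the threshold.
# Caps the edge count at max_edges (keeping the strongest) so accumulator
# time stays bounded on pathological frames.
edge_pixels <- function(gray, threshold = 0.08, max_edges = 20000L) {
  h <- nrow(gray); w <- ncol(gray)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  idx <- which(mag > threshold)
  if (length(idx) > max_edges) {
    idx <- idx[order(mag[idx], decreasing = TRUE)[seq_len(max_edges)]]
  }
  data.frame(x = ((idx - 1L) %/% h), y = ((idx - 1L) %% h),
             mag = mag[idx])
}

#' Search a grayscale frame for circles with a circular Hough transform
#'
#' Votes in (center, radius) space: a circle of radius R centered at
#' (a, b) traces x = a + R cos(theta), y = b + R sin(theta), so every edge
#' pixel votes for all centers at distance R from it, for each R in the
#' search window `expected_radius +/- radius_tolerance`. The accumulator
#' value at (a, b, R) is the number of edge pixels at rounded distance R
#' from (a, b). Candidates must reach `vote_threshold` times the
#' theoretical full-circle vote count (2*pi*R, the annulus area), which
#' makes the threshold scale-free across radii; near-duplicate peaks are
#' suppressed within `nms_distance` pixels of a stronger peak.
#'
#' @param gray_frame a single-plane `frame_image` or a numeric matrix with
#'   intensities in [0,1].
#' @param spec a [magnifier_spec()].
#' @param edge_threshold gradient-magnitude threshold for the edge map.
#' @param vote_threshold fraction of the theoretical full-circle vote count
#'   a candidate must reach (default 0.5).
#' @param nms_distance minimum center distance between reported candidates.
#' @return data.frame with columns `a`, `b` (0-based center), `R`, `votes`
#'   (accumulator count) and `score` (votes / (2*pi*R)), sorted by votes
#'   descending; zero rows when no circle exceeds the threshold.
#' @export
hough_circle_search <- function(gray_frame, spec,
                                edge_threshold = 0.08,
                                vote_threshold = 0.5,
                                nms_distance = 10) {
  gray <- if (inherits(gray_frame, "frame_image")) gray_frame$pixels else gray_frame
  if (!is.matrix(gray)) stopf("hough_circle_search expects a single-plane frame")
  rmin <- max(3L, as.integer(round(spec$expected_radius - spec$radius_tolerance)))
  rmax <- as.integer(round(spec$expected_radius + spec$radius_tolerance))
  if (rmax < rmin) stopf("empty radius search range")
  empty <- data.frame(a = integer(0), b = integer(0), R = integer(0),
                      votes = integer(0), score = numeric(0))
  if (min(dim(gray)) < 2 * rmin) {
    warnf("frame (%dx%d) smaller than twice the minimum radius %d; no search",
          ncol(gray), nrow(gray), rmin)
    return(empty)
  }
  ed <- edge_pixels(gray, edge_threshold)
  if (nrow(ed) == 0) return(empty)
  acc <- hough_votes_cpp(as.integer(ed$x), as.integer(ed$y),
                         ncol(gray), nrow(gray), rmin, rmax)
  radii <- rmin:rmax
  thr <- vote_threshold * 2 * pi * radii
  keep <- which(acc >= rep(thr, each = nrow(gray) * ncol(gray)))
  if (length(keep) == 0) return(empty)
  h <- nrow(gray); w <- ncol(gray)
  k0 <- keep - 1L
  b <- k0 %% h
  a <- (k0 %/% h) %% w
  R <- radii[k0 %/% (h * w) + 1L]
  cand <- data.frame(a = a, b = b, R = R, votes = acc[keep])
  cand$score <- cand$votes / (2 * pi * cand$R)
  cand <- cand[order(-cand$votes, cand$a, cand$b, cand$R), , drop = FALSE]
  # greedy non-maximum suppression on center distance
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) == 0) {
      sel <- i
    } else {
      d2 <- (cand$a[sel] - cand$a[i])^2 + (cand$b[sel] - cand$b[i])^2
      if (all(d2 > nms_distance^2)) sel <- c(sel, i)
    }
    if (length(sel) >= spec$max_candidates) break
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the magnifier circle among Hough candidates
#'
#' Implements the frame-disregard and closest-dimension rules: an empty
#' candidate list means the frame is disregarded (returns NULL); otherwise
#' the candidate whose radius is closest to the expected magnifier radius
#' wins, ties broken by higher vote count, then by smaller (a, b)
#' lexicographically.
#'
#' @param candidates data.frame as returned by [hough_circle_search()].
#' @param spec a [magnifier_spec()].
#' @return one-row data.frame (a, b, R, votes, score), or NULL.
#' @export
select_magnifier_circle <- function(candidates, spec) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  dr <- abs(candidates$R - spec$expected_radius)
  ord <- order(dr, -candidates$votes, candidates$a, candidates$b)
  out <- candidates[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop and resize the fundus field from a color frame
#'
#' Takes the square of side 2R centered on the selected circle, zero-pads
#' where the square exceeds the frame bounds, and resizes to a fixed
#' 256 x 256 with bilinear interpolation, so the fundus circle is inscribed
#' in the output.
#'
#' @param color_frame a `frame_image` or a height x width x 3 array (a
#'   matrix is promoted to three identical planes).
#' @param circle one-row data.frame (or list) with `a`, `b`, `R`.
#' @param size output side length (default 256).
#' @return object of class `fundus_crop` with fields `video_id`,
#'   `frame_index`, `circle`, `image` (size x size x 3).
#' @export
crop_fundus <- function(color_frame, circle, size = 256) {
  video_id <- NA_character_; frame_index <- NA_integer_
  if (inherits(color_frame, "frame_image")) {
    video_id <- color_frame$video_id
    frame_index <- color_frame$frame_index
    px <- color_frame$pixels
  } else {
    px <- color_frame
  }
  if (is.matrix(px)) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (is.null(circle) || circle$R <= 0) stopf("need a selected circle with R > 0")
  h <- dim(px)[1]; w <- dim(px)[2]
  side <- max(2L, as.integer(round(2 * circle$R)))
  x0 <- as.integer(round(circle$a - circle$R))
  y0 <- as.integer(round(circle$b - circle$R))
  crop <- array(0, dim = c(side, side, 3))
  xs <- x0:(x0 + side - 1L); ys <- y0:(y0 + side - 1L)
  in_x <- which(xs >= 0 & xs < w); in_y <- which(ys >= 0 & ys < h)
  if (length(in_x) > 0 && length(in_y) > 0) {
    crop[in_y, in_x, ] <- px[ys[in_y] + 1L, xs[in_x] + 1L, , drop = FALSE]
  }
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    out[, , ch] <- EBImage::imageData(
      EBImage::resize(crop[, , ch], w = size, h = size, filter = "bilinear"))
  }
  structure(list(video_id = video_id, frame_index = frame_index,
                 circle = as.list(circle)[c("a", "b", "R")],
                 image = clamp01(out)),
            class = "fundus_crop")
}

#' Estimate the radius search range from a calibration video
#'
#' Runs a wide-window Hough search over calibration frames, takes the mode
#' of the selected radii, and returns a window of the given half-width
#' around it. This realizes the "learned radius range" as a data-driven
#' refinement of the magnifier-derived window.
#'
#' @param gray_frames list of single-plane frames (matrices or
#'   `frame_image`s).
#' @param r_min,r_max wide search bounds in pixels.
#' @param half_width half-width of the returned window.
#' @param ... passed to [hough_circle_search()].
#' @return numeric vector `c(lower, upper)`.
#' @export
learn_radius_range <- function(gray_frames, r_min, r_max, half_width = 10, ...) {
  mid <- (r_min + r_max) / 2
  wide <- magnifier_spec(expected_radius = mid,
                         radius_tolerance = (r_max - r_min) / 2,
                         max_candidates = 1)
  radii <- vapply(gray_frames, function(fr) {
    cand <- hough_circle_search(fr, wide, ...)
    if (nrow(cand) == 0) NA_real_ else cand$R[1]
  }, numeric(1))
  radii <- radii[!is.na(radii)]
  if (length(radii) == 0) stopf("no circles found in calibration frames")
  tab <- table(radii)
  mode_r <- as.numeric(names(tab)[which.max(tab)])
  c(mode_r - half_width, mode_r + half_width)
}
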