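#' Ground truth for one synthetic video frame
#'
#' Records whether the magnifier circle is present, where it is, and which
#' artifact (if any) the frame carries. Validity is derived: a frame is
#' valid only when a full circle is present with no artifact.
#'
#' @param circle_present logical; FALSE for empty frames.
#' @param center_x,center_y circle center in 0-based pixel coordinates
#'   (x along width, y along height); NA when no circle is present.
#' @param radius circle radius in pixels; NA when no circle is present.
#' @param artifact one of "none", "blur", "glare", "partial", "empty".
#' @return object of class `frame_truth` with a derived `validity` field
#'   ("valid" or "invalid").
#' @export
frame_truth <- function(circle_present = TRUE, center_x = NA_real_,
                        center_y = NA_real_, radius = NA_real_,
                        artifact = c("none", "blur", "glare", "partial", "empty")) {
  artifact <- match.arg(artifact)
  if (artifact == "empty") circle_present <- FALSE
  if (!circle_present && !artifact %in% c("empty")) {
    stopf("a frame without a circle must carry the 'empty' artifact")
  }
  if (circle_present && (!is.finite(center_x) || !is.finite(center_y) ||
                         !is.finite(radius) || radius <= 0)) {
    stopf("circle_present frames need finite center and positive radius")
  }
  validity <- if (circle_present && artifact == "none") "valid" else "invalid"
  structure(list(circle_present = circle_present, center_x = center_x,
                 center_y = center_y, radius = radius, artifact = artifact,
                 validity = validity),
            class = "frame_truth")
}

# Sample a frame truth under the cohort spec's valid-frame rate. Valid
# frames (and blur/glare frames) place the circle fully inside the frame;
# partial frames push the center so the circle crosses a boundary.
sample_frame_truth <- function(spec) {
  r <- spec$radius + stats::runif(1, -spec$radius_jitter, spec$radius_jitter)
  if (stats::runif(1) < spec$valid_frame_rate) {
    artifact <- "none"
  } else {
    artifact <- sample(c("blur", "glare", "partial", "empty"), 1)
  }
  if (artifact == "empty") {
    return(frame_truth(circle_present = FALSE, artifact = "empty"))
  }
  if (artifact == "partial") {
    # center within the frame but close enough to an edge that 25-60% of
    # the circle diameter is cut off
    side <- sample(4, 1)
    off <- r * stats::runif(1, 0.4, 0.75)
    cx <- stats::runif(1, r + 2, spec$width - r - 2)
    cy <- stats::runif(1, r + 2, spec$height - r - 2)
    if (side == 1) cx <- off
    if (side == 2) cx <- spec$width - 1 - off
    if (side == 3) cy <- off
    if (side == 4) cy <- spec$height - 1 - off
    return(frame_truth(TRUE, cx, cy, r, "partial"))
  }
  margin <- r + 3
  cx <- stats::runif(1, margin, spec$width - 1 - margin)
  cy <- stats::runif(1, margin, spec$height - 1 - margin)
  frame_truth(TRUE, cx, cy, r, artifact)
}

# Rasterize one vessel segment onto the channel matrices (modified in
# place via the returned list). Coordinates in pixels, 0-based.
draw_vessels <- function(img, phantom, cx, cy, r) {
  h <- dim(img)[1]; w <- dim(img)[2]
  vessel_col <- c(0.30, 0.05, 0.05)
  for (seg in phantom$vessel_tree) {
    p0 <- seg$points[1, ] * r + c(cx, cy)
    p1 <- seg$points[2, ] * r + c(cx, cy)
    len <- sqrt(sum((p1 - p0)^2))
    if (len < 1) next
    n <- max(4L, ceiling(len * 2.5))
    t <- seq(0, 1, length.out = n)
    base <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
    # tortuosity: sinusoidal perpendicular displacement, amplitude scaled
    # by the phantom's tortuosity gain
    dirv <- (p1 - p0) / len
    normv <- c(-dirv[2], dirv[1])
    amp <- 0.011 * phantom$tortuosity_gain * r
    disp <- amp * sin(2 * pi * t * len / (0.28 * r) + seg$phase)
    pts <- base + outer(disp, normv)
    half <- max(0.6, 0.5 * seg$width * phantom$dilation_gain * r)
    kr <- ceiling(half)
    offs <- expand.grid(dx = -kr:kr, dy = -kr:kr)
    offs <- offs[offs$dx^2 + offs$dy^2 <= half^2, , drop = FALSE]
    px <- round(pts[, 1]); py <- round(pts[, 2])
    for (k in seq_len(nrow(offs))) {
      xs <- px + offs$dx[k]; ys <- py + offs$dy[k]
      keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
      if (!any(keep)) next
      idx <- cbind(ys[keep] + 1L, xs[keep] + 1L)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- vessel_col[ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Render one synthetic fundus video frame
#'
#' Draws a bright circular fundus field on a dark surround: an orange
#' fundus disk with radial vignetting, an optic-disc analog, a branching
#' vessel tree with tortuosity/dilation scaled by the phantom's gains,
#' and -- for ROP-positive eyes -- a bright circumferential demarcation-ridge
#' arc whose amplitude scales with the phantom's `ridge_arc$strength`.
#' Artifacts: `blur` applies isotropic Gaussian smoothing, `glare` inserts
#' saturated blobs, `partial` renders a circle crossing the frame border,
#' `empty` renders background only. Additive Gaussian noise is truncated at
#' three standard deviations so artifact-free background stays strictly
#' bounded; output is 8-bit quantized RGB in [0,1], so repeated renders and
#' PNG round trips are bit-identical.
#'
#' @param phantom an [make_phantom()] eye phantom.
#' @param truth a [frame_truth()].
#' @param width,height output size in pixels.
#' @param seed integer seed controlling noise and glare placement.
#' @param noise_sd,contrast see [cohort_spec()].
#' @param blur_sigma Gaussian sigma (px) used for the blur artifact.
#' @return list with `image` (height x width x 3 array in [0,1]) and `truth`.
#' @export
render_frame <- function(phantom, truth, width = 256, height = 256, seed = 1,
                         noise_sd = 0.02, contrast = 0.35, blur_sigma = 5) {
  stopifnot(inherits(phantom, "eye_phantom"), inherits(truth, "frame_truth"))
  if (width <= 0 || height <= 0) stopf("frame dimensions must be positive")
  if (truth$circle_present && truth$artifact != "partial" &&
      truth$radius >= min(width, height) / 2) {
    stopf("true_radius must be < min(width,height)/2 for full circles")
  }
  with_seed(seed, {
    bg <- 0.04
    img <- array(bg, dim = c(height, width, 3))
    X <- matrix(0:(width - 1), height, width, byrow = TRUE)
    Y <- matrix(0:(height - 1), height, width)

    if (truth$circle_present && truth$artifact != "empty") {
      cx <- truth$center_x; cy <- truth$center_y; r <- truth$radius
      D <- sqrt((X - cx)^2 + (Y - cy)^2)
      inside <- D <= r
      u <- pmin(D / r, 1)
      base_luma <- contrast * 1.45
      col_mix <- c(1.486, 0.882, 0.336)  # luma-normalized fundus tint
      vignette <- 1 - 0.3 * u^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- bg + base_luma * col_mix[ch] * vignette[inside]
        img[, , ch] <- plane
      }
      # optic disc analog
      dc <- phantom$disc_center * r + c(cx, cy)
      Dd2 <- (X - dc[1])^2 + (Y - dc[2])^2
      blob <- exp(-Dd2 / (2 * (0.10 * r)^2))
      disc_col <- c(0.30, 0.40, 0.30)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- plane[inside] + disc_col[ch] * blob[inside]
        img[, , ch] <- plane
      }
      img <- draw_vessels(img, phantom, cx, cy, r)
      # demarcation-ridge arc, ROP-positive eyes only
      if (!is.null(phantom$ridge_arc)) {
        ra <- phantom$ridge_arc
        theta <- atan2(Y - cy, X - cx)
        dth <- abs(((theta - ra$center_angle + pi) %% (2 * pi)) - pi)
        ang_mask <- dth < ra$width / 2
        taper <- cos(pi * dth / ra$width)^2
        radial <- exp(-(D - ra$radial_pos * r)^2 / (2 * (0.035 * r)^2))
        amp <- 0.30 * ra$strength
        ridge_col <- c(1.0, 0.85, 0.45)
        sel <- inside & ang_mask
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[sel] <- plane[sel] +
            amp * ridge_col[ch] * radial[sel] * taper[sel]
          img[, , ch] <- plane
        }
      }
      if (truth$artifact == "glare") {
        n_blob <- sample(1:3, 1)
        for (g in seq_len(n_blob)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- stats::runif(1, 0, 0.6) * r
          gc <- c(cx + rr * cos(ang), cy + rr * sin(ang))
          gs <- stats::runif(1, 0.08, 0.16) * r
          gb <- 1.6 * exp(-((X - gc[1])^2 + (Y - gc[2])^2) / (2 * gs^2))
          for (ch in 1:3) img[, , ch] <- img[, , ch] + gb
        }
      }
    }

    if (truth$artifact == "blur") {
      for (ch in 1:3) {
        img[, , ch] <- EBImage::imageData(EBImage::gblur(img[, , ch],
                                                         sigma = blur_sigma))
      }
    }
    if (noise_sd > 0) {
      noise <- stats::rnorm(length(img), 0, noise_sd)
      noise <- pmin(pmax(noise, -3 * noise_sd), 3 * noise_sd)
      img <- img + noise
    }
    list(image = quantize8(clamp01(img)), truth = truth)
  })
}

# Luma of an RGB array (BT.601 weights), returns a matrix.
luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
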