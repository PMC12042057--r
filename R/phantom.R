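#' Specify a synthetic screening cohort
#'
#' Bundles every knob of the synthetic fundus-video generator: cohort size,
#' ROP prevalence, per-video frame count, the fraction of frames that are
#' valid fundus views, and the strength of the rendered ROP signature.
#' The defaults describe the study conditions the rest of the package is
#' exercised under: 29.5% patient-level prevalence, 20 frames per video,
#' 70% valid frames, 256x256 frames with an expected magnifier radius of
#' 80 px, and a small chance of a second video per patient.
#'
#' @param n_patients number of synthetic patients (>= 1).
#' @param prevalence probability that a patient is ROP positive, in [0,1].
#' @param frames_per_video frames rendered per video (>= 1).
#' @param valid_frame_rate probability that a frame is a valid fundus view;
#'   invalid frames receive one of the blur/glare/partial/empty artifacts.
#' @param effect_strength dimensionless >= 0; scales the rendered ROP
#'   signature (ridge-arc brightness, vessel tortuosity and dilation).
#'   0 makes positive and negative eyes statistically identical.
#' @param seed integer seed; the whole cohort is a pure function of the spec.
#' @param width,height frame size in pixels.
#' @param radius expected magnifier circle radius in pixels.
#' @param radius_jitter half-width of the uniform radius jitter per frame.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (intensities live in [0,1]).
#' @param contrast mean intensity difference between the fundus disk and the
#'   dark surround.
#' @param p_second_video probability that a patient contributes two videos.
#' @return an object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_patients = 4, seed = 1)
#' spec$prevalence
#' @export
cohort_spec <- function(n_patients = 8,
                        prevalence = 0.295,
                        frames_per_video = 20,
                        valid_frame_rate = 0.7,
                        effect_strength = 1,
                        seed = 1,
                        width = 256, height = 256,
                        radius = 80, radius_jitter = 5,
                        noise_sd = 0.02,
                        contrast = 0.35,
                        p_second_video = 0.025) {
  if (!is_count(n_patients) || n_patients < 1) stopf("n_patients must be a count >= 1")
  if (!is_fraction(prevalence)) stopf("prevalence must lie in [0,1]")
  if (!is_count(frames_per_video) || frames_per_video < 1) stopf("frames_per_video must be a count >= 1")
  if (!is_fraction(valid_frame_rate)) stopf("valid_frame_rate must lie in [0,1]")
  if (!is.numeric(effect_strength) || effect_strength < 0) stopf("effect_strength must be >= 0")
  if (!is_count(abs(seed))) stopf("seed must be an integer")
  if (width < 32 || height < 32) stopf("frames must be at least 32x32")
  if (radius <= 0 || radius >= min(width, height) / 2) {
    stopf("radius must be positive and fit inside the frame")
  }
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    frames_per_video = as.integer(frames_per_video),
    valid_frame_rate = valid_frame_rate, effect_strength = effect_strength,
    seed = as.integer(seed), width = as.integer(width),
    height = as.integer(height), radius = radius,
    radius_jitter = radius_jitter, noise_sd = noise_sd,
    contrast = contrast, p_second_video = p_second_video
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d patients, prevalence %.3f, %d frames/video\n",
    x$n_patients, x$prevalence, x$frames_per_video))
  cat(sprintf("  valid-frame rate %.2f, effect strength %.2f, seed %d\n",
              x$valid_frame_rate, x$effect_strength, x$seed))
  cat(sprintf("  frames %dx%d, magnifier radius %g px (jitter %g)\n",
              x$width, x$height, x$radius, x$radius_jitter))
  invisible(x)
}

# Recursive random binary branching vessel tree in unit-disk coordinates.
# Each element is a list(points = n x 2 matrix, width, phase); widths are
# relative to the fundus radius, phases seed the tortuosity sinusoid.
make_vessel_tree <- function(disc_center, n_trunks = 5, depth = 3) {
  segs <- list()
  grow <- function(origin, angle, len, width, level) {
    jitter <- stats::runif(1, -0.45, 0.45)
    angle <- angle + jitter
    end <- origin + len * c(cos(angle), sin(angle))
    r <- sqrt(sum(end^2))
    if (r > 0.97) end <- end * (0.97 / r)
    segs[[length(segs) + 1L]] <<- list(
      points = rbind(origin, end),
      width = width,
      phase = stats::runif(1, 0, 2 * pi)
    )
    if (level < depth) {
      for (s in c(-1, 1)) {
        grow(end, angle + s * stats::runif(1, 0.2, 0.6),
             len * stats::runif(1, 0.6, 0.8), width * 0.75, level + 1)
      }
    }
  }
  base_angle <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(n_trunks)) {
    ang <- base_angle + 2 * pi * (k - 1) / n_trunks + stats::runif(1, -0.3, 0.3)
    grow(disc_center, ang, stats::runif(1, 0.3, 0.4), 0.022, 1)
  }
  segs
}

#' Draw one synthetic eye phantom
#'
#' Deterministically derives a patient's ground-truth eye model from a
#' cohort spec and patient index: ROP status (Bernoulli at the spec's
#' prevalence), an optic-disc analog, a branching vessel tree in unit-disk
#' coordinates, and -- for positive eyes only -- a demarcation-ridge arc
#' plus tortuosity and dilation gains scaled by `effect_strength`.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index 1-based patient index, `<= spec$n_patients`.
#' @return an object of class `eye_phantom` with fields `patient_id`,
#'   `rop_status` (0/1), `disc_center`, `vessel_tree`, `ridge_arc`
#'   (NULL for negatives), `tortuosity_gain`, `dilation_gain`.
#' @export
make_phantom <- function(spec, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is_count(patient_index) || patient_index < 1 || patient_index > spec$n_patients) {
    stopf("patient_index must be in 1..n_patients (%d)", spec$n_patients)
  }
  with_seed(child_seed(spec$seed, 11L, patient_index), {
    rop <- as.integer(stats::runif(1) < spec$prevalence)
    disc_angle <- stats::runif(1, 0, 2 * pi)
    disc_center <- 0.4 * c(cos(disc_angle), sin(disc_angle))
    tree <- make_vessel_tree(disc_center)
    ridge <- NULL
    tort <- 1
    dil <- 1
    if (rop == 1L) {
      ridge <- list(
        center_angle = stats::runif(1, 0, 2 * pi),
        width = stats::runif(1, pi / 3, 2 * pi / 3),
        radial_pos = stats::runif(1, 0.7, 0.9),
        strength = spec$effect_strength
      )
      tort <- 1 + 0.30 * spec$effect_strength
      dil <- 1 + 0.25 * spec$effect_strength
    }
    structure(list(
      patient_id = sprintf("P%04d", patient_index),
      rop_status = rop,
      disc_center = disc_center,
      vessel_tree = tree,
      ridge_arc = ridge,
      tortuosity_gain = tort,
      dilation_gain = dil
    ), class = "eye_phantom")
  })
}

#' @export
print.eye_phantom <- function(x, ...) {
  cat(sprintf("Eye phantom %s: %s, %d vessel segments%s\n",
              x$patient_id,
              if (x$rop_status == 1) "ROP positive" else "ROP negative",
              length(x$vessel_tree),
              if (is.null(x$ridge_arc)) "" else
                sprintf(", ridge arc at %.2f R", x$ridge_arc$radial_pos)))
  invisible(x)
}
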