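test_that("cohort spec validates its fields", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(prevalence = 1.2), "prevalence")
  expect_error(cohort_spec(frames_per_video = 0), "frames_per_video")
  expect_error(cohort_spec(effect_strength = -1), "effect_strength")
  expect_error(cohort_spec(radius = 200, width = 256), "radius")
})

test_that("phantom ROP status honors degenerate and intermediate prevalence", {
  s0 <- cohort_spec(n_patients = 20, prevalence = 0, seed = 1)
  s1 <- cohort_spec(n_patients = 20, prevalence = 1, seed = 1)
  for (i in c(1, 7, 20)) {
    p0 <- make_phantom(s0, i)
    p1 <- make_phantom(s1, i)
    expect_identical(p0$rop_status, 0L)
    expect_null(p0$ridge_arc)
    expect_identical(p1$rop_status, 1L)
    expect_false(is.null(p1$ridge_arc))
  }
  # binomial check at the study prevalence: fraction within 3 SE of 0.295
  sp <- cohort_spec(n_patients = 1000, prevalence = 0.295, seed = 7)
  frac <- mean(vapply(seq_len(1000),
                      function(i) make_phantom(sp, i)$rop_status, integer(1)))
  se <- sqrt(0.295 * (1 - 0.295) / 1000)
  expect_lt(abs(frac - 0.295), 3 * se)
})

test_that("phantom structure satisfies its invariants and is deterministic", {
  sp <- cohort_spec(n_patients = 10, prevalence = 0.5, seed = 3)
  for (i in 1:10) {
    ph <- make_phantom(sp, i)
    expect_identical(!is.null(ph$ridge_arc), ph$rop_status == 1L)
    if (ph$rop_status == 0L) {
      expect_equal(ph$tortuosity_gain, 1)
      expect_equal(ph$dilation_gain, 1)
    } else {
      expect_gte(ph$tortuosity_gain, 1)
      expect_gte(ph$dilation_gain, 1)
    }
    for (seg in ph$vessel_tree) {
      expect_true(all(sqrt(rowSums(seg$points^2)) <= 1))
    }
  }
  expect_identical(make_phantom(sp, 4), make_phantom(sp, 4))
  expect_error(make_phantom(sp, 11), "patient_index")
})

test_that("frame truth derives validity from circle presence and artifact", {
  expect_identical(frame_truth(TRUE, 100, 100, 80, "none")$validity, "valid")
  expect_identical(frame_truth(TRUE, 100, 100, 80, "blur")$validity, "invalid")
  expect_identical(frame_truth(TRUE, 5, 100, 80, "partial")$validity, "invalid")
  expect_identical(frame_truth(artifact = "empty")$validity, "invalid")
  expect_false(frame_truth(artifact = "empty")$circle_present)
  expect_error(frame_truth(FALSE, artifact = "none"), "empty")
})

test_that("rendered frames honor the contrast, background and determinism contracts", {
  sp <- cohort_spec(n_patients = 2, prevalence = 1, seed = 5)
  ph <- make_phantom(sp, 1)

  empty <- render_frame(ph, frame_truth(artifact = "empty"), seed = 9)$image
  bg <- 0.04
  expect_lte(max(empty), bg + 3 * sp$noise_sd + 1 / 255)

  tr <- frame_truth(TRUE, 128, 128, 80, "none")
  fr <- render_frame(ph, tr, seed = 9)$image
  g <- to_grayscale(fr)
  X <- matrix(0:255, 256, 256, byrow = TRUE); Y <- matrix(0:255, 256, 256)
  inside <- (X - 128)^2 + (Y - 128)^2 <= 80^2
  expect_gte(mean(g[inside]) - mean(g[!inside]), sp$contrast)

  expect_identical(fr, render_frame(ph, tr, seed = 9)$image)
  expect_false(identical(fr, render_frame(ph, tr, seed = 10)$image))

  glare <- render_frame(ph, frame_truth(TRUE, 128, 128, 80, "glare"),
                        seed = 9)$image
  expect_gt(sum(glare == 1), 50)

  blur <- render_frame(ph, frame_truth(TRUE, 128, 128, 80, "blur"),
                       seed = 9)$image
  lap_var <- function(m) {
    s <- nrow(m)
    stats::var(as.numeric(m[2:(s - 1), 2:(s - 1)] * 4 - m[1:(s - 2), 2:(s - 1)] -
                            m[3:s, 2:(s - 1)] - m[2:(s - 1), 1:(s - 2)] -
                            m[2:(s - 1), 3:s]))
  }
  expect_lt(lap_var(to_grayscale(blur)), lap_var(to_grayscale(fr)) / 2)

  expect_error(render_frame(ph, tr, width = 0), "dimensions|width")
  expect_error(render_frame(ph, frame_truth(TRUE, 128, 128, 140, "none")),
               "true_radius")
})

test_that("positive-eye frames carry the ridge arc and negatives do not", {
  sp <- cohort_spec(n_patients = 2, prevalence = 1, seed = 6,
                    effect_strength = 2)
  sn <- cohort_spec(n_patients = 2, prevalence = 0, seed = 6)
  tr <- frame_truth(TRUE, 128, 128, 80, "none")
  annulus_peak <- function(img) {
    featurize_crop(crop_fundus(img, list(a = 128, b = 128, R = 80)))[["sec_max_med"]]
  }
  pos <- annulus_peak(render_frame(make_phantom(sp, 1), tr, seed = 3)$image)
  neg <- annulus_peak(render_frame(make_phantom(sn, 1), tr, seed = 3)$image)
  expect_gt(pos, neg + 0.05)
})

test_that("cohort generation accounts, labels and reproduces exactly", {
  spec <- cohort_spec(n_patients = 4, frames_per_video = 10, seed = 13,
                      p_second_video = 0)
  co <- generate_cohort(spec)
  expect_length(co$videos, 4)
  expect_identical(nrow(co$frame_truth), 40L)
  expect_identical(nrow(co$patients), 4L)

  all_valid <- generate_cohort(cohort_spec(n_patients = 2,
                                           frames_per_video = 5,
                                           valid_frame_rate = 1, seed = 13))
  expect_true(all(all_valid$frame_truth$validity == "valid"))

  co2 <- generate_cohort(spec)
  expect_identical(co$frame_truth, co2$frame_truth)
  expect_identical(co$patients, co2$patients)
  expect_identical(co$videos[[1]]$source[[1]], co2$videos[[1]]$source[[1]])
})

test_that("PNG stacks round-trip bit-identically and CSVs are written", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 2, frames_per_video = 3, seed = 17,
                      p_second_video = 0)
  mem <- generate_cohort(spec)
  disk <- generate_cohort(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "frame_truth.csv")))
  expect_true(file.exists(file.path(dir, "patients.csv")))
  f_mem <- extract_frames(mem$videos[[1]], 1)
  f_disk <- extract_frames(disk$videos[[1]], 1)
  expect_identical(f_disk[[2]]$pixels, f_mem[[2]]$pixels)
  truth_back <- utils::read.csv(file.path(dir, "frame_truth.csv"))
  expect_identical(nrow(truth_back), nrow(mem$frame_truth))
})

test_that("a pixel-statistic discriminator tracks effect strength monotonically", {
  scores <- vapply(c(0, 1, 2), function(es) {
    sp <- cohort_spec(n_patients = 24, frames_per_video = 3, prevalence = 0.5,
                      effect_strength = es, seed = 31, p_second_video = 0)
    ds <- make_rop_dataset(generate_cohort(sp), sp)
    stat <- vapply(ds$crops,
                   function(cr) featurize_crop(cr)[["sec_max_med"]],
                   numeric(1))
    auroc(stat, ds$labels)
  }, numeric(1))
  expect_true(all(diff(scores) >= -0.02))
  expect_lt(abs(scores[1] - 0.5), 0.2)
  expect_gt(scores[3], 0.9)
})
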