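# Shared fixtures, built once per test run and memoized. Sizes are chosen
# so the whole suite stays desk-scale while every stage sees realistic
# inputs.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small mixed cohort for accounting / truth / screening tests
tiny_cohort <- function() {
  memo("tiny", function() {
    spec <- cohort_spec(n_patients = 4, frames_per_video = 6, seed = 2,
                        p_second_video = 0)
    list(spec = spec, cohort = generate_cohort(spec))
  })
}

# balanced valid/invalid quality dataset (~200 per class) and a model
quality_fixture <- function() {
  memo("quality", function() {
    spec <- cohort_spec(n_patients = 20, frames_per_video = 20,
                        valid_frame_rate = 0.5, seed = 11,
                        p_second_video = 0)
    cohort <- generate_cohort(spec)
    ds <- make_quality_dataset(cohort, spec)
    idx <- seq_along(ds$labels)
    val <- idx[idx %% 4 == 0]
    train <- setdiff(idx, val)
    model <- train_quality_classifier(
      list(crops = ds$crops[train], labels = ds$labels[train]),
      list(crops = ds$crops[val], labels = ds$labels[val]),
      seed = 3)
    list(spec = spec, cohort = cohort, ds = ds, train = train, val = val,
         model = model)
  })
}

# default-condition ROP dataset with patient-disjoint split and a
# calibrated model
rop_fixture <- function() {
  memo("rop", function() {
    spec <- cohort_spec(n_patients = 30, frames_per_video = 20, seed = 21,
                        p_second_video = 0)
    cohort <- generate_cohort(spec)
    ds <- make_rop_dataset(cohort, spec)
    pats <- unique(ds$patient_id)
    val_p <- pats[seq(1, length(pats), by = 5)]
    train <- which(!ds$patient_id %in% val_p)
    val <- which(ds$patient_id %in% val_p)
    model <- train_rop_classifier(rop_subset(ds, train), rop_subset(ds, val),
                                  rop_train_config(seed = 5))
    model <- calibrate_rop_model(model, rop_subset(ds, val))
    list(spec = spec, cohort = cohort, ds = ds, train = train, val = val,
         model = model)
  })
}

# quality + ROP models trained at the 128 px frame scale (radius 40),
# scale-matched to the large screening cohorts rendered at that size.
# The crop descriptors include sharpness terms that are sensitive to the
# capture resolution, so screening models are trained at deployment scale.
scale128_fixture <- function() {
  memo("scale128", function() {
    qspec <- cohort_spec(n_patients = 10, frames_per_video = 12,
                         valid_frame_rate = 0.5, width = 128, height = 128,
                         radius = 40, radius_jitter = 3, seed = 61,
                         p_second_video = 0)
    qds <- make_quality_dataset(generate_cohort(qspec), qspec)
    qi <- seq_along(qds$labels)
    qva <- qi[qi %% 4 == 0]; qtr <- setdiff(qi, qva)
    qm <- train_quality_classifier(
      list(crops = qds$crops[qtr], labels = qds$labels[qtr]),
      list(crops = qds$crops[qva], labels = qds$labels[qva]), seed = 3)
    rspec <- cohort_spec(n_patients = 20, frames_per_video = 12,
                         prevalence = 0.5, width = 128, height = 128,
                         radius = 40, radius_jitter = 3, seed = 62,
                         p_second_video = 0)
    rds <- make_rop_dataset(generate_cohort(rspec), rspec)
    pats <- unique(rds$patient_id)
    val_p <- pats[seq(1, length(pats), by = 5)]
    rtr <- which(!rds$patient_id %in% val_p)
    rva <- which(rds$patient_id %in% val_p)
    rm_ <- train_rop_classifier(rop_subset(rds, rtr), rop_subset(rds, rva),
                                rop_train_config(seed = 5))
    rm_ <- calibrate_rop_model(rm_, rop_subset(rds, rva))
    list(q = qm, r = rm_, ms = magnifier_spec(28, expected_radius = 40,
                                              radius_tolerance = 8))
  })
}

rop_subset <- function(ds, i) {
  list(crops = ds$crops[i], labels = ds$labels[i],
       patient_id = ds$patient_id[i])
}

# draw a clean filled disk (sharp edge) as a grayscale frame
disk_frame <- function(width, height, cx, cy, r, fg = 0.8, bg = 0.05) {
  X <- matrix(0:(width - 1), height, width, byrow = TRUE)
  Y <- matrix(0:(height - 1), height, width)
  m <- matrix(bg, height, width)
  m[(X - cx)^2 + (Y - cy)^2 <= r^2] <- fg
  m
}
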