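#' Data-augmentation settings for ROP training
#'
#' Photometric-plus-geometric augmentation: random rotation, horizontal
#' and vertical flips, and photometric jittering (brightness, contrast,
#' saturation). A spec with all knobs zero/off is the exact identity.
#'
#' @param rotation_max_degrees maximum absolute rotation, in [0,180].
#' @param horizontal_flip,vertical_flip enable random flips.
#' @param jitter named numeric vector of photometric half-widths
#'   (`brightness`, `contrast`, `saturation`), each >= 0.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_max_degrees = 15,
                              horizontal_flip = TRUE,
                              vertical_flip = TRUE,
                              jitter = c(brightness = 0.05, contrast = 0.05,
                                         saturation = 0.05)) {
  if (rotation_max_degrees < 0 || rotation_max_degrees > 180) {
    stopf("rotation_max_degrees must be in [0,180]")
  }
  jit <- c(brightness = 0, contrast = 0, saturation = 0)
  jit[names(jitter)] <- jitter
  if (any(jit < 0)) stopf("jitter half-widths must be >= 0")
  structure(list(rotation_max_degrees = rotation_max_degrees,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 jitter = jit),
            class = "augmentation_spec")
}

#' Rotate a square image about its center
#'
#' Inverse-mapped bilinear rotation; pixels sampled from outside the input
#' are 0. With x rightward and y downward (0-based, center at
#' (s-1)/2), a pixel at offset (dx, dy) from the center moves to offset
#' (-dy, dx) under a +90 degree rotation.
#'
#' @param img square matrix or array.
#' @param degrees rotation angle.
#' @return rotated image, same dimensions.
#' @export
rotate_image <- function(img, degrees) {
  if (degrees == 0) return(img)
  is_mat <- is.matrix(img)
  if (is_mat) img <- array(img, dim = c(dim(img), 1))
  s <- dim(img)[1]
  th <- degrees * pi / 180
  c0 <- (s - 1) / 2
  X <- matrix(0:(s - 1), s, s, byrow = TRUE) - c0
  Y <- matrix(0:(s - 1), s, s) - c0
  # inverse map: source = Rot(-theta) %*% (p - c) + c
  sx <- cos(th) * X + sin(th) * Y + c0
  sy <- -sin(th) * X + cos(th) * Y + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- array(0, dim = dim(img))
  pick <- function(plane, xs, ys) {
    v <- matrix(0, s, s)
    ok <- xs >= 0 & xs < s & ys >= 0 & ys < s
    v[ok] <- plane[cbind(ys[ok] + 1L, xs[ok] + 1L)]
    v
  }
  for (ch in seq_len(dim(img)[3])) {
    pl <- img[, , ch]
    out[, , ch] <-
      pick(pl, x0, y0) * (1 - fx) * (1 - fy) +
      pick(pl, x0 + 1L, y0) * fx * (1 - fy) +
      pick(pl, x0, y0 + 1L) * (1 - fx) * fy +
      pick(pl, x0 + 1L, y0 + 1L) * fx * fy
  }
  if (is_mat) out[, , 1] else out
}

#' Apply a random augmentation to a crop
#'
#' Deterministic for a fixed seed; the all-off spec returns the input
#' unchanged. Output size equals input size.
#'
#' @param crop a `fundus_crop` or image array.
#' @param spec an [augmentation_spec()].
#' @param seed integer seed.
#' @return augmented crop, same kind of object.
#' @export
augment <- function(crop, spec = augmentation_spec(), seed = 1) {
  stopifnot(inherits(spec, "augmentation_spec"))
  identity_spec <- spec$rotation_max_degrees == 0 &&
    !spec$horizontal_flip && !spec$vertical_flip && all(spec$jitter == 0)
  if (identity_spec) return(crop)
  img <- if (inherits(crop, "fundus_crop")) crop$image else crop
  is_mat <- is.matrix(img)
  if (is_mat) img <- array(img, dim = c(dim(img), 1))
  img <- with_seed(seed, {
    if (spec$rotation_max_degrees > 0) {
      ang <- stats::runif(1, -spec$rotation_max_degrees,
                          spec$rotation_max_degrees)
      img <- rotate_image(img, ang)
    }
    if (spec$horizontal_flip && stats::runif(1) < 0.5) {
      img <- img[, dim(img)[2]:1, , drop = FALSE]
    }
    if (spec$vertical_flip && stats::runif(1) < 0.5) {
      img <- img[dim(img)[1]:1, , , drop = FALSE]
    }
    jit <- spec$jitter
    if (any(jit > 0)) {
      b <- stats::runif(1, -jit["brightness"], jit["brightness"])
      ct <- stats::runif(1, -jit["contrast"], jit["contrast"])
      sa <- stats::runif(1, -jit["saturation"], jit["saturation"])
      m <- mean(img)
      img <- (img - m) * (1 + ct) + m + b
      if (dim(img)[3] == 3 && sa != 0) {
        g <- luma(img)
        for (ch in 1:3) img[, , ch] <- g + (img[, , ch] - g) * (1 + sa)
      }
      img <- clamp01(img)
    }
    img
  })
  if (is_mat) img <- img[, , 1]
  if (inherits(crop, "fundus_crop")) {
    crop$image <- img
    crop
  } else {
    img
  }
}

#' Training configuration for the ROP frame classifier
#'
#' @param learning_rate Adam step size (default 0.0001).
#' @param w_pos positive-class loss weight; `NULL` (default) derives it
#'   from the data as `(negatives / positives) * penalty_factor`, the
#'   sensitivity-first convention of penalizing false negatives harder.
#' @param penalty_factor multiplier on the class-ratio weight.
#' @param max_epochs,patience early-stopping control ("train until
#'   convergence").
#' @param seed integer seed.
#' @param augmentation an [augmentation_spec()]; set all knobs off to
#'   disable.
#' @param augment_reps augmented copies of each training crop appended to
#'   the training set.
#' @param input_size classifier input side length.
#' @param hidden hidden units of the [fundus_net()].
#' @return object of class `rop_train_config`.
#' @export
rop_train_config <- function(learning_rate = 0.0001, w_pos = NULL,
                             penalty_factor = 1.5,
                             max_epochs = 4000, patience = 150, seed = 1,
                             augmentation = augmentation_spec(),
                             augment_reps = 1, input_size = 64, hidden = 8) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (!is.null(w_pos) && w_pos < 1) stopf("w_pos must be >= 1")
  structure(list(learning_rate = learning_rate, w_pos = w_pos,
                 penalty_factor = penalty_factor, max_epochs = max_epochs,
                 patience = patience, seed = seed,
                 augmentation = augmentation, augment_reps = augment_reps,
                 input_size = input_size, hidden = hidden),
            class = "rop_train_config")
}

#' Train the binary ROP frame classifier
#'
#' Fits a [fundus_net()] on crop descriptors with the weighted binary
#' cross-entropy loss (higher penalty on false negatives), Adam
#' optimization and early stopping on validation loss, after augmenting the
#' training crops per the config. Patients must be disjoint across train
#' and validation; overlap raises a `patient_leakage` error.
#'
#' @param train,val lists with `crops` (list of crops), `labels` (1 = ROP)
#'   and optionally `patient_id` (character vector, used for the leakage
#'   check).
#' @param config an [rop_train_config()].
#' @return object of class `rop_model` (uncalibrated until
#'   [calibrate_rop_model()] or [fit_temperature()] is applied).
#' @export
train_rop_classifier <- function(train, val, config = rop_train_config()) {
  stopifnot(inherits(config, "rop_train_config"))
  if (length(unique(train$labels)) < 2) {
    stopf("ROP training set must contain both classes")
  }
  if (!is.null(train$patient_id) && !is.null(val$patient_id)) {
    leak <- intersect(unique(train$patient_id), unique(val$patient_id))
    if (length(leak) > 0) {
      stop(structure(class = c("patient_leakage", "error", "condition"),
                     list(message = sprintf(
                       "patient_leakage: %d patient(s) appear in both train and validation (e.g. %s)",
                       length(leak), leak[1]), call = NULL)))
    }
  }
  crops <- lapply(train$crops, downscale_crop, size = config$input_size)
  labels <- train$labels
  if (config$augment_reps > 0) {
    aug_crops <- list()
    aug_labels <- integer(0)
    for (rep_i in seq_len(config$augment_reps)) {
      for (i in seq_along(crops)) {
        aug_crops[[length(aug_crops) + 1L]] <-
          augment(crops[[i]], config$augmentation,
                  seed = child_seed(config$seed, 57L, rep_i, i))
        aug_labels <- c(aug_labels, labels[i])
      }
    }
    crops <- c(crops, aug_crops)
    labels <- c(labels, aug_labels)
  }
  xtr <- featurize_crops(crops)
  xva <- featurize_crops(lapply(val$crops, downscale_crop,
                                size = config$input_size))
  w_pos <- config$w_pos
  if (is.null(w_pos)) {
    w_pos <- max(1, sum(train$labels == 0) / max(1, sum(train$labels == 1)) *
                   config$penalty_factor)
  }
  net <- fundus_net(xtr, labels, xva, val$labels,
                    hidden = config$hidden,
                    learning_rate = config$learning_rate, w_pos = w_pos,
                    max_epochs = config$max_epochs,
                    patience = config$patience, seed = config$seed)
  structure(list(net = net, config = config, w_pos = w_pos,
                 temperature = NULL, val_auroc = net$val_auroc),
            class = "rop_model")
}

#' @export
print.rop_model <- function(x, ...) {
  cat(sprintf("ROP frame classifier (input %dx%d), w_pos %.2f, val AUROC %.3f\n",
              x$config$input_size, x$config$input_size, x$w_pos, x$val_auroc))
  if (is.null(x$temperature)) {
    cat("  uncalibrated (no temperature fitted)\n")
  } else {
    cat(sprintf("  temperature-calibrated, T = %.3f\n", x$temperature$T))
  }
  invisible(x)
}

#' @export
predict.rop_model <- function(object, crops,
                              type = c("prob", "logit", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(crops, "fundus_crop") || (is.array(crops) && !is.list(crops))) {
    crops <- list(crops)
  }
  x <- featurize_crops(lapply(crops, downscale_crop,
                              size = object$config$input_size))
  z <- unname(predict(object$net, x, type = "logit"))
  if (type == "logit") return(z)
  p <- if (is.null(object$temperature)) sigmoid(z) else
    apply_temperature(z, object$temperature)
  if (type == "prob") p else as.integer(p >= threshold)
}

#' Fit a calibration temperature on validation logits
#'
#' Finds the scalar T > 0 minimizing the validation negative log-likelihood
#' of `sigmoid(z / T)` (golden-section search on log T over [0.05, 20]).
#' One scalar is fitted; the ranking of logits -- hence AUROC -- is
#' unchanged by its application.
#'
#' @param val_logits numeric vector of uncalibrated logits.
#' @param val_labels 0/1 labels (both classes required).
#' @return object of class `temperature` with fields `T`, `nll`
#'   (at the fitted T) and `nll_t1` (at T = 1).
#' @export
fit_temperature <- function(val_logits, val_labels) {
  val_labels <- as.numeric(val_labels)
  if (length(unique(val_labels)) < 2) {
    stopf("temperature fitting needs both classes in the validation set")
  }
  nll <- function(logT) {
    p <- sigmoid(val_logits / exp(logT))
    mean(weighted_bce(p, val_labels, 1))
  }
  opt <- stats::optimize(nll, interval = c(log(0.05), log(20)), tol = 1e-8)
  structure(list(T = exp(opt$minimum), nll = opt$objective,
                 nll_t1 = nll(0)),
            class = "temperature")
}

#' @export
print.temperature <- function(x, ...) {
  cat(sprintf("Calibration temperature T = %.4f (val NLL %.4f; %.4f at T=1)\n",
              x$T, x$nll, x$nll_t1))
  invisible(x)
}

#' Apply a calibration temperature to logits
#'
#' @param z numeric logits.
#' @param temperature a [fit_temperature()] object or a positive scalar.
#' @return calibrated probabilities `sigmoid(z / T)`, strictly increasing
#'   in `z`.
#' @export
apply_temperature <- function(z, temperature) {
  T <- if (inherits(temperature, "temperature")) temperature$T else temperature
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T <= 0) {
    stopf("temperature must be a positive scalar")
  }
  sigmoid(z / T)
}

#' Calibrate an ROP model on a validation set
#'
#' @param model an [train_rop_classifier()] model.
#' @param val list with `crops` and `labels`.
#' @return the model with its `temperature` fitted.
#' @export
calibrate_rop_model <- function(model, val) {
  z <- predict(model, val$crops, type = "logit")
  model$temperature <- fit_temperature(z, val$labels)
  model
}
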