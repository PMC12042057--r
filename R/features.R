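# Fixed image descriptors for fundus crops.
#
# Both classifiers operate on a fixed descriptor vector rather than raw
# pixels: radial intensity profile (fundus structure, vignetting, the
# demarcation-ridge band), sector statistics of the 0.7-0.9 R annulus (an
# arc shows up as one bright sector), sharpness and saturation measures
# (blur/glare artifacts), and padding/darkness fractions (partial/empty
# frames). Descriptors are rotation-covariant where the signal is (sector
# max), rotation-invariant elsewhere.

feature_cache <- new.env(parent = emptyenv())

# per-size geometry: radial bin index and sector index per pixel
crop_geometry <- function(s) {
  key <- as.character(s)
  if (!is.null(feature_cache[[key]])) return(feature_cache[[key]])
  c0 <- (s - 1) / 2
  X <- matrix(0:(s - 1), s, s, byrow = TRUE) - c0
  Y <- matrix(0:(s - 1), s, s) - c0
  u <- sqrt(X^2 + Y^2) / (s / 2)
  theta <- atan2(Y, X)
  rbin <- pmin(12L, pmax(1L, ceiling(u * 12)))
  rbin[u > 1] <- NA_integer_
  sector <- pmin(16L, 1L + floor((theta + pi) / (2 * pi) * 16))
  geom <- list(u = u, rbin = rbin, sector = sector,
               inside = u <= 1, annulus = u >= 0.7 & u <= 0.9,
               core = u <= 0.65)
  feature_cache[[key]] <- geom
  geom
}

#' Descriptor vector for a fundus crop
#'
#' @param crop a `fundus_crop`, or a square image array/matrix in [0,1].
#' @return named numeric vector (length 27).
#' @export
featurize_crop <- function(crop) {
  img <- if (inherits(crop, "fundus_crop")) crop$image else crop
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  s <- dim(img)[1]
  if (dim(img)[2] != s) stopf("crops must be square")
  g <- crop_geometry(s)
  gray <- luma(img)
  gin <- gray[g$inside]
  mean_in <- mean(gin)

  # radial intensity profile, 12 bins
  prof <- vapply(1:12, function(b) {
    v <- gray[which(g$rbin == b)]
    if (length(v)) mean(v) else 0
  }, numeric(1))

  # sector means over the ridge-band annulus
  ann_idx <- which(g$annulus)
  sec <- vapply(1:16, function(k) {
    v <- gray[ann_idx[g$sector[ann_idx] == k]]
    if (length(v)) mean(v) else 0
  }, numeric(1))

  # sharpness / texture: 4-neighbor Laplacian
  lap <- matrix(0, s, s)
  lap[2:(s - 1), 2:(s - 1)] <- gray[1:(s - 2), 2:(s - 1)] +
    gray[3:s, 2:(s - 1)] + gray[2:(s - 1), 1:(s - 2)] +
    gray[2:(s - 1), 3:s] - 4 * gray[2:(s - 1), 2:(s - 1)]
  lap_in <- lap[g$inside]

  dark_core <- mean(gray[g$core] < 0.5 * max(mean_in, 0.05))

  c(mean_in = mean_in,
    sd_in = stats::sd(gin),
    corner_mean = mean(gray[!g$inside]),
    frac_saturated = mean(gin > 0.97),
    frac_dark = mean(gin < 0.08),
    lap_var = stats::var(lap_in),
    lap_absmean = mean(abs(lap_in)),
    edge_density = mean(abs(lap_in) > 0.05),
    mean_r = mean(img[, , 1][g$inside]),
    mean_g = mean(img[, , 2][g$inside]),
    mean_b = mean(img[, , 3][g$inside]),
    chroma = mean_in - min(mean(img[, , 1][g$inside]),
                           mean(img[, , 2][g$inside]),
                           mean(img[, , 3][g$inside])),
    dark_core = dark_core,
    sec_max_med = max(sec) - stats::median(sec),
    sec_sd = stats::sd(sec),
    stats::setNames(prof, paste0("rprof_", 1:12)))
}

# Batch featurization: list of crops -> matrix (n x p)
featurize_crops <- function(crops) {
  t(vapply(crops, featurize_crop, featurize_crop(crops[[1]])))
}

#' Downscale a crop to the classifier input size
#'
#' Bilinear resize of the crop image; provenance fields are preserved.
#' @param crop `fundus_crop` or image array.
#' @param size output side length.
#' @return same kind of object as the input.
#' @export
downscale_crop <- function(crop, size = 64) {
  img <- if (inherits(crop, "fundus_crop")) crop$image else crop
  if (dim(img)[1] == size && dim(img)[2] == size) {
    out_img <- img
  } else if (is.matrix(img)) {
    out_img <- EBImage::imageData(EBImage::resize(img, w = size, h = size,
                                                  filter = "bilinear"))
  } else {
    out_img <- array(0, dim = c(size, size, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) {
      out_img[, , ch] <- EBImage::imageData(
        EBImage::resize(img[, , ch], w = size, h = size, filter = "bilinear"))
    }
  }
  if (inherits(crop, "fundus_crop")) {
    crop$image <- out_img
    crop
  } else {
    out_img
  }
}
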