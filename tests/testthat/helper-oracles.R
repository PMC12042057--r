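# Independent oracles, deliberately brute-force.

# Exhaustive circular Hough accumulator: for every integer center on the
# frame and every radius in [rmin, rmax], count the edge pixels whose
# rounded distance equals the radius. O(width * height * edges); direct
# per-center counting, no stamping.
brute_force_hough <- function(edges, width, height, rmin, rmax) {
  radii <- rmin:rmax
  best <- list(votes = -1L)
  for (a in 0:(width - 1)) {
    dx2 <- (edges$x - a)^2
    for (b in 0:(height - 1)) {
      d <- floor(sqrt(dx2 + (edges$y - b)^2) + 0.5)
      d <- d[d >= rmin & d <= rmax]
      if (length(d) == 0) next
      cnt <- tabulate(d - rmin + 1L, nbins = length(radii))
      m <- max(cnt)
      if (m > best$votes) {
        best <- list(a = a, b = b, R = radii[which.max(cnt)], votes = m)
      }
    }
  }
  best
}

# All-pairs concordance AUROC with ties counted one half.
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# edge map identical in definition to the package's internal extractor
oracle_edges <- function(gray, threshold = 0.08) {
  h <- nrow(gray); w <- ncol(gray)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  idx <- which(mag > threshold)
  data.frame(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# report to one decimal, half-up (the reporting convention for percentages)
round_ref <- function(x) floor(x * 10 + 0.5) / 10

# 10-equal-width-bin expected calibration error
ece10 <- function(prob, labels) {
  bins <- pmin(10L, pmax(1L, ceiling(prob * 10)))
  err <- 0
  for (b in 1:10) {
    i <- which(bins == b)
    if (length(i) == 0) next
    err <- err + length(i) / length(prob) * abs(mean(prob[i]) - mean(labels[i]))
  }
  err
}
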