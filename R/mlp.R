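#' Weighted binary cross-entropy loss
#'
#' `-(w_pos * y * log(p) + (1 - y) * log(1 - p))`, elementwise. The weight
#' multiplies only the positive-label term, so raising `w_pos` penalizes
#' false negatives more heavily while leaving the negative term untouched;
#' `w_pos = 1` recovers standard binary cross-entropy. Probabilities are
#' clamped to (0, 1) before the logs.
#'
#' @param p predicted probabilities in (0,1) (clamped at 1e-12).
#' @param y binary labels (0/1).
#' @param w_pos positive-class weight, >= 1.
#' @return numeric vector of losses, >= 0.
#' @examples
#' weighted_bce(0.8, 1, w_pos = 2)  # -2*log(0.8) = 0.4463
#' @export
weighted_bce <- function(p, y, w_pos = 1) {
  if (any(is.na(p)) || any(is.na(y))) stopf("NaN/NA inputs to weighted_bce")
  if (any(w_pos < 1)) stopf("w_pos must be >= 1")
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(w_pos * y * log(p) + (1 - y) * log(1 - p))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass of the single-hidden-layer net; returns logits.
net_forward <- function(par, X) {
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, `+`))
  drop(H %*% par$W2) + par$b2
}

#' Fit a compact neural frame classifier
#'
#' A single-hidden-layer (tanh) neural network on the fixed crop
#' descriptors of [featurize_crop()], trained full-batch with Adam on the
#' weighted binary cross-entropy loss, with early stopping on validation
#' loss. Features are standardized by training-set mean/sd. Training is a
#' pure function of the seed: identical inputs and config give identical
#' weights and logs.
#'
#' @param x,y training feature matrix (n x p) and 0/1 labels.
#' @param x_val,y_val validation set used for early stopping.
#' @param hidden hidden units.
#' @param learning_rate Adam step size.
#' @param w_pos positive-class loss weight (>= 1).
#' @param max_epochs,patience early stopping: training halts when the
#'   validation loss has not improved for `patience` epochs, and the best
#'   weights are restored.
#' @param seed integer seed for weight initialization.
#' @return object of class `fundus_net` with the fitted weights, the
#'   standardization, a per-epoch `log` (train/validation loss) and the
#'   validation AUROC.
#' @export
fundus_net <- function(x, y, x_val, y_val, hidden = 8,
                       learning_rate = 0.01, w_pos = 1,
                       max_epochs = 3000, patience = 100, seed = 1) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.numeric(y); y_val <- as.numeric(y_val)
  if (length(unique(y)) < 2) stopf("training set must contain both classes")
  p <- ncol(x); n <- nrow(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  Xv <- sweep(sweep(x_val, 2, center), 2, scale, `/`)

  par <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1),
    b2 = 0
  ))
  adam <- lapply(par, function(w) list(m = w * 0, v = w * 0))
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8

  loss_of <- function(z, yy) mean(weighted_bce(sigmoid(z), yy, w_pos))
  best <- list(loss = Inf, par = par, epoch = 0L)
  log_tr <- numeric(0); log_val <- numeric(0)
  stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    H <- tanh(sweep(Xs %*% par$W1, 2, par$b1, `+`))
    z <- drop(H %*% par$W2) + par$b2
    pr <- sigmoid(z)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    # d(loss)/dz for the weighted BCE
    dz <- (-w_pos * y * (1 - pr) + (1 - y) * pr) / n
    gW2 <- t(H) %*% dz
    gb2 <- sum(dz)
    dH <- (dz %*% t(par$W2)) * (1 - H^2)
    gW1 <- t(Xs) %*% dH
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(par)) {
      adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grads[[nm]]
      adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1^epoch)
      vhat <- adam[[nm]]$v / (1 - b2m^epoch)
      par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
    tl <- loss_of(net_forward(par, Xs), y)
    vl <- loss_of(net_forward(par, Xv), y_val)
    log_tr <- c(log_tr, tl); log_val <- c(log_val, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, par = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  val_logits <- net_forward(best$par, Xv)
  obj <- structure(list(
    par = best$par, center = center, scale = scale,
    feature_names = colnames(x), hidden = hidden,
    config = list(learning_rate = learning_rate, w_pos = w_pos,
                  max_epochs = max_epochs, patience = patience, seed = seed),
    log = data.frame(epoch = seq_along(log_tr), train_loss = log_tr,
                     val_loss = log_val),
    best_epoch = best$epoch,
    val_loss = best$loss,
    val_auroc = if (length(unique(y_val)) < 2) NA_real_ else
      auroc(val_logits, y_val)
  ), class = "fundus_net")
  obj
}

#' @export
predict.fundus_net <- function(object, newdata,
                               type = c("prob", "logit", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  z <- net_forward(object$par, Xs)
  switch(type,
         logit = z,
         prob = sigmoid(z),
         class = as.integer(sigmoid(z) >= threshold))
}

#' @export
print.fundus_net <- function(x, ...) {
  cat(sprintf(
    "Fundus frame classifier: %d features -> %d hidden -> 1 (tanh/logistic)\n",
    length(x$center), x$hidden))
  cat(sprintf("  trained %d epochs (best %d), w_pos = %.2f, val loss %.4f, val AUROC %.3f\n",
              nrow(x$log), x$best_epoch, x$config$w_pos, x$val_loss,
              x$val_auroc))
  invisible(x)
}

#' @export
summary.fundus_net <- function(object, ...) {
  print(object)
  cat("Largest-magnitude first-layer feature weights:\n")
  w <- sqrt(rowSums(object$par$W1^2))
  names(w) <- object$feature_names
  print(round(sort(w, decreasing = TRUE)[1:min(8, length(w))], 3))
  invisible(object)
}

#' @export
plot.fundus_net <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l",
                 xlab = "epoch", ylab = "weighted BCE loss",
                 ylim = range(c(x$log$train_loss, x$log$val_loss)), ...)
  graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
coef.fundus_net <- function(object, ...) {
  object$par
}
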