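# Window classifier: a small 1-D convolutional network over 42-sample x
# 8-channel sensor windows, deciding whether an exercise window was executed
# correctly. Implemented directly in base R: the convolution is unrolled
# into an im2col matrix so forward and backward passes are dense matrix
# products; training is full-batch Adam, single-threaded and fully
# determined by the seed.

#' Describe the window-classifier architecture
#'
#' @param n_filters Number of convolution filters (default 8).
#' @param kernel Kernel length in time steps (default 7, i.e. 1/3 s at
#'   21 Hz).
#' @param epochs Full-batch training epochs (default 200).
#' @param lr Adam learning rate (default 0.02).
#' @return A list of class `window_cnn_architecture`.
#' @export
window_cnn <- function(n_filters = 8L, kernel = 7L, epochs = 200L,
                       lr = 0.02) {
  stopifnot(n_filters >= 1, kernel >= 1, epochs >= 1, lr > 0)
  structure(list(type = "conv1d", n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), epochs = as.integer(epochs),
                 lr = lr),
            class = "window_cnn_architecture")
}

# resolve a channel-group name or explicit channel subset
resolve_channels <- function(channels) {
  if (length(channels) == 1L && channels %in%
      c("full", "no_IMU", "no_flex")) {
    return(switch(channels,
                  full = .rg_channels,
                  no_IMU = .rg_flex_channels,
                  no_flex = .rg_imu_channels))
  }
  bad <- setdiff(channels, .rg_channels)
  if (length(bad))
    stop("unknown channel(s) or channel group: ",
         paste(bad, collapse = ", "), call. = FALSE)
  .rg_channels[.rg_channels %in% channels]   # fixed canonical order
}

# unroll (N, T, C) windows into the (N * T_out, kernel * C) im2col matrix
.im2col <- function(x, kernel) {
  n <- dim(x)[1L]; T_ <- dim(x)[2L]; C <- dim(x)[3L]
  t_out <- T_ - kernel + 1L
  if (t_out < 1L)
    stop("windows shorter than the convolution kernel", call. = FALSE)
  out <- matrix(0, n * t_out, kernel * C)
  for (c in seq_len(C)) for (o in seq_len(kernel))
    out[, (c - 1L) * kernel + o] <-
      as.vector(t(x[, o:(o + t_out - 1L), c, drop = TRUE]))
  list(m = out, t_out = t_out)
}

.forward <- function(Xu, grp, t_out, par) {
  Z <- sweep(Xu %*% par$W1, 2L, par$b1, "+")
  H <- pmax(Z, 0)
  P <- rowsum(H, grp, reorder = FALSE) / t_out
  logits <- drop(P %*% par$w2) + par$b2
  list(Z = Z, H = H, P = P, logits = logits, p = plogis(logits))
}

#' Train the window classifier
#'
#' Fits a binary (correct / incorrect execution) 1-D convolutional
#' classifier on labelled sensor windows. Channel masking is applied by
#' dropping the masked channels from the input before training; prediction
#' applies the identical mask, so values on excluded channels can never
#' influence the output. Channels are standardized with training-set means
#' and SDs. Training is full-batch Adam on the binary cross-entropy;
#' the loss trace is stored and a warning is raised if the final loss
#' exceeds the initial one.
#'
#' @param dataset A [build_dataset()] result (its `"train"` part is used
#'   unless `part = "all"`).
#' @param channels Channel mask: `"full"`, `"no_IMU"`, `"no_flex"`, or an
#'   explicit subset of channel names.
#' @param architecture A [window_cnn()] descriptor.
#' @param seed Integer seed fixing the weight initialization; with
#'   single-threaded execution this makes training deterministic.
#' @param part `"train"` (default) or `"all"`: which part of the dataset to
#'   fit on.
#' @return An object of class `window_classifier` with `predict` and
#'   `print` methods.
#' @export
#' @examples
#' ds <- build_dataset(lapply(exercise_catalog()[1:2], exercise_signal_model),
#'                     n_per_class = 3, duration_seconds = 4, seed = 1)
#' clf <- fit_window_classifier(ds, seed = 1,
#'                              architecture = window_cnn(epochs = 50))
#' clf
fit_window_classifier <- function(dataset, channels = "full",
                                  architecture = window_cnn(), seed = 1,
                                  part = c("train", "all")) {
  stopifnot(inherits(dataset, "window_dataset"),
            inherits(architecture, "window_cnn_architecture"))
  part <- match.arg(part)
  if (part == "train") dataset <- dataset_part(dataset, "train")
  chans <- resolve_channels(channels)
  x <- dataset$x[, , chans, drop = FALSE]
  y <- dataset$y
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("training data must contain both correctness classes",
         call. = FALSE)
  n <- dim(x)[1L]; T_ <- dim(x)[2L]; C <- dim(x)[3L]

  mu <- apply(x, 3L, mean)
  sg <- apply(x, 3L, sd); sg[sg == 0] <- 1
  for (c in seq_len(C)) x[, , c] <- (x[, , c] - mu[c]) / sg[c]

  ic <- .im2col(x, architecture$kernel)
  grp <- rep(seq_len(n), each = ic$t_out)
  ytgt <- as.numeric(y == "correct")

  k <- architecture$kernel; f <- architecture$n_filters
  par <- with_seed(seed, list(
    W1 = matrix(rnorm(k * C * f, 0, sqrt(2 / (k * C))), k * C, f),
    b1 = numeric(f),
    w2 = matrix(rnorm(f, 0, sqrt(2 / f)), f, 1L),
    b2 = 0))

  # Adam state
  mstate <- lapply(par, function(z) z * 0)
  vstate <- lapply(par, function(z) z * 0)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8; lr <- architecture$lr
  loss <- numeric(architecture$epochs)
  for (e in seq_len(architecture$epochs)) {
    fw <- .forward(ic$m, grp, ic$t_out, par)
    pr <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    loss[e] <- -mean(ytgt * log(pr) + (1 - ytgt) * log(1 - pr))
    dlog <- matrix((fw$p - ytgt) / n, ncol = 1L)
    grad <- list(
      W1 = NULL, b1 = NULL,
      w2 = crossprod(fw$P, dlog),
      b2 = sum(dlog))
    dP <- dlog %*% t(par$w2)
    dZ <- (dP[grp, , drop = FALSE] / ic$t_out) * (fw$Z > 0)
    grad$W1 <- crossprod(ic$m, dZ)
    grad$b1 <- colSums(dZ)
    for (nm in names(par)) {
      mstate[[nm]] <- b1a * mstate[[nm]] + (1 - b1a) * grad[[nm]]
      vstate[[nm]] <- b2a * vstate[[nm]] + (1 - b2a) * grad[[nm]]^2
      mh <- mstate[[nm]] / (1 - b1a^e)
      vh <- vstate[[nm]] / (1 - b2a^e)
      par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  if (loss[length(loss)] > loss[1L])
    warning("training loss did not decrease over epochs", call. = FALSE)

  structure(list(par = par, channels = chans, channel_mask = channels,
                 architecture = architecture, center = mu, scale = sg,
                 window_samples = T_, seed = seed, loss = loss,
                 classes = c("correct", "incorrect"), trained = TRUE),
            class = "window_classifier")
}

#' @export
print.window_classifier <- function(x, ...) {
  a <- x$architecture
  cat("<window_classifier> conv1d(", a$n_filters, " filters, kernel ",
      a$kernel, ") on ", length(x$channels), "/8 channels [",
      paste(x$channels, collapse = ", "), "]\n", sep = "")
  cat("  input ", x$window_samples, " x ", length(x$channels),
      ", trained ", a$epochs, " epochs (final loss ",
      sprintf("%.4f", x$loss[length(x$loss)]), "), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# coerce the accepted newdata forms to an (N, T, 8) array
.as_window_array <- function(newdata) {
  if (inherits(newdata, "window_dataset")) return(newdata$x)
  if (inherits(newdata, "sensor_windows") ||
      (is.list(newdata) && !is.array(newdata))) {
    n <- length(newdata)
    if (n == 0L) stop("no windows to predict on", call. = FALSE)
    x <- array(0, c(n, nrow(newdata[[1L]]), length(.rg_channels)),
               dimnames = list(NULL, NULL, .rg_channels))
    for (j in seq_len(n)) x[j, , ] <- newdata[[j]]
    return(x)
  }
  if (is.matrix(newdata)) {
    x <- array(newdata, c(1L, nrow(newdata), ncol(newdata)))
    dimnames(x) <- list(NULL, NULL, colnames(newdata))
    return(x)
  }
  if (is.array(newdata) && length(dim(newdata)) == 3L) return(newdata)
  stop("unsupported `newdata` for window prediction", call. = FALSE)
}

#' Predict correctness of sensor windows
#'
#' @param object A trained [fit_window_classifier()] model.
#' @param newdata A `window_dataset`, a [make_windows()] result, a single
#'   window matrix, or an (N, T, 8) array.
#' @param type `"class"` for correctness labels, `"prob"` for the
#'   probability of correct execution.
#' @param ... Unused.
#' @return Factor of `"correct"`/`"incorrect"` or numeric probabilities.
#' @export
predict.window_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained))
    stop("classifier has not been trained", call. = FALSE)
  x <- .as_window_array(newdata)
  if (dim(x)[2L] != object$window_samples)
    stop("windows have ", dim(x)[2L], " samples; classifier expects ",
         object$window_samples, call. = FALSE)
  if (is.null(dimnames(x)[[3L]])) {
    if (dim(x)[3L] != length(.rg_channels))
      stop("unnamed window channels must cover all 8 channels",
           call. = FALSE)
    dimnames(x)[[3L]] <- .rg_channels
  }
  missing_ch <- setdiff(object$channels, dimnames(x)[[3L]])
  if (length(missing_ch))
    stop("windows lack channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  x <- x[, , object$channels, drop = FALSE]
  for (c in seq_along(object$channels))
    x[, , c] <- (x[, , c] - object$center[c]) / object$scale[c]
  ic <- .im2col(x, object$architecture$kernel)
  grp <- rep(seq_len(dim(x)[1L]), each = ic$t_out)
  p <- .forward(ic$m, grp, ic$t_out, object$par)$p
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, "correct", "incorrect"), object$classes)
}

#' Save / load a window classifier checkpoint
#'
#' The checkpoint is a self-describing JSON file holding the architecture
#' descriptor, trained weights, channel mask, standardization constants and
#' training seed; `load_classifier()` restores a model whose predictions
#' are identical to the saved one's.
#'
#' @param classifier A trained [fit_window_classifier()] model.
#' @param path Checkpoint file path.
#' @return `save_classifier()` invisibly returns `path`;
#'   `load_classifier()` returns the restored `window_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "window_classifier"))
  obj <- list(
    architecture = unclass(classifier$architecture),
    channel_mask = classifier$channel_mask,
    channels = classifier$channels,
    window_samples = classifier$window_samples,
    seed = classifier$seed,
    center = classifier$center, scale = classifier$scale,
    classes = classifier$classes,
    weights = list(W1 = classifier$par$W1, b1 = classifier$par$b1,
                   w2 = as.vector(classifier$par$w2),
                   b2 = classifier$par$b2),
    final_loss = classifier$loss[length(classifier$loss)])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- do.call(window_cnn, obj$architecture[c("n_filters", "kernel",
                                                 "epochs", "lr")])
  par <- list(W1 = matrix(obj$weights$W1, arch$kernel *
                            length(obj$channels), arch$n_filters,
                          byrow = FALSE),
              b1 = as.numeric(obj$weights$b1),
              w2 = matrix(as.numeric(obj$weights$w2), ncol = 1L),
              b2 = as.numeric(obj$weights$b2))
  structure(list(par = par, channels = obj$channels,
                 channel_mask = obj$channel_mask, architecture = arch,
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 window_samples = obj$window_samples, seed = obj$seed,
                 loss = obj$final_loss, classes = obj$classes,
                 trained = TRUE),
            class = "window_classifier")
}
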