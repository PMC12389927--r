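# Seeded generators for labelled glove/IMU exercise streams.
#
# Signal family: every exercise has a deterministic multichannel template
# built from class-specific sinusoids (fundamental + second harmonic with
# exercise-and-channel-specific phases) plus a motion component common to all
# exercises; i.i.d. Gaussian noise is added per channel. The fraction of
# class-discriminative energy carried by the IMU channels is the
# `imu_signal_share` knob: with the default (0.75) a classifier using only
# IMU channels must beat one using only flex channels, mirroring the
# sensor-ablation finding the harness is built to study.

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Describe the synthetic signal signature of one exercise
#'
#' Bundles the parameters of the synthetic motion model for a single
#' exercise: its fundamental tempo, per-channel amplitudes (ADC counts for
#' the flex channels, m/s^2 for the accelerometer, deg/s for the gyroscope),
#' the share of class-discriminative signal energy carried by the six IMU
#' channels, and the per-channel relative noise level.
#'
#' @param exercise_id Exercise identifier; one of [exercise_catalog()] (other
#'   identifiers are allowed but then `base_frequency` must be given).
#' @param base_frequency Fundamental movement tempo in Hz; default
#'   `0.4 + 0.15 * k` for the k-th catalogue exercise (0.55-1.6 Hz).
#' @param amplitude Named list of channel amplitudes; defaults: flex 600 ADC
#'   counts about mid-range 2048, accelerometer 3 m/s^2 about gravity on
#'   `az`, gyroscope 60 deg/s.
#' @param imu_signal_share Fraction in `[0, 1]` of class-discriminative
#'   energy carried by the IMU channels (default 0.75; values above 0.5 make
#'   the IMU the dominant feature set).
#' @param noise_sd Noise standard deviation relative to each channel's
#'   amplitude (default 0.35).
#' @return An object of class `exercise_signal_model`.
#' @export
exercise_signal_model <- function(exercise_id,
                                  base_frequency = NULL,
                                  amplitude = list(flex = 600, accel = 3,
                                                   gyro = 60),
                                  imu_signal_share = 0.75,
                                  noise_sd = 0.35) {
  k <- match(exercise_id, .rg_exercises)
  if (is.null(base_frequency)) {
    if (is.na(k))
      stop("`base_frequency` must be given for exercises outside the ",
           "default catalogue", call. = FALSE)
    base_frequency <- 0.4 + 0.15 * k
  }
  if (imu_signal_share < 0 || imu_signal_share > 1)
    stop("`imu_signal_share` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(exercise_id = exercise_id,
                 class_index = if (is.na(k)) 0L else k,
                 base_frequency = base_frequency,
                 amplitude = amplitude,
                 imu_signal_share = imu_signal_share,
                 noise_sd = noise_sd),
            class = "exercise_signal_model")
}

# deterministic per-(exercise, channel) phases, independent of the RNG
.template_phases <- function(model) {
  k <- if (model$class_index > 0L) model$class_index else
    sum(utf8ToInt(as.character(model$exercise_id)))
  ch <- seq_along(.rg_channels)
  list(phi = ((k * 2.399963) + ch * 1.246979) %% (2 * pi),
       psi = ((k * 0.761 + 1.1) + ch * 2.015) %% (2 * pi))
}

# normalized (unit-amplitude) channel signals; distortion applies to the
# class-discriminative component only
.template_signal <- function(model, t, tempo = 1, damp = 1, phase = NULL) {
  ph <- .template_phases(model)
  s <- model$imu_signal_share
  gain <- ifelse(.rg_channels %in% .rg_imu_channels, sqrt(s), sqrt(1 - s))
  f <- model$base_frequency * tempo
  common <- sin(2 * pi * 0.8 * t)           # shared across exercises
  out <- matrix(0, length(t), length(.rg_channels),
                dimnames = list(NULL, .rg_channels))
  for (j in seq_along(.rg_channels)) {
    phi <- if (is.null(phase)) ph$phi[j] else phase[j]
    psi <- if (is.null(phase)) ph$psi[j] else phase[j] + 2.015
    disc <- sin(2 * pi * f * t + phi) + 0.5 * sin(2 * pi * 2 * f * t + psi)
    out[, j] <- damp * gain[j] * disc + 0.6 * common
  }
  out
}

# map normalized signals to physical channel units
.scale_channels <- function(norm, model) {
  amp <- model$amplitude
  df <- data.frame(
    flex_middle = 2048 + amp$flex * norm[, "flex_middle"],
    flex_thumb  = 2048 + amp$flex * norm[, "flex_thumb"],
    ax = amp$accel * norm[, "ax"],
    ay = amp$accel * norm[, "ay"],
    az = 9.81 + amp$accel * norm[, "az"],
    gx = amp$gyro * norm[, "gx"],
    gy = amp$gyro * norm[, "gy"],
    gz = amp$gyro * norm[, "gz"])
  for (ch in .rg_flex_channels)
    df[[ch]] <- as.integer(pmin(pmax(round(df[[ch]]), 0), .rg_adc_max))
  df
}

#' Simulate one labelled exercise recording
#'
#' Generates a seeded synthetic glove/IMU stream for one exercise. A
#' `"correct"` execution is the exercise template plus channel noise; an
#' `"incorrect"` execution corrupts the class-discriminative component of
#' the movement by one of three seeded distortions -- tempo halving,
#' amplitude damping (x 0.4), or phase scrambling -- so the two correctness
#' classes remain separable by construction.
#'
#' With `noise_sd = 0` and `correctness = "correct"` the output is the
#' noiseless exercise template and does not depend on the seed.
#'
#' @param model An [exercise_signal_model()].
#' @param correctness `"correct"` or `"incorrect"`.
#' @param duration_seconds Recording length in seconds; must cover at least
#'   one 2-s window.
#' @param seed Integer seed; the same seed reproduces the stream exactly.
#' @param sampling_rate Sampling rate in Hz (default 21).
#' @return A [sensor_stream()] of `round(duration_seconds * sampling_rate)`
#'   samples carrying the exercise and correctness labels.
#' @export
#' @examples
#' s <- simulate_exercise_stream(exercise_signal_model("fist_open_close"),
#'                               duration_seconds = 10, seed = 7)
#' s
simulate_exercise_stream <- function(model,
                                     correctness = c("correct", "incorrect"),
                                     duration_seconds = 10,
                                     seed = 1,
                                     sampling_rate = 21) {
  stopifnot(inherits(model, "exercise_signal_model"))
  correctness <- match.arg(correctness)
  if (duration_seconds < 2)
    stop("`duration_seconds` must cover at least one 2-s window",
         call. = FALSE)
  n <- round(duration_seconds * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  with_seed(seed, {
    tempo <- 1; damp <- 1; phase <- NULL
    if (correctness == "incorrect") {
      mode <- sample(c("tempo_halving", "amplitude_damping",
                       "phase_scrambling"), 1L)
      if (mode == "tempo_halving") tempo <- 0.5
      if (mode == "amplitude_damping") damp <- 0.4
      if (mode == "phase_scrambling")
        phase <- runif(length(.rg_channels), 0, 2 * pi)
    }
    norm <- .template_signal(model, t, tempo = tempo, damp = damp,
                             phase = phase)
    if (model$noise_sd > 0)
      norm <- norm + matrix(rnorm(length(norm), 0, model$noise_sd),
                            nrow(norm), ncol(norm))
    df <- .scale_channels(norm, model)
    sensor_stream(cbind(data.frame(t = t), df),
                  sampling_rate = sampling_rate,
                  exercise_label = model$exercise_id,
                  correctness_label = correctness)
  })
}

#' Build a labelled window dataset with a stratified train/test split
#'
#' Simulates correct and incorrect recordings for a set of exercises,
#' segments them into classifier windows, and splits the windows into
#' train/test sets stratified by (exercise, correctness) class so class
#' balance is preserved to within one window per class.
#'
#' @param models List of [exercise_signal_model()]s (default: one per
#'   catalogue exercise with default parameters).
#' @param n_per_class Recordings per (exercise, correctness) class (>= 2).
#' @param duration_seconds Length of each recording (default 8 s).
#' @param seed Master seed; per-stream seeds and the split are derived from
#'   it, so the whole dataset is reproducible.
#' @param train_frac Training fraction of the stratified split (default 0.7).
#' @param window_seconds,hop_samples Passed to [make_windows()].
#' @return An object of class `window_dataset`: list with the window array
#'   `x` (n x 42 x 8), correctness labels `y`, exercise labels `exercise`,
#'   split membership `split` (`"train"`/`"test"`), and the generation
#'   parameters.
#' @export
build_dataset <- function(models = lapply(exercise_catalog(),
                                          exercise_signal_model),
                          n_per_class = 10, duration_seconds = 8, seed = 1,
                          train_frac = 0.7, window_seconds = 2,
                          hop_samples = 21L) {
  if (length(models) < 2L)
    stop("at least 2 exercise classes are required", call. = FALSE)
  if (n_per_class < 2)
    stop("`n_per_class` must be at least 2", call. = FALSE)
  with_seed(seed, {
    stream_seeds <- sample.int(.Machine$integer.max,
                               length(models) * 2L * n_per_class)
    xs <- list(); ys <- character(0); exs <- character(0)
    i <- 0L
    for (m in models) for (corr in c("correct", "incorrect"))
      for (r in seq_len(n_per_class)) {
        i <- i + 1L
        s <- simulate_exercise_stream(m, corr, duration_seconds,
                                      seed = stream_seeds[i])
        w <- make_windows(s, window_seconds, hop_samples)
        for (win in w) {
          xs[[length(xs) + 1L]] <- win
          ys <- c(ys, corr); exs <- c(exs, m$exercise_id)
        }
      }
    n <- length(xs)
    wlen <- nrow(xs[[1L]])
    x <- array(0, c(n, wlen, length(.rg_channels)),
               dimnames = list(NULL, NULL, .rg_channels))
    for (j in seq_len(n)) x[j, , ] <- xs[[j]]
    split <- character(n)
    for (cls in unique(paste(exs, ys))) {
      idx <- which(paste(exs, ys) == cls)
      n_tr <- round(train_frac * length(idx))
      split[sample(idx, n_tr)] <- "train"
    }
    split[split == ""] <- "test"
    structure(list(x = x, y = factor(ys, c("correct", "incorrect")),
                   exercise = factor(exs),
                   split = factor(split, c("train", "test")),
                   channels = .rg_channels, window_samples = wlen,
                   seed = seed, train_frac = train_frac,
                   n_per_class = n_per_class),
              class = "window_dataset")
  })
}

#' @export
print.window_dataset <- function(x, ...) {
  cat("<window_dataset> ", dim(x$x)[1], " windows of ", x$window_samples,
      " x ", length(x$channels), ", ", nlevels(x$exercise),
      " exercise(s)\n", sep = "")
  print(table(split = x$split, label = x$y))
  invisible(x)
}

#' Subset a window dataset to its train or test part
#'
#' @param dataset A [build_dataset()] result.
#' @param part `"train"` or `"test"`.
#' @return A `window_dataset` restricted to the requested split.
#' @export
dataset_part <- function(dataset, part = c("train", "test")) {
  part <- match.arg(part)
  keep <- dataset$split == part
  out <- dataset
  out$x <- dataset$x[keep, , , drop = FALSE]
  out$y <- droplevels(dataset$y[keep])
  out$y <- factor(as.character(out$y), levels(dataset$y))
  out$exercise <- dataset$exercise[keep]
  out$split <- dataset$split[keep]
  out
}
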