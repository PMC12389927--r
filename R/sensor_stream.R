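#' Construct a sensor stream
#'
#' A sensor stream is the package's container for one glove recording: a
#' time-ordered table with a timestamp column `t` (seconds from stream
#' start), two flex-sensor channels as raw 12-bit ADC counts
#' (`flex_middle`, `flex_thumb`, integers in 0-4095), and six IMU channels
#' (`ax`, `ay`, `az` accelerometer in m/s^2; `gx`, `gy`, `gz` gyroscope in
#' deg/s), sampled at a nominal rate (21 Hz by default).
#'
#' Validation enforces the hard invariants (strictly increasing `t`, ADC
#' counts inside `[0, 4095]`) and warns -- without aborting -- when sample
#' spacing deviates from the nominal period by more than `jitter_tol`
#' (a fraction of the period, default 10%).
#'
#' @param data Data frame with columns `t`, `flex_middle`, `flex_thumb`,
#'   `ax`, `ay`, `az`, `gx`, `gy`, `gz`. Extra columns are dropped.
#' @param sampling_rate Nominal sampling rate in Hz (> 0), default 21.
#' @param exercise_label Exercise identifier or `NA` if unlabelled.
#' @param correctness_label One of `"correct"`, `"incorrect"`, `"unlabeled"`.
#' @param jitter_tol Allowed relative deviation of consecutive sample spacing
#'   from `1/sampling_rate` before a warning is raised.
#' @return An object of class `sensor_stream`.
#' @export
#' @examples
#' s <- sensor_stream(data.frame(
#'   t = (0:41) / 21,
#'   flex_middle = 2048L, flex_thumb = 2048L,
#'   ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0))
#' nrow(s$data)
sensor_stream <- function(data, sampling_rate = 21,
                          exercise_label = NA_character_,
                          correctness_label = c("unlabeled", "correct",
                                                "incorrect"),
                          jitter_tol = 0.10) {
  correctness_label <- match.arg(correctness_label)
  if (!is.data.frame(data))
    stop("`data` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c("t", .rg_channels), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  data <- data[, c("t", .rg_channels), drop = FALSE]

  n <- nrow(data)
  if (n > 0L) {
    if (any(data$t < 0))
      stop("timestamps must be non-negative (first offending row: ",
           which(data$t < 0)[1L], ")", call. = FALSE)
    if (n > 1L && any(diff(data$t) <= 0))
      stop("timestamps must be strictly increasing (first offending row: ",
           which(diff(data$t) <= 0)[1L] + 1L, ")", call. = FALSE)
    for (ch in .rg_flex_channels) {
      bad <- which(data[[ch]] < 0 | data[[ch]] > .rg_adc_max |
                     data[[ch]] != round(data[[ch]]))
      if (length(bad))
        stop("`", ch, "` must hold integer ADC counts in [0, ", .rg_adc_max,
             "] (first offending row: ", bad[1L], ")", call. = FALSE)
      data[[ch]] <- as.integer(data[[ch]])
    }
    if (n > 1L) {
      period <- 1 / sampling_rate
      jitter <- abs(diff(data$t) - period) / period
      if (any(jitter > jitter_tol))
        warning(sum(jitter > jitter_tol), " sample interval(s) deviate from ",
                "the nominal period by more than ", 100 * jitter_tol, "%",
                call. = FALSE)
    }
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         exercise_label = exercise_label,
         correctness_label = correctness_label),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat("<sensor_stream> ", nrow(x$data), " samples @ ", x$sampling_rate,
      " Hz (", sprintf("%.2f", nrow(x$data) / x$sampling_rate), " s)\n",
      sep = "")
  cat("  exercise: ", if (is.na(x$exercise_label)) "<none>" else
    x$exercise_label, " | correctness: ", x$correctness_label, "\n", sep = "")
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) nrow(x$data)

#' Segment a stream into fixed-size classifier windows
#'
#' Cuts a sensor stream into the moving windows fed to the window
#' classifier. The window length in samples is
#' `round(window_seconds * sampling_rate)`; at the device defaults
#' (2 s, 21 Hz) this is exactly 42 samples. Windows start at sample offsets
#' `0, hop_samples, 2 * hop_samples, ...` (0-based, half-open
#' `[start, start + w)`); only fully contained windows are produced, so a
#' stream of `L` samples yields `floor((L - w) / hop) + 1` windows when
#' `L >= w` and none otherwise.
#'
#' @param stream A [sensor_stream()].
#' @param window_seconds Window length in seconds (default 2).
#' @param hop_samples Hop between consecutive window starts, in samples
#'   (default 21, i.e. 1 s / 50% overlap at the device rate).
#' @return An object of class `sensor_windows`: a list of 42 x 8 (generally
#'   `w` x 8) numeric matrices with columns in the fixed order
#'   `flex_middle, flex_thumb, ax, ay, az, gx, gy, gz`, each carrying a
#'   `start_index` attribute; the list carries the stream's labels.
#' @export
#' @examples
#' s <- simulate_exercise_stream(exercise_signal_model("fist_open_close"),
#'                               duration_seconds = 4, seed = 1)
#' w <- make_windows(s)
#' length(w); dim(w[[1]])
make_windows <- function(stream, window_seconds = 2, hop_samples = 21L) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is.numeric(hop_samples) || length(hop_samples) != 1L ||
      hop_samples < 1 || hop_samples != round(hop_samples))
    stop("`hop_samples` must be a positive integer", call. = FALSE)
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stop("`window_seconds` must be positive", call. = FALSE)
  w <- as.integer(round(window_seconds * stream$sampling_rate))
  if (w < 1L)
    stop("window shorter than one sample at this sampling rate",
         call. = FALSE)
  hop <- as.integer(hop_samples)
  L <- nrow(stream$data)
  n_win <- if (L >= w) (L - w) %/% hop + 1L else 0L
  mat <- as.matrix(stream$data[, .rg_channels, drop = FALSE])
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    start <- (i - 1L) * hop            # 0-based
    win <- mat[(start + 1L):(start + w), , drop = FALSE]
    attr(win, "start_index") <- start
    out[[i]] <- win
  }
  structure(out, class = "sensor_windows",
            window_samples = w, hop_samples = hop,
            exercise_label = stream$exercise_label,
            correctness_label = stream$correctness_label)
}

#' @export
print.sensor_windows <- function(x, ...) {
  cat("<sensor_windows> ", length(x), " window(s) of ",
      attr(x, "window_samples"), " x ", length(.rg_channels),
      ", hop ", attr(x, "hop_samples"), "\n", sep = "")
  invisible(x)
}

#' Read / write sensor streams as CSV
#'
#' One row per sample; header columns `t, flex_middle, flex_thumb, ax, ay,
#' az, gx, gy, gz` in any order (columns are mapped by name), optional
#' `exercise_label` and `correctness_label` columns carrying the stream-level
#' labels, UTF-8, `"."` decimal separator. `write_stream_csv()` prints
#' floating-point fields with 17 significant digits so a write/read
#' round-trip reproduces the stream bit-identically.
#'
#' @param path File path.
#' @param sampling_rate,jitter_tol Passed to [sensor_stream()].
#' @return `read_stream_csv()` returns a [sensor_stream()];
#'   `write_stream_csv()` invisibly returns `path`.
#' @export
read_stream_csv <- function(path, sampling_rate = 21, jitter_tol = 0.10) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("t", .rg_channels), names(df))
  if (length(missing_cols))
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (ch in c("t", .rg_imu_channels))   # whole numbers must stay double
    df[[ch]] <- as.numeric(df[[ch]])
  ex <- if ("exercise_label" %in% names(df) && nrow(df))
    as.character(df$exercise_label[1L]) else NA_character_
  corr <- if ("correctness_label" %in% names(df) && nrow(df))
    as.character(df$correctness_label[1L]) else "unlabeled"
  sensor_stream(df[, c("t", .rg_channels), drop = FALSE],
                sampling_rate = sampling_rate, exercise_label = ex,
                correctness_label = corr, jitter_tol = jitter_tol)
}

#' @param stream A [sensor_stream()].
#' @rdname read_stream_csv
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- stream$data
  out <- data.frame(t = sprintf("%.17g", df$t))
  for (ch in .rg_channels)
    out[[ch]] <- if (ch %in% .rg_flex_channels) df[[ch]] else
      sprintf("%.17g", df[[ch]])
  if (!is.na(stream$exercise_label))
    out$exercise_label <- stream$exercise_label
  if (!identical(stream$correctness_label, "unlabeled"))
    out$correctness_label <- stream$correctness_label
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
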