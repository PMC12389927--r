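# Star-based feedback scoring and session scheduling: five exercises per
# session, five minutes each with five-minute breaks in between (no break
# after the last), i.e. 25 min active and 20 min rest; five stars are
# awarded at >= 80% window-classification accuracy.

#' Map an accuracy fraction to a 0-5 star score
#'
#' Five stars are awarded whenever at least 80% of an exercise block's
#' windows are classified as correctly executed -- the built-in margin of
#' error: perfection is not required. Below the 80% threshold, stars fall
#' in equal-width bins of `bin_width` (default 0.16, so the bins reach five
#' stars exactly at 0.80 and the map is monotone and exhaustive on [0, 1]).
#'
#' @param accuracy_fraction Fraction in `[0, 1]` of windows classified
#'   correct within one exercise block.
#' @param five_star_threshold Accuracy at which five stars are awarded
#'   (default 0.80).
#' @param bin_width Width of the sub-five-star accuracy bins (default
#'   `five_star_threshold / 5`).
#' @return An object of class `star_score`: list with `stars` (integer 0-5)
#'   and `accuracy_fraction`.
#' @export
#' @examples
#' accuracy_to_stars(0.80)  # 5 stars
#' accuracy_to_stars(0.50)  # 3 stars
accuracy_to_stars <- function(accuracy_fraction,
                              five_star_threshold = 0.80,
                              bin_width = five_star_threshold / 5) {
  if (!is.numeric(accuracy_fraction) || length(accuracy_fraction) != 1L ||
      is.na(accuracy_fraction) ||
      accuracy_fraction < 0 || accuracy_fraction > 1)
    stop("`accuracy_fraction` must be a single number in [0, 1]",
         call. = FALSE)
  stars <- if (accuracy_fraction >= five_star_threshold) 5L else
    min(4L, as.integer(floor(accuracy_fraction / bin_width + 1e-9)))
  structure(list(stars = stars, accuracy_fraction = accuracy_fraction),
            class = "star_score")
}

#' @export
print.star_score <- function(x, ...) {
  cat("<star_score> ", strrep("*", x$stars), strrep(".", 5L - x$stars),
      " (", x$stars, "/5 at accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy_fraction), ")\n", sep = "")
  invisible(x)
}

#' Plan an exercise session
#'
#' Draws the session's exercises uniformly at random from the catalogue --
#' with replacement by default, so the same exercise can recur within a
#' session -- and attaches the fixed timing structure: each exercise lasts
#' `exercise_minutes` and is followed by `break_minutes` of rest, except
#' the last. With the defaults (5 exercises x 5 min, 5-min breaks) every
#' plan totals 25 min active, 20 min rest, 45 min overall.
#'
#' @param catalog Character vector of available exercises; the standard
#'   catalogue has 8 (a different size warns but is allowed; an empty
#'   catalogue errors).
#' @param seed Integer seed; the same seed reproduces the plan.
#' @param exercises_per_session Number of exercises drawn (default 5).
#' @param exercise_minutes,break_minutes Timing in minutes (defaults 5/5).
#' @param replace Draw with replacement (default `TRUE`).
#' @return An object of class `session_plan`.
#' @export
#' @examples
#' plan_session(seed = 3)
plan_session <- function(catalog = exercise_catalog(), seed = 1,
                         exercises_per_session = 5L, exercise_minutes = 5,
                         break_minutes = 5, replace = TRUE) {
  if (length(catalog) == 0L)
    stop("exercise catalogue is empty", call. = FALSE)
  if (length(catalog) != 8L)
    warning("exercise catalogue has ", length(catalog),
            " entries (standard set has 8)", call. = FALSE)
  if (!replace && exercises_per_session > length(catalog))
    stop("cannot draw ", exercises_per_session,
         " distinct exercises from a catalogue of ", length(catalog),
         call. = FALSE)
  exercises <- with_seed(seed,
                         sample(catalog, exercises_per_session,
                                replace = replace))
  structure(list(exercises = exercises,
                 exercise_minutes = exercise_minutes,
                 break_minutes = break_minutes, seed = seed),
            class = "session_plan")
}

#' Session timing totals in minutes
#'
#' @param plan A [plan_session()] result.
#' @return Named numeric vector with `active`, `rest` and `total` minutes.
#' @export
session_minutes <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  k <- length(plan$exercises)
  active <- k * plan$exercise_minutes
  rest <- (k - 1L) * plan$break_minutes   # no break after the last exercise
  c(active = active, rest = rest, total = active + rest)
}

#' @export
print.session_plan <- function(x, ...) {
  m <- session_minutes(x)
  cat("<session_plan> ", length(x$exercises), " exercises x ",
      x$exercise_minutes, " min, ", x$break_minutes,
      " min breaks (active ", m["active"], " / rest ", m["rest"],
      " / total ", m["total"], " min)\n", sep = "")
  for (i in seq_along(x$exercises))
    cat("  ", i, ". ", x$exercises[i], "\n", sep = "")
  invisible(x)
}

#' Run a planned session through the classifier
#'
#' Executes a session plan against recorded (or simulated) sensor streams:
#' each planned exercise's stream is segmented into windows, the classifier
#' labels every window, the block accuracy is the fraction of windows
#' labelled correct, and the star score is attached. Streams too short to
#' yield a single window are logged with zero windows and zero stars and
#' flagged.
#'
#' @param plan A [plan_session()] result.
#' @param classifier A trained [fit_window_classifier()] model.
#' @param streams Either a list of [sensor_stream()]s, one per planned
#'   exercise in plan order, or a function `(exercise_id, position)`
#'   returning such a stream.
#' @param window_seconds,hop_samples Passed to [make_windows()].
#' @return An object of class `session_log`: data frame with one row per
#'   planned exercise (`exercise`, `n_windows`, `accuracy_fraction`,
#'   `stars`, `start_minute`, `end_minute`, `flagged`).
#' @export
run_session <- function(plan, classifier, streams, window_seconds = 2,
                        hop_samples = 21L) {
  stopifnot(inherits(plan, "session_plan"),
            inherits(classifier, "window_classifier"))
  k <- length(plan$exercises)
  get_stream <- if (is.function(streams)) streams else {
    if (length(streams) != k)
      stop("`streams` must supply one stream per planned exercise (",
           k, ")", call. = FALSE)
    function(ex, i) streams[[i]]
  }
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    s <- get_stream(plan$exercises[i], i)
    stopifnot(inherits(s, "sensor_stream"))
    w <- make_windows(s, window_seconds, hop_samples)
    if (length(w) == 0L) {
      acc <- 0; nw <- 0L; flag <- TRUE
    } else {
      pred <- predict(classifier, w)
      acc <- mean(pred == "correct"); nw <- length(w); flag <- FALSE
    }
    start_min <- (i - 1L) * (plan$exercise_minutes + plan$break_minutes)
    rows[[i]] <- data.frame(
      exercise = plan$exercises[i], n_windows = nw,
      accuracy_fraction = acc,
      stars = if (flag) 0L else accuracy_to_stars(acc)$stars,
      start_minute = start_min,
      end_minute = start_min + plan$exercise_minutes,
      flagged = flag)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("session_log", "data.frame")
  attr(out, "plan") <- plan
  out
}

#' @export
print.session_log <- function(x, ...) {
  cat("Session log (", nrow(x), " exercises, ",
      sum(x$stars), "/", 5L * nrow(x), " stars)\n", sep = "")
  y <- as.data.frame(x)
  y$accuracy_fraction <- round(y$accuracy_fraction, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialize a session plan or log to JSON
#'
#' @param x A `session_plan` or `session_log`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
session_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "session_plan")) {
    m <- session_minutes(x)
    list(exercises = x$exercises, exercise_minutes = x$exercise_minutes,
         break_minutes = x$break_minutes, seed = x$seed,
         minutes = as.list(m))
  } else if (inherits(x, "session_log")) {
    as.data.frame(x)
  } else stop("`x` must be a session plan or log", call. = FALSE)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
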