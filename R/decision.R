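#' Prediction queue for mode-vote post-processing
#'
#' Streaming per-window predictions are condensed into stable final gestures:
#' once the queue holds `capacity` predictions, the modal label becomes the
#' final prediction provided it fills at least the confidence fraction
#' `theta` of the queue; otherwise the window of predictions is deemed too
#' random and the final decision is `"Unknown"` (optionally replaced by the
#' last confident gesture). The buffer then slides by one.
#'
#' @param capacity Queue length before a decision is made (default 10).
#' @param theta Confidence fraction the mode must reach, in (0, 1\]
#'   (default 0.75).
#' @param hold_last_confident If `TRUE`, emit the last confident gesture
#'   instead of `"Unknown"` during unconfident periods (default `FALSE`).
#' @return An object of class `prediction_queue`.
#' @export
prediction_queue <- function(capacity = 10L, theta = 0.75,
                             hold_last_confident = FALSE) {
  capacity <- as.integer(capacity)
  if (capacity < 1L) stop("'capacity' must be >= 1", call. = FALSE)
  if (theta <= 0 || theta > 1) stop("'theta' must be in (0, 1]", call. = FALSE)
  structure(list(capacity = capacity, theta = theta,
                 hold_last_confident = isTRUE(hold_last_confident),
                 buffer = character(0), last_confident = NULL),
            class = "prediction_queue")
}

#' Push one prediction and decide
#'
#' @param queue A [prediction_queue()].
#' @param label The incoming per-window prediction.
#' @return List with `queue` (updated) and `decision`: `"pending"` while the
#'   buffer is filling, else the modal label or `"Unknown"`.
#' @export
push_and_decide <- function(queue, label) {
  stopifnot(inherits(queue, "prediction_queue"),
            is.character(label), length(label) == 1L)
  queue$buffer <- c(queue$buffer, label)
  if (length(queue$buffer) < queue$capacity) {
    return(list(queue = queue, decision = "pending"))
  }
  counts <- table(queue$buffer)
  top <- max(counts)
  # deterministic tie-break: alphabetically first modal label
  mode_label <- sort(names(counts)[counts == top])[1]
  if (top / queue$capacity >= queue$theta) {
    decision <- mode_label
    queue$last_confident <- mode_label
  } else if (queue$hold_last_confident && !is.null(queue$last_confident)) {
    decision <- queue$last_confident
  } else {
    decision <- "Unknown"
  }
  queue$buffer <- queue$buffer[-1L]   # slide by one
  list(queue = queue, decision = decision)
}

is_gesture <- function(x) {
  !is.null(x) && !is.na(x) && !(x %in% c("Unknown", "pending"))
}

#' State-change debouncing
#'
#' Commands are transmitted only when the final gesture changes state:
#' repeat recognition of the same gesture never re-transmits, and `Unknown`
#' or `pending` decisions never transmit.
#'
#' @param previous The previously emitted gesture (or `NULL` before any).
#' @param current The current final decision.
#' @return `TRUE` iff `current` is a real gesture differing from `previous`.
#' @export
debounce <- function(previous, current) {
  is_gesture(current) && (is.null(previous) || !identical(previous, current))
}

#' Shortest signed angular difference
#'
#' Difference `a - b` mapped onto the shortest arc, in \[-180, 180) degrees.
#'
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
angle_diff <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

#' Spatial-augmentation state
#'
#' Holds the proportional-control configuration and, while a gesture is
#' active, the Euler setpoint captured at gesture onset. Orientation is never
#' part of the classifier's features; it only augments the decision after a
#' gesture has been predicted, so augmentation can be toggled without
#' touching recognition.
#'
#' @param axis_by_gesture Named list/vector mapping gesture labels to the
#'   single Euler axis considered while that gesture is held (`"yaw"`,
#'   `"pitch"` or `"roll"`). Gestures not listed default to `default_axis`.
#' @param default_axis Axis used for unlisted gestures (default `"yaw"`).
#' @param gain Proportional gain applied to the angular delta (default 1).
#' @param mode Output interpretation: `"repeat_rate"` (codes per second
#'   proportional to the delta), `"index_increment"` (code index =
#'   floor(output / step)), or `"discrete"` (three-state threshold).
#' @param step Degrees per index step in `index_increment` mode (default 10).
#' @param rate_scale Codes/second per degree in `repeat_rate` mode
#'   (default 0.1).
#' @param thresholds Signed degree thresholds for `discrete` mode
#'   (default `c(-10, 10)`): output above the upper one maps to `"lateral"`,
#'   below the lower one to `"medial"`, else `"neutral"`.
#' @return An object of class `spatial_state`.
#' @export
spatial_state <- function(axis_by_gesture = list(), default_axis = "yaw",
                          gain = 1, mode = c("repeat_rate",
                                             "index_increment", "discrete"),
                          step = 10, rate_scale = 0.1,
                          thresholds = c(-10, 10)) {
  mode <- match.arg(mode)
  default_axis <- match.arg(default_axis, c("yaw", "pitch", "roll"))
  stopifnot(step > 0, rate_scale > 0, length(thresholds) == 2L,
            thresholds[1] < thresholds[2])
  structure(list(axis_by_gesture = axis_by_gesture,
                 default_axis = default_axis, gain = gain, mode = mode,
                 step = step, rate_scale = rate_scale,
                 thresholds = thresholds,
                 active = NULL, setpoint = NULL),
            class = "spatial_state")
}

#' Update spatial augmentation with a new decision and orientation
#'
#' On gesture onset the current Euler triplet is captured as the setpoint and
#' the controller output is zero. While the gesture is held, the output is
#' `gain` times the shortest signed angular difference between the current
#' and setpoint orientation on the gesture's configured axis. On `Unknown`,
#' `pending` or no gesture, the controller is disengaged and produces no
#' output.
#'
#' @param state A [spatial_state()].
#' @param decision Final decision from the prediction queue.
#' @param euler Named numeric triplet `c(yaw=, pitch=, roll=)` in degrees,
#'   required whenever spatial mode is driven.
#' @return List with `state` (updated) and `output`: `NULL` when no gesture
#'   is active, else a list with `gesture`, `axis`, `value` (the
#'   proportional output in degrees x gain) and the mode-specific
#'   interpretation (`rate` in codes/s, `index`, or `state` in
#'   \{"medial", "neutral", "lateral"\}).
#' @export
spatial_update <- function(state, decision, euler) {
  stopifnot(inherits(state, "spatial_state"))
  if (!is_gesture(decision)) {
    state$active <- NULL
    state$setpoint <- NULL
    return(list(state = state, output = NULL))
  }
  if (missing(euler) || is.null(euler) || anyNA(euler)) {
    stop("spatial mode requires euler orientation data", call. = FALSE)
  }
  euler <- as.numeric(euler[c("yaw", "pitch", "roll")])
  names(euler) <- c("yaw", "pitch", "roll")
  if (is.null(state$active) || !identical(state$active, decision)) {
    state$active <- decision          # onset: capture setpoint
    state$setpoint <- euler
  }
  axis <- state$axis_by_gesture[[decision]]
  if (is.null(axis)) axis <- state$default_axis
  value <- state$gain * angle_diff(euler[[axis]], state$setpoint[[axis]])
  out <- list(gesture = decision, axis = axis, value = value)
  out <- switch(state$mode,
    repeat_rate = c(out, list(rate = abs(value) * state$rate_scale)),
    index_increment = c(out, list(index = floor(value / state$step))),
    discrete = c(out, list(state = if (value > state$thresholds[2]) {
      "lateral"
    } else if (value < state$thresholds[1]) "medial" else "neutral"))
  )
  list(state = state, output = out)
}

#' Run a prediction stream through the decision chain
#'
#' Convenience driver: feeds per-window predictions through the queue, the
#' debouncer and (optionally) spatial augmentation, returning a log of every
#' step. This is the software analogue of the real-time loop in which the
#' user watches current gestures and transmissions in text form.
#'
#' @param labels Character vector of streamed per-window predictions.
#' @param euler Optional matrix (length(labels) x 3, columns yaw/pitch/roll)
#'   of orientations synchronous with the predictions.
#' @param queue A [prediction_queue()].
#' @param spatial Optional [spatial_state()]; enables spatial augmentation.
#' @return Data frame with columns `step`, `input`, `decision`, `emit`
#'   (debounced state change) and, with spatial on, `output_value`.
#' @export
run_decision_stream <- function(labels, euler = NULL,
                                queue = prediction_queue(),
                                spatial = NULL) {
  n <- length(labels)
  decisions <- character(n)
  emits <- logical(n)
  values <- rep(NA_real_, n)
  last_emitted <- NULL
  for (i in seq_len(n)) {
    res <- push_and_decide(queue, labels[[i]])
    queue <- res$queue
    decisions[i] <- res$decision
    emits[i] <- debounce(last_emitted, res$decision)
    if (emits[i]) last_emitted <- res$decision
    if (!is.null(spatial)) {
      e <- if (!is.null(euler)) {
        stats::setNames(as.numeric(euler[i, ]), c("yaw", "pitch", "roll"))
      }
      su <- spatial_update(spatial, res$decision, e)
      spatial <- su$state
      if (!is.null(su$output)) values[i] <- su$output$value
    }
  }
  out <- data.frame(step = seq_len(n), input = labels, decision = decisions,
                    emit = emits)
  if (!is.null(spatial)) out$output_value <- values
  out
}
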