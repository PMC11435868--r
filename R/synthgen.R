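#' Gesture profile
#'
#' Describes one static (or quasi-dynamic) gesture as the set of held
#' relative-pressure levels it produces in the five pneumatic chambers of the
#' armband, the sigmoid onset ramp from rest to the held level, and an
#' optional slow Euler-angle sweep for quasi-dynamic variants.
#'
#' @param label Gesture name, e.g. `"Fist"`.
#' @param chamber_means Numeric vector of exactly 5 relative-pressure offsets
#'   (arbitrary kPa-equivalent units, relative to the rest baseline).
#' @param onset_ramp Duration in milliseconds of the sigmoid ramp from rest to
#'   the held level. Must be >= 0. Default 200 ms.
#' @param euler_sweep Optional list with elements `axis` (one of `"yaw"`,
#'   `"pitch"`, `"roll"`), `start` and `end` (degrees in \[-180, 180\]).
#'   When given, the generated Euler trace interpolates linearly from `start`
#'   to `end` over the recording on that axis.
#' @return An object of class `gesture_profile`.
#' @export
gesture_profile <- function(label, chamber_means, onset_ramp = 200,
                            euler_sweep = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (length(chamber_means) != 5L || !is.numeric(chamber_means) ||
      anyNA(chamber_means)) {
    stop("'chamber_means' must be 5 finite numeric values, got ",
         length(chamber_means), call. = FALSE)
  }
  if (!is.numeric(onset_ramp) || length(onset_ramp) != 1L || onset_ramp < 0) {
    stop("'onset_ramp' must be a single non-negative duration (ms)",
         call. = FALSE)
  }
  if (!is.null(euler_sweep)) {
    if (!is.list(euler_sweep) ||
        !all(c("axis", "start", "end") %in% names(euler_sweep))) {
      stop("'euler_sweep' must be list(axis=, start=, end=)", call. = FALSE)
    }
    euler_sweep$axis <- match.arg(euler_sweep$axis, c("yaw", "pitch", "roll"))
    ang <- c(euler_sweep$start, euler_sweep$end)
    if (any(!is.finite(ang)) || any(ang < -180) || any(ang > 180)) {
      stop("sweep angles must lie in [-180, 180] degrees", call. = FALSE)
    }
  }
  structure(
    list(label = label, chamber_means = as.numeric(chamber_means),
         onset_ramp = onset_ramp, euler_sweep = euler_sweep),
    class = "gesture_profile"
  )
}

#' Default gesture set
#'
#' Five common myography gestures (Fist, Pinch, Spread Fingers, Wave In,
#' Wave Out) with shipped chamber-mean vectors. The numeric levels are honest
#' inventions: no published pressure values exist for this armband, so the
#' defaults only reproduce the qualitative structure reported for it --
#' Fist and Spread Fingers differ strongly on chamber 1 while chamber 2
#' (over the pronator teres, unused by these gestures) stays near one common
#' level across all five gestures.
#'
#' @param quasi_dynamic If `TRUE`, attach the slow orientation sweeps of the
#'   quasi-dynamic variants (Fist: roll; Pinch / Wave Out: yaw;
#'   Spread Fingers / Wave In: pitch).
#' @return List of five [gesture_profile()] objects.
#' @export
default_gestures <- function(quasi_dynamic = FALSE) {
  means <- list(
    "Fist"           = c(8.0, 3.0, 5.5, 2.0, 6.5),
    "Pinch"          = c(2.5, 3.1, 1.5, 4.5, 2.0),
    "Spread Fingers" = c(1.0, 3.0, 6.5, 7.5, 3.5),
    "Wave In"        = c(5.0, 2.9, 2.5, 6.0, 8.0),
    "Wave Out"       = c(3.5, 3.2, 8.0, 1.0, 4.5)
  )
  sweeps <- list(
    "Fist"           = list(axis = "roll",  start = 0, end = 60),
    "Pinch"          = list(axis = "yaw",   start = 0, end = 45),
    "Spread Fingers" = list(axis = "pitch", start = 0, end = 40),
    "Wave In"        = list(axis = "pitch", start = 0, end = -40),
    "Wave Out"       = list(axis = "yaw",   start = 0, end = -45)
  )
  lapply(names(means), function(g) {
    gesture_profile(g, means[[g]],
                    euler_sweep = if (quasi_dynamic) sweeps[[g]] else NULL)
  })
}

#' Session specification for the synthetic generator
#'
#' Bundles the gesture set and the acquisition / variability parameters of one
#' recording session. Defaults mirror the armband's acquisition protocol:
#' 2000 samples per recording at a 1.35 ms sampling period (740 Hz), three
#' trials per session.
#'
#' @param gestures List of [gesture_profile()] objects.
#' @param n_trials Trials per session (default 3).
#' @param samples_per_recording Samples per gesture recording (default 2000).
#' @param sampling_period Seconds between samples (default 0.00135).
#' @param noise_sd Standard deviation of i.i.d. Gaussian sample noise
#'   (default 0.35 pressure units).
#' @param trial_offset_sd Standard deviation of the additive offset drawn once
#'   per (trial, chamber), emulating gesture re-initiation variability
#'   (default 0.25).
#' @param drift_slope Slow linear drift in pressure units per second
#'   (default 0.02).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(gestures = default_gestures(),
                         n_trials = 3L,
                         samples_per_recording = 2000L,
                         sampling_period = 0.00135,
                         noise_sd = 0.35,
                         trial_offset_sd = 0.25,
                         drift_slope = 0.02,
                         seed = 1L) {
  if (!length(gestures) ||
      !all(vapply(gestures, inherits, logical(1), "gesture_profile"))) {
    stop("'gestures' must be a non-empty list of gesture_profile objects",
         call. = FALSE)
  }
  if (n_trials < 1L) stop("'n_trials' must be >= 1", call. = FALSE)
  if (samples_per_recording < 2L) {
    stop("'samples_per_recording' must be >= 2", call. = FALSE)
  }
  if (!is.numeric(sampling_period) || sampling_period <= 0) {
    stop("'sampling_period' must be positive", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, trial_offset_sd >= 0, is.finite(drift_slope))
  structure(
    list(gestures = gestures, n_trials = as.integer(n_trials),
         samples_per_recording = as.integer(samples_per_recording),
         sampling_period = sampling_period, noise_sd = noise_sd,
         trial_offset_sd = trial_offset_sd, drift_slope = drift_slope,
         seed = as.integer(seed)),
    class = "session_spec"
  )
}

#' Construct a sample stream
#'
#' A time-aligned block of five-channel relative pressures (rows = samples,
#' columns = chambers) with an optional Euler orientation triplet per sample.
#'
#' @param pressures Numeric matrix, n_samples x 5.
#' @param label,session_id,trial_id Provenance identifiers.
#' @param sampling_period Seconds between samples.
#' @param euler Optional numeric matrix, n_samples x 3 (yaw, pitch, roll in
#'   degrees).
#' @return An object of class `sample_stream`.
#' @export
sample_stream <- function(pressures, label, session_id = 1L, trial_id = 1L,
                          sampling_period = 0.00135, euler = NULL) {
  pressures <- as.matrix(pressures)
  if (ncol(pressures) != 5L) stop("pressures must have 5 columns", call. = FALSE)
  if (anyNA(pressures)) stop("pressures contain missing values", call. = FALSE)
  if (!is.null(euler)) {
    euler <- as.matrix(euler)
    if (nrow(euler) != nrow(pressures) || ncol(euler) != 3L) {
      stop("euler must be n_samples x 3", call. = FALSE)
    }
    if (anyNA(euler)) stop("euler contains missing values", call. = FALSE)
    colnames(euler) <- c("yaw", "pitch", "roll")
  }
  colnames(pressures) <- paste0("p", 1:5)
  structure(
    list(label = label, session_id = session_id, trial_id = trial_id,
         pressures = pressures, euler = euler,
         sampling_period = sampling_period),
    class = "sample_stream"
  )
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf(
    "<sample_stream> '%s' session %s trial %s: %d samples x 5 chambers (%.4g s)%s\n",
    x$label, x$session_id, x$trial_id, nrow(x$pressures),
    nrow(x$pressures) * x$sampling_period,
    if (is.null(x$euler)) "" else " + euler"))
  invisible(x)
}

# sigmoid onset envelope: ~0 at t=0, ~1 at t=ramp_ms, 0.5 at the midpoint
onset_envelope <- function(n, ramp_ms, sampling_period) {
  if (ramp_ms <= 0) return(rep(1, n))
  t_ms <- (seq_len(n) - 1) * sampling_period * 1000
  1 / (1 + exp(-10 * (t_ms - ramp_ms / 2) / ramp_ms))
}

#' Generate one synthetic session
#'
#' Produces `n_trials` x `length(gestures)` labelled [sample_stream()]s. Each
#' stream is built as: rest baseline (zero, pressures are baseline-relative) +
#' sigmoid onset ramp to the gesture's chamber means + an offset drawn once
#' per (trial, chamber) + linear drift + i.i.d. Gaussian noise. The Euler
#' trace is constant (0, 0, 0) unless the profile carries a sweep, in which
#' case the swept axis interpolates linearly from start to end angle over the
#' recording. Fully reproducible from `spec$seed`.
#'
#' @param spec A [session_spec()].
#' @param session_id Identifier stamped on every stream (default 1).
#' @return List of [sample_stream()] objects, ordered trial-major then
#'   gesture.
#' @export
generate_session <- function(spec, session_id = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  n <- spec$samples_per_recording
  t_s <- (seq_len(n) - 1) * spec$sampling_period
  streams <- vector("list", spec$n_trials * length(spec$gestures))
  k <- 0L
  # private RNG stream: session_id folds into the seed so sessions differ
  withr_seed <- spec$seed + 7919L * (as.integer(session_id) - 1L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(withr_seed %% .Machine$integer.max)
  for (trial in seq_len(spec$n_trials)) {
    for (g in spec$gestures) {
      trial_offset <- stats::rnorm(5L, 0, spec$trial_offset_sd)
      env <- onset_envelope(n, g$onset_ramp, spec$sampling_period)
      base <- outer(env, g$chamber_means)           # n x 5 ramped plateau
      base <- sweep(base, 2L, trial_offset, "+")
      base <- base + spec$drift_slope * t_s         # common slow drift
      noise <- matrix(stats::rnorm(n * 5L, 0, spec$noise_sd), nrow = n)
      euler <- matrix(0, nrow = n, ncol = 3L,
                      dimnames = list(NULL, c("yaw", "pitch", "roll")))
      if (!is.null(g$euler_sweep)) {
        ax <- g$euler_sweep$axis
        euler[, ax] <- seq(g$euler_sweep$start, g$euler_sweep$end,
                           length.out = n)
      }
      k <- k + 1L
      streams[[k]] <- sample_stream(
        base + noise, label = g$label, session_id = session_id,
        trial_id = trial, sampling_period = spec$sampling_period,
        euler = euler)
    }
  }
  streams
}

#' Force one chamber to be uninformative
#'
#' Returns a copy of `spec` in which every gesture shares a single common mean
#' at the given chamber, emulating the observation that a chamber sitting over
#' a muscle unused by the gesture set holds one pressure level across all
#' gestures. Used to test that selection and classification degrade
#' gracefully when a channel carries no between-gesture signal.
#'
#' @param spec A [session_spec()].
#' @param chamber_index Chamber to flatten, 1-based in 1..5.
#' @param common_mean Level shared by all gestures at that chamber; default is
#'   the across-gesture average of the existing means there.
#' @return A modified [session_spec()].
#' @export
make_redundant_chamber <- function(spec, chamber_index, common_mean = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  if (!is.numeric(chamber_index) || length(chamber_index) != 1L ||
      chamber_index < 1 || chamber_index > 5) {
    stop("'chamber_index' must be in 1..5", call. = FALSE)
  }
  ci <- as.integer(chamber_index)
  if (is.null(common_mean)) {
    common_mean <- mean(vapply(spec$gestures,
                               function(g) g$chamber_means[ci], numeric(1)))
  }
  spec$gestures <- lapply(spec$gestures, function(g) {
    g$chamber_means[ci] <- common_mean
    g
  })
  spec
}
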