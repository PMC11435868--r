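#' Sliding-window configuration
#'
#' Defaults follow the acquisition protocol: 100-sample windows
#' (about 135 ms at the 1.35 ms sampling period) advancing by a 50-sample
#' stride, i.e. 50% overlap.
#'
#' @param window_length Window length W in samples (>= 2).
#' @param stride Stride S in samples, 1 <= S <= W.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_length = 100L, stride = 50L) {
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  if (window_length < 2L) stop("'window_length' must be >= 2", call. = FALSE)
  if (stride < 1L || stride > window_length) {
    stop("'stride' must satisfy 1 <= stride <= window_length", call. = FALSE)
  }
  structure(list(window_length = window_length, stride = stride),
            class = "windowing_config")
}

#' Segment a stream into overlapping windows
#'
#' Windows start at sample 1, 1 + S, 1 + 2S, ...; the count is
#' floor((N - W)/S) + 1, which reduces to the textbook N/S - 1 when W = 2S
#' and S divides N. Trailing samples that do not fill a window are dropped.
#' Consecutive windows overlap by W - S samples.
#'
#' @param stream A [sample_stream()].
#' @param cfg A [windowing_config()].
#' @return List of windows; each is a list with `pressures` (W x 5 matrix),
#'   `start` (1-based index into the stream), and the parent identifiers
#'   `label`, `session_id`, `trial_id`.
#' @export
segment <- function(stream, cfg = windowing_config()) {
  stopifnot(inherits(stream, "sample_stream"),
            inherits(cfg, "windowing_config"))
  n <- nrow(stream$pressures)
  w <- cfg$window_length
  s <- cfg$stride
  if (n < w) {
    stop(sprintf("stream has %d samples, shorter than one %d-sample window",
                 n, w), call. = FALSE)
  }
  starts <- seq.int(1L, n - w + 1L, by = s)
  lapply(starts, function(st) {
    list(pressures = stream$pressures[st:(st + w - 1L), , drop = FALSE],
         start = st, label = stream$label,
         session_id = stream$session_id, trial_id = stream$trial_id)
  })
}

#' Pressure spike alert scan
#'
#' Flags abnormal pressure transients during a nominally static gesture: any
#' point where the pressure value changes, relative to some earlier value
#' within the look-back horizon, by more than `rel_threshold` (default 20%
#' over less than one second). "Pressure value" means the short
#' moving-average reading, not the raw sample: the rule targets genuine
#' pressure transients, not sample-to-sample sensor noise. The onset
#' transient at the start of the recording (the gesture forming) is excluded
#' via `settle_frac`, matching the rule's scope of a held static gesture.
#' The relative-change denominator is floored at a fraction of the stream's
#' dynamic range: streams carry baseline-relative pressures, so a barely
#' engaged chamber sits near zero, where a ratio against the pointwise value
#' would flag ordinary noise; the floor keeps the 20% rule anchored to the
#' pressure scale of an engaged chamber.
#'
#' @param stream A [sample_stream()].
#' @param rel_threshold Relative change threshold (> 0, default 0.20).
#' @param horizon_s Look-back horizon in seconds (> 0, default 1.0).
#' @param floor_frac Denominator floor as a fraction of the stream's dynamic
#'   range (default 0.2).
#' @param smooth Moving-average width in samples defining the "pressure
#'   value" at each instant (default 100, one analysis window, about
#'   135 ms; capped at a quarter of the stream).
#' @param settle_frac Fraction of initial samples excluded as onset
#'   transient (default 0.1).
#' @return Data frame with columns `channel` and `sample` (1-based index of
#'   the later point of the offending pair); zero rows when clean.
#' @export
spike_alert <- function(stream, rel_threshold = 0.20, horizon_s = 1.0,
                        floor_frac = 0.2, smooth = 100L,
                        settle_frac = 0.1) {
  stopifnot(inherits(stream, "sample_stream"))
  if (rel_threshold <= 0) stop("'rel_threshold' must be > 0", call. = FALSE)
  if (horizon_s <= 0) stop("'horizon_s' must be > 0", call. = FALSE)
  p <- stream$pressures
  n <- nrow(p)
  smooth <- max(1L, min(as.integer(smooth), n %/% 4L))
  lag_max <- min(n - 1L, floor(horizon_s / stream$sampling_period))
  dyn <- diff(range(p))
  floor_val <- max(floor_frac * dyn, .Machine$double.eps)
  first <- max(smooth, floor(settle_frac * n) + 1L)
  hits <- vector("list", 0L)
  for (ch in seq_len(ncol(p))) {
    # trailing moving average = the instantaneous pressure reading
    x <- as.numeric(stats::filter(p[, ch], rep(1 / smooth, smooth),
                                  sides = 1L))
    flagged <- rep(FALSE, n)
    for (lag in seq_len(lag_max)) {
      # both readings of the comparison must lie in the held portion
      idx <- max(first + lag, lag + smooth):n
      if (!length(idx) || idx[1] > n) break
      prev <- x[idx - lag]
      ratio <- abs(x[idx] - prev) / pmax(abs(prev), floor_val)
      flagged[idx] <- flagged[idx] | (!is.na(ratio) & ratio > rel_threshold)
      if (all(flagged[idx])) break
    }
    if (any(flagged)) {
      hits[[length(hits) + 1L]] <-
        data.frame(channel = ch, sample = which(flagged))
    }
  }
  if (!length(hits)) {
    return(data.frame(channel = integer(0), sample = integer(0)))
  }
  do.call(rbind, hits)
}

#' Band-pass validity check
#'
#' Advisory integrity check: a Butterworth band-pass copy of the stream is
#' produced for inspection, and a flag is raised when the fraction of signal
#' energy lying outside the pass band exceeds `max_out_fraction`. The
#' spectral check uses the held portion of the recording (the first
#' `settle_frac` of samples, which contain the known onset transient, are
#' excluded) after removing the linear trend, so the gesture plateau and slow
#' drift -- which are the signal, not an artifact -- do not count as
#' out-of-band energy. The classification path always consumes the unfiltered
#' stream; for steady pFMG plateaus filtering was found unnecessary and this
#' check is a fail-safe only.
#'
#' @param stream A [sample_stream()].
#' @param order Filter order (default 5).
#' @param band Pass band in Hz, `c(lo, hi)` with 0 < lo < hi < Nyquist.
#'   Default `c(0.5, 330)` at the 740 Hz sampling rate.
#' @param max_out_fraction Out-of-band energy fraction that raises the flag
#'   (default 0.25).
#' @param settle_frac Fraction of initial samples excluded from the spectral
#'   check as onset transient (default 0.1).
#' @return List with `filtered` (a [sample_stream()]), `flag` (logical), and
#'   `out_fraction` (per-channel out-of-band energy fractions).
#' @export
validity_filter <- function(stream, order = 5L, band = c(0.5, 330),
                            max_out_fraction = 0.25, settle_frac = 0.1) {
  stopifnot(inherits(stream, "sample_stream"))
  if (order < 1L) stop("'order' must be >= 1", call. = FALSE)
  fs <- 1 / stream$sampling_period
  nyq <- fs / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= nyq) {
    stop(sprintf("band edges must satisfy 0 < lo < hi < %.3g Hz (Nyquist)",
                 nyq), call. = FALSE)
  }
  p <- stream$pressures
  n <- nrow(p)
  bf <- signal::butter(order, band / nyq, type = "pass")
  filt <- apply(p, 2L, function(x) signal::filtfilt(bf, x))
  held <- max(1L, floor(settle_frac * n) + 1L):n
  m <- length(held)
  freqs <- (seq_len(m) - 1) * fs / m
  # fold onto [0, Nyquist]
  freqs <- pmin(freqs, fs - freqs)
  tt <- seq_len(m)
  out_frac <- apply(p[held, , drop = FALSE], 2L, function(x) {
    x <- stats::lm.fit(cbind(1, tt), x)$residuals  # drop plateau + drift
    pw <- Mod(stats::fft(x))^2
    tot <- sum(pw)
    if (tot < .Machine$double.eps) return(0)
    sum(pw[freqs < band[1] | freqs > band[2]]) / tot
  })
  flag <- any(out_frac > max_out_fraction)
  list(filtered = sample_stream(filt, label = stream$label,
                                session_id = stream$session_id,
                                trial_id = stream$trial_id,
                                sampling_period = stream$sampling_period,
                                euler = stream$euler),
       flag = flag, out_fraction = out_frac)
}
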