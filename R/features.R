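#' The 17-member candidate feature registry
#'
#' Canonical order of the time-domain features the pipeline computes per
#' window and channel: Integrated Absolute Value (IAV), Waveform Length (WL),
#' Average Amplitude Change (AAC), Slope Sign Change (SSC), Simple Square
#' Integral (SSI), Root Mean Square (RMS), Variance (VAR), Mean Absolute
#' Value (MAV) and its centre-weighted variants MAV1 / MAV2, Zero Crossing
#' (ZC), 3rd/4th/5th Temporal Moments (TM3, TM4, TM5), Willison Amplitude
#' (WAMP), Difference Absolute Standard Deviation Value (DASDV) and Myopulse
#' Percentage Rate (MYOP).
#'
#' @format Character vector of length 17.
#' @export
FEATURE_NAMES <- c("IAV", "WL", "AAC", "SSC", "SSI", "RMS", "VAR",
                   "MAV", "MAV1", "MAV2", "ZC", "TM3", "TM4", "TM5",
                   "WAMP", "DASDV", "MYOP")

#' Feature-set definition
#'
#' Selects an ordered subset of the candidate registry together with the
#' amplitude thresholds used by the counting features. By default every
#' threshold is `NA`, meaning "1% of the window's dynamic range", evaluated
#' per window; fixed numeric thresholds may be given instead.
#'
#' @param names Ordered subset of [FEATURE_NAMES] (unique). Default: all 17.
#' @param eps_zc,eps_ssc,eps_wamp,eps_myop Thresholds for ZC, SSC, WAMP and
#'   MYOP. `NA` = adaptive 1% of window dynamic range; otherwise a fixed
#'   value >= 0.
#' @param eps_frac Dynamic-range fraction used for adaptive thresholds
#'   (default 0.01).
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(names = FEATURE_NAMES, eps_zc = NA, eps_ssc = NA,
                        eps_wamp = NA, eps_myop = NA, eps_frac = 0.01) {
  names <- as.character(names)
  if (!length(names) || anyDuplicated(names) ||
      !all(names %in% FEATURE_NAMES)) {
    stop("feature names must be a unique subset of the 17-member registry",
         call. = FALSE)
  }
  eps <- c(zc = eps_zc, ssc = eps_ssc, wamp = eps_wamp, myop = eps_myop)
  if (any(!is.na(eps) & eps < 0)) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(names = names, eps = eps, eps_frac = eps_frac),
            class = "feature_set")
}

resolve_eps <- function(fs, x) {
  dyn <- diff(range(x))
  vapply(fs$eps, function(e) if (is.na(e)) fs$eps_frac * dyn else e,
         numeric(1))
}

#' Compute time-domain features for one window channel
#'
#' Applies the selected feature formulas to a single channel's window of W
#' samples. Definitions (x the samples, W the window length):
#' IAV = sum|x|; WL = sum|x_{i+1} - x_i|; AAC = WL/W;
#' SSC = #\{(x_i - x_{i-1})(x_i - x_{i+1}) > eps\};
#' SSI = sum x^2; RMS = sqrt(SSI/W); VAR = sum (x - mean)^2 / (W-1);
#' MAV = IAV/W; MAV1, MAV2 = centre-weighted MAV; ZC = # sign changes with
#' |x_i - x_{i+1}| >= eps; TMk = |sum x^k / W| for k = 3, 4, 5;
#' WAMP = #\{|x_{i+1} - x_i| > eps\}; DASDV = sqrt(sum diff^2 / (W-1));
#' MYOP = #\{|x_i| > eps\} / W.
#'
#' @param x Numeric vector of W >= 2 finite samples.
#' @param fs A [feature_set()].
#' @return Named numeric vector in `fs$names` order.
#' @export
compute_features <- function(x, fs = feature_set()) {
  stopifnot(inherits(fs, "feature_set"))
  if (length(x) < 2L) stop("window must hold at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("window contains non-finite samples", call. = FALSE)
  w <- length(x)
  eps <- resolve_eps(fs, x)
  d <- diff(x)
  ax <- abs(x)
  iav <- sum(ax)
  wl <- sum(abs(d))
  ssi <- sum(x^2)

  # centre-weighted windows (standard modified-MAV weightings)
  i <- seq_len(w)
  w1 <- ifelse(i >= 0.25 * w & i <= 0.75 * w, 1, 0.5)
  w2 <- ifelse(i < 0.25 * w, 4 * i / w,
               ifelse(i > 0.75 * w, 4 * (w - i) / w, 1))

  vals <- c(
    IAV   = iav,
    WL    = wl,
    AAC   = wl / w,
    SSC   = if (w >= 3) {
      xm <- x[2:(w - 1)]
      sum((xm - x[1:(w - 2)]) * (xm - x[3:w]) > eps[["ssc"]])
    } else 0,
    SSI   = ssi,
    RMS   = sqrt(ssi / w),
    VAR   = sum((x - mean(x))^2) / (w - 1),
    MAV   = iav / w,
    MAV1  = sum(w1 * ax) / w,
    MAV2  = sum(w2 * ax) / w,
    ZC    = sum(x[-w] * x[-1] < 0 & abs(d) >= eps[["zc"]]),
    TM3   = abs(sum(x^3) / w),
    TM4   = abs(sum(x^4) / w),
    TM5   = abs(sum(x^5) / w),
    WAMP  = sum(abs(d) > eps[["wamp"]]),
    DASDV = sqrt(sum(d^2) / (w - 1)),
    MYOP  = sum(ax > eps[["myop"]]) / w
  )
  vals[fs$names]
}

#' Build featured frames for a stream
#'
#' Segments the stream, computes per-channel feature vectors for every
#' window, and concatenates them across the five channels in fixed order
#' into one "featured frame" per window -- the classifier's input row.
#'
#' @param stream A [sample_stream()].
#' @param cfg A [windowing_config()].
#' @param fs A [feature_set()].
#' @return Data frame with one row per window: `label`, `session`, `trial`,
#'   `window`, then `c<chan>_<feature>` columns
#'   (5 x `length(fs$names)` of them). Carries the feature set as attribute
#'   `feature_set`.
#' @export
build_frames <- function(stream, cfg = windowing_config(),
                         fs = feature_set()) {
  wins <- segment(stream, cfg)
  nf <- length(fs$names)
  feat <- matrix(NA_real_, nrow = length(wins), ncol = 5L * nf)
  colnames(feat) <- as.vector(vapply(
    1:5, function(ch) paste0("c", ch, "_", fs$names), character(nf)))
  for (i in seq_along(wins)) {
    p <- wins[[i]]$pressures
    feat[i, ] <- as.vector(vapply(
      1:5, function(ch) compute_features(p[, ch], fs), numeric(nf)))
  }
  out <- data.frame(
    label = stream$label,
    session = stream$session_id,
    trial = stream$trial_id,
    window = seq_along(wins),
    feat, check.names = FALSE
  )
  attr(out, "feature_set") <- fs
  out
}

#' Build featured frames for many streams
#'
#' @param streams List of [sample_stream()] objects.
#' @inheritParams build_frames
#' @return Row-bound data frame of featured frames (see [build_frames()]),
#'   with a `trial` column made globally unique across sessions as
#'   `"s<session>t<trial>"`.
#' @export
build_frame_table <- function(streams, cfg = windowing_config(),
                              fs = feature_set()) {
  tabs <- lapply(streams, build_frames, cfg = cfg, fs = fs)
  out <- do.call(rbind, tabs)
  out$trial <- paste0("s", out$session, "t", out$trial)
  attr(out, "feature_set") <- fs
  rownames(out) <- NULL
  out
}

frame_feature_cols <- function(frames) {
  grep("^c[1-5]_", names(frames), value = TRUE)
}

#' Write / read a featured-frame table as delimited text
#'
#' @param frames Featured-frame data frame from [build_frame_table()].
#' @param path File path (tab-separated, header row).
#' @return `write_frames`: invisibly the path; `read_frames`: the table.
#' @export
write_frames <- function(frames, path) {
  utils::write.table(frames, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
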