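# shared fixtures and independent oracles, built in code at test time

# tiny two-gesture spec for fast pipeline tests
tiny_spec <- function(noise_sd = 0, trial_offset_sd = 0, drift_slope = 0,
                      onset_ramp = 0, n_trials = 2L, n_samples = 200L,
                      seed = 7L,
                      means = list(A = c(1, 2, 3, 4, 5),
                                   B = c(5, 4, 3, 2, 1))) {
  gestures <- lapply(names(means), function(g) {
    gesture_profile(g, means[[g]], onset_ramp = onset_ramp)
  })
  session_spec(gestures = gestures, n_trials = n_trials,
               samples_per_recording = n_samples,
               noise_sd = noise_sd, trial_offset_sd = trial_offset_sd,
               drift_slope = drift_slope, seed = seed)
}

# literal-summation oracle for all 17 time-domain features; deliberately
# loop-based and independent of the vectorised implementation
oracle_features <- function(x, eps = c(zc = 0, ssc = 0, wamp = 0, myop = 0)) {
  w <- length(x)
  iav <- 0; for (v in x) iav <- iav + abs(v)
  wl <- 0; for (i in 1:(w - 1)) wl <- wl + abs(x[i + 1] - x[i])
  ssc <- 0
  if (w >= 3) {
    for (i in 2:(w - 1)) {
      if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > eps[["ssc"]]) ssc <- ssc + 1
    }
  }
  ssi <- 0; for (v in x) ssi <- ssi + v^2
  mu <- sum(x) / w
  vv <- 0; for (v in x) vv <- vv + (v - mu)^2
  mav1 <- 0; mav2 <- 0
  for (i in 1:w) {
    w1 <- if (i >= 0.25 * w && i <= 0.75 * w) 1 else 0.5
    w2 <- if (i < 0.25 * w) 4 * i / w else if (i > 0.75 * w) {
      4 * (w - i) / w
    } else 1
    mav1 <- mav1 + w1 * abs(x[i])
    mav2 <- mav2 + w2 * abs(x[i])
  }
  zc <- 0; wamp <- 0; dsq <- 0
  for (i in 1:(w - 1)) {
    d <- x[i + 1] - x[i]
    if (x[i] * x[i + 1] < 0 && abs(d) >= eps[["zc"]]) zc <- zc + 1
    if (abs(d) > eps[["wamp"]]) wamp <- wamp + 1
    dsq <- dsq + d^2
  }
  myop <- 0; for (v in x) if (abs(v) > eps[["myop"]]) myop <- myop + 1
  tm <- function(k) abs(sum(x^k) / w)
  c(IAV = iav, WL = wl, AAC = wl / w, SSC = ssc, SSI = ssi,
    RMS = sqrt(ssi / w), VAR = vv / (w - 1), MAV = iav / w,
    MAV1 = mav1 / w, MAV2 = mav2 / w, ZC = zc,
    TM3 = tm(3), TM4 = tm(4), TM5 = tm(5), WAMP = wamp,
    DASDV = sqrt(dsq / (w - 1)), MYOP = myop / w)
}

# feature set with all thresholds pinned to fixed values
fixed_fs <- function(eps = 0) {
  feature_set(eps_zc = eps, eps_ssc = eps, eps_wamp = eps, eps_myop = eps)
}

# constant-pressure stream fixture
constant_stream <- function(values = 1:5, n = 200L, label = "A",
                            sampling_period = 0.00135) {
  sample_stream(matrix(rep(values, each = n), nrow = n), label = label,
                sampling_period = sampling_period)
}
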