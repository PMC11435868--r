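test_that("split plans enumerate all binomial-coefficient partitions", {
  p6 <- make_split_plan(6L, 1 / 3)
  expect_length(p6$partitions, 15L)          # C(6, 2)
  p3 <- make_split_plan(3L, 1 / 3)
  expect_length(p3$partitions, 3L)           # C(3, 1)
  p2 <- make_split_plan(2L, 1 / 2)
  expect_length(p2$partitions, 2L)           # C(2, 1)

  # pairwise distinct, disjoint, covering
  keys <- vapply(p6$partitions, function(p) paste(sort(p$test),
                                                  collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (p in p6$partitions) {
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), 1:6)
  }
  expect_error(make_split_plan(3L, 1), "no training")
  expect_error(make_split_plan(3L, 0.01), "no trial")
  expect_error(make_split_plan(1L), "at least 2")
})

test_that("noise-free well-separated sessions are perfectly linearly separable", {
  # zero sample noise; drift and onset ramp provide the within-class spread
  spec <- session_spec(noise_sd = 0, trial_offset_sd = 0.05, seed = 21L,
                       samples_per_recording = 800L)
  fr <- build_frame_table(generate_session(spec))
  plan <- make_split_plan(unique(fr$trial))
  rep <- evaluate_classifiers(fr, plan, models = "LDA")
  expect_true(all(rep$accuracy[, "LDA"] == 1))
})

test_that("label shuffling drops accuracy to chance level", {
  spec <- session_spec(seed = 13L, samples_per_recording = 800L)
  fr <- build_frame_table(generate_session(spec))
  set.seed(13)
  fr$label <- sample(fr$label)
  plan <- make_split_plan(unique(fr$trial))
  rep <- evaluate_classifiers(fr, plan, models = "LDA")
  # 50% window overlap halves the effective number of independent windows
  n_eff <- nrow(fr) / 2
  se <- sqrt(0.2 * 0.8 / n_eff)
  expect_lt(abs(rep$summary$accuracy_mean - 0.2), 3 * se)
})

test_that("trial segregation and input validation are enforced", {
  fr <- build_frame_table(generate_session(tiny_spec(noise_sd = 0.2,
                                                     n_samples = 200L)))
  plan <- make_split_plan(unique(fr$trial))
  expect_error(evaluate_classifiers(fr, plan, models = "SVM9000"),
               "unknown model")
  plan_bad <- make_split_plan(c(unique(fr$trial), "s9t9"))
  expect_error(evaluate_classifiers(fr, plan_bad, models = "LDA"),
               "no frames")
  # a training fold missing one label errors instead of silently skipping
  fr2 <- fr
  fr2 <- fr2[!(fr2$label == "A" & fr2$trial == "s1t1"), ]
  # gesture A exists only in trial 2; the partition testing on trial 2
  # trains without A
  expect_error(evaluate_classifiers(fr2, plan, models = "LDA"),
               "lacks label")
  one_label <- fr[fr$label == "A", ]
  expect_error(evaluate_classifiers(one_label, plan, models = "LDA"),
               "2 gesture labels")
})

test_that("mean accuracy is invariant to partition enumeration order", {
  fr <- build_frame_table(generate_session(tiny_spec(noise_sd = 0.5,
                                                     n_trials = 3L,
                                                     n_samples = 200L)))
  plan <- make_split_plan(unique(fr$trial))
  rev_plan <- plan
  rev_plan$partitions <- rev(plan$partitions)
  r1 <- evaluate_classifiers(fr, plan, models = "LDA")
  r2 <- evaluate_classifiers(fr, rev_plan, models = "LDA")
  expect_equal(r1$summary$accuracy_mean, r2$summary$accuracy_mean)
})

test_that("every classifier in the zoo runs and reports sane metrics", {
  spec <- tiny_spec(noise_sd = 0.4, trial_offset_sd = 0.1, n_trials = 3L,
                    n_samples = 1000L, seed = 17L)
  fr <- build_frame_table(generate_session(spec))
  plan <- make_split_plan(unique(fr$trial))
  # restrict to compact continuous features so QDA's per-class covariance
  # stays well-conditioned at this problem size (counting features such as
  # ZC saturate to within-class constants on clean plateaus)
  rep <- evaluate_classifiers(
    fr, plan, features = feature_set(c("RMS", "WL", "DASDV", "MAV")))
  expect_setequal(rep$summary$model, CLASSIFIER_NAMES)
  expect_true(all(rep$summary$accuracy_mean >= 0 &
                    rep$summary$accuracy_mean <= 1))
  expect_true(all(is.finite(rep$summary$logloss_mean)))
  expect_true(all(rep$summary$time_mean_s >= 0))
})

test_that("inter-session training beats inter-trial on matched seeds", {
  spec <- session_spec(seed = 29L, samples_per_recording = 600L,
                       noise_sd = 0.8, trial_offset_sd = 0.6)
  streams <- c(generate_session(spec, session_id = 1L),
               generate_session(spec, session_id = 2L))
  fr <- build_frame_table(streams)
  fr1 <- fr[fr$session == 1L, ]
  acc_trial <- evaluate_classifiers(
    fr1, make_split_plan(unique(fr1$trial)),
    models = "LDA")$summary$accuracy_mean
  acc_session <- evaluate_classifiers(
    fr, make_split_plan(unique(fr$trial)),
    models = "LDA")$summary$accuracy_mean
  expect_gte(acc_session, acc_trial)
})

test_that("confusion matrices are row-normalised with mass where expected", {
  spec <- session_spec(noise_sd = 0, trial_offset_sd = 0.05, seed = 21L,
                       samples_per_recording = 600L)
  fr <- build_frame_table(generate_session(spec))
  plan <- make_split_plan(unique(fr$trial))
  cm <- confusion_matrix(fr, plan, "LDA")
  expect_equal(unname(rowSums(cm)), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(diag(cm)), rep(1, 5))   # perfect classifier: identity

  # two gestures sharing chamber means except one small offset confuse
  # mostly with each other
  means <- list("Wave Out" = c(3.5, 3.2, 8.0, 1.0, 4.5),
                "Spread Fingers" = c(3.5, 3.2, 8.3, 1.0, 4.5),
                "Fist" = c(8.0, 3.0, 5.5, 2.0, 6.5))
  spec2 <- tiny_spec(noise_sd = 0.6, trial_offset_sd = 0.3, n_trials = 3L,
                     n_samples = 600L, seed = 23L, means = means)
  fr2 <- build_frame_table(generate_session(spec2))
  cm2 <- confusion_matrix(fr2, make_split_plan(unique(fr2$trial)), "LDA")
  off <- cm2
  diag(off) <- 0
  for (g in c("Wave Out", "Spread Fingers")) {
    other <- setdiff(c("Wave Out", "Spread Fingers"), g)
    if (any(off[g, ] > 0)) {
      expect_equal(colnames(off)[which.max(off[g, ])], other)
    }
  }
  expect_gt(off["Wave Out", "Spread Fingers"] +
              off["Spread Fingers", "Wave Out"], 0)
})

test_that("classifier reports serialise to a delimited summary", {
  fr <- build_frame_table(generate_session(tiny_spec(noise_sd = 0.3,
                                                     n_samples = 200L)))
  rep <- evaluate_classifiers(fr, make_split_plan(unique(fr$trial)),
                              models = c("LDA", "DT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classifier_report(rep, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$model, c("LDA", "DT"))
  expect_true(all(c("accuracy_mean", "accuracy_sd", "logloss_mean",
                    "time_mean_s") %in% names(tab)))
})
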