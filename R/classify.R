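#' All train/test trial partitions at a given hold-out fraction
#'
#' Enumerates every unique combination of r = round(test_fraction * n) held
#' out trials from n, in deterministic lexicographic order: C(n, r)
#' partitions in total. With the protocol's 2:1 train:test ratio this gives
#' 3 partitions for a 3-trial session (inter-trial) and 15 for the 6 trials
#' of two sessions (inter-session).
#'
#' @param trial_ids Vector of distinct trial identifiers (or a single count
#'   n, expanded to `1:n`).
#' @param test_fraction Fraction of trials held out per partition
#'   (default 1/3).
#' @return An object of class `split_plan`: list with `n`, `r`, and
#'   `partitions` -- a list of `list(train=, test=)` id sets.
#' @export
make_split_plan <- function(trial_ids, test_fraction = 1 / 3) {
  if (length(trial_ids) == 1L && is.numeric(trial_ids)) {
    trial_ids <- seq_len(trial_ids)
  }
  trial_ids <- sort(unique(trial_ids))
  n <- length(trial_ids)
  if (n < 2L) stop("need at least 2 trials", call. = FALSE)
  r <- round(test_fraction * n)
  if (r < 1L) stop("test_fraction holds out no trial", call. = FALSE)
  if (r >= n) stop("test_fraction leaves no training trial", call. = FALSE)
  combs <- utils::combn(n, r)
  partitions <- lapply(seq_len(ncol(combs)), function(j) {
    idx <- combs[, j]
    list(train = trial_ids[-idx], test = trial_ids[idx])
  })
  structure(list(n = n, r = r, trial_ids = trial_ids,
                 partitions = partitions),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> C(%d, %d) = %d trial-segregated partitions\n",
              x$n, x$r, length(x$partitions)))
  invisible(x)
}

#' The seven-classifier zoo
#'
#' Model names accepted by [evaluate_classifiers()]: Gaussian naive Bayes,
#' nu-support-vector classification, quadratic and linear discriminant
#' analysis, random forest, k-nearest neighbours and decision tree.
#'
#' @format Character vector of length 7.
#' @export
CLASSIFIER_NAMES <- c("GaussianNB", "NuSVC", "QDA", "LDA", "RF", "K-NN", "DT")

# standardiser fitted on training rows only; drops zero-variance columns and
# linearly dependent ones (pivoted QR), e.g. MAV duplicating IAV/W, which
# would make the discriminant models' covariance estimates singular
fit_scaler <- function(xtrain) {
  mu <- colMeans(xtrain)
  sdv <- apply(xtrain, 2L, stats::sd)
  keep <- which(is.finite(sdv) & sdv > 1e-12)
  if (!length(keep)) stop("all features constant on training fold", call. = FALSE)
  z <- scale(xtrain[, keep, drop = FALSE], center = mu[keep],
             scale = sdv[keep])
  dec <- qr(z, tol = 1e-7)
  keep <- keep[sort(dec$pivot[seq_len(dec$rank)])]
  list(mu = mu[keep], sd = sdv[keep], keep = keep)
}

apply_scaler <- function(scaler, x) {
  scale(x[, scaler$keep, drop = FALSE], center = scaler$mu,
        scale = scaler$sd)
}

# LDA with near-collinearity warnings muffled: residual correlation among
# the time-domain features (e.g. MAV vs IAV) is structural, not a data fault
fit_lda <- function(xtr, ytr) {
  withCallingHandlers(
    MASS::lda(xtr, ytr),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# fit one named model and return class probabilities for xte (rows x labels)
fit_predict <- function(model, xtr, ytr, xte, seed = 1L) {
  labs <- levels(ytr)
  probs <- switch(
    model,
    "GaussianNB" = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte, type = "raw")
    },
    "NuSVC" = {
      fit <- e1071::svm(xtr, ytr, type = "nu-classification",
                        probability = TRUE)
      attr(stats::predict(fit, xte, probability = TRUE), "probabilities")
    },
    "QDA" = {
      fit <- MASS::qda(xtr, ytr)
      stats::predict(fit, xte)$posterior
    },
    "LDA" = {
      fit <- fit_lda(xtr, ytr)
      stats::predict(fit, xte)$posterior
    },
    "RF" = {
      old <- globalenv()$.Random.seed
      set.seed(seed)
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      stats::predict(fit, xte, type = "prob")
    },
    "K-NN" = {
      fit <- caret::knn3(xtr, ytr, k = 5)
      stats::predict(fit, xte, type = "prob")
    },
    "DT" = {
      dtr <- data.frame(.y = ytr, xtr, check.names = TRUE)
      dte <- data.frame(xte, check.names = TRUE)
      names(dte) <- names(dtr)[-1]
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
      stats::predict(fit, dte, type = "prob")
    },
    stop("unknown model name: ", model, call. = FALSE)
  )
  probs <- as.matrix(probs)
  # align column order to the label set; absent columns get probability 0
  out <- matrix(0, nrow = nrow(probs), ncol = length(labs),
                dimnames = list(NULL, labs))
  common <- intersect(colnames(probs), labs)
  out[, common] <- probs[, common]
  out
}

log_loss <- function(probs, ytrue, eps = 1e-15) {
  p <- probs[cbind(seq_along(ytrue), as.integer(ytrue))]
  -mean(log(pmin(pmax(p, eps), 1 - eps)))
}

#' Trial-segregated classifier evaluation
#'
#' For every partition of the split plan, fits each requested model on the
#' training trials' frames and predicts the held-out trials' frames. All
#' frames of a trial always land on the same side of the split -- the
#' protocol's guard against windows of one recording leaking between train
#' and test. Feature standardisation (zero mean, unit variance; zero-variance
#' columns dropped) is fitted on the training fold only. Reported accuracy
#' and log loss are averages over partitions.
#'
#' @param frames Featured-frame table with a `trial` column.
#' @param plan A [make_split_plan()] over the table's trial ids.
#' @param models Character vector of model names from the supported zoo:
#'   GaussianNB, NuSVC, QDA, LDA, RF, K-NN, DT.
#' @param features Optional [feature_set()] restricting the columns used.
#' @param seed Seed for the stochastic learners (default 1).
#' @return An object of class `classifier_report`: data frame `summary`
#'   (model, accuracy_mean, accuracy_sd, logloss_mean, logloss_sd,
#'   time_mean_s), matrix `accuracy` (partition x model), and list
#'   `predictions` of per-model data frames (partition, truth, predicted).
#' @export
evaluate_classifiers <- function(frames, plan,
                                 models = CLASSIFIER_NAMES,
                                 features = NULL, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  bad <- setdiff(models, CLASSIFIER_NAMES)
  if (length(bad)) stop("unknown model name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cols <- frame_feature_cols(frames)
  if (!is.null(features)) {
    stopifnot(inherits(features, "feature_set"))
    cols <- cols[sub("^c[1-5]_", "", cols) %in% features$names]
  }
  if (length(unique(frames$label)) < 2L) {
    stop("need at least 2 gesture labels", call. = FALSE)
  }
  missing_trials <- setdiff(plan$trial_ids, frames$trial)
  if (length(missing_trials)) {
    stop("plan refers to trials with no frames: ",
         paste(missing_trials, collapse = ", "), call. = FALSE)
  }
  y_all <- factor(frames$label)
  x_all <- as.matrix(frames[, cols, drop = FALSE])
  np <- length(plan$partitions)
  acc <- matrix(NA_real_, np, length(models),
                dimnames = list(NULL, models))
  ll <- matrix(NA_real_, np, length(models), dimnames = list(NULL, models))
  tm <- matrix(NA_real_, np, length(models), dimnames = list(NULL, models))
  preds <- stats::setNames(vector("list", length(models)), models)
  for (m in models) preds[[m]] <- vector("list", np)

  for (j in seq_len(np)) {
    part <- plan$partitions[[j]]
    tr <- frames$trial %in% part$train
    te <- frames$trial %in% part$test
    stopifnot(!any(tr & te))           # trial segregation, asserted every run
    ytr <- droplevels(y_all[tr])
    yte <- y_all[te]
    lacking <- setdiff(levels(droplevels(yte)), levels(ytr))
    if (length(lacking)) {
      stop("partition ", j, " training set lacks label(s): ",
           paste(lacking, collapse = ", "), call. = FALSE)
    }
    scaler <- fit_scaler(x_all[tr, , drop = FALSE])
    xtr <- apply_scaler(scaler, x_all[tr, , drop = FALSE])
    xte <- apply_scaler(scaler, x_all[te, , drop = FALSE])
    for (m in models) {
      t0 <- proc.time()[["elapsed"]]
      probs <- fit_predict(m, xtr, ytr, xte, seed = seed)
      tm[j, m] <- proc.time()[["elapsed"]] - t0
      pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                     levels = levels(y_all))
      acc[j, m] <- mean(pred == yte)
      yte_f <- factor(as.character(yte), levels = colnames(probs))
      ll[j, m] <- log_loss(probs, yte_f)
      preds[[m]][[j]] <- data.frame(partition = j,
                                    truth = as.character(yte),
                                    predicted = as.character(pred))
    }
  }
  summary <- data.frame(
    model = models,
    accuracy_mean = colMeans(acc), accuracy_sd = apply(acc, 2L, stats::sd),
    logloss_mean = colMeans(ll), logloss_sd = apply(ll, 2L, stats::sd),
    time_mean_s = colMeans(tm), row.names = NULL
  )
  structure(list(summary = summary, accuracy = acc,
                 predictions = lapply(preds, function(p) do.call(rbind, p)),
                 labels = levels(y_all)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, digits = 3, ...) {
  cat("<classifier_report> mean over", nrow(x$accuracy),
      "trial-segregated partitions\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Row-normalised confusion matrix under the split plan
#'
#' Aggregates a model's predictions over all partitions of the plan and
#' normalises each true-label row by its count, so each row sums to 1 for
#' labels that occur in the test data.
#'
#' @inheritParams evaluate_classifiers
#' @param model A single model name.
#' @return Square numeric matrix, rows = true labels, columns = predicted.
#' @export
confusion_matrix <- function(frames, plan, model = "LDA",
                             features = NULL, seed = 1L) {
  rep <- evaluate_classifiers(frames, plan, models = model,
                              features = features, seed = seed)
  p <- rep$predictions[[model]]
  labs <- rep$labels
  tab <- table(factor(p$truth, levels = labs),
               factor(p$predicted, levels = labs))
  cm <- unclass(tab / pmax(rowSums(tab), 1L))
  cm[rowSums(tab) == 0, ] <- NA_real_
  cm
}

#' Write a classifier report and confusion matrices as delimited text
#'
#' @param report A `classifier_report`.
#' @param path Output file for the summary table (tab-separated).
#' @return Invisibly, the path.
#' @export
write_classifier_report <- function(report, path) {
  stopifnot(inherits(report, "classifier_report"))
  utils::write.table(report$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
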