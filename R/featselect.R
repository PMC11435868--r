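#' Intra-/inter-gesture coefficient-of-variation report
#'
#' For every (feature, channel, gesture) triple the intra-gesture CV is the
#' sample standard deviation over that gesture's frames divided by the
#' absolute intra-gesture mean. The inter-gesture CV of a (feature, channel)
#' pair is the CV across gestures of those intra-gesture means. A feature is
#' discriminative and stable when its intra CV is low and its inter CV high.
#' Means with absolute value below `eps_mean` fall back to `eps_mean` in the
#' denominator and are marked unstable.
#'
#' @param frames Featured-frame table ([build_frame_table()]); needs >= 2
#'   gestures with >= 2 frames each.
#' @param eps_mean Denominator floor guarding CVs of near-zero-mean features
#'   (default 1e-12).
#' @return An object of class `variance_report`: list with
#'   `intra` (data frame: feature, channel, gesture, intra_mean, intra_cv,
#'   unstable), `inter` (data frame: feature, channel, inter_cv), and
#'   `by_feature` (data frame: feature, intra_score, inter_score -- scores
#'   averaged over channels, intra additionally over gestures).
#' @export
variance_report <- function(frames, eps_mean = 1e-12) {
  gestures <- unique(frames$label)
  if (length(gestures) < 2L) {
    stop("need frames from at least 2 gestures", call. = FALSE)
  }
  if (any(table(frames$label) < 2L)) {
    stop("every gesture needs at least 2 frames", call. = FALSE)
  }
  cols <- frame_feature_cols(frames)
  parts <- strsplit(cols, "_", fixed = TRUE)
  chans <- vapply(parts, function(p) as.integer(sub("^c", "", p[[1]])),
                  integer(1))
  feats <- vapply(parts, function(p) paste(p[-1], collapse = "_"),
                  character(1))

  intra <- do.call(rbind, lapply(gestures, function(g) {
    sub <- as.matrix(frames[frames$label == g, cols, drop = FALSE])
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, stats::sd)
    denom <- pmax(abs(mu), eps_mean)
    data.frame(feature = feats, channel = chans, gesture = g,
               intra_mean = unname(mu), intra_cv = unname(sdv / denom),
               unstable = unname(abs(mu) < eps_mean), row.names = NULL)
  }))

  inter <- do.call(rbind, lapply(split(intra, list(intra$feature,
                                                   intra$channel),
                                       drop = TRUE), function(d) {
    mu <- mean(d$intra_mean)
    data.frame(feature = d$feature[1], channel = d$channel[1],
               inter_cv = stats::sd(d$intra_mean) / max(abs(mu), eps_mean),
               unstable = abs(mu) < eps_mean, row.names = NULL)
  }))
  rownames(inter) <- NULL

  intra_by_feat <- tapply(intra$intra_cv, intra$feature, mean)
  inter_by_feat <- tapply(inter$inter_cv, inter$feature, mean)
  fl <- sort(unique(feats))
  by_feature <- data.frame(feature = fl,
                           intra_score = as.numeric(intra_by_feat[fl]),
                           inter_score = as.numeric(inter_by_feat[fl]),
                           row.names = NULL)
  structure(list(intra = intra, inter = inter, by_feature = by_feature),
            class = "variance_report")
}

#' Diagnostic threshold mask
#'
#' Optional view of which (feature, channel) pairs satisfy fixed CV
#' thresholds (intra below `intra_max`, inter above `inter_min`). This
#' masking approach proved ineffective as a selector -- a feature can pass on
#' one chamber and fail on another within the same gesture -- and is kept
#' only as a diagnostic; ranking ([rank_features()]) is the selector.
#'
#' @param report A [variance_report()].
#' @param intra_max Intra-gesture CV ceiling (default 0.10).
#' @param inter_min Inter-gesture CV floor (default 0.20).
#' @return Data frame: feature, channel, passes (logical).
#' @export
cv_mask <- function(report, intra_max = 0.10, inter_min = 0.20) {
  stopifnot(inherits(report, "variance_report"))
  intra_max_by <- stats::aggregate(intra_cv ~ feature + channel,
                                   data = report$intra, FUN = max)
  m <- merge(intra_max_by, report$inter, by = c("feature", "channel"))
  data.frame(feature = m$feature, channel = m$channel,
             passes = m$intra_cv < intra_max & m$inter_cv > inter_min)
}

#' Rank features by channel-averaged variance scores
#'
#' Features are ranked separately on the inter-gesture score (high is good)
#' and the intra-gesture score (low is good); the composite is the weighted
#' sum of the two rank positions, with the inter-gesture ranking weighted
#' more (`w_inter` > `w_intra`, defaults 2 and 1). Ties break
#' alphabetically, giving a deterministic total order.
#'
#' @param report A [variance_report()].
#' @param w_inter,w_intra Rank weights (defaults 2 and 1).
#' @return Data frame ordered best-first: feature, inter_score, intra_score,
#'   inter_rank, intra_rank, composite.
#' @export
rank_features <- function(report, w_inter = 2, w_intra = 1) {
  stopifnot(inherits(report, "variance_report"))
  bf <- report$by_feature
  if (anyNA(bf$intra_score) || anyNA(bf$inter_score)) {
    stop("variance report has missing feature entries", call. = FALSE)
  }
  inter_rank <- rank(-bf$inter_score, ties.method = "min")
  intra_rank <- rank(bf$intra_score, ties.method = "min")
  composite <- w_inter * inter_rank + w_intra * intra_rank
  ord <- order(composite, bf$feature)
  data.frame(feature = bf$feature[ord],
             inter_score = bf$inter_score[ord],
             intra_score = bf$intra_score[ord],
             inter_rank = inter_rank[ord], intra_rank = intra_rank[ord],
             composite = composite[ord], row.names = NULL)
}

#' Keep the top fraction of a ranking
#'
#' Retains the best `floor(fraction * n)` features (at least one); the floor
#' convention halves an odd-sized candidate list downward, so 14 features at
#' fraction 0.5 keep 7 and the full 17-member registry keeps 8.
#'
#' @param ranked Ranking from [rank_features()] (or a character vector,
#'   best first).
#' @param fraction Fraction to keep, in (0, 1] (default 0.5).
#' @param ... Passed to [feature_set()] (thresholds).
#' @return A [feature_set()] holding the retained features in rank order.
#' @export
select_top <- function(ranked, fraction = 0.5, ...) {
  names <- if (is.data.frame(ranked)) ranked$feature else as.character(ranked)
  if (!length(names)) stop("empty ranking", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  keep <- max(1L, floor(fraction * length(names)))
  feature_set(names = names[seq_len(keep)], ...)
}

#' Serialise a variance report as a tidy delimited table
#'
#' @param report A [variance_report()].
#' @param path Output file (tab-separated).
#' @return Invisibly, the path.
#' @export
write_variance_report <- function(report, path) {
  stopifnot(inherits(report, "variance_report"))
  tidy <- merge(report$intra,
                report$inter[, c("feature", "channel", "inter_cv")],
                by = c("feature", "channel"))
  ranked <- rank_features(report)
  tidy <- merge(tidy, data.frame(feature = ranked$feature,
                                 score = ranked$composite,
                                 rank = seq_len(nrow(ranked))),
                by = "feature")
  tidy <- tidy[order(tidy$rank, tidy$channel, tidy$gesture), ]
  utils::write.table(tidy, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
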