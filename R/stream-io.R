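#' Write sample streams as delimited text plus a manifest
#'
#' Each stream becomes one tab-separated file with columns
#' `t, p1..p5, yaw, pitch, roll` (orientation columns present only when the
#' stream carries Euler data), alongside a single JSON manifest recording
#' label, session, trial, sampling period and generator seed per file.
#' The round trip through [read_streams()] is lossless at full double
#' precision.
#'
#' @param streams List of [sample_stream()] objects.
#' @param dir Output directory (created if missing).
#' @param seed Optional generator seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_streams <- function(streams, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    s <- streams[[i]]
    stopifnot(inherits(s, "sample_stream"))
    fname <- sprintf("stream_%03d.tsv", i)
    n <- nrow(s$pressures)
    df <- data.frame(t = (seq_len(n) - 1) * s$sampling_period,
                     s$pressures, check.names = FALSE)
    if (!is.null(s$euler)) df <- cbind(df, s$euler)
    # 17 significant digits keep doubles exact through the text round trip
    utils::write.table(format(df, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       file.path(dir, fname),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    entries[[i]] <- list(file = fname, label = s$label,
                         session_id = s$session_id, trial_id = s$trial_id,
                         sampling_period = s$sampling_period,
                         has_euler = !is.null(s$euler))
  }
  manifest <- list(format = "pfmg-streams/1", seed = seed, streams = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read sample streams written by [write_streams()]
#'
#' @param dir Directory containing `manifest.json` and the stream files.
#' @return List of [sample_stream()] objects in manifest order.
#' @export
read_streams <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(path)
  lapply(manifest$streams, function(e) {
    df <- utils::read.table(file.path(dir, e$file), header = TRUE, sep = "\t")
    euler <- if (isTRUE(e$has_euler)) {
      as.matrix(df[, c("yaw", "pitch", "roll")])
    }
    sample_stream(as.matrix(df[, paste0("p", 1:5)]),
                  label = e$label, session_id = e$session_id,
                  trial_id = e$trial_id,
                  sampling_period = e$sampling_period, euler = euler)
  })
}
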