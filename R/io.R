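#' Write spike trains to a tab-separated file
#'
#' Two-column format with header `channel<TAB>time_ms`, one row per spike,
#' sorted by time; the duration and periodicity are stored in `#`-prefixed
#' header comments so that the round trip is lossless.
#'
#' @param x a [spike_train_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  ch <- rep(seq_len(x$n_channels), lengths(x$spike_times))
  tm <- unlist(x$spike_times, use.names = FALSE)
  o <- order(tm, ch)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_ms=%.17g", x$duration),
               sprintf("# periodic=%d", as.integer(x$periodic)),
               sprintf("# n_channels=%d", x$n_channels),
               "channel\ttime_ms"), con)
  if (length(tm))
    writeLines(sprintf("%d\t%.17g", ch[o], tm[o]), con)
  invisible(path)
}

#' Read spike trains from a tab-separated file
#'
#' Inverse of [write_spike_trains()]; validates sortedness and range and
#' reports the offending line on malformed input.
#'
#' @param path input file.
#' @return a [spike_train_set()].
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("missing header comment '# ", key, "=' in ", path)
    as.numeric(sub(paste0("^# ", key, "="), "", m[1]))
  }
  duration <- get_hdr("duration_ms")
  periodic <- get_hdr("periodic") == 1
  n_channels <- as.integer(get_hdr("n_channels"))
  body_at <- which(lines == "channel\ttime_ms")
  if (!length(body_at)) stop("missing 'channel\\ttime_ms' header in ", path)
  rows <- lines[-seq_len(body_at[1])]
  rows <- rows[nzchar(rows)]
  trains <- rep(list(numeric(0)), n_channels)
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      ch <- suppressWarnings(as.integer(p[1]))
      tm <- suppressWarnings(as.numeric(p[2]))
      if (length(p) != 2 || is.na(ch) || is.na(tm))
        stop("malformed spike record at line ", body_at[1] + k, " of ", path)
      if (ch < 1 || ch > n_channels)
        stop("channel out of range at line ", body_at[1] + k, " of ", path)
      trains[[ch]] <- c(trains[[ch]], tm)
    }
  }
  spike_train_set(trains, duration, periodic)
}

#' Write aligned traces to a delimited table
#'
#' First column `time_ms`, one named column per trace; full double
#' precision so the round trip through [read_traces()] is exact.
#'
#' @param traces named list or data frame of equal-length numeric vectors.
#' @param dt grid step (ms).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, dt, path) {
  traces <- as.data.frame(traces)
  df <- cbind(time_ms = (seq_len(nrow(traces)) - 1) * dt, traces)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace table written by [write_traces()]
#'
#' @param path input file.
#' @return data frame with `time_ms` first.
#' @export
read_traces <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
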