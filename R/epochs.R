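#' Construct an epoch set
#'
#' The canonical in-memory container for segmented EEG: a numeric array of
#' trials x channels x samples plus a per-trial metadata table.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param trials Data frame with one row per trial; must contain at least
#'   `participant`, `movie_id`, `role`, `repetition`.
#' @param channels Character vector of channel names.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param t_start_s Time of the first sample relative to movie onset.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, trials, channels, sample_rate_hz, t_start_s = -0.5) {
  if (length(dim(data)) != 3)
    stop("`data` must be a 3-d array (trials x channels x samples)", call. = FALSE)
  required <- c("participant", "movie_id", "role", "repetition")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(trials) != dim(data)[1])
    stop("trial table rows must match the first data dimension", call. = FALSE)
  if (length(channels) != dim(data)[2])
    stop("channel names must match the second data dimension", call. = FALSE)
  structure(list(
    data = data,
    trials = trials,
    channels = as.character(channels),
    sample_rate_hz = sample_rate_hz,
    time = t_start_s + (seq_len(dim(data)[3]) - 1) / sample_rate_hz
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz (%.2f..%.2f s)\n",
              d[1], d[2], d[3], x$sample_rate_hz, min(x$time), max(x$time)))
  cat(sprintf("participants: %d; roles: %s\n",
              length(unique(x$trials$participant)),
              paste(names(table(x$trials$role)), collapse = "/")))
  invisible(x)
}

subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE],
            epochs$trials[idx, , drop = FALSE],
            epochs$channels, epochs$sample_rate_hz, epochs$time[1])
}

#' Write an epoch set to the native container
#'
#' The container is a directory holding the sample payload as little-endian
#' float64 (`payload.bin`), the axis/channel metadata as JSON (`meta.json`)
#' and the trial table as CSV (`trials.csv`). The round trip is lossless for
#' the payload (bit-identical doubles).
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    container = "waversa-epochs",
    version = 1L,
    dims = dim(epochs$data),
    channels = epochs$channels,
    sample_rate_hz = epochs$sample_rate_hz,
    t_start_s = epochs$time[1]
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "payload.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  utils::write.csv(epochs$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read an epoch set
#'
#' Only the native container format is supported (see [write_epochs()]).
#'
#' @param path Container directory.
#' @param format Input format; `"container"` is the native layout.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path, format = c("container", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format != "container")
    stop("format '", format, "' is not supported by this build; ",
         "use the native container", call. = FALSE)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("malformed container: missing meta.json under ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("dims", "channels", "sample_rate_hz", "t_start_s"))
    if (is.null(meta[[field]]))
      stop("malformed container metadata: missing field `", field, "`",
           call. = FALSE)
  dims <- as.integer(meta$dims)
  con <- file(file.path(path, "payload.bin"), "rb")
  on.exit(close(con))
  payload <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  if (length(payload) != prod(dims))
    stop("payload length does not match metadata dims", call. = FALSE)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  required <- c("participant", "movie_id", "role", "repetition")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("container trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  epoch_set(array(payload, dims), trials, meta$channels,
            meta$sample_rate_hz, meta$t_start_s)
}

#' Recode behavioural responses
#'
#' Correct responses slower than `rt_limit_s` or given with the lowest
#' ("guessing") confidence rating are recoded as incorrect, so that responses
#' plausibly based on reasoning rather than memory do not count as remembered.
#'
#' @param trials Trial table with `ac_correct`, `source_correct`, `confidence`,
#'   `rt_s` columns.
#' @param rt_limit_s Response-time limit in seconds.
#' @param guess_level Confidence level treated as guessing.
#' @return The trial table with recoded accuracy columns; the number of
#'   recoded responses per column is attached as attribute `n_recoded`.
#' @export
recode_behavior <- function(trials, rt_limit_s = 10, guess_level = 1) {
  n_recoded <- c(ac_correct = 0L, source_correct = 0L)
  flag <- trials$rt_s > rt_limit_s | trials$confidence == guess_level
  flag[is.na(flag)] <- FALSE
  for (col in names(n_recoded)) {
    if (is.null(trials[[col]])) next
    hit <- flag & trials[[col]] == 1
    n_recoded[[col]] <- sum(hit)
    trials[[col]][hit] <- 0L
  }
  attr(trials, "n_recoded") <- n_recoded
  trials
}
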