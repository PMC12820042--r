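#' Canonical movie segment schedule
#'
#' Every movie tiles 13 s of content after t = 0 with five segments:
#' first Sim alone (2 s), first Sim acting in its context (3 s), a fixation
#' cross (1 s), the second Sim alone (2 s), and both Sims interacting in the
#' context (5 s). t = 0 is the onset of the first Sim display; the leading
#' fixation sits in [-1, 0) and is only partly inside the -0.5..13.5 s epoch.
#'
#' @return A data frame with columns `segment`, `start_s`, `end_s`.
#' @export
segment_schedule <- function() {
  data.frame(
    segment = c("sim_first", "sim_first_context", "fixation",
                "sim_second", "joint_context"),
    start_s = c(0, 2, 5, 6, 8),
    end_s   = c(2, 5, 6, 8, 13),
    stringsAsFactors = FALSE
  )
}

#' Build an experiment design
#'
#' Encodes the associative-inference movie schema: `n_triads` AB movies, each
#' with a corresponding BC movie sharing its triad, plus `n_triads` XY movies
#' sharing no triad with any AB movie; every movie is shown `n_repetitions`
#' times. The segment schedule is fixed (see [segment_schedule()]); the
#' channel neighbour graph is built from a supplied adjacency or from a
#' deterministic grid layout.
#'
#' @param n_triads Number of AB/BC/XY triads (study design: 24).
#' @param n_repetitions Presentations per movie (study design: 5).
#' @param sample_rate_hz Sampling rate of the epochs in Hz.
#' @param channels Character vector of channel names, or an integer giving the
#'   number of synthetic channels to create.
#' @param neighbor_graph Optional symmetric logical/0-1 adjacency matrix over
#'   channels; by default a grid layout adjacency is constructed.
#' @return An object of class `experiment_design`.
#' @export
build_design <- function(n_triads = 24, n_repetitions = 5, sample_rate_hz = 500,
                         channels = 62, neighbor_graph = NULL) {
  if (!is.numeric(n_triads) || length(n_triads) != 1 || n_triads < 1 ||
      n_triads != round(n_triads))
    stop("`n_triads` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_repetitions) || length(n_repetitions) != 1 ||
      n_repetitions < 1 || n_repetitions != round(n_repetitions))
    stop("`n_repetitions` must be a positive integer", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be positive", call. = FALSE)
  if (is.numeric(channels) && length(channels) == 1)
    channels <- sprintf("ch%02d", seq_len(channels))
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("duplicate channel names: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)

  n_triads <- as.integer(n_triads)
  n_repetitions <- as.integer(n_repetitions)
  ids <- function(role, k) sprintf("%s%02d", role, k)
  movies <- rbind(
    data.frame(movie_id = ids("AB", seq_len(n_triads)), role = "AB",
               triad_id = seq_len(n_triads), stringsAsFactors = FALSE),
    data.frame(movie_id = ids("BC", seq_len(n_triads)), role = "BC",
               triad_id = seq_len(n_triads), stringsAsFactors = FALSE),
    data.frame(movie_id = ids("XY", seq_len(n_triads)), role = "XY",
               triad_id = n_triads + seq_len(n_triads), stringsAsFactors = FALSE)
  )

  if (is.null(neighbor_graph)) {
    neighbor_graph <- grid_neighbor_graph(channels)
  } else {
    neighbor_graph <- (neighbor_graph | t(neighbor_graph)) * 1
    if (!identical(dim(neighbor_graph), c(length(channels), length(channels))))
      stop("`neighbor_graph` must be a square matrix over channels", call. = FALSE)
    dimnames(neighbor_graph) <- list(channels, channels)
  }

  structure(list(
    n_triads = n_triads,
    n_repetitions = n_repetitions,
    movies = movies,
    segment_table = segment_schedule(),
    epoch_window = c(-0.5, 13.5),
    sample_rate_hz = sample_rate_hz,
    channel_names = channels,
    neighbor_graph = neighbor_graph
  ), class = "experiment_design")
}

# Deterministic near-square grid layout; channels are placed row-major and
# orthogonal grid neighbours are adjacent.
grid_neighbor_graph <- function(channels) {
  n <- length(channels)
  ncol_ <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1) %/% ncol_
  col <- (seq_len(n) - 1) %% ncol_
  adj <- matrix(0L, n, n, dimnames = list(channels, channels))
  for (i in seq_len(n)) {
    d <- abs(row - row[i]) + abs(col - col[i])
    adj[i, d == 1] <- 1L
  }
  adj
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design: %d triads x %d repetitions, %d channels @ %g Hz\n",
              x$n_triads, x$n_repetitions, length(x$channel_names),
              x$sample_rate_hz))
  cat(sprintf("epoch %g..%g s; segments: %s\n", x$epoch_window[1],
              x$epoch_window[2],
              paste(x$segment_table$segment, collapse = ", ")))
  invisible(x)
}

design_movie <- function(design, movie_id) {
  i <- match(movie_id, design$movies$movie_id)
  if (is.na(i)) stop("unknown movie_id: ", movie_id, call. = FALSE)
  design$movies[i, ]
}

#' Corresponding AB movie of a BC movie
#'
#' @param design An `experiment_design`.
#' @param bc_movie_id A BC movie id.
#' @return The AB movie id sharing the BC movie's triad.
#' @export
corresponding_ab <- function(design, bc_movie_id) {
  m <- design_movie(design, bc_movie_id)
  if (m$role != "BC") stop(bc_movie_id, " is not a BC movie", call. = FALSE)
  ab <- design$movies[design$movies$role == "AB" &
                        design$movies$triad_id == m$triad_id, "movie_id"]
  stopifnot(length(ab) == 1)
  ab
}

rep_pairs <- function(n_repetitions) {
  if (n_repetitions < 2)
    return(data.frame(rep_1 = integer(0), rep_2 = integer(0)))
  idx <- utils::combn(seq_len(n_repetitions) - 1L, 2)
  data.frame(rep_1 = idx[1, ], rep_2 = idx[2, ])
}

#' Enumerate within-movie repetition pairs
#'
#' All unordered repetition pairs of one AB movie: choose(R, 2) pairs, ten for
#' the five-repetition study design. Enumeration order is lexicographic, so
#' downstream averages are bit-for-bit reproducible.
#'
#' @param design An `experiment_design`.
#' @param movie_id An AB movie id.
#' @return A `pair_set` data frame with columns `movie_id_1`, `rep_1`,
#'   `movie_id_2`, `rep_2` and attribute `pair_kind = "within_movie"`.
#' @export
enumerate_within_pairs <- function(design, movie_id) {
  m <- design_movie(design, movie_id)
  if (m$role != "AB") stop("within-movie pairs are enumerated for AB movies", call. = FALSE)
  rp <- rep_pairs(design$n_repetitions)
  out <- data.frame(movie_id_1 = rep(movie_id, nrow(rp)), rep_1 = rp$rep_1,
                    movie_id_2 = rep(movie_id, nrow(rp)), rep_2 = rp$rep_2,
                    stringsAsFactors = FALSE)
  structure(out, pair_kind = "within_movie", class = c("pair_set", "data.frame"))
}

#' Enumerate between-movie pairs for one anchor AB movie
#'
#' Pairs the anchor AB movie with every other AB movie using the same
#' unordered repetition-index scheme (rep_1 < rep_2), i.e.
#' (n_AB - 1) * choose(R, 2) pairs — 230 for the 24-movie, 5-repetition
#' design. A design with a single AB movie yields an empty set.
#'
#' @inheritParams enumerate_within_pairs
#' @return A `pair_set` data frame with attribute `pair_kind = "between_movie"`.
#' @export
enumerate_between_pairs <- function(design, movie_id) {
  m <- design_movie(design, movie_id)
  if (m$role != "AB") stop("between-movie pairs are enumerated for AB movies", call. = FALSE)
  others <- design$movies$movie_id[design$movies$role == "AB" &
                                     design$movies$movie_id != movie_id]
  rp <- rep_pairs(design$n_repetitions)
  if (length(others) == 0 || nrow(rp) == 0) {
    out <- data.frame(movie_id_1 = character(0), rep_1 = integer(0),
                      movie_id_2 = character(0), rep_2 = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(pair = seq_len(nrow(rp)), other = others,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(movie_id_1 = rep(movie_id, nrow(grid)),
                      rep_1 = rp$rep_1[grid$pair],
                      movie_id_2 = grid$other,
                      rep_2 = rp$rep_2[grid$pair],
                      stringsAsFactors = FALSE)
    out <- out[order(out$movie_id_2, out$rep_1, out$rep_2), ]
    rownames(out) <- NULL
  }
  structure(out, pair_kind = "between_movie", class = c("pair_set", "data.frame"))
}

#' Segment time window
#'
#' @param design An `experiment_design`.
#' @param segment A segment name from the canonical schedule.
#' @return Numeric `c(start_s, end_s)`.
#' @export
segment_window <- function(design, segment) {
  st <- design$segment_table
  i <- match(segment, st$segment)
  if (is.na(i)) stop("unknown segment: ", segment, call. = FALSE)
  c(st$start_s[i], st$end_s[i])
}

# Channel adjacency as a 0-based neighbour list for the C++ cluster kernels.
neighbor_list <- function(adj) {
  if (is.null(adj)) return(NULL)
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] != 0) - 1L)
}

#' Serialise a design to disk
#'
#' Writes the design as JSON plus the segment schedule as a BED-like TSV
#' (`segment`, `start_s`, `end_s`) for auditability.
#'
#' @param design An `experiment_design`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(design)
  out$neighbor_graph <- NULL
  jsonlite::write_json(out, file.path(path, "design.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.table(design$segment_table, file.path(path, "segments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(design$neighbor_graph, file.path(path, "neighbors.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(path)
}
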