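template_cells <- function(template) {
  # (channel, freq) cells with any time support, channel-major order
  # (frequency ascending within channel, channels concatenated head to tail)
  any_t <- apply(template$mask, c(1, 2), any)
  idx <- which(t(any_t), arr.ind = TRUE)     # rows: (freq, channel) pairs
  if (!nrow(idx)) return(NULL)
  data.frame(channel = idx[, 2], freq = idx[, 1])[order(idx[, 2], idx[, 1]), ]
}

# Map each template timepoint to the TFR timepoints it covers (half a
# template step on either side); computed once per (template, time axis).
template_time_map <- function(template, tfr_times) {
  step <- if (length(template$times) > 1) diff(template$times[1:2]) else Inf
  lapply(template$times, function(s)
    which(tfr_times >= s - step / 2 & tfr_times < s + step / 2))
}

# TFR timepoints covered by the template's time support for one cell.
cell_time_support <- function(template, channel, freq, tfr_times,
                              time_map = NULL) {
  on_sel <- template$mask[channel, freq, ]
  if (!any(on_sel)) return(integer(0))
  if (is.null(time_map)) time_map <- template_time_map(template, tfr_times)
  sort(unique(unlist(time_map[on_sel])))
}

#' Extract the feature vector of an AB movie
#'
#' Averages the dB-scaled cubes of a movie's repetitions, restricts the
#' average to the template's (channel, frequency, time) support, takes the
#' median over time per (channel, frequency) cell — a stable estimate under
#' small temporal shifts across repetitions — and concatenates the cells
#' channel head-to-tail (frequency ascending within channel).
#'
#' @param cubes List of dB-scaled `tfr_cube`s, one per repetition of the
#'   movie.
#' @param template A `feature_template` with a nonempty mask.
#' @param movie_id Identifier carried in the result.
#' @return A `feature_vector`: `values`, `cells` (channel/freq indices),
#'   `segment`, `movie_id`.
#' @export
extract_ab_features <- function(cubes, template, movie_id = NA_character_) {
  if (!length(cubes)) stop("no cubes supplied", call. = FALSE)
  if (any(vapply(cubes, function(cb) cb$scale, "") != "db"))
    stop("feature extraction needs dB-scaled cubes", call. = FALSE)
  cells <- template_cells(template)
  if (is.null(cells))
    stop("empty feature template for segment '", template$segment,
         "': refusing to extract features", call. = FALSE)
  avg <- cubes[[1]]$power
  if (length(cubes) > 1)
    for (i in 2:length(cubes)) avg <- avg + cubes[[i]]$power
  avg <- avg / length(cubes)
  tfr_times <- cubes[[1]]$times
  tmap <- template_time_map(template, tfr_times)
  values <- vapply(seq_len(nrow(cells)), function(i) {
    tix <- cell_time_support(template, cells$channel[i], cells$freq[i],
                             tfr_times, tmap)
    stats::median(avg[cells$channel[i], cells$freq[i], tix])
  }, numeric(1))
  structure(list(values = values, cells = cells,
                 segment = template$segment, movie_id = movie_id),
            class = "feature_vector")
}

#' Time-resolved similarity between an AB feature vector and a target epoch
#'
#' At each timepoint of the target cube, the (channel, frequency) slice is
#' masked and ordered exactly like the anchor vector, Pearson-correlated with
#' it, and Fisher z-transformed (|r| clipped at 1 - 1e-7 before atanh).
#' Timepoints with invalid (edge) samples or zero variance are marked NA.
#'
#' @param anchor A `feature_vector`.
#' @param target_cube A dB-scaled `tfr_cube`.
#' @param template The `feature_template` the anchor was extracted with.
#' @return A `similarity_series`: `z`, `times`, `anchor`, `target`,
#'   `baseline_applied = "none"`.
#' @export
similarity_timecourse <- function(anchor, target_cube, template) {
  if (target_cube$scale != "db")
    stop("target cube must be dB-scaled", call. = FALSE)
  cells <- anchor$cells
  M <- masked_cell_matrix(target_cube, cells)
  z <- cor_fisher_z(matrix(anchor$values, ncol = 1), M,
                    masked_valid(target_cube, cells))
  structure(list(z = as.vector(z), times = target_cube$times,
                 anchor = list(movie_id = anchor$movie_id,
                               segment = anchor$segment),
                 target = target_cube$trial[c("movie_id", "role", "repetition")] %||%
                   NULL,
                 baseline_applied = "none"),
            class = "similarity_series")
}

# cells x timepoints matrix of one cube's masked values
masked_cell_matrix <- function(cube, cells) {
  d <- dim(cube$power)
  lin <- cells$channel + (cells$freq - 1) * d[1]
  matrix(cube$power[outer(lin, (seq_len(d[3]) - 1) * d[1] * d[2], "+")],
         nrow(cells), d[3])
}

masked_valid <- function(cube, cells) {
  colSums(!cube$valid[cells$freq, , drop = FALSE]) == 0
}

# Pearson -> clipped Fisher z of every anchor column against every timepoint
# column; returns anchors x timepoints with NA at invalid/degenerate points.
cor_fisher_z <- function(A, M, ok_t) {
  n <- nrow(M)
  mu <- colMeans(M)
  ss <- colSums(M^2) - n * mu^2
  use <- ok_t & !is.na(ss) & ss > 0
  z <- matrix(NA_real_, ncol(A), ncol(M))
  a_ok <- apply(A, 2, function(a) stats::sd(a) > 0)
  if (any(use) && any(a_ok)) {
    r <- stats::cor(A[, a_ok, drop = FALSE], M[, use, drop = FALSE])
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
    z[a_ok, use] <- atanh(r)
  }
  z
}

#' Baseline a similarity series against control series
#'
#' Subtracts, at each timepoint, the mean Fisher z over the baseline series
#' (averaging in z space) from the corresponding-movie series. Baselines are
#' either AB-vs-XY series or AB-vs-non-corresponding-BC series.
#'
#' @param sim_corr A `similarity_series` for the corresponding BC movie.
#' @param sim_baselines Nonempty list of `similarity_series` on the same time
#'   axis.
#' @param mode `"vs_xy"` or `"vs_noncorresponding_bc"`.
#' @return A `similarity_series` with the contrast in `z`.
#' @export
baseline_contrast <- function(sim_corr, sim_baselines,
                              mode = c("vs_xy", "vs_noncorresponding_bc")) {
  mode <- match.arg(mode)
  if (!length(sim_baselines))
    stop("empty baseline list", call. = FALSE)
  for (b in sim_baselines)
    if (!isTRUE(all.equal(b$times, sim_corr$times)))
      stop("baseline series are not on the corresponding series' time axis",
           call. = FALSE)
  B <- vapply(sim_baselines, `[[`, numeric(length(sim_corr$z)), "z")
  if (is.null(dim(B))) B <- matrix(B, ncol = length(sim_baselines))
  bmean <- rowMeans(B, na.rm = TRUE)
  bmean[!is.finite(bmean)] <- NA_real_
  out <- sim_corr
  out$z <- sim_corr$z - bmean
  out$baseline_applied <- mode
  out
}

#' Average a similarity series over a time window
#'
#' @param series A `similarity_series`.
#' @param window `c(start_s, end_s)`; timepoints in `[start, end)`.
#' @return Mean Fisher z over the valid timepoints in the window.
#' @export
window_average <- function(series, window) {
  inside <- series$times >= window[1] & series$times < window[2]
  vals <- series$z[inside]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop(sprintf("no valid timepoints in window [%g, %g) for anchor %s",
                 window[1], window[2],
                 series$anchor$movie_id %||% "?"), call. = FALSE)
  mean(vals)
}

#' Channel-neighbourhood topography of similarity
#'
#' Repeats the similarity time course per channel using only the template
#' cells of that channel and its montage neighbours, yielding a topographic
#' Fisher-z map (channels x timepoints). Channels whose neighbourhood holds
#' fewer than two template cells are marked invalid (all-NA rows). A graph
#' with no edges degenerates to single-channel neighbourhoods.
#'
#' @param ab_cubes dB cubes of the anchor movie's repetitions.
#' @param target_cube dB cube of the target epoch.
#' @param template A `feature_template`.
#' @param neighbor_graph Channel adjacency matrix.
#' @return Matrix channels x timepoints of Fisher z.
#' @export
neighborhood_topography <- function(ab_cubes, target_cube, template,
                                    neighbor_graph) {
  n_ch <- dim(target_cube$power)[1]
  out <- matrix(NA_real_, n_ch, dim(target_cube$power)[3])
  full <- extract_ab_features(ab_cubes, template)
  for (c0 in seq_len(n_ch)) {
    hood <- c(c0, which(neighbor_graph[c0, ] != 0))
    keep <- full$cells$channel %in% hood
    if (sum(keep) < 2) next
    anchor <- full
    anchor$values <- full$values[keep]
    anchor$cells <- full$cells[keep, ]
    s <- similarity_timecourse(anchor, target_cube, template)
    out[c0, ] <- s$z
  }
  rownames(out) <- template$channels
  out
}
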