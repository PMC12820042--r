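#' Smoothing specification for wavelet coherence
#'
#' Coherence needs a smoothing operator: without it the magnitude-squared
#' coherence is identically 1. Time smoothing uses a Gaussian kernel whose SD
#' defaults to `time_halfwidth_periods` wavelet periods at each frequency
#' (frequency-dependent), or a fixed `time_halfwidth_s`; scale smoothing is a
#' boxcar over `scale_halfwidth_bins` adjacent frequency bins.
#'
#' @param time_halfwidth_periods Gaussian SD in wavelet periods (per
#'   frequency); ignored if `time_halfwidth_s` is given.
#' @param time_halfwidth_s Fixed Gaussian SD in seconds, or `NULL`.
#' @param scale_halfwidth_bins Boxcar halfwidth over frequency bins.
#' @return A `smoothing_spec` list.
#' @export
smoothing_spec <- function(time_halfwidth_periods = 3, time_halfwidth_s = NULL,
                           scale_halfwidth_bins = 1) {
  structure(list(time_halfwidth_periods = time_halfwidth_periods,
                 time_halfwidth_s = time_halfwidth_s,
                 scale_halfwidth_bins = as.integer(scale_halfwidth_bins)),
            class = "smoothing_spec")
}

smoothing_sigma_samples <- function(smoothing, freq, grid_rate_hz) {
  if (!is.null(smoothing$time_halfwidth_s))
    return(smoothing$time_halfwidth_s * grid_rate_hz)
  smoothing$time_halfwidth_periods / freq * grid_rate_hz
}

# Boxcar over the frequency dimension of a channels x freq x time array,
# truncated at the grid edges.
boxcar_freq <- function(arr, hw) {
  if (hw < 1) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  cs <- array(0, c(d[1], d[2] + 1, d[3]))
  for (f in seq_len(d[2])) cs[, f + 1, ] <- cs[, f, ] + arr[, f, ]
  for (f in seq_len(d[2])) {
    lo <- max(1, f - hw); hi <- min(d[2], f + hw)
    out[, f, ] <- (cs[, hi + 1, ] - cs[, lo, ]) / (hi - lo + 1)
  }
  out
}

smooth_time_arr <- function(arr, smoothing, freqs, grid_rate_hz) {
  # arr: channels x freq x time; Gaussian time smoothing per frequency
  d <- dim(arr)
  out <- array(0, d)
  for (f in seq_len(d[2])) {
    sigma <- smoothing_sigma_samples(smoothing, freqs[f], grid_rate_hz)
    out[, f, ] <- t(cpp_gauss_smooth(t(arr[, f, , drop = TRUE]), sigma))
  }
  out
}

#' Wavelet coherence between two epochs
#'
#' Magnitude-squared coherence |S(Wx conj(Wy))|^2 / (S(|Wx|^2) S(|Wy|^2))
#' per channel, frequency and timepoint, where S is the smoothing operator of
#' [smoothing_spec()] (Gaussian over time, boxcar over adjacent frequency
#' bins). Values lie in [0, 1]; the map is symmetric in its two inputs, and
#' identical inputs give coherence 1 everywhere valid.
#'
#' @param x,y Channels x samples matrices of equal shape.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param freqs Integer frequency grid in Hz.
#' @param n_cycles Morlet cycles (shared with the TFR analysis).
#' @param time_step_s Time grid of the coherence map.
#' @param smoothing A [smoothing_spec()].
#' @param t_start_s Time of the first sample.
#' @return A `coherence_map`: `coherence` and `phase` arrays (channels x
#'   frequencies x timepoints), `freqs_hz`, `times`, `valid`, `smoothing`.
#' @export
wavelet_coherence <- function(x, y, sample_rate_hz, freqs = 3:30, n_cycles = 5,
                              time_step_s = 0.1,
                              smoothing = smoothing_spec(), t_start_s = 0) {
  if (!identical(dim(x), dim(y)))
    stop("epochs must have identical shape", call. = FALSE)
  stride <- max(1L, round(time_step_s * sample_rate_hz))
  grid_rate <- sample_rate_hz / stride
  family <- morlet_family(freqs, n_cycles, sample_rate_hz)
  mx <- morlet_coefficients(x, sample_rate_hz, freqs, n_cycles, stride, family)
  my <- morlet_coefficients(y, sample_rate_hz, freqs, n_cycles, stride, family)
  cross <- mx$coef * Conj(my$coef)
  sr <- smooth_time_arr(Re(cross), smoothing, freqs, grid_rate)
  si <- smooth_time_arr(Im(cross), smoothing, freqs, grid_rate)
  ax <- smooth_time_arr(Mod(mx$coef)^2, smoothing, freqs, grid_rate)
  ay <- smooth_time_arr(Mod(my$coef)^2, smoothing, freqs, grid_rate)
  hw <- smoothing$scale_halfwidth_bins
  sr <- boxcar_freq(sr, hw); si <- boxcar_freq(si, hw)
  ax <- boxcar_freq(ax, hw); ay <- boxcar_freq(ay, hw)
  denom <- ax * ay
  coh <- (sr^2 + si^2) / denom
  coh <- pmin(pmax(coh, 0), 1)
  phase <- atan2(si, sr)
  valid_ft <- mx$valid & my$valid
  valid <- array(rep(as.vector(valid_ft), each = nrow(x)), dim(coh)) &
    denom > 0
  coh[!valid] <- NA_real_
  phase[!valid] <- NA_real_
  structure(list(coherence = coh, phase = phase, freqs_hz = freqs,
                 times = t_start_s + (mx$idx - 1) / sample_rate_hz,
                 valid = valid, smoothing = smoothing),
            class = "coherence_map")
}

#' Wavelet coefficient bank for coherence analysis
#'
#' Complex Morlet coefficients on the coherence time grid for every epoch of
#' one participant, keyed `"movie_id:repetition"`.
#'
#' @param epochs An `epoch_set` (one participant).
#' @inheritParams wavelet_coherence
#' @return List with `coef` (timepoints x channels x frequencies x epochs
#'   complex array), `keys`, `valid`, `times`, `freqs_hz`, `grid_rate_hz`.
#' @export
coherence_coefficients <- function(epochs, freqs = 3:30, n_cycles = 5,
                                   time_step_s = 0.1) {
  sr <- epochs$sample_rate_hz
  stride <- max(1L, round(time_step_s * sr))
  family <- morlet_family(freqs, n_cycles, sr)
  n_ep <- nrow(epochs$trials)
  n_ch <- dim(epochs$data)[2]
  n <- dim(epochs$data)[3]
  max_h <- max(vapply(family, `[[`, 1, "halfwidth"))
  N <- fft_length(n + 2 * max_h + 1, stride)
  idx <- seq(1, n, by = stride)
  X <- matrix(0, N, n_ch * n_ep)
  for (j in seq_len(n_ep))
    X[1:n, (j - 1) * n_ch + seq_len(n_ch)] <- t(epochs$data[j, , ])
  Xf <- stats::mvfft(X)
  coef <- array(NA_complex_, c(length(idx), n_ch, length(freqs), n_ep))
  valid <- matrix(FALSE, length(freqs), length(idx))
  for (fi in seq_along(freqs)) {
    ker <- family[[fi]]$kernel
    h <- family[[fi]]$halfwidth
    Kf <- stats::fft(c(ker, rep(0, N - length(ker))))
    y <- ifft_decimated(Xf * Kf, h, stride)[seq_along(idx), , drop = FALSE]
    coef[, , fi, ] <- array(y, c(length(idx), n_ch, n_ep))
    valid[fi, ] <- (idx - h >= 1) & (idx + h <= n)
  }
  list(coef = coef,
       keys = paste(epochs$trials$movie_id, epochs$trials$repetition, sep = ":"),
       valid = valid,
       times = epochs$time[1] + (idx - 1) / sr,
       freqs_hz = freqs,
       grid_rate_hz = sr / stride)
}

#' Participant-level within/between coherence summary
#'
#' Averages wavelet coherence over all within-movie repetition pairs and all
#' between-movie pairs of a participant's AB epochs (240 and 5520 pairs for
#' the full study design), yielding one within map and one between map per
#' participant. Pairs whose epochs are missing are skipped and counted;
#' movies with no epochs at all raise an error.
#'
#' @param bank A coefficient bank from [coherence_coefficients()].
#' @param pairs_within,pairs_between `pair_set` data frames (stacked over
#'   movies).
#' @param smoothing A [smoothing_spec()].
#' @param chunk Pairs processed per block (memory/speed trade-off).
#' @return List with `within`, `between` (channels x frequencies x timepoints
#'   arrays), `times`, `freqs_hz`, `valid`, `n_pairs`, `n_skipped`.
#' @export
participant_coherence_summary <- function(bank, pairs_within, pairs_between,
                                          smoothing = smoothing_spec()) {
  d <- dim(bank$coef)            # T x ch x freq x epochs
  Tn <- d[1]; n_ch <- d[2]; n_f <- d[3]
  freqs <- bank$freqs_hz
  hw <- smoothing$scale_halfwidth_bins
  sig_samp <- vapply(freqs, smoothing_sigma_samples, numeric(1),
                     smoothing = smoothing, grid_rate_hz = bank$grid_rate_hz)

  accumulate <- function(pairs) {
    missing_movie <- setdiff(unique(c(pairs$movie_id_1, pairs$movie_id_2)),
                             sub(":.*", "", bank$keys))
    if (length(missing_movie))
      stop("no epochs for movie(s): ", paste(missing_movie, collapse = ", "),
           call. = FALSE)
    ii <- match(paste(pairs$movie_id_1, pairs$rep_1, sep = ":"), bank$keys)
    jj <- match(paste(pairs$movie_id_2, pairs$rep_2, sep = ":"), bank$keys)
    ok <- !is.na(ii) & !is.na(jj)
    n_skip <- sum(!ok)
    if (n_skip) message(n_skip, " pair(s) skipped: missing repetition(s)")
    ii <- ii[ok]; jj <- jj[ok]
    if (!length(ii))
      return(list(map = array(NA_real_, c(n_ch, n_f, Tn)), n = 0L,
                  n_skipped = n_skip))
    res <- cpp_pair_coherence(bank$coef, d, ii, jj, sig_samp, hw)
    map <- res$sum / res$count
    map[res$count == 0] <- NA_real_
    list(map = map, n = length(ii), n_skipped = n_skip)
  }

  w <- accumulate(pairs_within)
  b <- accumulate(pairs_between)
  valid <- array(rep(as.vector(bank$valid), each = n_ch), c(n_ch, n_f, Tn))
  w$map[!valid] <- NA; b$map[!valid] <- NA
  list(within = w$map, between = b$map, times = bank$times,
       freqs_hz = freqs, valid = valid,
       n_pairs = c(within = w$n, between = b$n),
       n_skipped = c(within = w$n_skipped, between = b$n_skipped))
}

#' Select movie-content-sensitive time-frequency templates
#'
#' Contrasts per-participant within-AB against between-AB coherence maps with
#' a positive-tail cluster-based permutation test, separately within each of
#' the four AB movie segment windows (first Sim, first Sim in context, second
#' Sim, joint context). Each segment's template mask is the union of its
#' significant clusters' members; an empty mask is returned with a warning
#' when no cluster survives (downstream feature extraction refuses empty
#' masks).
#'
#' @param within_maps,between_maps Lists (one element per participant) of
#'   channels x frequencies x timepoints coherence maps on a common grid.
#' @param design An `experiment_design` (segment windows, channel adjacency).
#' @param times,freqs Axes of the coherence maps.
#' @param segments Segment names to test.
#' @param n_permutations,cluster_alpha,alpha,seed Cluster-test settings (see
#'   [paired_cluster_test()]).
#' @return A named list of `feature_template` objects, one per segment:
#'   `segment`, `mask` (channels x frequencies x window timepoints), `times`,
#'   `freqs_hz`, `channels`, `cluster` (the `cluster_result`).
#' @export
select_template <- function(within_maps, between_maps, design, times, freqs,
                            segments = c("sim_first", "sim_first_context",
                                         "sim_second", "joint_context"),
                            n_permutations = 1000, cluster_alpha = 0.05,
                            alpha = 0.05, seed = 1L) {
  stopifnot(length(within_maps) == length(between_maps),
            length(within_maps) >= 2)
  n <- length(within_maps)
  templates <- list()
  for (seg in segments) {
    win <- segment_window(design, seg)
    tidx <- which(times >= win[1] & times < win[2])
    dims <- c(dim(within_maps[[1]])[1:2], length(tidx))
    w <- t(vapply(within_maps, function(m) as.vector(m[, , tidx, drop = FALSE]),
                  numeric(prod(dims))))
    b <- t(vapply(between_maps, function(m) as.vector(m[, , tidx, drop = FALSE]),
                  numeric(prod(dims))))
    res <- paired_cluster_test(w, b, dims = dims,
                               chan_adj = design$neighbor_graph,
                               n_permutations = n_permutations,
                               cluster_alpha = cluster_alpha, alpha = alpha,
                               tail = "pos", seed = seed)
    sig_ids <- res$clusters$id[res$clusters$significant & res$clusters$sign > 0]
    mask <- array(res$labels %in% sig_ids, dims)
    if (!any(mask))
      warning("no significant coherence cluster in segment '", seg, "'",
              call. = FALSE)
    templates[[seg]] <- structure(list(
      segment = seg, mask = mask, times = times[tidx], freqs_hz = freqs,
      channels = design$channel_names, cluster = res
    ), class = "feature_template")
  }
  templates
}

#' @export
print.feature_template <- function(x, ...) {
  cat(sprintf("feature_template '%s': %d/%d cells selected, %d (channel,freq) cells, %.2f..%.2f s\n",
              x$segment, sum(x$mask), length(x$mask),
              sum(apply(x$mask, c(1, 2), any)), min(x$times), max(x$times)))
  invisible(x)
}
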