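#' Morlet wavelet family
#'
#' Complex Morlet wavelets (a complex sinusoid under a Gaussian envelope)
#' with a fixed number of cycles, normalised to unit discrete energy so that
#' unit-variance white noise has flat expected power across frequencies.
#'
#' @param freqs Centre frequencies in Hz.
#' @param n_cycles Number of cycles (sets sigma_t = n_cycles / (2 pi f)).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return List with one element per frequency: `kernel` (complex vector) and
#'   `halfwidth` (samples).
#' @keywords internal
morlet_family <- function(freqs, n_cycles, sample_rate_hz) {
  lapply(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    h <- ceiling(3.5 * sigma_t * sample_rate_hz)
    t <- (-h:h) / sample_rate_hz
    psi <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
    psi <- psi / sqrt(sum(Mod(psi)^2))
    list(kernel = psi, halfwidth = h)
  })
}

# Exact inverse FFT of a spectrum evaluated only at samples s0 + stride*m
# (0-based), via spectral folding: decimating by `stride` aliases the
# spectrum onto N/stride bins, so a length-N/stride inverse FFT suffices.
# Z: N x K spectrum; requires stride | N. Returns (N/stride) x K.
ifft_decimated <- function(Z, s0, stride) {
  N <- nrow(Z)
  if (stride == 1) {
    y <- stats::mvfft(Z, inverse = TRUE) / N
    return(y[(s0 + 1):N, , drop = FALSE])
  }
  M <- N %/% stride
  # fold with per-block scalar twiddles, then one short twiddle: for
  # k = j + b*M, exp(2i pi k s0 / N) = exp(2i pi j s0 / N) exp(2i pi b s0 / stride)
  folded <- Z[1:M, , drop = FALSE]
  for (b in seq_len(stride - 1)) {
    w <- exp(2i * pi * b * s0 / stride)
    folded <- folded + w * Z[(b * M + 1):((b + 1) * M), , drop = FALSE]
  }
  if (s0 != 0) folded <- folded * exp(2i * pi * (0:(M - 1)) * s0 / N)
  stats::mvfft(folded, inverse = TRUE) / N
}

# smallest FFT length >= n that is a multiple of stride with smooth factors
fft_length <- function(n, stride) {
  stride * stats::nextn(ceiling(n / stride), factors = c(2, 3, 5))
}

# Complex Morlet coefficients of one epoch (channels x samples matrix).
# Returns coef[channel, freq, timepoint] on the decimated grid plus a
# freq x timepoint validity mask (FALSE where the wavelet support sticks out
# of the epoch).
morlet_coefficients <- function(x, sample_rate_hz, freqs, n_cycles, stride,
                                family = NULL) {
  n <- ncol(x)
  if (is.null(family)) family <- morlet_family(freqs, n_cycles, sample_rate_hz)
  max_h <- max(vapply(family, `[[`, 1, "halfwidth"))
  if (2 * max_h + 1 > n)
    stop("epoch too short for the lowest-frequency wavelet", call. = FALSE)
  N <- fft_length(n + 2 * max_h + 1, stride)
  Xf <- stats::mvfft(rbind(t(x), matrix(0, N - n, nrow(x))))
  idx <- seq(1, n, by = stride)
  coef <- array(NA_complex_, c(nrow(x), length(freqs), length(idx)))
  valid <- matrix(FALSE, length(freqs), length(idx))
  for (k in seq_along(freqs)) {
    ker <- family[[k]]$kernel
    h <- family[[k]]$halfwidth
    Kf <- stats::fft(c(ker, rep(0, N - length(ker))))
    w <- ifft_decimated(Xf * Kf, h, stride)[seq_along(idx), , drop = FALSE]
    coef[, k, ] <- t(w)                      # centre-aligned samples
    valid[k, ] <- (idx - h >= 1) & (idx + h <= n)
  }
  list(coef = coef, valid = valid, idx = idx)
}

#' Morlet time-frequency decomposition
#'
#' Decomposes epochs into power over channel x frequency x time using complex
#' Morlet wavelets. The defaults (3-30 Hz in 1-Hz steps — 28 bins — 5 cycles,
#' 0.02 s resolution) mirror the encoding analysis. Timepoints where the
#' wavelet support exceeds the epoch are flagged invalid in `valid`, not
#' silently zero-padded.
#'
#' @param x A channels x samples numeric matrix or an `epoch_set`.
#' @param sample_rate_hz Sampling rate (taken from the epoch set if given).
#' @param freq_lo,freq_hi Frequency range in Hz (integer 1-Hz grid).
#' @param n_cycles Wavelet cycles.
#' @param time_step_s Temporal resolution of the output grid.
#' @param t_start_s Time of the first sample (matrix input only).
#' @param ... Passed between methods.
#' @return A `tfr_cube`: list with `power` (channels x frequencies x
#'   timepoints, linear scale), `freqs_hz`, `times`, `valid`
#'   (frequencies x timepoints), `scale`, `channels`. For an `epoch_set`, a
#'   list of cubes (one per trial, in trial-table order).
#' @export
morlet_transform <- function(x, ...) UseMethod("morlet_transform")

#' @rdname morlet_transform
#' @export
morlet_transform.matrix <- function(x, sample_rate_hz, freq_lo = 3,
                                    freq_hi = 30, n_cycles = 5,
                                    time_step_s = 0.02, t_start_s = 0, ...) {
  if (freq_lo <= 0 || freq_hi < freq_lo)
    stop("invalid frequency range", call. = FALSE)
  freqs <- seq(freq_lo, freq_hi)
  stride <- max(1L, round(time_step_s * sample_rate_hz))
  mc <- morlet_coefficients(x, sample_rate_hz, freqs, n_cycles, stride)
  power <- Re(mc$coef)^2 + Im(mc$coef)^2
  structure(list(
    power = power,
    freqs_hz = freqs,
    times = t_start_s + (mc$idx - 1) / sample_rate_hz,
    valid = mc$valid,
    scale = "linear",
    channels = rownames(x) %||% sprintf("ch%02d", seq_len(nrow(x)))
  ), class = "tfr_cube")
}

#' @rdname morlet_transform
#' @export
morlet_transform.epoch_set <- function(x, freq_lo = 3, freq_hi = 30,
                                       n_cycles = 5, time_step_s = 0.02, ...) {
  lapply(seq_len(nrow(x$trials)), function(i) {
    m <- x$data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rownames(m) <- x$channels
    cube <- morlet_transform(m, sample_rate_hz = x$sample_rate_hz,
                             freq_lo = freq_lo, freq_hi = freq_hi,
                             n_cycles = n_cycles, time_step_s = time_step_s,
                             t_start_s = x$time[1])
    cube$trial <- x$trials[i, ]
    cube
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear-power cubes for many epochs at once: one forward FFT batch over all
# (channel, epoch) series, one inverse per frequency. Same output as calling
# morlet_transform() per epoch.
morlet_power_many <- function(data, rows, sample_rate_hz, freqs, n_cycles,
                              time_step_s, t_start_s, channels) {
  n <- dim(data)[3]
  n_ch <- dim(data)[2]
  k <- length(rows)
  family <- morlet_family(freqs, n_cycles, sample_rate_hz)
  max_h <- max(vapply(family, `[[`, 1, "halfwidth"))
  stride <- max(1L, round(time_step_s * sample_rate_hz))
  N <- fft_length(n + 2 * max_h + 1, stride)
  idx <- seq(1, n, by = stride)
  X <- matrix(0, N, n_ch * k)
  for (j in seq_len(k))
    X[1:n, (j - 1) * n_ch + seq_len(n_ch)] <- t(data[rows[j], , ])
  Xf <- stats::mvfft(X)
  power <- array(NA_real_, c(n_ch, length(freqs), length(idx), k))
  valid <- matrix(FALSE, length(freqs), length(idx))
  for (fi in seq_along(freqs)) {
    ker <- family[[fi]]$kernel
    h <- family[[fi]]$halfwidth
    Kf <- stats::fft(c(ker, rep(0, N - length(ker))))
    y <- ifft_decimated(Xf * Kf, h, stride)[seq_along(idx), , drop = FALSE]
    w <- Re(y)^2 + Im(y)^2
    power[, fi, , ] <- aperm(array(w, c(length(idx), n_ch, k)), c(2, 1, 3))
    valid[fi, ] <- (idx - h >= 1) & (idx + h <= n)
  }
  times <- t_start_s + (idx - 1) / sample_rate_hz
  lapply(seq_len(k), function(j) {
    pw <- power[, , , j, drop = FALSE]
    dim(pw) <- dim(power)[1:3]
    structure(list(power = pw,
                   freqs_hz = freqs, times = times, valid = valid,
                   scale = "linear", channels = channels),
              class = "tfr_cube")
  })
}

#' @export
print.tfr_cube <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("tfr_cube [%s]: %d channels x %d freqs (%g-%g Hz) x %d timepoints (%.2f..%.2f s)\n",
              x$scale, d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Decibel normalisation relative to the epoch-average power
#'
#' Transforms a linear-power cube to dB relative to the mean power across the
#' epoch, per channel and frequency: `10 * log10(P / mean_t(P))`. The epoch
#' mean runs over valid (non-edge) timepoints only. This emphasises relative
#' power fluctuations tied to movie content and removes the 1/f profile.
#'
#' @param cube A linear-scale `tfr_cube`.
#' @return The cube in dB scale; the per-cell reference means are kept in
#'   `db_ref` so [db_denormalize()] can invert the transform.
#' @export
db_normalize <- function(cube) {
  if (!inherits(cube, "tfr_cube")) stop("not a tfr_cube", call. = FALSE)
  if (cube$scale != "linear")
    stop("cube is already dB-scaled", call. = FALSE)
  d <- dim(cube$power)
  ref <- matrix(NA_real_, d[1], d[2])
  for (k in seq_len(d[2])) {
    ok <- cube$valid[k, ]
    if (!any(ok))
      stop("no valid timepoints at frequency ", cube$freqs_hz[k], call. = FALSE)
    ref[, k] <- rowMeans(cube$power[, k, ok, drop = FALSE], na.rm = TRUE)
  }
  bad <- which(ref <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("zero epoch-mean power at channel %s, frequency %g Hz",
                 cube$channels[bad[1, 1]], cube$freqs_hz[bad[1, 2]]),
         call. = FALSE)
  cube$power <- cpp_db(cube$power, as.vector(ref))
  cube$scale <- "db"
  cube$db_ref <- ref
  cube
}

#' Invert [db_normalize()]
#'
#' @param cube A dB-scaled `tfr_cube` produced by [db_normalize()].
#' @return The cube back on the linear scale.
#' @export
db_denormalize <- function(cube) {
  stopifnot(inherits(cube, "tfr_cube"))
  if (cube$scale != "db" || is.null(cube$db_ref))
    stop("cube is not dB-scaled with a stored reference", call. = FALSE)
  cube$power <- 10^(cube$power / 10) * as.vector(cube$db_ref)
  cube$scale <- "linear"
  cube$db_ref <- NULL
  cube
}
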