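#' Simulation parameters for the synthetic-EEG generator
#'
#' The generator plants, per movie and segment, a channel-by-frequency
#' oscillatory signature that is stable across repetitions (up to temporal
#' jitter and additive pink noise). Corresponding AB/BC movie pairs share a
#' scaled common pattern component while the novel first Sim of the BC movie
#' is on screen (`integration_effect` >= 0) and an anti-correlated component
#' while the shared second Sim is on screen (`separation_effect` <= 0).
#' Setting both to zero yields a fully null dataset.
#'
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   epoch sets.
#' @param n_participants Number of simulated participants.
#' @param noise_sd Standard deviation of the additive pink noise.
#' @param pink_exponent Spectral exponent of the noise (power ~ 1/f^exponent).
#' @param signature_bands Data frame with `band_low_hz`, `band_high_hz`,
#'   `amplitude`: the oscillatory bands carrying movie signatures. Each
#'   integer frequency bin of a band holds one constant-modulus spectral
#'   line whose phase trajectory is movie-specific (frozen across
#'   repetitions) and drifts with `line_width_hz` bandwidth, so repetitions
#'   of the same movie are phase-coherent while different movies decorrelate
#'   within the coherence smoothing window.
#' @param pattern_sd SD of the movie/segment-specific log-amplitude
#'   deviations that define each movie's channel x frequency pattern
#'   (amplitude = band amplitude x exp(deviation)).
#' @param line_width_hz Lorentzian linewidth of the phase drift in Hz.
#' @param segment_gain Per-role multiplicative amplitude gains per segment.
#'   The defaults weight the reference (epoch-mean) power away from the
#'   windows carrying planted patterns, so the dB normalisation does not
#'   reabsorb the planted components.
#' @param bc_power_effect Multiplicative amplitude gain on the BC movies'
#'   first-Sim segments (univariate power manipulation; < 1 plants a power
#'   decrease relative to XY, 1 = none).
#' @param anchor_pattern_scale Multiplier on the AB movies' joint-segment
#'   pattern deviations. Matching it to the planted-effect scale passes the
#'   anchor and the planted target component through the same log-amplitude
#'   nonlinearity, so the planted correlation survives feature extraction.
#' @param repetition_jitter_s Maximal temporal jitter between repetitions.
#' @param integration_effect Scale of the common AB->BC pattern component
#'   planted during the first-Sim segments of BC movies (>= 0).
#' @param separation_effect Scale of the anti-correlated component planted
#'   during the second-Sim segment of BC movies (<= 0).
#' @param behavior_link Logistic-link coefficients tying trial outcomes to the
#'   planted (dis)similarities; see [generate_outcomes()].
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              n_participants = 12,
                              noise_sd = 0.5,
                              pink_exponent = 1,
                              signature_bands = data.frame(
                                band_low_hz = c(3, 5, 9, 16, 28),
                                band_high_hz = c(3, 5, 9, 16, 28),
                                amplitude = 2.5),
                              pattern_sd = 0.3,
                              line_width_hz = 0.1,
                              segment_gain = list(
                                AB = c(joint_context = 0.5),
                                BC = c(fixation = 2.5, joint_context = 2.5)),
                              bc_power_effect = 1,
                              anchor_pattern_scale = 2.5,
                              repetition_jitter_s = 0.05,
                              integration_effect = 6.0,
                              separation_effect = -6.0,
                              behavior_link = list(
                                intercept_ac = -3, beta_ac_on_similarity = 0.6,
                                intercept_source = -3,
                                beta_source_on_dissimilarity = -0.6)) {
  if (integration_effect < 0)
    stop("`integration_effect` must be >= 0", call. = FALSE)
  if (separation_effect > 0)
    stop("`separation_effect` must be <= 0", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    noise_sd = noise_sd, pink_exponent = pink_exponent,
    signature_bands = signature_bands, pattern_sd = pattern_sd,
    line_width_hz = line_width_hz, segment_gain = segment_gain,
    bc_power_effect = bc_power_effect,
    anchor_pattern_scale = anchor_pattern_scale,
    repetition_jitter_s = repetition_jitter_s,
    integration_effect = integration_effect,
    separation_effect = separation_effect,
    behavior_link = behavior_link
  ), class = "simulation_params")
}

# Brownian phase trajectories (Lorentzian linewidth), one column per series.
phase_drift <- function(n, k, line_width_hz, sample_rate) {
  s_phi <- sqrt(2 * pi * line_width_hz / sample_rate)
  apply(matrix(stats::rnorm(n * k, sd = s_phi), n, k), 2, cumsum)
}

# Pink noise, one column per series, scaled to unit SD.
pink_noise <- function(n, k, exponent, sample_rate) {
  w <- matrix(stats::rnorm(n * k), n, k)
  W <- stats::mvfft(w)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  g <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::mvfft(W * g, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Generate a synthetic epoch set
#'
#' Builds one epoch per (participant, movie, repetition) following the movie
#' segment schedule. Movie signatures are band-limited noise waveforms, frozen
#' across repetitions of the same movie, with channel x frequency amplitude
#' patterns that differ by segment; repetitions are jittered in time and
#' embedded in pink noise. BC movies carry the planted integration and
#' separation components relative to their corresponding AB movie (see
#' [simulation_params()]). Trial outcomes are generated from the planted
#' (dis)similarities via [generate_outcomes()].
#'
#' @param design An `experiment_design`.
#' @param params A `simulation_params` object.
#' @return An `epoch_set`; its trial table carries the planted per-trial
#'   (dis)similarity scalars and the simulated behavioural outcomes.
#' @export
generate_epochs <- function(design, params) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "simulation_params"))
  sr <- design$sample_rate_hz
  seg <- design$segment_table
  if (any(abs(seg$start_s * sr - round(seg$start_s * sr)) > 1e-9) ||
      any(abs(seg$end_s * sr - round(seg$end_s * sr)) > 1e-9))
    stop("segment boundaries are not representable at this sample rate",
         call. = FALSE)
  n_samp <- round(diff(design$epoch_window) * sr)
  time <- design$epoch_window[1] + (seq_len(n_samp) - 1) / sr
  channels <- design$channel_names
  n_ch <- length(channels)
  movies <- design$movies
  R <- design$n_repetitions

  bands <- params$signature_bands
  bins <- do.call(rbind, lapply(seq_len(nrow(bands)), function(b) {
    f <- seq(ceiling(bands$band_low_hz[b]), floor(bands$band_high_hz[b]))
    data.frame(freq = f, amplitude = bands$amplitude[b])
  }))
  n_bin <- nrow(bins)
  seg_of_sample <- rep(NA_integer_, n_samp)
  for (s in seq_len(nrow(seg))) {
    inside <- time >= seg$start_s[s] & time < seg$end_s[s]
    seg_of_sample[inside] <- s
  }

  set.seed(params$seed)
  trials_per_p <- nrow(movies) * R
  n_trials <- params$n_participants * trials_per_p
  data <- array(0, c(n_trials, n_ch, n_samp))
  trial_rows <- vector("list", params$n_participants)
  row0 <- 0L

  for (p in seq_len(params$n_participants)) {
    # movie/segment-specific pattern deviations: delta[cell, segment, movie]
    delta <- array(stats::rnorm(n_ch * n_bin * nrow(seg) * nrow(movies),
                                sd = params$pattern_sd),
                   c(n_ch * n_bin, nrow(seg), nrow(movies)))
    # frozen per-movie waveforms: a coherent comb of constant-modulus
    # spectral lines per (movie, channel). All lines of one channel share a
    # Brownian phase trajectory (plus fixed per-line offsets), so
    # repetitions of the same movie stay phase-coherent while different
    # movies decorrelate within the coherence smoothing window, and the
    # line interference at the wavelet output is deterministic rather than
    # stochastic.
    drift <- phase_drift(n_samp, n_ch * nrow(movies), params$line_width_hz, sr)
    tvec <- (seq_len(n_samp) - 1) / sr
    wave <- array(0, c(n_samp, n_ch * n_bin, nrow(movies)))
    for (b in seq_len(n_bin)) {
      cols <- (b - 1) * n_ch + seq_len(n_ch)
      # line phase offsets are per (channel, bin) but shared across movies,
      # so the wavelet's cross-line interference acts as the same fixed
      # mixing operator on every movie's amplitude pattern
      theta <- matrix(rep(stats::runif(n_ch, 0, 2 * pi), nrow(movies)),
                      n_samp, n_ch * nrow(movies), byrow = TRUE)
      wv <- sqrt(2) * cos(2 * pi * bins$freq[b] * tvec + theta + drift)
      wave[, cols, ] <- array(wv, c(n_samp, n_ch, nrow(movies)))
    }

    joint_idx <- match("joint_context", seg$segment)
    delta[, joint_idx, movies$role == "AB"] <-
      delta[, joint_idx, movies$role == "AB"] * params$anchor_pattern_scale
    tt <- expand.grid(repetition = seq_len(R) - 1L,
                      movie = seq_len(nrow(movies)),
                      KEEP.OUT.ATTRS = FALSE)
    tt <- data.frame(participant = p,
                     movie_id = movies$movie_id[tt$movie],
                     role = movies$role[tt$movie],
                     triad_id = movies$triad_id[tt$movie],
                     repetition = tt$repetition,
                     movie_idx = tt$movie,
                     stringsAsFactors = FALSE)
    tt$u_int <- stats::runif(nrow(tt), 0.85, 1.15)
    tt$u_sep <- stats::runif(nrow(tt), 0.85, 1.15)
    tt$jitter <- round(stats::runif(nrow(tt), -1, 1) *
                         params$repetition_jitter_s * sr)
    is_bc <- tt$role == "BC"
    tt$planted_similarity <- ifelse(is_bc, params$integration_effect * tt$u_int, 0)
    tt$planted_dissimilarity <- ifelse(is_bc, params$separation_effect * tt$u_sep, 0)

    amp_base <- rep(bins$amplitude, each = n_ch)   # cell order: channel-major per bin
    seg_first <- match(c("sim_first", "sim_first_context"), seg$segment)
    seg_second <- match("sim_second", seg$segment)

    noise <- pink_noise(n_samp, n_ch * nrow(tt), params$pink_exponent, sr) *
      params$noise_sd

    # summed oscillatory signal of movie m with pattern deviations d;
    # log-amplitude patterns keep planted correlations exact (no clipping).
    # Note the log-normal mean effect: segments carrying strong planted
    # patterns also carry more mean power (heavier amplitude tails), which
    # the univariate BC-vs-XY contrast picks up as a broadband difference.
    build_signal <- function(m, d) {
      amp <- matrix(amp_base * exp(as.vector(d)),
                    n_ch * n_bin, nrow(seg))       # cells x segments
      gains <- params$segment_gain[[movies$role[m]]]
      if (!is.null(gains))
        for (gs in names(gains))
          amp[, match(gs, seg$segment)] <- amp[, match(gs, seg$segment)] * gains[[gs]]
      if (movies$role[m] == "BC" && params$bc_power_effect != 1)
        amp[, seg_first] <- amp[, seg_first] * params$bc_power_effect
      env <- matrix(amp_base, n_samp, n_ch * n_bin, byrow = TRUE)
      ok <- !is.na(seg_of_sample)
      env[ok, ] <- t(amp[, seg_of_sample[ok]])
      sig <- wave[, , m] * env
      x <- matrix(0, n_samp, n_ch)
      for (b in seq_len(n_bin)) x <- x + sig[, (b - 1) * n_ch + seq_len(n_ch)]
      x
    }
    # AB/XY envelopes are repetition-invariant: build their signal once
    base_sig <- vector("list", nrow(movies))
    for (m in which(movies$role != "BC"))
      base_sig[[m]] <- build_signal(m, delta[, , m])

    for (i in seq_len(nrow(tt))) {
      m <- tt$movie_idx[i]
      if (is_bc[i]) {
        d <- delta[, , m]
        ab <- match(corresponding_ab(design, tt$movie_id[i]), movies$movie_id)
        anchor <- delta[, joint_idx, ab]
        # additive planting: pattern correlation with the anchor pattern is
        # e*u / sqrt(1 + (e*u)^2), sign from the effect's sign
        d[, seg_first] <- d[, seg_first] +
          params$integration_effect / params$anchor_pattern_scale *
          tt$u_int[i] * anchor
        d[, seg_second] <- d[, seg_second] +
          params$separation_effect / params$anchor_pattern_scale *
          tt$u_sep[i] * anchor
        x <- build_signal(m, d)
      } else {
        x <- base_sig[[m]]
      }
      if (tt$jitter[i] != 0) {               # whole-signal repetition jitter
        sh <- tt$jitter[i] %% n_samp
        if (sh != 0) x <- rbind(x[(n_samp - sh + 1):n_samp, , drop = FALSE],
                                x[1:(n_samp - sh), , drop = FALSE])
      }
      x <- x + noise[, (i - 1) * n_ch + seq_len(n_ch)]
      data[row0 + i, , ] <- t(x)
    }
    tt$movie_idx <- NULL
    trial_rows[[p]] <- tt
    row0 <- row0 + nrow(tt)
  }

  trials <- do.call(rbind, trial_rows)
  outcomes <- generate_outcomes(
    trials[, c("planted_similarity", "planted_dissimilarity")],
    behavior_link = params$behavior_link,
    seed = params$seed + 1000L)
  trials <- cbind(trials, outcomes)
  rownames(trials) <- NULL
  epoch_set(data, trials, channels, sr, design$epoch_window[1])
}

#' Generate trial outcomes from planted (dis)similarities
#'
#' Associative (AC) accuracy follows a Bernoulli draw with a logistic link on
#' the planted similarity; source-memory accuracy uses a logistic link on the
#' planted dissimilarity. Confidence (1 = guessing, 2 = maybe, 3 = sure) and
#' response time are generated with monotone links so the behavioural
#' recoding rules (see [recode_behavior()]) have material to act on.
#'
#' @param planted Data frame with numeric columns `planted_similarity` and
#'   `planted_dissimilarity`, one row per trial.
#' @param behavior_link List with `intercept_ac`, `beta_ac_on_similarity`,
#'   `intercept_source`, `beta_source_on_dissimilarity`.
#' @param seed Integer seed.
#' @return Data frame with `ac_correct`, `source_correct`, `confidence`,
#'   `rt_s`.
#' @export
generate_outcomes <- function(planted, behavior_link, seed = 1L) {
  if (is.null(planted$planted_similarity) ||
      is.null(planted$planted_dissimilarity))
    stop("`planted` needs columns planted_similarity and planted_dissimilarity",
         call. = FALSE)
  sim <- planted$planted_similarity
  dis <- planted$planted_dissimilarity
  if (length(sim) != length(dis))
    stop("similarity and dissimilarity must have one value per trial",
         call. = FALSE)
  n <- length(sim)
  set.seed(seed)
  p_ac <- stats::plogis(behavior_link$intercept_ac +
                          behavior_link$beta_ac_on_similarity * sim)
  p_src <- stats::plogis(behavior_link$intercept_source +
                           behavior_link$beta_source_on_dissimilarity * dis)
  ac <- stats::rbinom(n, 1, p_ac)
  src <- stats::rbinom(n, 1, p_src)
  latent <- 0.5 * sim + stats::rlogis(n)
  confidence <- cut(latent, c(-Inf, -1, 1.2, Inf), labels = FALSE)
  rt <- exp(log(2.5) - 0.15 * sim + stats::rnorm(n, sd = 0.45))
  slow <- stats::runif(n) < 0.03
  rt[slow] <- rt[slow] + 9
  data.frame(ac_correct = ac, source_correct = src,
             confidence = as.integer(confidence), rt_s = rt)
}
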