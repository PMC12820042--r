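# small fixtures shared across tests; everything is generated in code

tiny_design <- function(n_triads = 2, n_repetitions = 3, sample_rate_hz = 100,
                        n_channels = 4) {
  build_design(n_triads, n_repetitions, sample_rate_hz, n_channels)
}

# a dB-scale cube built directly from a value array (channels x freqs x times)
fake_db_cube <- function(values, freqs = NULL, times = NULL) {
  d <- dim(values)
  if (is.null(freqs)) freqs <- seq_len(d[2]) + 2
  if (is.null(times)) times <- (seq_len(d[3]) - 1) * 0.02
  structure(list(power = values, freqs_hz = freqs, times = times,
                 valid = matrix(TRUE, d[2], d[3]), scale = "db",
                 channels = sprintf("ch%02d", seq_len(d[1]))),
            class = "tfr_cube")
}

# a full-mask feature template matching a cube geometry
full_template <- function(n_ch, n_freq, times, segment = "joint_context",
                          freqs = NULL) {
  structure(list(segment = segment,
                 mask = array(TRUE, c(n_ch, n_freq, length(times))),
                 times = times,
                 freqs_hz = freqs %||% (seq_len(n_freq) + 2),
                 channels = sprintf("ch%02d", seq_len(n_ch))),
            class = "feature_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerical-integration oracle for the NIG marginal likelihood ratio
# (Savage-Dickey cross-check): log-space quadrature over (mu, sigma^2) under
# H1 and over sigma^2 with mu = 0 under H0, using sufficient statistics.
numeric_bf10 <- function(y, mu0 = 0, v = 30, alpha = 15, beta = 15) {
  n <- length(y)
  ybar <- mean(y)
  ssq <- sum(y^2)
  loglik <- function(mu, s2)              # vectorised over mu
    -n / 2 * log(2 * pi * s2) - (ssq - 2 * mu * n * ybar + n * mu^2) / (2 * s2)
  lprior_s2 <- function(s2, a) a * log(beta) - lgamma(a) -
    (a + 1) * log(s2) - beta / s2
  s2_grid <- exp(seq(log(0.02), log(60), length.out = 500))
  ds2 <- c(diff(s2_grid), 0)
  # Savage-Dickey pairing: the point-null model inherits the conditional
  # variance prior p(sigma^2 | mu = 0) = IG(alpha + 1/2, beta)
  l0 <- loglik(0, s2_grid) + lprior_s2(s2_grid, alpha + 1 / 2)
  lm0 <- max(l0) + log(sum(exp(l0 - max(l0)) * ds2))
  l1 <- vapply(s2_grid, function(s2) {
    sdmu <- sqrt(s2 / v)
    se <- sqrt(s2 / n)
    lo <- min(mu0 - 8 * sdmu, ybar - 8 * se)
    hi <- max(mu0 + 8 * sdmu, ybar + 8 * se)
    mu_grid <- seq(lo, hi, length.out = 600)
    lv <- loglik(mu_grid, s2) + stats::dnorm(mu_grid, mu0, sdmu, log = TRUE)
    mx <- max(lv)
    mx + log(sum(exp(lv - mx)) * (mu_grid[2] - mu_grid[1])) +
      lprior_s2(s2, alpha)
  }, 0)
  lm1 <- max(l1) + log(sum(exp(l1 - max(l1)) * ds2))
  exp(lm1 - lm0)
}
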