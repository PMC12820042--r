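#' Normal-Inverse-Gamma prior
#'
#' Conjugate prior for a Gaussian mean and variance:
#' sigma^2 ~ Inv-Gamma(alpha, beta), mu | sigma^2 ~ N(mu0, sigma^2 / v).
#' `v` is the pseudo-observation precision weight on the mean. The defaults
#' are the informative prior used for the time-resolved similarity
#' statistics (alpha = 15, beta = 15, mu0 = 0, v = 30).
#'
#' @param mu0 Prior mean location.
#' @param v Pseudo-observation weight on the mean.
#' @param alpha,beta Inverse-gamma shape and scale of the variance.
#' @return An object of class `nig`.
#' @export
nig_prior <- function(mu0 = 0, v = 30, alpha = 15, beta = 15) {
  if (alpha <= 0 || beta <= 0 || v <= 0)
    stop("alpha, beta and v must be positive", call. = FALSE)
  structure(list(mu = mu0, v = v, alpha = alpha, beta = beta, n = 0L),
            class = "nig")
}

#' Conjugate NIG update
#'
#' Standard batch update: v_n = v + n, mu_n = (v mu0 + n ybar)/v_n,
#' alpha_n = alpha + n/2,
#' beta_n = beta + sum((y - ybar)^2)/2 + n v (ybar - mu0)^2 / (2 v_n).
#' Sequential one-at-a-time updating equals the batch formula (order
#' invariance); zero observations return the prior unchanged.
#'
#' @param prior An `nig` object.
#' @param y Numeric observations.
#' @return The posterior `nig` object.
#' @export
nig_update <- function(prior, y) {
  stopifnot(inherits(prior, "nig"))
  if (!length(y)) return(prior)
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite observation at index ", bad[1], call. = FALSE)
  n <- length(y)
  ybar <- mean(y)
  vn <- prior$v + n
  structure(list(
    mu = (prior$v * prior$mu + n * ybar) / vn,
    v = vn,
    alpha = prior$alpha + n / 2,
    beta = prior$beta + sum((y - ybar)^2) / 2 +
      n * prior$v * (ybar - prior$mu)^2 / (2 * vn),
    n = prior$n + n
  ), class = "nig")
}

# density of the marginal (scaled, shifted t) distribution of mu at x
nig_marginal_density <- function(par, x) {
  df <- 2 * par$alpha
  scale <- sqrt(par$beta / (par$alpha * par$v))
  stats::dt((x - par$mu) / scale, df = df) / scale
}

#' Savage-Dickey Bayes factor against mu = 0
#'
#' BF10 = prior marginal density of mu at 0 divided by the posterior marginal
#' density at 0. The marginal of mu under an NIG(mu, v, alpha, beta) is a t
#' distribution with 2 alpha degrees of freedom, location mu and scale
#' sqrt(beta / (alpha v)). A posterior equal to the prior gives BF10 = 1.
#'
#' @param prior,posterior `nig` objects.
#' @return The Bayes factor BF10 (evidence for a nonzero mean).
#' @export
bf10_vs_zero <- function(prior, posterior) {
  stopifnot(inherits(prior, "nig"), inherits(posterior, "nig"))
  d0 <- nig_marginal_density(prior, 0)
  d1 <- nig_marginal_density(posterior, 0)
  if (!is.finite(d0) || !is.finite(d1) || d1 < 0)
    stop("degenerate marginal density", call. = FALSE)
  d0 / d1
}

#' Bayesian evidence trace over timepoints
#'
#' For each timepoint, updates the NIG prior with all participants'
#' contrast values and computes the Savage-Dickey BF10 against zero.
#'
#' @param x Participants x timepoints matrix of Fisher-z contrasts (NAs
#'   dropped per timepoint).
#' @param times Time axis in seconds.
#' @param prior An `nig` prior.
#' @return An `evidence_trace` data frame: per timepoint the posterior
#'   parameters, `bf10` and the group `mean_contrast`.
#' @export
nig_trace <- function(x, times, prior = nig_prior()) {
  stopifnot(is.matrix(x), ncol(x) == length(times))
  k <- length(times)
  out <- data.frame(time = times, mu_n = NA_real_, v_n = NA_real_,
                    alpha_n = NA_real_, beta_n = NA_real_, bf10 = NA_real_,
                    mean_contrast = NA_real_, n_obs = 0L)
  for (t0 in seq_len(k)) {
    y <- x[, t0]
    y <- y[is.finite(y)]
    out$n_obs[t0] <- length(y)
    if (length(y) < 2) next
    post <- nig_update(prior, y)
    out$mu_n[t0] <- post$mu; out$v_n[t0] <- post$v
    out$alpha_n[t0] <- post$alpha; out$beta_n[t0] <- post$beta
    out$bf10[t0] <- bf10_vs_zero(prior, post)
    out$mean_contrast[t0] <- mean(y)
  }
  class(out) <- c("evidence_trace", "data.frame")
  out
}

#' Detect supra-threshold evidence windows
#'
#' Maximal runs of consecutive timepoints with BF10 at or above `threshold`
#' and a consistent sign of the mean contrast; runs lasting no more than
#' `min_duration_s` (n_samples x step) are dropped. Positive-contrast
#' windows mark similarity (integration), negative ones dissimilarity
#' (separation). Runs separated by any sub-threshold timepoint are never
#' merged.
#'
#' @param trace An `evidence_trace` (or data frame with `time`, `bf10`,
#'   `mean_contrast`).
#' @param threshold BF10 criterion (default 3, moderate evidence).
#' @param min_duration_s Minimal window duration in seconds (default 0.1).
#' @return Data frame with `start_s`, `end_s`, `duration_s`, `sign`
#'   (`"similarity"`/`"dissimilarity"`), `mean_contrast`, `min_bf10`,
#'   `n_points`.
#' @export
detect_windows <- function(trace, threshold = 3, min_duration_s = 0.1) {
  bf <- trace$bf10
  sgn <- sign(trace$mean_contrast)
  sgn[is.na(sgn)] <- 0
  supra <- !is.na(bf) & bf >= threshold & sgn != 0
  step <- if (nrow(trace) > 1) stats::median(diff(trace$time)) else NA_real_
  # run ids: break at sub-threshold points and at contrast sign changes
  brk <- c(TRUE, diff(supra) != 0 | (supra[-1] & sgn[-1] != sgn[-nrow(trace)]))
  run <- cumsum(brk)
  out <- list()
  for (r in unique(run[supra])) {
    idx <- which(run == r & supra)
    if (!length(idx)) next
    dur <- length(idx) * step
    if (!is.na(dur) && dur <= min_duration_s) next
    out[[length(out) + 1]] <- data.frame(
      start_s = trace$time[idx[1]], end_s = trace$time[idx[length(idx)]],
      duration_s = dur,
      sign = if (sgn[idx[1]] > 0) "similarity" else "dissimilarity",
      mean_contrast = mean(trace$mean_contrast[idx]),
      min_bf10 = min(bf[idx]), n_points = length(idx))
  }
  if (!length(out))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), sign = character(0),
                      mean_contrast = numeric(0), min_bf10 = numeric(0),
                      n_points = integer(0)))
  do.call(rbind, out)
}

#' Bayesian linear regression with a Multivariate-NIG prior
#'
#' Conjugate regression y = X b + e with b | sigma^2 ~ N(0, sigma^2
#' Lambda0^-1), Lambda0 = lambda_scale I, sigma^2 ~ Inv-Gamma(alpha, beta).
#' Posterior: Lambda_n = X'X + Lambda0, m_n = Lambda_n^-1 X'y, alpha_n =
#' alpha + n/2, beta_n = beta + (y'y - m_n' Lambda_n m_n)/2. Per-coefficient
#' BF10 is the Savage-Dickey ratio of the marginal t densities at zero.
#' With `standardize = TRUE` the response and predictors are z-scored before
#' fitting, so coefficients are standardized betas.
#'
#' @param y Numeric response (trial level).
#' @param X Data frame or matrix of predictors (no intercept column; one is
#'   added, and exempted from standardization).
#' @param lambda_scale Prior precision scale (30, the study's prior).
#' @param alpha,beta Inverse-gamma parameters (15, 15).
#' @param standardize Z-score y and predictors before fitting.
#' @return An `mvnig_result` with `coefficients` (term, beta, bf10),
#'   posterior parameters and the configuration.
#' @export
mvnig_regression <- function(y, X, lambda_scale = 30, alpha = 15, beta = 15,
                             standardize = TRUE) {
  X <- as.data.frame(X)
  terms <- names(X)
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  n <- length(y)
  if (n != nrow(Xm)) stop("y and X must have the same length", call. = FALSE)
  if (n <= ncol(Xm) + 1) stop("need n > number of predictors", call. = FALSE)
  const <- which(apply(Xm, 2, function(col) stats::sd(col) == 0))
  if (length(const))
    stop("constant (zero-variance) predictor column(s): ",
         paste(terms[const], collapse = ", "), call. = FALSE)
  qrX <- qr(cbind(1, Xm))
  if (qrX$rank < ncol(Xm) + 1) {
    dep <- terms[qrX$pivot[seq(qrX$rank + 1, ncol(Xm) + 1)] - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  if (standardize) {
    y <- as.vector(scale(y))
    Xm <- scale(Xm)
  }
  Xd <- cbind("(Intercept)" = 1, Xm)
  p <- ncol(Xd)
  Lambda0 <- diag(lambda_scale, p)
  Lambda_n <- crossprod(Xd) + Lambda0
  Lninv <- solve(Lambda_n)
  m_n <- Lninv %*% crossprod(Xd, y)
  alpha_n <- alpha + n / 2
  beta_n <- beta + (sum(y^2) - t(m_n) %*% Lambda_n %*% m_n)[1] / 2
  marg_density0 <- function(loc, scale2, a) {
    df <- 2 * a
    sc <- sqrt(scale2)
    stats::dt((0 - loc) / sc, df) / sc
  }
  bf <- vapply(seq_len(p), function(j) {
    prior_d <- marg_density0(0, beta / alpha / lambda_scale, alpha)
    post_d <- marg_density0(m_n[j], beta_n / alpha_n * Lninv[j, j], alpha_n)
    prior_d / post_d
  }, numeric(1))
  structure(list(
    coefficients = data.frame(term = colnames(Xd), beta = as.vector(m_n),
                              bf10 = bf, row.names = NULL),
    posterior = list(m_n = as.vector(m_n), Lambda_n = Lambda_n,
                     alpha_n = alpha_n, beta_n = beta_n),
    prior = list(lambda_scale = lambda_scale, alpha = alpha, beta = beta),
    n = n, standardized = standardize
  ), class = "mvnig_result")
}

#' @export
print.mvnig_result <- function(x, ...) {
  cat(sprintf("mvnig_result: n = %d trials%s\n", x$n,
              if (x$standardized) " (standardized)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Monte-Carlo comparison of effect sizes across conditions
#'
#' Draws `n_iter` normal samples per condition from (estimate, SE) and, for
#' each pair of conditions, converts the fraction of sampled differences
#' above/below zero into a two-tailed p-value
#' (p = 2 min(P(diff > 0), P(diff < 0))).
#'
#' @param estimates Named numeric vector of per-condition effect sizes.
#' @param ses Standard errors, same names/length; all > 0.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @param criterion Significance criterion attached to the output.
#' @return Data frame of condition pairs with `p_value` and `significant`.
#' @export
monte_carlo_effect_comparison <- function(estimates, ses, n_iter = 10000,
                                          seed = 1L, criterion = 0.05) {
  if (length(estimates) != length(ses))
    stop("estimates and ses must have equal length", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  if (is.null(names(estimates)))
    names(estimates) <- paste0("cond", seq_along(estimates))
  set.seed(seed)
  draws <- sapply(seq_along(estimates), function(i)
    stats::rnorm(n_iter, estimates[i], ses[i]))
  pairs <- utils::combn(seq_along(estimates), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dd <- draws[, i] - draws[, j]
    p <- 2 * min(mean(dd > 0), mean(dd < 0))
    data.frame(cond_1 = names(estimates)[i], cond_2 = names(estimates)[j],
               difference = estimates[i] - estimates[j], p_value = p)
  }))
  out$significant <- out$p_value < criterion
  attr(out, "n_iter") <- n_iter
  out
}
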