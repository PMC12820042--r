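test_that("the conjugate update matches its formulas and is order-invariant", {
  pr <- nig_prior()
  expect_identical(nig_update(pr, numeric(0)), pr)  # n = 0 -> prior
  set.seed(41)
  y <- rnorm(25, 0.4, 0.3)
  po <- nig_update(pr, y)
  expect_equal(po$v, 30 + 25)
  expect_equal(po$mu, (30 * 0 + 25 * mean(y)) / 55)
  expect_equal(po$alpha, 15 + 12.5)
  expect_equal(po$beta, 15 + sum((y - mean(y))^2) / 2 +
                 25 * 30 * mean(y)^2 / (2 * 55))
  # sequential over a shuffled order equals the batch update
  po_seq <- pr
  for (v in sample(y)) po_seq <- nig_update(po_seq, v)
  expect_equal(unlist(po_seq[c("mu", "v", "alpha", "beta")]),
               unlist(po[c("mu", "v", "alpha", "beta")]), tolerance = 1e-12)
  expect_error(nig_update(pr, c(1, NA, 3)), "index 2")
  expect_error(nig_prior(v = 0), "must be positive")
})

test_that("the posterior mean matches a numerical-integration oracle", {
  set.seed(42)
  y <- rnorm(10, 0.5, 0.1)
  po <- nig_update(nig_prior(), y)
  # grid posterior over (mu, sigma^2), normalised numerically
  mu_grid <- seq(-2, 2, length.out = 801)
  s2_grid <- seq(0.05, 8, length.out = 401)
  lik <- function(mu, s2) prod(dnorm(y, mu, sqrt(s2)))
  w <- outer(mu_grid, s2_grid, Vectorize(function(mu, s2)
    lik(mu, s2) * dnorm(mu, 0, sqrt(s2 / 30)) *
      s2^(-16) * exp(-15 / s2)))
  mu_hat <- sum(mu_grid * rowSums(w)) / sum(w)
  expect_lt(abs(po$mu - mu_hat), 1e-3)
})

test_that("Savage-Dickey BF10 is exact against the marginal-likelihood ratio", {
  pr <- nig_prior()
  expect_equal(bf10_vs_zero(pr, pr), 1)
  set.seed(43)
  for (case in 1:3) {
    y <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 1))
    bf <- bf10_vs_zero(pr, nig_update(pr, y))
    expect_lt(abs(bf / numeric_bf10(y) - 1), 0.01)
  }
})

test_that("BF10 grows monotonically with the sample mean magnitude", {
  pr <- nig_prior()
  sdv <- 0.3
  set.seed(44)
  base <- scale(rnorm(12))[, 1] * sdv
  bfs <- vapply(seq(0, 2, by = 0.25), function(m)
    bf10_vs_zero(pr, nig_update(pr, base + m)), 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("window detection applies the BF and duration rules exactly", {
  mk_trace <- function(bf, mc) data.frame(time = (seq_along(bf) - 1) * 0.02,
                                          bf10 = bf, mean_contrast = mc)
  # all sub-threshold -> nothing
  expect_equal(nrow(detect_windows(mk_trace(rep(2.9, 50), rep(1, 50)))), 0)
  # 4 supra samples (0.08 s) dropped; 7 samples (0.14 s) kept
  bf <- rep(1, 40); bf[5:8] <- 5; bf[20:26] <- 5
  w <- detect_windows(mk_trace(bf, rep(0.5, 40)))
  expect_equal(nrow(w), 1)
  expect_equal(w$n_points, 7)
  expect_equal(w$sign, "similarity")
  # runs separated by one sub-threshold sample are never merged
  bf2 <- rep(1, 40); bf2[5:14] <- 5; bf2[15] <- 2; bf2[16:25] <- 5
  w2 <- detect_windows(mk_trace(bf2, rep(-0.5, 40)))
  expect_equal(nrow(w2), 2)
  expect_true(all(w2$sign == "dissimilarity"))
  # a contrast sign change splits a run
  mc <- rep(0.5, 40); mc[5:14] <- 0.5; mc[15:24] <- -0.5
  bf3 <- rep(1, 40); bf3[5:24] <- 5
  w3 <- detect_windows(mk_trace(bf3, mc))
  expect_equal(nrow(w3), 2)
  expect_equal(w3$sign, c("similarity", "dissimilarity"))
  # padding with sub-threshold samples changes nothing
  w4 <- detect_windows(mk_trace(c(rep(1, 10), bf, rep(1, 10)),
                                rep(0.5, 60)))
  expect_equal(w4$n_points, w$n_points)
})

test_that("MVNIG regression recovers least squares in the flat-prior limit", {
  set.seed(45)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)  # orthonormal-ish
  X <- as.data.frame(scale(X)); names(X) <- c("a", "b")
  y <- as.vector(scale(0.5 * X$a - 0.3 * X$b + rnorm(n, sd = 0.5)))
  fit <- mvnig_regression(y, X, lambda_scale = 1e-8, standardize = FALSE)
  ls <- coef(lm(y ~ a + b, data = X))
  expect_equal(fit$coefficients$beta, unname(ls), tolerance = 1e-6)
})

test_that("degenerate designs are surfaced, not silently fitted", {
  set.seed(46)
  X <- data.frame(a = rnorm(30), b = 1)
  expect_error(mvnig_regression(rnorm(30), X), "constant.*b")
  X2 <- data.frame(a = rnorm(30))
  X2$b <- 2 * X2$a
  expect_error(mvnig_regression(rnorm(30), X2), "collinear")
  expect_error(mvnig_regression(rnorm(3), data.frame(a = rnorm(3),
                                                     b = rnorm(3),
                                                     c = rnorm(3))),
               "n > number of predictors")
})

test_that("trial-level regression flags planted couplings and spares nulls", {
  set.seed(47)
  n <- 600
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n, sd = sqrt(1 - 0.09))
  fit <- mvnig_regression(y, data.frame(x = x, rep = sample(0:3, n, TRUE)))
  bx <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_gt(bx$beta, 0.2)
  expect_gt(bx$bf10, 3)
  y0 <- rnorm(n)
  fit0 <- mvnig_regression(y0, data.frame(x = x))
  expect_lt(abs(fit0$coefficients$beta[2]), 0.15)
})

test_that("Monte-Carlo effect comparison behaves at its anchors", {
  same <- monte_carlo_effect_comparison(c(a = 1, b = 1), c(a = 0.2, b = 0.2),
                                        seed = 4)
  expect_gt(same$p_value, 0.95)
  far <- monte_carlo_effect_comparison(c(a = 0, b = 1), c(a = 0.1, b = 0.1),
                                       seed = 4)
  expect_lt(far$p_value, 0.001)
  expect_true(far$significant)
  expect_equal(attr(far, "n_iter"), 10000)
  expect_error(monte_carlo_effect_comparison(c(1, 2), c(0.1, 0)), "> 0")
  expect_error(monte_carlo_effect_comparison(c(1, 2), 0.1), "equal length")
})
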