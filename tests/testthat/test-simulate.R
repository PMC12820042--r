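small_params <- function(seed = 5, ...) {
  simulation_params(seed = seed, n_participants = 2, ...)
}

test_that("identical seed and parameters give bit-identical epoch sets", {
  d <- tiny_design()
  e1 <- generate_epochs(d, small_params())
  e2 <- generate_epochs(d, small_params())
  expect_identical(e1$data, e2$data)
  expect_identical(e1$trials, e2$trials)
  e3 <- generate_epochs(d, small_params(seed = 6))
  expect_false(identical(e1$data, e3$data))
})

test_that("epoch geometry and trial bookkeeping follow the design", {
  d <- tiny_design()
  ep <- generate_epochs(d, small_params())
  expect_equal(dim(ep$data)[3], round(14 * d$sample_rate_hz))
  expect_equal(nrow(ep$trials), 2 * nrow(d$movies) * d$n_repetitions)
  # every (participant, movie, repetition) combination appears exactly once
  key <- with(ep$trials, paste(participant, movie_id, repetition))
  expect_false(anyDuplicated(key) > 0)
  expect_equal(range(ep$time), c(-0.5, 13.5 - 1 / d$sample_rate_hz))
})

test_that("planted effect scalars sit only on BC trials and null them out", {
  d <- tiny_design()
  ep <- generate_epochs(d, small_params())
  tr <- ep$trials
  expect_true(all(tr$planted_similarity[tr$role != "BC"] == 0))
  expect_true(all(tr$planted_similarity[tr$role == "BC"] > 0))
  expect_true(all(tr$planted_dissimilarity[tr$role == "BC"] < 0))
  ep0 <- generate_epochs(d, small_params(integration_effect = 0,
                                         separation_effect = 0))
  expect_true(all(ep0$trials$planted_similarity == 0))
  expect_error(simulation_params(integration_effect = -1), "must be >= 0")
  expect_error(simulation_params(separation_effect = 1), "must be <= 0")
})

test_that("noise spectral slope matches the pink exponent within 0.2", {
  set.seed(3)
  x <- waversa:::pink_noise(2^14, 4, exponent = 1, sample_rate = 100)
  ps <- Mod(stats::mvfft(x))^2
  f <- (seq_len(2^14) - 1) * 100 / 2^14
  keep <- f > 0.5 & f < 40
  slope <- -stats::coef(stats::lm(log(rowMeans(ps)[keep]) ~ log(f[keep])))[2]
  expect_lt(abs(slope - 1), 0.2)
})

test_that("movie waveforms are frozen across repetitions (phase-coherent)", {
  d <- tiny_design()
  ep <- generate_epochs(d, small_params(noise_sd = 0.01,
                                        repetition_jitter_s = 0))
  tr <- ep$trials
  i1 <- which(tr$participant == 1 & tr$movie_id == "AB01" & tr$repetition == 0)
  i2 <- which(tr$participant == 1 & tr$movie_id == "AB01" & tr$repetition == 1)
  j2 <- which(tr$participant == 1 & tr$movie_id == "AB02" & tr$repetition == 1)
  r_same <- cor(as.vector(ep$data[i1, , ]), as.vector(ep$data[i2, , ]))
  r_diff <- cor(as.vector(ep$data[i1, , ]), as.vector(ep$data[j2, , ]))
  expect_gt(r_same, 0.95)
  expect_lt(abs(r_diff), 0.3)
})

test_that("outcome generation follows the logistic links", {
  n <- 5000
  planted <- data.frame(planted_similarity = runif(n, 0, 2),
                        planted_dissimilarity = -runif(n, 0, 2))
  link <- list(intercept_ac = 1e6, beta_ac_on_similarity = 0,
               intercept_source = 0, beta_source_on_dissimilarity = -0.6)
  out <- generate_outcomes(planted, link, seed = 2)
  expect_true(all(out$ac_correct == 1))          # logistic saturation
  expect_true(all(out$confidence %in% 1:3))
  expect_true(all(out$rt_s > 0))
  # zero slope -> no similarity/outcome association
  link0 <- list(intercept_ac = 0, beta_ac_on_similarity = 0,
                intercept_source = 0, beta_source_on_dissimilarity = 0)
  out0 <- generate_outcomes(planted, link0, seed = 3)
  expect_lt(abs(cor(planted$planted_similarity, out0$ac_correct)), 0.05)
  # positive slope -> positive association
  link1 <- list(intercept_ac = 0, beta_ac_on_similarity = 2,
                intercept_source = 0, beta_source_on_dissimilarity = 0)
  out1 <- generate_outcomes(planted, link1, seed = 4)
  expect_gt(cor(planted$planted_similarity, out1$ac_correct), 0.15)
  expect_error(generate_outcomes(data.frame(planted_similarity = 1:3), link0),
               "planted_dissimilarity")
})

test_that("unrepresentable segment boundaries are rejected", {
  d <- tiny_design()
  d$sample_rate_hz <- 0.3
  expect_error(generate_epochs(d, small_params()), "not representable")
})

test_that("a strong planted outcome link is recoverable by MVNIG regression", {
  set.seed(9)
  n <- 600
  planted <- data.frame(planted_similarity = runif(n, 0, 2),
                        planted_dissimilarity = runif(n, -2, 0))
  link <- list(intercept_ac = 0, beta_ac_on_similarity = 0,
               intercept_source = -4, beta_source_on_dissimilarity = -4)
  out <- generate_outcomes(planted, link, seed = 10)
  fit <- mvnig_regression(planted$planted_dissimilarity,
                          data.frame(source_correct = out$source_correct))
  co <- fit$coefficients[fit$coefficients$term == "source_correct", ]
  expect_lt(co$beta, 0)
  expect_gt(co$bf10, 3)
})
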