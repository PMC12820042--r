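test_that("self-coherence is 1 and coherence is symmetric and bounded", {
  set.seed(21)
  x <- matrix(rnorm(2 * 800), 2, 800)
  y <- matrix(rnorm(2 * 800), 2, 800)
  self <- wavelet_coherence(x, x, 100)
  expect_equal(max(abs(self$coherence - 1), na.rm = TRUE), 0, tolerance = 1e-9)
  cxy <- wavelet_coherence(x, y, 100)
  cyx <- wavelet_coherence(y, x, 100)
  expect_equal(cxy$coherence, cyx$coherence, tolerance = 1e-9)
  expect_true(all(cxy$coherence >= 0 & cxy$coherence <= 1, na.rm = TRUE))
  # independent noise stays well away from the Cauchy-Schwarz ceiling
  expect_lt(mean(cxy$coherence, na.rm = TRUE), 0.5)
  expect_error(wavelet_coherence(x, y[, 1:100, drop = FALSE], 100),
               "identical shape")
})

test_that("a 25 ms delayed copy shows the analytic cross-spectrum phase", {
  sr <- 200
  t <- seq(0, 9.995, by = 1 / sr)
  base <- sin(2 * pi * 8 * t) + 0.05 * rnorm(length(t))
  lag <- round(0.025 * sr)
  x <- matrix(base, 1)
  y <- matrix(c(rep(0, lag), base[1:(length(t) - lag)]), 1)
  wc <- wavelet_coherence(x, y, sr, time_step_s = 0.05)
  mid <- which(wc$times > 3 & wc$times < 7)
  k8 <- match(8, wc$freqs_hz)
  expect_gt(mean(wc$coherence[1, k8, mid]), 0.95)
  expect_lt(abs(mean(wc$phase[1, k8, mid]) - 2 * pi * 8 * 0.025), 0.15)
})

test_that("the pair-averaged summary matches the single-pair estimator", {
  d <- build_design(1, 2, 100, 2)
  params <- simulation_params(seed = 23, n_participants = 1)
  ep <- generate_epochs(d, params)
  tr <- ep$trials
  rows <- which(tr$role == "AB")
  bank <- coherence_coefficients(waversa:::subset_epochs(ep, rows))
  pw <- enumerate_within_pairs(d, "AB01")
  pb <- enumerate_between_pairs(d, "AB01")  # empty for a single-AB design
  summ <- participant_coherence_summary(bank, pw, pb)
  expect_equal(summ$n_pairs, c(within = 1L, between = 0L))
  # oracle: the public single-pair path on the same two epochs
  x1 <- matrix(ep$data[rows[1], , ], 2)
  x2 <- matrix(ep$data[rows[2], , ], 2)
  wc <- wavelet_coherence(x1, x2, 100, t_start_s = -0.5)
  expect_equal(summ$within, wc$coherence, tolerance = 1e-8)
})

test_that("missing repetitions are skipped with a count; absent movies error", {
  d <- build_design(2, 3, 100, 2)
  params <- simulation_params(seed = 24, n_participants = 1)
  ep <- generate_epochs(d, params)
  tr <- ep$trials
  rows <- which(tr$role == "AB" & !(tr$movie_id == "AB01" & tr$repetition == 2))
  bank <- coherence_coefficients(waversa:::subset_epochs(ep, rows))
  pw <- do.call(rbind, lapply(c("AB01", "AB02"), enumerate_within_pairs,
                              design = d))
  pb <- do.call(rbind, lapply(c("AB01", "AB02"), enumerate_between_pairs,
                              design = d))
  expect_message(summ <- participant_coherence_summary(bank, pw, pb),
                 "skipped")
  expect_equal(unname(summ$n_skipped["within"]), 2L)  # pairs (0,2) and (1,2)
  bad <- pw
  bad$movie_id_1[1] <- "AB99"
  expect_error(participant_coherence_summary(bank, bad, pb), "AB99")
})

test_that("within-movie coherence exceeds between-movie coherence in-band", {
  d <- build_design(3, 3, 100, 4)
  params <- simulation_params(seed = 25, n_participants = 1,
                              signature_bands = data.frame(
                                band_low_hz = 10, band_high_hz = 10,
                                amplitude = 3),
                              line_width_hz = 1.5, pink_exponent = 0)
  ep <- generate_epochs(d, params)
  tr <- ep$trials
  bank <- coherence_coefficients(
    waversa:::subset_epochs(ep, which(tr$participant == 1 & tr$role == "AB")))
  ab <- d$movies$movie_id[d$movies$role == "AB"]
  pw <- do.call(rbind, lapply(ab, enumerate_within_pairs, design = d))
  pb <- do.call(rbind, lapply(ab, enumerate_between_pairs, design = d))
  summ <- participant_coherence_summary(bank, pw, pb)
  tin <- summ$times > 1 & summ$times < 12
  k10 <- match(10, summ$freqs_hz)
  in_band <- mean(summ$within[, k10, tin], na.rm = TRUE) -
    mean(summ$between[, k10, tin], na.rm = TRUE)
  far <- match(25:28, summ$freqs_hz)
  out_band <- mean(summ$within[, far, tin], na.rm = TRUE) -
    mean(summ$between[, far, tin], na.rm = TRUE)
  expect_gt(in_band, 0.3)
  expect_lt(abs(out_band), 0.15)   # white noise floor: no systematic contrast
})

test_that("template selection finds planted bands and rejects null contrasts", {
  d <- build_design(2, 3, 100, 4)
  # narrow line + strong white floor: coherent line-tail leakage must stay
  # below the noise floor for the selection to localise
  params <- simulation_params(seed = 26, n_participants = 5,
                              signature_bands = data.frame(
                                band_low_hz = 10, band_high_hz = 10,
                                amplitude = 3),
                              noise_sd = 2, line_width_hz = 0.8,
                              pink_exponent = 0)
  ep <- generate_epochs(d, params)
  tr <- ep$trials
  ab <- d$movies$movie_id[d$movies$role == "AB"]
  pw <- do.call(rbind, lapply(ab, enumerate_within_pairs, design = d))
  pb <- do.call(rbind, lapply(ab, enumerate_between_pairs, design = d))
  wmaps <- list(); bmaps <- list(); times <- NULL
  for (p in 1:5) {
    bank <- coherence_coefficients(
      waversa:::subset_epochs(ep, which(tr$participant == p & tr$role == "AB")))
    s <- participant_coherence_summary(bank, pw, pb)
    wmaps[[p]] <- s$within; bmaps[[p]] <- s$between; times <- s$times
  }
  tpl <- select_template(wmaps, bmaps, d, times, 3:30,
                         n_permutations = 300, seed = 2)
  expect_named(tpl, c("sim_first", "sim_first_context", "sim_second",
                      "joint_context"))
  jt <- tpl$joint_context
  expect_gt(sum(jt$mask), 0)
  sel <- apply(jt$mask, 2, any)
  # the planted band is fully selected; cluster bleed into adjacent weakly
  # coherent bins is expected, but the far end of the grid stays out
  expect_true(all(sel[jt$freqs_hz %in% 9:11]))
  expect_false(any(sel[jt$freqs_hz >= 24]))
  # within == between: all templates empty, with a structured warning
  expect_warning(
    tpl0 <- select_template(wmaps, wmaps, d, times, 3:30,
                            n_permutations = 200, seed = 2),
    "no significant coherence cluster")
  expect_true(all(vapply(tpl0, function(tp) sum(tp$mask), 0) == 0))
})
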