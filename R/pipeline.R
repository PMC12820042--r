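#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one place;
#' all randomness derives from `seed`, and the full configuration (plus its
#' hash) is embedded in the run report. The `"desk"` profile (12
#' participants, 6 triads, 8 channels, 100 Hz) runs the identical code paths
#' as the `"full"` study-scale profile (36 participants, 24 triads, 62
#' channels, 500 Hz).
#'
#' @param profile `"desk"` or `"full"`.
#' @param seed Integer master seed.
#' @param ... Overrides for any top-level field of the returned list.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("desk", "full"), seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(n_participants = 12L, n_triads = 6L, n_channels = 8L,
         sample_rate_hz = 100, n_repetitions = 5L, n_permutations = 500L)
  } else {
    list(n_participants = 36L, n_triads = 24L, n_channels = 62L,
         sample_rate_hz = 500, n_repetitions = 5L, n_permutations = 1000L)
  }
  cfg <- list(
    profile = profile, seed = as.integer(seed),
    n_participants = base$n_participants, n_triads = base$n_triads,
    n_channels = base$n_channels, sample_rate_hz = base$sample_rate_hz,
    n_repetitions = base$n_repetitions,
    sim = list(),   # overrides for simulation_params() defaults
    freq_lo = 3, freq_hi = 30, n_cycles = 5, tfr_step_s = 0.02,
    coherence_step_s = 0.1,
    smoothing = smoothing_spec(),
    n_permutations = base$n_permutations, cluster_alpha = 0.05, alpha = 0.05,
    prior = list(mu0 = 0, v = 30, alpha = 15, beta = 15),
    bf_threshold = 3, min_window_s = 0.1,
    anchor_segment = "joint_context",
    baseline_modes = c("vs_xy", "vs_noncorresponding_bc"),
    exclude_repetition_zero = TRUE,
    rt_limit_s = 10, guess_level = 1, ceiling_accuracy = 0.9,
    univariate_stat_stride = 5L,
    stages = list(rsa = TRUE, univariate = TRUE, behavior = TRUE),
    input_path = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# linear-power cubes of selected trials of one participant's epochs
participant_cubes <- function(epochs, rows, cfg) {
  if (!length(rows)) return(list())
  cubes <- morlet_power_many(epochs$data, rows, epochs$sample_rate_hz,
                             seq(cfg$freq_lo, cfg$freq_hi), cfg$n_cycles,
                             cfg$tfr_step_s, epochs$time[1], epochs$channels)
  for (j in seq_along(rows)) cubes[[j]]$trial <- epochs$trials[rows[j], ]
  cubes
}

#' Run the end-to-end encoding analysis
#'
#' Executes simulate (or ingest) -> time-frequency decomposition ->
#' wavelet-coherence feature selection -> time-resolved RSA with dual
#' baselines -> Bayesian evidence accumulation and window detection ->
#' trial-level memory regressions -> univariate BC-vs-XY contrast with
#' power-similarity linkage, and returns a structured report. Re-running
#' with the same configuration reproduces all outputs.
#'
#' @param config A [run_config()].
#' @param epochs Optional pre-built `epoch_set` (otherwise simulated from the
#'   config, or read from `config$input_path`).
#' @return A `waversa_report` list; see the print method for a summary.
#' @export
run_pipeline <- function(config = run_config(), epochs = NULL) {
  t0 <- Sys.time()
  cfg <- config
  design <- build_design(cfg$n_triads, cfg$n_repetitions, cfg$sample_rate_hz,
                         cfg$n_channels)
  if (is.null(epochs)) {
    if (!is.null(cfg$input_path)) {
      epochs <- read_epochs(cfg$input_path)
    } else {
      params <- do.call(simulation_params,
                        c(list(seed = cfg$seed,
                               n_participants = cfg$n_participants),
                          cfg$sim))
      epochs <- generate_epochs(design, params)
    }
  }
  participants <- sort(unique(epochs$trials$participant))
  freqs <- seq(cfg$freq_lo, cfg$freq_hi)
  ab_ids <- design$movies$movie_id[design$movies$role == "AB"]
  bc_ids <- design$movies$movie_id[design$movies$role == "BC"]
  xy_ids <- design$movies$movie_id[design$movies$role == "XY"]
  pairs_within <- do.call(rbind, lapply(ab_ids, enumerate_within_pairs,
                                        design = design))
  pairs_between <- do.call(rbind, lapply(ab_ids, enumerate_between_pairs,
                                         design = design))

  ## ---- pass A: wavelet-coherence maps per participant ----
  within_maps <- list(); between_maps <- list()
  coh_times <- NULL
  for (p in participants) {
    rows_ab <- which(epochs$trials$participant == p & epochs$trials$role == "AB")
    sub_ab <- subset_epochs(epochs, rows_ab)
    bank <- coherence_coefficients(sub_ab, freqs, cfg$n_cycles,
                                   cfg$coherence_step_s)
    summ <- participant_coherence_summary(bank, pairs_within, pairs_between,
                                          cfg$smoothing)
    within_maps[[as.character(p)]] <- summ$within
    between_maps[[as.character(p)]] <- summ$between
    coh_times <- summ$times
  }
  n_rep0_excluded <- if (cfg$exclude_repetition_zero)
    sum(epochs$trials$role %in% c("BC", "XY") & epochs$trials$repetition == 0)
  else 0L

  ## ---- feature selection (group level) ----
  templates <- select_template(within_maps, between_maps, design,
                               times = coh_times, freqs = freqs,
                               n_permutations = cfg$n_permutations,
                               cluster_alpha = cfg$cluster_alpha,
                               alpha = cfg$alpha, seed = cfg$seed + 11L)
  anchor_template <- templates[[cfg$anchor_segment]]
  rsa_possible <- cfg$stages$rsa && !is.null(anchor_template) &&
    any(anchor_template$mask)

  ## ---- pass B: one transform per epoch; RSA series + univariate means ----
  trial_meta <- list(); trial_z <- list()
  mean_series <- lapply(cfg$baseline_modes, function(m) list())
  names(mean_series) <- cfg$baseline_modes
  contrasts <- list()
  tfr_times <- NULL

  if (rsa_possible || cfg$stages$univariate) {
    for (p in participants) {
      tr <- epochs$trials
      keep_rep <- if (cfg$exclude_repetition_zero) tr$repetition > 0 else TRUE
      rows_t <- which(tr$participant == p & tr$role %in% c("BC", "XY") & keep_rep)
      target_lin <- participant_cubes(epochs, rows_t, cfg)
      tmeta <- tr[rows_t, ]
      if (cfg$stages$univariate)
        contrasts[[as.character(p)]] <-
          power_contrast(target_lin[tmeta$role == "BC"],
                         target_lin[tmeta$role == "XY"])
      if (!rsa_possible) next

      rows_ab <- which(tr$participant == p & tr$role == "AB")
      ab_cubes <- lapply(participant_cubes(epochs, rows_ab, cfg), db_normalize)
      names(ab_cubes) <- paste(tr$movie_id[rows_ab], tr$repetition[rows_ab],
                               sep = ":")
      anchors <- lapply(ab_ids, function(m) {
        reps <- ab_cubes[grep(paste0("^", m, ":"), names(ab_cubes))]
        extract_ab_features(reps, anchor_template, m)
      })
      names(anchors) <- ab_ids

      target_db <- lapply(target_lin, db_normalize)
      tfr_times <- target_db[[1]]$times
      # z series for every (anchor, target epoch), batched per target
      A <- vapply(anchors, `[[`, numeric(length(anchors[[1]]$values)),
                  "values")
      acells <- anchors[[1]]$cells
      zser <- lapply(target_db, function(cb) {
        M <- masked_cell_matrix(cb, acells)
        zm <- t(cor_fisher_z(A, M, masked_valid(cb, acells)))
        colnames(zm) <- names(anchors)
        zm
      })   # list over targets of T x n_anchor matrices
      p_first <- length(trial_z) + 1L
      for (i in which(tmeta$role == "BC")) {
        mb <- tmeta$movie_id[i]; r <- tmeta$repetition[i]
        ab <- corresponding_ab(design, mb)
        z_corr <- zser[[i]][, ab]
        z_modes <- list()
        if ("vs_xy" %in% cfg$baseline_modes) {
          jx <- which(tmeta$role == "XY" & tmeta$repetition == r)
          z_modes$vs_xy <- z_corr -
            rowMeans(vapply(jx, function(j) zser[[j]][, ab],
                            numeric(length(tfr_times))), na.rm = TRUE)
        }
        if ("vs_noncorresponding_bc" %in% cfg$baseline_modes) {
          jb <- which(tmeta$role == "BC" & tmeta$repetition == r &
                        tmeta$movie_id != mb)
          z_modes$vs_noncorresponding_bc <- z_corr -
            rowMeans(vapply(jb, function(j) zser[[j]][, ab],
                            numeric(length(tfr_times))), na.rm = TRUE)
        }
        trial_meta[[length(trial_meta) + 1]] <- tmeta[i, ]
        trial_z[[length(trial_z) + 1]] <- z_modes
      }
      for (m in cfg$baseline_modes) {
        zz <- vapply(trial_z[seq(p_first, length(trial_z))],
                     function(l) l[[m]], numeric(length(tfr_times)))
        mean_series[[m]][[as.character(p)]] <- rowMeans(zz, na.rm = TRUE)
      }
    }
  }

  ## ---- univariate statistics and trial-level cluster power ----
  univ <- list()
  sig_clusters <- NULL
  cluster_power <- list()
  if (cfg$stages$univariate && length(contrasts) >= 2) {
    univ <- segmentwise_tests(contrasts, design,
                              n_permutations = cfg$n_permutations,
                              cluster_alpha = cfg$cluster_alpha,
                              alpha = cfg$alpha, seed = cfg$seed + 12L,
                              time_stride = cfg$univariate_stat_stride)
    sig_clusters <- do.call(rbind, lapply(names(univ), function(seg) {
      cl <- univ[[seg]]$clusters
      cl <- cl[cl$significant, , drop = FALSE]
      if (nrow(cl)) cbind(segment = seg, cl) else NULL
    }))
    if (!is.null(sig_clusters) && nrow(sig_clusters) && length(trial_meta)) {
      # pass C: trial-level mean power inside each significant cluster
      for (p in participants) {
        tr <- epochs$trials
        keep_rep <- if (cfg$exclude_repetition_zero) tr$repetition > 0 else TRUE
        rows_bc <- which(tr$participant == p & tr$role == "BC" & keep_rep)
        bc_lin <- participant_cubes(epochs, rows_bc, cfg)
        for (cube in bc_lin) {
          cp <- vapply(seq_len(nrow(sig_clusters)), function(k) {
            cluster_mean_power(cube, univ[[sig_clusters$segment[k]]],
                               sig_clusters$id[k])
          }, numeric(1))
          cluster_power[[length(cluster_power) + 1]] <- cp
        }
      }
    }
  }

  ## ---- Bayesian evidence traces and windows ----
  prior <- nig_prior(cfg$prior$mu0, cfg$prior$v, cfg$prior$alpha,
                     cfg$prior$beta)
  traces <- list(); windows <- list()
  for (m in cfg$baseline_modes) {
    if (!rsa_possible || !length(mean_series[[m]])) {
      traces[[m]] <- NULL
      windows[[m]] <- detect_windows(
        data.frame(time = numeric(0), bf10 = numeric(0),
                   mean_contrast = numeric(0)),
        threshold = cfg$bf_threshold, min_duration_s = cfg$min_window_s)
      next
    }
    X <- do.call(rbind, mean_series[[m]])
    traces[[m]] <- nig_trace(X, tfr_times, prior)
    windows[[m]] <- detect_windows(traces[[m]], threshold = cfg$bf_threshold,
                                   min_duration_s = cfg$min_window_s)
  }

  ## ---- trial-level regressions against memory outcomes ----
  reg_mode <- if ("vs_noncorresponding_bc" %in% cfg$baseline_modes)
    "vs_noncorresponding_bc" else cfg$baseline_modes[1]
  trials_bc <- if (length(trial_meta)) do.call(rbind, trial_meta) else NULL
  counts <- list(n_rep0_excluded = n_rep0_excluded)
  regressions <- list()
  power_links <- list()
  behavior <- NULL
  if (!is.null(trials_bc)) {
    trials_bc <- recode_behavior(trials_bc, cfg$rt_limit_s, cfg$guess_level)
    counts$n_recoded <- attr(trials_bc, "n_recoded")
    win_reg <- windows[[reg_mode]]
    if (nrow(win_reg)) {
      zmat <- vapply(trial_z, function(l) l[[reg_mode]],
                     numeric(length(tfr_times)))   # T x trials
      for (w in seq_len(nrow(win_reg))) {
        inside <- tfr_times >= win_reg$start_s[w] &
          tfr_times <= win_reg$end_s[w]
        y_all <- colMeans(zmat[inside, , drop = FALSE], na.rm = TRUE)
        wname <- sprintf("%s_%.2fs", win_reg$sign[w], win_reg$start_s[w])
        for (outcome in c("ac_correct", "source_correct")) {
          acc <- tapply(trials_bc[[outcome]], trials_bc$participant, mean)
          keep_p <- names(acc)[acc <= cfg$ceiling_accuracy]
          sel <- trials_bc$participant %in% keep_p
          counts[[paste0("participants_", outcome)]] <- length(keep_p)
          X <- data.frame(trials_bc[sel, outcome], trials_bc$repetition[sel])
          names(X) <- c(outcome, "repetition")
          if (outcome == "source_correct")
            X$ac_correct <- trials_bc$ac_correct[sel]
          fit <- try(mvnig_regression(y_all[sel], X), silent = TRUE)
          if (!inherits(fit, "try-error"))
            regressions[[paste(wname, outcome, sep = "~")]] <- fit
        }
        # power -> similarity linkage for clusters in matching segments
        if (length(cluster_power) == length(trial_z) && !is.null(sig_clusters) &&
            nrow(sig_clusters)) {
          cpm <- do.call(rbind, cluster_power)
          for (k in seq_len(nrow(sig_clusters))) {
            seg_win <- segment_window(design, sig_clusters$segment[k])
            overlap <- min(win_reg$end_s[w], seg_win[2]) -
              max(win_reg$start_s[w], seg_win[1])
            if (overlap <= 0) next
            fit <- try(power_similarity_link(cpm[, k], y_all,
                                             controls = data.frame(
                                               repetition = trials_bc$repetition)),
                       silent = TRUE)
            if (!inherits(fit, "try-error"))
              power_links[[paste(wname, sig_clusters$segment[k],
                                 sig_clusters$id[k], sep = "~")]] <- fit
          }
        }
      }
    }
    # behavioural effect-size comparison across association types
    beh <- recode_behavior(epochs$trials, cfg$rt_limit_s, cfg$guess_level)
    est <- ses <- c()
    for (role in c("AB", "BC", "XY")) {
      d <- beh[beh$role == role, ]
      fit <- try(stats::glm(source_correct ~ ac_correct, data = d,
                            family = stats::binomial()), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        sm <- summary(fit)$coefficients
        if ("ac_correct" %in% rownames(sm)) {
          est[role] <- sm["ac_correct", "Estimate"]
          ses[role] <- sm["ac_correct", "Std. Error"]
        }
      }
    }
    if (length(est) >= 2)
      behavior <- monte_carlo_effect_comparison(est, ses, n_iter = 10000,
                                                seed = cfg$seed + 13L)
  }

  report <- structure(list(
    config = cfg,
    config_hash = rlang::hash(unclass(cfg)),
    design = design,
    counts = counts,
    templates = templates,
    template_sizes = vapply(templates, function(tp) sum(tp$mask), numeric(1)),
    rsa_possible = rsa_possible,
    traces = traces,
    windows = windows,
    regressions = regressions,
    univariate = univ,
    significant_clusters = sig_clusters,
    power_links = power_links,
    behavior = behavior,
    package_version = as.character(utils::packageVersion("waversa")),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "waversa_report")
  report
}

#' @export
print.waversa_report <- function(x, ...) {
  cat(sprintf("waversa_report [%s profile, seed %d, hash %s]\n",
              x$config$profile, x$config$seed, substr(x$config_hash, 1, 8)))
  cat(sprintf("template cells per segment: %s\n",
              paste(sprintf("%s=%d", names(x$template_sizes),
                            x$template_sizes), collapse = ", ")))
  for (m in names(x$windows)) {
    w <- x$windows[[m]]
    cat(sprintf("windows (%s): %d\n", m, nrow(w)))
    if (nrow(w)) print(w)
  }
  if (length(x$regressions))
    cat("regressions:", paste(names(x$regressions), collapse = "; "), "\n")
  cat(sprintf("runtime: %.1f s\n", x$runtime_s))
  invisible(x)
}
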