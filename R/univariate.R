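#' BC-vs-XY power contrast index
#'
#' Per participant, averages the linear-power cubes across all BC trials and
#' all XY trials (repetition zero excluded upstream) and forms the relative
#' index (BC - XY) / BC elementwise. Elements with nonpositive BC power are
#' flagged invalid and excluded from statistics.
#'
#' @param bc_cubes,xy_cubes Lists of linear-scale `tfr_cube`s (one
#'   participant's trials).
#' @return A `power_contrast`: `index` (channels x frequencies x timepoints),
#'   `valid`, `freqs_hz`, `times`, `n_trials`.
#' @export
power_contrast <- function(bc_cubes, xy_cubes) {
  if (!length(bc_cubes) || !length(xy_cubes))
    stop("need at least one BC and one XY cube", call. = FALSE)
  for (cb in c(bc_cubes, xy_cubes))
    if (cb$scale != "linear")
      stop("power contrast runs on linear-scale cubes", call. = FALSE)
  mean_cube <- function(cubes) {
    s <- cubes[[1]]$power
    if (length(cubes) > 1) for (i in 2:length(cubes)) s <- s + cubes[[i]]$power
    s / length(cubes)
  }
  bc <- mean_cube(bc_cubes)
  xy <- mean_cube(xy_cubes)
  idx <- (bc - xy) / bc
  valid_ft <- bc_cubes[[1]]$valid & xy_cubes[[1]]$valid
  valid <- array(rep(as.vector(valid_ft), each = dim(bc)[1]), dim(bc)) & bc > 0
  idx[!valid] <- NA_real_
  structure(list(index = idx, valid = valid,
                 freqs_hz = bc_cubes[[1]]$freqs_hz,
                 times = bc_cubes[[1]]$times,
                 n_trials = c(bc = length(bc_cubes), xy = length(xy_cubes))),
            class = "power_contrast")
}

#' Segment-wise cluster tests of the power contrast
#'
#' One-sample sign-flip cluster permutation of the (BC - XY)/BC index
#' against zero, both tails, run separately within each movie segment window
#' (the fixation segment is skipped by default, mirroring the four
#' segment-wise comparisons of the encoding analysis).
#'
#' @param contrasts List of `power_contrast` objects, one per participant.
#' @param design An `experiment_design`.
#' @param segments Segment names to test.
#' @param n_permutations,cluster_alpha,alpha,seed See
#'   [one_sample_cluster_test()].
#' @param time_stride Subsampling stride of the contrast's time axis for the
#'   cluster statistics (1 = full resolution).
#' @return Named list of `cluster_result` objects (plus `window` and `tidx`
#'   attributes per segment; `tidx` indexes the full time axis).
#' @export
segmentwise_tests <- function(contrasts, design,
                              segments = c("sim_first", "sim_first_context",
                                           "sim_second", "joint_context"),
                              n_permutations = 1000, cluster_alpha = 0.05,
                              alpha = 0.05, seed = 1L, time_stride = 1L) {
  if (length(contrasts) < 2)
    stop("need at least two participants", call. = FALSE)
  full_times <- contrasts[[1]]$times
  sub <- seq(1, length(full_times), by = max(1L, time_stride))
  times <- full_times[sub]
  out <- list()
  for (seg in segments) {
    win <- segment_window(design, seg)
    tidx_sub <- which(times >= win[1] & times < win[2])
    tidx <- sub[tidx_sub]
    if (!length(tidx)) {
      warning("empty segment window '", seg, "', skipped", call. = FALSE)
      next
    }
    dims <- c(dim(contrasts[[1]]$index)[1:2], length(tidx))
    x <- t(vapply(contrasts,
                  function(pc) as.vector(pc$index[, , tidx, drop = FALSE]),
                  numeric(prod(dims))))
    res <- one_sample_cluster_test(x, dims = dims,
                                   chan_adj = design$neighbor_graph,
                                   n_permutations = n_permutations,
                                   cluster_alpha = cluster_alpha,
                                   alpha = alpha, tail = "two_sided",
                                   seed = seed)
    res$window <- win
    res$tidx <- tidx
    res$segment <- seg
    out[[seg]] <- res
  }
  out
}

#' Trial-level mean power within a cluster
#'
#' @param cube A linear `tfr_cube` of one trial.
#' @param result A `cluster_result` from [segmentwise_tests()].
#' @param id Cluster id within the result.
#' @return Mean linear power over the cluster's member elements.
#' @export
cluster_mean_power <- function(cube, result, id) {
  mem <- cluster_members(result, id)
  tix <- result$tidx[mem[, "time"]]
  mean(cube$power[cbind(mem[, "channel"], mem[, "freq"], tix)])
}

#' Does cluster power predict neural (dis)similarity?
#'
#' Trial-level Bayesian linear regression of the RSA window similarity on
#' the cluster-mean power (standardized coefficients, MVNIG prior); thin
#' wrapper over [mvnig_regression()].
#'
#' @param cluster_power Numeric vector of trial-level cluster-mean power.
#' @param window_similarity Numeric vector of trial-level window-averaged
#'   Fisher-z (dis)similarities, aligned with `cluster_power`.
#' @param controls Optional data frame of control predictors.
#' @param ... Passed to [mvnig_regression()].
#' @return An `mvnig_result`.
#' @export
power_similarity_link <- function(cluster_power, window_similarity,
                                  controls = NULL, ...) {
  if (length(cluster_power) != length(window_similarity))
    stop("power and similarity must be aligned trial-for-trial; lengths ",
         length(cluster_power), " vs ", length(window_similarity),
         call. = FALSE)
  X <- data.frame(power = cluster_power)
  if (!is.null(controls)) X <- cbind(X, controls)
  mvnig_regression(window_similarity, X, ...)
}
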