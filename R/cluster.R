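#' One-sample cluster-based permutation test (sign-flip)
#'
#' Element-wise one-sample t statistics over channel x frequency x time maps
#' are thresholded at the two-tailed `cluster_alpha` t quantile; supra-
#' threshold elements are clustered under the adjacency (+-1 frequency bin,
#' +-1 timepoint, montage channel neighbours), positive and negative clusters
#' separately. Cluster mass is the summed t statistic. The null distribution
#' is built by random sign flips of the per-participant maps (full
#' enumeration when feasible); the observed labelling is always included in
#' the null (the "+1" convention), so p > 0.
#'
#' @param x Participant maps: an n x (C*F*T) matrix, or an array
#'   `n x C x F x T`.
#' @param dims `c(channels, frequencies, timepoints)` (taken from the array
#'   if `x` is 4-d).
#' @param chan_adj Channel adjacency matrix, or `NULL` for no channel
#'   neighbours (each channel isolated).
#' @param n_permutations Number of sign-flip permutations.
#' @param cluster_alpha Two-tailed alpha of the cluster-forming threshold.
#' @param alpha Familywise alpha for reporting significant clusters.
#' @param tail `"two_sided"` (max |mass| null), `"pos"` or `"neg"`.
#' @param seed Integer seed for the sign flips.
#' @return A `cluster_result`: data frame of clusters (`id`, `sign`, `mass`,
#'   `p_value`, `n_members`, `significant`), `labels` array, the observed
#'   t map, and the test configuration.
#' @export
one_sample_cluster_test <- function(x, dims = NULL, chan_adj = NULL,
                                    n_permutations = 1000,
                                    cluster_alpha = 0.05, alpha = 0.05,
                                    tail = c("two_sided", "pos", "neg"),
                                    seed = 1L) {
  tail <- match.arg(tail)
  if (is.array(x) && length(dim(x)) == 4) {
    dims <- dim(x)[2:4]
    x <- matrix(x, nrow = dim(x)[1])
  }
  if (is.null(dims)) stop("`dims` required for matrix input", call. = FALSE)
  dims <- as.integer(dims)
  if (ncol(x) != prod(dims)) stop("map size does not match dims", call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("need at least two participants", call. = FALSE)
  if (n_permutations < 100)
    warning("fewer than 100 permutations; p-values will be coarse")

  adj_list <- if (is.null(chan_adj)) {
    rep(list(integer(0)), dims[1])
  } else {
    neighbor_list(chan_adj)
  }

  # elements with any non-finite participant value are excluded: their t is
  # pinned to zero so they can never enter a cluster
  col_ok <- colSums(!is.finite(x)) == 0
  x[, !col_ok] <- 0
  ssq <- colSums(x^2)
  m_obs <- colMeans(x)
  t_of <- function(m) {
    v <- (ssq_rep(ssq, m) - n * m^2) / (n - 1)   # sign-flip-invariant SSQ
    v[v < 0] <- 0
    tt <- m / sqrt(v / n)
    deg <- v == 0
    tt[deg] <- ifelse(m[deg] == 0, 0, sign(m[deg]) * Inf)
    if (is.matrix(tt)) tt[, !col_ok] <- 0 else tt[!col_ok] <- 0
    tt
  }
  ssq_rep <- function(ssq, m) if (is.matrix(m)) matrix(ssq, nrow(m), ncol(m), byrow = TRUE) else ssq
  t_obs <- t_of(m_obs)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  cl <- cpp_cluster_grid(t_obs, dims, adj_list, tcrit)
  # permutation signs
  full_enum <- 2^n <= n_permutations
  if (full_enum) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_permutations <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                    n_permutations, n)
  }
  tail_code <- match(tail, c("two_sided", "pos", "neg")) - 1L
  # permuted t maps in blocks to bound memory
  null_max <- numeric(n_permutations)
  block <- max(1L, min(n_permutations, floor(4e6 / ncol(x))))
  for (b0 in seq(1, n_permutations, by = block)) {
    rows <- b0:min(b0 + block - 1, n_permutations)
    Mp <- (signs[rows, , drop = FALSE] %*% x) / n
    Tp <- t_of(Mp)
    Tp[!is.finite(Tp)] <- 0
    null_max[rows] <- cpp_perm_max_mass(Tp, dims, adj_list, tcrit, tail_code)
  }

  keep <- switch(tail, two_sided = rep(TRUE, length(cl$mass)),
                 pos = cl$sign > 0, neg = cl$sign < 0)
  stat <- switch(tail, two_sided = abs(cl$mass), pos = cl$mass,
                 neg = -cl$mass)
  p <- vapply(seq_along(cl$mass), function(i) {
    if (!keep[i]) return(NA_real_)
    (1 + sum(null_max >= stat[i])) / (1 + n_permutations)
  }, numeric(1))

  clusters <- data.frame(
    id = seq_along(cl$mass), sign = cl$sign, mass = cl$mass,
    p_value = p, n_members = tabulate(cl$labels, nbins = length(cl$mass)),
    significant = !is.na(p) & p <= alpha
  )
  structure(list(
    clusters = clusters,
    labels = array(cl$labels, dims),
    t_map = array(t_obs, dims),
    dims = dims,
    n_permutations = n_permutations,
    full_enumeration = full_enum,
    cluster_alpha = cluster_alpha, alpha = alpha, tail = tail, seed = seed,
    null_max_mass = null_max
  ), class = "cluster_result")
}

#' Paired cluster-based permutation test
#'
#' Contrasts two conditions measured in the same participants by sign-flip
#' permutation of the per-participant difference maps (see
#' [one_sample_cluster_test()]).
#'
#' @param cond_a,cond_b Per-participant maps of identical shape:
#'   `n x C x F x T` arrays or n x (C*F*T) matrices.
#' @inheritParams one_sample_cluster_test
#' @return A `cluster_result`.
#' @export
paired_cluster_test <- function(cond_a, cond_b, dims = NULL, chan_adj = NULL,
                                n_permutations = 1000, cluster_alpha = 0.05,
                                alpha = 0.05,
                                tail = c("two_sided", "pos", "neg"),
                                seed = 1L) {
  if (!identical(dim(cond_a), dim(cond_b)))
    stop("condition maps must have identical shape", call. = FALSE)
  one_sample_cluster_test(cond_a - cond_b, dims = dims, chan_adj = chan_adj,
                          n_permutations = n_permutations,
                          cluster_alpha = cluster_alpha, alpha = alpha,
                          tail = match.arg(tail), seed = seed)
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(x$clusters$significant)
  cat(sprintf("cluster_result (%s, %d perms%s): %d cluster(s), %d significant at alpha=%g\n",
              x$tail, x$n_permutations,
              if (x$full_enumeration) ", full enumeration" else "",
              nrow(x$clusters), sig, x$alpha))
  if (nrow(x$clusters)) print(utils::head(x$clusters[order(x$clusters$p_value), ], 10))
  invisible(x)
}

#' Member elements of a cluster
#'
#' @param result A `cluster_result`.
#' @param id Cluster id.
#' @return Integer matrix with columns `channel`, `freq`, `time` (indices).
#' @export
cluster_members <- function(result, id) {
  which(result$labels == id, arr.ind = TRUE, useNames = FALSE) |>
    `colnames<-`(c("channel", "freq", "time"))
}
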