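#' @title Cohort-level inference
#' @name group_stats
#' @description
#' Paired comparisons of neural features across task states: 2 x IQR
#' outlier exclusion, paired two-tailed t-tests with Cohen's
#' `d = t / sqrt(n)`, electrode-cluster permutation testing with
#' condition-label reversal in half of the participants, and brain-behaviour
#' correlation (Pearson r plus OLS).
NULL

#' 2 x IQR outlier exclusion
#'
#' Keeps values within `[Q1 - 2 IQR, Q3 + 2 IQR]`; quartiles by linear
#' interpolation between order statistics (R type 7). Note the factor 2,
#' not the common 1.5.
#'
#' @param values numeric vector, length >= 4.
#' @return list with `keep` (logical mask) and `excluded` (indices).
#' @export
exclude_outliers <- function(values) {
  if (length(values) < 4) stop("outlier exclusion needs n >= 4")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 2 * iqr & values <= q[2] + 2 * iqr
  list(keep = keep, excluded = which(!keep))
}

# vectorized per-column paired t on a difference matrix (n x m)
.col_t <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  sd <- sqrt(colSums(sweep(d, 2, mu)^2) / (n - 1))
  t <- mu / (sd / sqrt(n))
  t[sd == 0 & mu == 0] <- 0
  t
}

#' Paired two-tailed t-test with effect size
#'
#' Outliers are excluded on the paired differences (2 x IQR rule) before
#' testing; `d = t / sqrt(n)` with `n` the retained pair count,
#' `df = n - 1`.
#'
#' @param a,b numeric vectors of matched per-participant values.
#' @param exclude apply outlier exclusion (default TRUE).
#' @return an `effect_stats` list: `t`, `df`, `p`, `n`, `d`, `excluded`.
#' @export
paired_t <- function(a, b, exclude = TRUE) {
  stopifnot(length(a) == length(b))
  diffs <- a - b
  excluded <- integer(0)
  if (exclude && length(diffs) >= 4) {
    ex <- exclude_outliers(diffs)
    excluded <- ex$excluded
    diffs <- diffs[ex$keep]
  }
  n <- length(diffs)
  if (n < 3) stop("fewer than 3 pairs after exclusion")
  mu <- mean(diffs)
  s <- stats::sd(diffs)
  t <- if (s == 0) {
    if (mu == 0) 0 else sign(mu) * Inf
  } else {
    mu / (s / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(t = t, df = n - 1L, p = p, n = n, d = t / sqrt(n),
                 excluded = excluded), class = "effect_stats")
}

#' @export
print.effect_stats <- function(x, ...) {
  cat(sprintf("<effect_stats> t(%d) = %.3f, p = %.4g, d = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$d, x$n))
  invisible(x)
}

#' Cluster-based permutation test over electrodes
#'
#' Per-electrode paired t-tests; clusters are connected components (in the
#' adjacency graph) of electrodes with `p < p_thresh`, split by t sign, of
#' size `>= min_cluster`. Each cluster is scored by its summed t
#' (`t_sum`). The null distribution records, for each permutation --
#' condition labels reversed in a fresh random `floor(n/2)`-participant
#' subset -- the maximum `|t_sum|` over the clusters found in the permuted
#' data (0 if none); cluster `p = (1 + #{max |t'_sum| >= |t_sum|}) /
#' (n_perm + 1)` (family-wise control by the max statistic).
#'
#' @param features numeric array participants x electrodes x 2 (conditions
#'   A, B), with electrode labels as `dimnames[[2]]`, or a list
#'   `list(A = matrix, B = matrix)`.
#' @param adjacency an `eeg_adjacency` covering all electrodes.
#' @param p_thresh electrode-level threshold (default 0.01).
#' @param min_cluster minimum cluster size (default 4 electrodes).
#' @param n_perm number of permutations (default 2000; < 100 warns).
#' @param seed integer seed for the permutations.
#' @return a `cluster_test` list: `t_map` (named per-electrode t),
#'   `clusters` (list of `electrodes`, `sign`, `t_sum`, `p`), `null`
#'   (permutation maxima), `n_perm`.
#' @export
cluster_permutation_test <- function(features, adjacency, p_thresh = 0.01,
                                     min_cluster = 4, n_perm = 2000,
                                     seed = 1) {
  if (is.list(features) && !is.array(features)) {
    stopifnot(all(c("A", "B") %in% names(features)))
    a <- as.matrix(features$A); b <- as.matrix(features$B)
    stopifnot(all(dim(a) == dim(b)))
    d <- a - b
    labels <- colnames(a)
  } else {
    stopifnot(length(dim(features)) == 3, dim(features)[3] == 2)
    d <- features[, , 1] - features[, , 2]
    labels <- dimnames(features)[[2]]
  }
  n <- nrow(d); m <- ncol(d)
  if (m < 2) stop("need >= 2 electrodes")
  if (n < 4) stop("need >= 4 participants")
  if (is.null(labels)) labels <- paste0("e", seq_len(m))
  missing <- setdiff(labels, adjacency$nodes)
  if (length(missing)) stop("adjacency missing electrode(s): ",
                            paste(missing, collapse = ", "))
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  nb <- .adjacency_index(adjacency, labels)

  crit <- stats::qt(1 - p_thresh / 2, df = n - 1)
  find_clusters <- function(tvals) {
    out <- list()
    for (sgn in c(1, -1)) {
      members <- which(sgn * tvals > crit)
      if (length(members) < min_cluster) next
      for (comp in .connected_components(members, nb)) {
        if (length(comp) >= min_cluster) {
          out[[length(out) + 1]] <- list(electrodes = labels[comp],
                                         sign = sgn,
                                         t_sum = sum(tvals[comp]))
        }
      }
    }
    out
  }

  t_obs <- .col_t(d)
  names(t_obs) <- labels
  clusters <- find_clusters(t_obs)

  set.seed(seed)
  k <- floor(n / 2)
  null_max <- vapply(seq_len(n_perm), function(i) {
    flip <- sample.int(n, k)
    dp <- d
    dp[flip, ] <- -dp[flip, ]
    cl <- find_clusters(.col_t(dp))
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "t_sum"))) else 0
  }, numeric(1))

  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (1 + sum(null_max >= abs(clusters[[i]]$t_sum))) /
      (n_perm + 1)
  }
  structure(list(t_map = t_obs, clusters = clusters, null = null_max,
                 n_perm = n_perm, p_thresh = p_thresh,
                 min_cluster = min_cluster), class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", length(x$t_map), " electrodes, ",
      length(x$clusters), " cluster(s), ", x$n_perm, " permutations\n",
      sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster (%d electrodes): t_sum = %.2f, p = %.4f\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$electrodes), cl$t_sum, cl$p))
  }
  invisible(x)
}

#' Brain-behaviour correlation
#'
#' Pearson correlation (two-tailed) and OLS regression of a behavioural
#' performance measure on a per-participant neural feature difference,
#' after 2 x IQR outlier exclusion applied to each variable.
#'
#' @param x per-participant neural feature (typically a between-state
#'   difference).
#' @param y per-participant behavioural performance.
#' @param exclude apply outlier exclusion (default TRUE).
#' @return list: `r`, `p`, `n`, `slope`, `intercept`, `excluded`.
#' @export
behavior_correlation <- function(x, y, exclude = TRUE) {
  stopifnot(length(x) == length(y))
  excluded <- integer(0)
  if (exclude && length(x) >= 4) {
    keep <- exclude_outliers(x)$keep & exclude_outliers(y)$keep
    excluded <- which(!keep)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 4) stop("fewer than 4 pairs after exclusion")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), excluded = excluded)
}
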