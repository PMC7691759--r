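# Yield-environment classification.
#
# Trials are grouped by k-means (k = 3) on their mean yield. One-dimensional
# k-means admits an exact dynamic-programming solution (optimal clusters are
# contiguous in sorted order), which removes any dependence on random
# restarts and makes the stage deterministic. Lloyd's algorithm with
# multi-start is retained in the test suite as a cross-check only.

#' Exact one-dimensional k-means
#'
#' Dynamic program over the sorted values: the globally optimal k-means
#' partition in one dimension is contiguous in sorted order, so the optimum is
#' found exactly in O(k n^2) using prefix sums.
#'
#' @param x numeric vector.
#' @param k number of clusters; requires at least `k` distinct values.
#' @return list with `cluster` (assignment 1..k in the original order of `x`,
#'   numbered by ascending cluster center), `centers` (ascending cluster
#'   means) and `tot_withinss` (the optimal within-cluster sum of squares).
#' @export
kmeans1d <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (length(unique(x)) < k)
    stop("kmeans1d requires at least k distinct values", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # cost of putting xs[a..b] in one cluster
  segcost <- function(a, b) {
    s <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    s2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    s2 - s^2 / (b - a + 1L)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)       # first index of the last cluster
  for (i in seq_len(n)) { D[1L, i] <- segcost(1L, i); B[1L, i] <- 1L }
  if (k > 1L) {
    for (m in 2L:k) {
      for (i in m:n) {
        best <- Inf; barg <- m
        for (j in m:i) {
          v <- D[m - 1L, j - 1L] + segcost(j, i)
          if (v < best) { best <- v; barg <- j }
        }
        D[m, i] <- best; B[m, i] <- barg
      }
    }
  }
  bounds <- integer(k)
  i <- n
  for (m in k:1L) { bounds[m] <- B[m, i]; i <- bounds[m] - 1L }
  cl_sorted <- integer(n)
  for (m in seq_len(k)) {
    hi <- if (m < k) bounds[m + 1L] - 1L else n
    cl_sorted[bounds[m]:hi] <- m
  }
  centers <- vapply(seq_len(k), function(m) mean(xs[cl_sorted == m]), 0)
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  list(cluster = cluster, centers = centers, tot_withinss = D[k, n])
}

#' Classify retained trials into yield environments
#'
#' Runs exact one-dimensional k-means (default k = 3) on the trial mean
#' yields, pooled over all retained trials, and labels the clusters by
#' ascending center as LYE (low-), MYE (medium-) and HYE (high-yielding
#' environments). The high class is flagged for exclusion downstream.
#'
#' @param summaries retained trial summaries (see [filter_trials()]); must
#'   contain `trial_id` and `mean_yield`.
#' @param k number of clusters (default 3; labels LYE/MYE/HYE require k = 3,
#'   other k get labels `C1..Ck`).
#' @param seed accepted for interface stability; the exact dynamic-programming
#'   solver is deterministic, so the seed is not consumed.
#' @return data frame `trial_id, class_label, cluster_center` plus attributes
#'   `centers` and `tot_withinss`.
#' @export
classify_environments <- function(summaries, k = 3L, seed = NULL) {
  if (NROW(summaries) < k || length(unique(summaries$mean_yield)) < k)
    stop("classification requires at least k trials with distinct mean yields",
         call. = FALSE)
  km <- kmeans1d(summaries$mean_yield, k)
  labels <- if (k == 3L) c("LYE", "MYE", "HYE") else sprintf("C%d", seq_len(k))
  out <- data.frame(trial_id = summaries$trial_id,
                    class_label = labels[km$cluster],
                    cluster_center = km$centers[km$cluster],
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- stats::setNames(km$centers, labels)
  attr(out, "tot_withinss") <- km$tot_withinss
  out
}
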