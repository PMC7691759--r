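# Coefficient of parentage from a tabular pedigree, and PCA grouping.
#
# The coancestry f(i, j) is the probability that random alleles drawn from i
# and j are identical by descent. It satisfies the textbook recursion
#   f(i, j) = 1/2 [ f(p1(i), j) + f(p2(i), j) ]   (i not an ancestor of j)
#   f(i, i) = 1/2 [ 1 + f(p1(i), p2(i)) ]
# with unknown parents treated as unique, unrelated, non-inbred founders.

#' Validate a 3-column pedigree table
#'
#' Checks that parent references resolve (or are unknown, coded `NA` or an
#' empty string), that the parent relation is acyclic, and returns the rows in
#' topological order (parents before offspring). A selfed ancestor is
#' represented by `parent1 == parent2`.
#'
#' @param df data frame with columns `id`, `parent1`, `parent2`.
#' @return the validated table, class `pedigree`.
#' @export
as_pedigree <- function(df) {
  req <- c("id", "parent1", "parent2")
  if (!all(req %in% names(df)))
    stop("pedigree needs columns id, parent1, parent2", call. = FALSE)
  ped <- data.frame(id = as.character(df$id),
                    parent1 = as.character(df$parent1),
                    parent2 = as.character(df$parent2),
                    stringsAsFactors = FALSE)
  ped$parent1[!is.na(ped$parent1) & ped$parent1 == ""] <- NA_character_
  ped$parent2[!is.na(ped$parent2) & ped$parent2 == ""] <- NA_character_
  if (anyDuplicated(ped$id))
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  known <- c(ped$parent1, ped$parent2)
  known <- known[!is.na(known)]
  missing <- setdiff(known, ped$id)
  if (length(missing))
    stop("parent id(s) not in pedigree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  # Kahn topological sort; a leftover individual implies a cycle
  placed <- character(0)
  remaining <- ped
  order_rows <- integer(0)
  repeat {
    ready <- with(remaining,
                  (is.na(parent1) | parent1 %in% placed) &
                    (is.na(parent2) | parent2 %in% placed))
    if (!any(ready)) break
    order_rows <- c(order_rows, match(remaining$id[ready], ped$id))
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
    if (nrow(remaining) == 0L) break
  }
  if (nrow(remaining) > 0L)
    stop("pedigree contains a cycle involving: ",
         paste(remaining$id, collapse = ", "), call. = FALSE)
  out <- ped[order_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree CSV (id, parent1, parent2; empty field = unknown)
#' @param path file path.
#' @return a validated [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character", na.strings = c("NA", "")))
}

# Full coancestry matrix over every individual, tabular method in
# topological order. Cached on the pedigree via an attribute-free memo
# environment keyed by the pedigree content.
cop_full <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  p1 <- match(ped$parent1, ids)
  p2 <- match(ped$parent2, ids)
  f <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    a <- p1[i]; b <- p2[i]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      fj <- 0.5 * ((if (is.na(a)) 0 else f[a, js]) +
                     (if (is.na(b)) 0 else f[b, js]))
      f[i, js] <- fj
      f[js, i] <- fj
    }
    f[i, i] <- 0.5 * (1 + if (is.na(a) || is.na(b)) 0 else f[a, b])
  }
  f
}

#' Coancestry (coefficient of parentage) of two individuals
#'
#' Recursive coancestry with memoization: repeated queries against the same
#' pedigree object reuse a cached table.
#'
#' @param ped a [as_pedigree()] object.
#' @param i,j individual identifiers.
#' @return the coancestry value in `[0, 1]` (0.5 for a non-inbred individual
#'   with itself).
#' @export
cop <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  if (!i %in% ped$id) stop("unknown id: ", i, call. = FALSE)
  if (!j %in% ped$id) stop("unknown id: ", j, call. = FALSE)
  f <- cop_memo(ped)
  f[i, j]
}

# one-entry cache: recompute only when the pedigree changes
.cop_cache <- new.env(parent = emptyenv())
cop_memo <- function(ped) {
  key <- paste(ped$id, ped$parent1, ped$parent2, collapse = ";")
  if (!identical(.cop_cache$key, key)) {
    .cop_cache$key <- key
    .cop_cache$f <- cop_full(ped)
  }
  .cop_cache$f
}

#' Coancestry matrix over a set of individuals
#'
#' @param ped a [as_pedigree()] object.
#' @param ids identifiers to include (default: all).
#' @return symmetric matrix of coancestries with `ids` as dimnames, class
#'   `cop_matrix`.
#' @export
cop_matrix <- function(ped, ids = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  bad <- setdiff(ids, ped$id)
  if (length(bad)) stop("unknown id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  f <- cop_memo(ped)[ids, ids, drop = FALSE]
  class(f) <- c("cop_matrix", class(f))
  f
}

#' Group lines by principal components of the coancestry matrix
#'
#' Performs a PCA of the (column-centered, by default) coancestry matrix,
#' keeps the leading two component scores, and clusters them by seeded
#' multi-start k-means. Groups are relabeled in decreasing size order, the
#' layout used when tabulating lines per group.
#'
#' @param copm a [cop_matrix()].
#' @param n_groups number of groups (>= 2, <= number of lines).
#' @param seed integer seed for the k-means restarts.
#' @param center center the columns before the eigendecomposition (default
#'   TRUE).
#' @return data frame `id, pc1, pc2, group`, with the k-means object attached
#'   as attribute `kmeans` and the proportion of variance of the two leading
#'   components as attribute `var_explained`.
#' @export
group_lines <- function(copm, n_groups = 4L, seed = 1L, center = TRUE) {
  n <- nrow(copm)
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L || n_groups > n)
    stop("n_groups must be in [2, number of lines]", call. = FALSE)
  M <- unclass(copm)
  pc <- stats::prcomp(M, center = center, scale. = FALSE)
  if (sum(pc$sdev > 1e-9) < 2L)
    stop("coancestry matrix has rank < 2; PCA grouping undefined", call. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  if (n_groups == n) {
    new_lab <- seq_len(n)            # one line per group: clustering is moot
    km <- NULL
  } else {
    km <- with_seed(seed, stats::kmeans(scores, centers = n_groups,
                                        nstart = 25L, iter.max = 100L))
    sizes <- tabulate(km$cluster, n_groups)
    relabel <- order(-sizes, seq_len(n_groups))
    new_lab <- match(km$cluster, relabel)
  }
  out <- data.frame(id = rownames(M), pc1 = scores[, 1], pc2 = scores[, 2],
                    group = new_lab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "kmeans") <- km
  attr(out, "var_explained") <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  out
}
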