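# Cosine k-means and cross-subgroup synergy sorting.

# Lloyd iterations with distance 1 - cosine similarity. Centroid update is
# the arithmetic mean of member vectors (cosine is scale-invariant, so
# centroids are not re-normalized). Empty clusters are re-seeded with the
# point farthest from its current centroid.
cosine_kmeans_once <- function(X, k, centers, max_iter) {
  Xn <- normalize_rows(X)
  cluster <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    Cn <- normalize_rows(centers)
    sim <- Xn %*% t(Cn)
    new_cluster <- max.col(sim, ties.method = "first")
    # empty-cluster repair: re-seed with the point farthest from its
    # centroid, never stealing a cluster's only member
    empty <- setdiff(seq_len(k), unique(new_cluster))
    if (length(empty) > 0) {
      d_own <- 1 - sim[cbind(seq_len(nrow(X)), new_cluster)]
      for (e in empty) {
        counts <- tabulate(new_cluster, k)
        movable <- which(counts[new_cluster] >= 2L)
        far <- movable[which.max(d_own[movable])]
        new_cluster[far] <- e
        d_own[far] <- -Inf
      }
    }
    if (identical(new_cluster, cluster)) break
    cluster <- new_cluster
    centers <- t(vapply(seq_len(k), function(cl) {
      colMeans(X[cluster == cl, , drop = FALSE])
    }, numeric(ncol(X))))
  }
  Cn <- normalize_rows(centers)
  totd <- sum(1 - (Xn %*% t(Cn))[cbind(seq_len(nrow(X)), cluster)])
  list(cluster = cluster, centers = centers, tot_distance = totd)
}

#' k-means clustering under cosine distance
#'
#' Clusters the rows of `X` into `k` groups using distance `1 - cosine
#' similarity`, with multiple random restarts keeping the solution with the
#' lowest total within-cluster distance. Used to reorder synergy weight
#' vectors consistently across 10-cycle subgroups.
#'
#' @param X Numeric matrix, one vector per row; no row may have zero norm.
#' @param k Number of clusters.
#' @param replicas Random restarts (default 15).
#' @param max_iter Maximum Lloyd iterations per restart (default 1e5).
#' @param seed Integer seed for the restarts.
#' @param centers Optional k x ncol(X) initial centroids; when supplied a
#'   single run from these centroids is performed (no restarts).
#' @return A list: `cluster` (assignments), `centers`, `tot_distance`.
#' @export
cosine_kmeans <- function(X, k, replicas = 15L, max_iter = 1e5L, seed = 1L,
                          centers = NULL) {
  X <- as.matrix(X)
  if (any(rowSums(X^2) == 0)) {
    abort("cosine k-means undefined for zero-norm vectors",
          class = "choosyn_zero_norm")
  }
  if (k > nrow(X)) abort("more clusters than points", class = "choosyn_domain")
  if (!is.null(centers)) {
    return(cosine_kmeans_once(X, k, as.matrix(centers), max_iter))
  }
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(replicas)) {
      init <- X[sample(nrow(X), k), , drop = FALSE]
      res <- cosine_kmeans_once(X, k, init, max_iter)
      if (is.null(best) || res$tot_distance < best$tot_distance) best <- res
    }
    best
  })
}

#' Sort synergies consistently across subgroups
#'
#' For a fixed order n, pools the weight columns of every subgroup and
#' clusters them with cosine k-means (k = n, 15 replicas). Within each
#' subgroup, synergies are then matched to clusters one-to-one (optimal
#' assignment minimizing total cosine distance to the centroids, exhaustive
#' over permutations), activation coefficients are reordered accordingly,
#' and centroids are recomputed as arithmetic means across subgroups.
#'
#' @param fits List of `nmf_fit` objects (one per subgroup) at the same
#'   order n >= 2, each carrying `C_avg`.
#' @param replicas,max_iter,seed Passed to [cosine_kmeans()].
#' @return A list: `W_sorted` (list per subgroup of m x n), `C_sorted`
#'   (list per subgroup of n x 1000), `W_centroid` (m x n), `C_centroid`
#'   (n x 1000), `order_n`.
#' @export
sort_synergies <- function(fits, replicas = 15L, max_iter = 1e5L, seed = 1L) {
  n <- fits[[1]]$order_n
  if (n < 2L) abort("sorting needs order n >= 2", class = "choosyn_domain")
  S <- length(fits)
  m <- nrow(fits[[1]]$W)
  # rows = all subgroups' weight columns
  X <- do.call(rbind, lapply(fits, function(f) t(f$W)))
  if (any(rowSums(X^2) == 0)) {
    abort("a subgroup produced an all-zero weight vector; cannot sort",
          class = "choosyn_zero_norm")
  }
  km <- cosine_kmeans(X, n, replicas = replicas, max_iter = max_iter,
                      seed = seed)
  Cn <- normalize_rows(km$centers)
  W_sorted <- vector("list", S)
  C_sorted <- vector("list", S)
  for (g in seq_len(S)) {
    Wg <- fits[[g]]$W                     # m x n, unit-norm columns
    cost <- 1 - t(Wg / rep(sqrt(colSums(Wg^2)), each = m)) %*% t(Cn)
    perm <- assign_one_to_one(cost)       # synergy col i -> cluster perm[i]
    inv <- order(perm)                    # cluster i <- synergy col inv[i]
    W_sorted[[g]] <- Wg[, inv, drop = FALSE]
    C_sorted[[g]] <- fits[[g]]$C_avg[inv, , drop = FALSE]
  }
  W_centroid <- Reduce(`+`, W_sorted) / S
  C_centroid <- Reduce(`+`, C_sorted) / S
  list(W_sorted = W_sorted, C_sorted = C_sorted,
       W_centroid = W_centroid, C_centroid = C_centroid, order_n = n)
}

#' Build the sorted synergy stack for orders 2..8
#'
#' Applies [sort_synergies()] at every order of the extraction (orders >= 2)
#' and carries the per-order VAF curve along.
#'
#' @param extraction A `synergy_extraction`.
#' @param replicas,max_iter,seed Passed to [cosine_kmeans()].
#' @return An object of class `synergy_stack`: `levels` (list indexed by
#'   order n of [sort_synergies()] results), `vaf` (tibble), `n_range`.
#' @export
build_synergy_stack <- function(extraction, replicas = 15L, max_iter = 1e5L,
                                seed = 1L) {
  orders <- extraction$n_range[extraction$n_range >= 2L]
  levels <- list()
  for (n in orders) {
    fits <- lapply(seq_len(extraction$n_subgroups),
                   function(g) extraction$fits[[g]][[n]])
    levels[[as.character(n)]] <-
      sort_synergies(fits, replicas = replicas, max_iter = max_iter,
                     seed = seed + n)
  }
  structure(list(levels = levels, vaf = extraction$vaf,
                 n_range = extraction$n_range),
            class = "synergy_stack")
}

#' @export
print.synergy_stack <- function(x, ...) {
  cat("<synergy_stack> sorted orders ",
      paste(names(x$levels), collapse = ", "), "\n", sep = "")
  invisible(x)
}
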