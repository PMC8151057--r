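# The ChoOSyn criterion: consistency across subgroups (ICV) plus intra-level
# similarity (WS, CS), combined into per-order profiles whose steps and local
# minima locate the optimal number of synergies.

#' Intra-cluster variability of synergies across subgroups
#'
#' For each synergy i, the cosine similarity between each subgroup's vector
#' and the cross-subgroup centroid is averaged across subgroups; the ICV is
#' the worst case, `max_i (1 - mean_j cos(member_ij, centroid_i))`. 0 means
#' perfectly repeatable synergies, 1 completely different across subgroups.
#'
#' @param members List (per subgroup) of matrices whose columns (weights,
#'   m x n) or rows (coefficients, n x T) are synergy vectors; pass
#'   matrices with synergies in columns.
#' @param centroids Matrix of centroids, synergies in columns.
#' @return A scalar in \[0, 1\].
#' @export
intra_cluster_variability <- function(members, centroids) {
  n <- ncol(centroids)
  worst <- 0
  for (i in seq_len(n)) {
    sims <- vapply(members,
                   function(M) cosine_similarity(M[, i], centroids[, i]),
                   numeric(1))
    worst <- max(worst, 1 - mean(sims))
  }
  worst
}

#' Worst-case similarity between weight centroids
#'
#' The maximum cosine similarity over all unordered pairs of weight
#' centroids at one order: high values flag redundant synergies.
#'
#' @param W_centroid Matrix of centroids, synergies in columns (n >= 2).
#' @return A scalar in \[0, 1\] for non-negative weights.
#' @export
weight_similarity <- function(W_centroid) {
  n <- ncol(W_centroid)
  if (n < 2L) abort("needs at least two synergies", class = "choosyn_domain")
  best <- -Inf
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      best <- max(best, cosine_similarity(W_centroid[, i], W_centroid[, k]))
    }
  }
  best
}

#' Identify the pair of synergies produced by a split from order n-1
#'
#' Clusters the n weight centroids of level n into n-1 clusters initialized
#' at the level-(n-1) centroids (cosine k-means); by pigeonhole, at least
#' one cluster holds two or more level-n synergies — those are the split
#' products. For n = 2 the pair is trivially (1, 2). If several clusters
#' hold multiple members, the within-cluster pair with the highest
#' coefficient similarity is returned (worst case).
#'
#' @param W_n Level-n weight centroids (m x n), n >= 2.
#' @param W_prev Level-(n-1) weight centroids (m x (n-1)); ignored for n = 2.
#' @param C_n Level-n coefficient centroids (n x T), used to resolve
#'   degenerate clusterings; may be NULL (first pair then wins).
#' @return An integer vector of two synergy indices at level n.
#' @export
find_split_pair <- function(W_n, W_prev = NULL, C_n = NULL) {
  n <- ncol(W_n)
  if (n == 2L) return(c(1L, 2L))
  km <- cosine_kmeans(t(W_n), n - 1L, centers = t(W_prev), max_iter = 100L)
  pairs <- list()
  for (cl in unique(km$cluster)) {
    mem <- which(km$cluster == cl)
    if (length(mem) >= 2L) {
      cmb <- utils::combn(mem, 2L)
      for (p in seq_len(ncol(cmb))) pairs[[length(pairs) + 1L]] <- cmb[, p]
    }
  }
  if (length(pairs) == 0L) {
    abort("split-pair clustering degenerated; cannot identify a split",
          class = "choosyn_domain")
  }
  if (length(pairs) == 1L || is.null(C_n)) return(as.integer(pairs[[1]]))
  cs <- vapply(pairs, function(p) {
    cosine_similarity(C_n[p[1], ], C_n[p[2], ])
  }, numeric(1))
  as.integer(pairs[[which.max(cs)]])
}

#' Coefficient similarity of a split pair
#'
#' Cosine similarity between the two coefficient centroids identified by
#' [find_split_pair()]: near 1 means the new synergy at level n adds little
#' information.
#'
#' @param C_centroid Coefficient centroids (n x T).
#' @param pair Two synergy indices.
#' @return A scalar in \[0, 1\] for non-negative coefficients.
#' @export
coefficient_similarity <- function(C_centroid, pair) {
  cosine_similarity(C_centroid[pair[1], ], C_centroid[pair[2], ])
}

#' Build the ChoOSyn profile over orders 2..8
#'
#' Computes, for every order n of the stack, the intra-cluster variability
#' of weights and coefficients (ICVW, ICVC), the weight similarity (WS) and
#' the split-pair coefficient similarity (CS), and combines them as
#' `ChoOSynW(n) = WS(n) + ICVW(n)` and `ChoOSynC(n) = CS(n) + ICVC(n)`.
#'
#' @param stack A `synergy_stack` covering consecutive orders (2..8 in the
#'   standard pipeline).
#' @return An object of class `choosyn_profile` wrapping a tibble with
#'   columns n, icv_w, icv_c, ws, cs, choosyn_w, choosyn_c, and the signed
#'   first differences delta_w, delta_c (`value(n+1) - value(n)`, NA at the
#'   last order).
#' @export
build_profile <- function(stack) {
  orders <- sort(as.integer(names(stack$levels)))
  if (length(orders) == 0L || orders[1] != 2L || any(diff(orders) != 1L)) {
    abort("stack must cover consecutive orders starting at 2",
          class = "choosyn_incomplete_stack")
  }
  rows <- lapply(orders, function(n) {
    lvl <- stack$levels[[as.character(n)]]
    members_w <- lvl$W_sorted
    members_c <- lapply(lvl$C_sorted, t)    # synergies in columns
    icv_w <- intra_cluster_variability(members_w, lvl$W_centroid)
    icv_c <- intra_cluster_variability(members_c, t(lvl$C_centroid))
    ws <- weight_similarity(lvl$W_centroid)
    prev <- if (n == 2L) NULL else stack$levels[[as.character(n - 1L)]]$W_centroid
    pair <- find_split_pair(lvl$W_centroid, prev, lvl$C_centroid)
    cs <- coefficient_similarity(lvl$C_centroid, pair)
    tibble(n = n, icv_w = icv_w, icv_c = icv_c, ws = ws, cs = cs,
           choosyn_w = ws + icv_w, choosyn_c = cs + icv_c)
  })
  pf <- dplyr::bind_rows(rows)
  pf$delta_w <- c(diff(pf$choosyn_w), NA_real_)
  pf$delta_c <- c(diff(pf$choosyn_c), NA_real_)
  structure(list(profile = pf), class = "choosyn_profile")
}

#' @export
print.choosyn_profile <- function(x, ...) {
  cat("<choosyn_profile>\n")
  print(x$profile)
  invisible(x)
}

#' Detect step and local-minimum candidates on one ChoOSyn profile
#'
#' With signed first differences `d(n) = value(n+1) - value(n)` (n = 2..7)
#' and threshold `theta = mean(|d|)`: a STEP sits at n when `d(n) > theta`
#' and the preceding difference is stable (`|d(n-1)| <= theta`, or n = 2) —
#' the candidate is the level before the sharp rise; a LOCAL MINIMUM sits at
#' n when `-d(n-1) > theta` and `d(n) > theta` (an abrupt decrease followed
#' by an abrupt increase). Of all candidates, only the two highest orders
#' are kept. A flat profile yields no candidates.
#'
#' @param values Numeric vector of profile values at n = 2..8 (length 7),
#'   or more generally at consecutive orders starting at `n_min`.
#' @param n_min First order of `values` (default 2).
#' @return A tibble with columns `n` and `kind` ("step" or
#'   "local_minimum"), at most two rows, ordered by n.
#' @export
#' @examples
#' detect_candidates(c(0.30, 0.32, 0.31, 0.75, 0.80, 0.85, 0.90)) # step at 4
detect_candidates <- function(values, n_min = 2L) {
  d <- diff(values)                       # d[i] at order n_min + i - 1
  theta <- mean(abs(d))
  ns <- n_min + seq_along(d) - 1L         # orders carrying a difference
  cand <- list()
  for (i in seq_along(d)) {
    n <- ns[i]
    if (d[i] > theta && (i == 1L || abs(d[i - 1L]) <= theta)) {
      cand[[length(cand) + 1L]] <- tibble(n = n, kind = "step")
    }
    if (i > 1L && -d[i - 1L] > theta && d[i] > theta) {
      cand[[length(cand) + 1L]] <- tibble(n = n, kind = "local_minimum")
    }
  }
  out <- if (length(cand)) dplyr::bind_rows(cand) else
    tibble(n = integer(), kind = character())
  out <- dplyr::arrange(out, .data$n)
  if (nrow(out) > 2L) out <- out[(nrow(out) - 1L):nrow(out), ]
  out
}

#' Select the number of synergies from a ChoOSyn profile
#'
#' Candidates are detected separately on the ChoOSynW and ChoOSynC
#' profiles. If the two candidate sets share an order, the common order is
#' selected (two common orders: the one with the smaller
#' `ChoOSynW + ChoOSynC`, exact ties to the smaller n). Otherwise the order
#' minimizing `ChoOSynW(n) + ChoOSynC(n)` over the union of candidates
#' wins. If both candidate sets are empty the minimizer over all orders is
#' returned, flagged as a fallback.
#'
#' @param profile A `choosyn_profile`.
#' @return An object of class `choosyn_selection`: `n` (the selection),
#'   `rule` ("common", "lowest-sum" or "fallback"), `candidates_w`,
#'   `candidates_c` (tibbles from [detect_candidates()]), `fallback`
#'   (logical), `profile`.
#' @export
select_n_choosyn <- function(profile) {
  pf <- profile$profile
  n_min <- min(pf$n)
  cand_w <- detect_candidates(pf$choosyn_w, n_min = n_min)
  cand_c <- detect_candidates(pf$choosyn_c, n_min = n_min)
  sums <- pf$choosyn_w + pf$choosyn_c
  pick_min_sum <- function(ns) {
    s <- sums[match(ns, pf$n)]
    ns[order(s, ns)][1]
  }
  common <- intersect(cand_w$n, cand_c$n)
  if (length(common) >= 1L) {
    n_sel <- pick_min_sum(common)
    rule <- "common"
    fallback <- FALSE
  } else if (nrow(cand_w) + nrow(cand_c) > 0L) {
    n_sel <- pick_min_sum(union(cand_w$n, cand_c$n))
    rule <- "lowest-sum"
    fallback <- FALSE
  } else {
    n_sel <- pick_min_sum(pf$n)
    rule <- "fallback"
    fallback <- TRUE
  }
  structure(list(n = as.integer(n_sel), rule = rule,
                 candidates_w = cand_w, candidates_c = cand_c,
                 fallback = fallback, profile = pf),
            class = "choosyn_selection")
}

#' @export
print.choosyn_selection <- function(x, ...) {
  cat("<choosyn_selection> n = ", x$n, " (rule: ", x$rule, ")\n", sep = "")
  invisible(x)
}
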