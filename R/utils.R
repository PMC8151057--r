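# Internal helpers shared across modules.

#' Cosine similarity between two vectors
#'
#' For non-negative vectors (weights, activation coefficients) the value lies
#' in \[0, 1\]; 1 means proportional vectors, 0 means disjoint support.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1)) # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine similarity undefined for a zero-norm vector",
          class = "choosyn_zero_norm")
  }
  sum(a * b) / (na * nb)
}

# rows of X normalised to unit Euclidean norm; zero rows -> error upstream
normalize_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  X / n
}

# all permutations of 1..n as a matrix (n! rows); cached per n
perms_cache <- new.env(parent = emptyenv())

all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(perms_cache[[key]])) return(perms_cache[[key]])
  p <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- all_perms(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    row <- 1L
    for (k in seq_len(n)) {
      rest <- setdiff(seq_len(n), k)
      for (r in seq_len(nrow(sub))) {
        out[row, ] <- c(k, rest[sub[r, ]])
        row <- row + 1L
      }
    }
    out
  }
  perms_cache[[key]] <- p
  p
}

# minimal-cost one-to-one assignment of rows to columns of a square cost
# matrix by exhaustive search (n <= 8 here, at most 40,320 permutations)
assign_one_to_one <- function(cost) {
  n <- nrow(cost)
  p <- all_perms(n)
  idx <- matrix(rep(seq_len(n), nrow(p)), ncol = n, byrow = TRUE)
  totals <- rowSums(matrix(cost[cbind(as.vector(idx), as.vector(p))],
                           ncol = n))
  p[which.min(totals), ]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
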