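#' Non-negative matrix factorization by alternating NNLS
#'
#' Factorizes a non-negative matrix `V` (muscles x samples) as `W %*% C`
#' with `W` (m x n) and `C` (n x T) non-negative, alternating exact
#' non-negative least-squares solves for each factor (block principal
#' pivoting). Iteration stops at `max_iter`, when the relative Frobenius
#' residual `||V - WC|| / ||V||` drops below `tol_residual`, or when the
#' largest relative change of the factor entries between successive
#' iterations drops below `tol_change`. The algorithm restarts `reruns`
#' times from independent uniform-random initializations (seeded `seed + r`)
#' and keeps the restart with the smallest residual. Columns of `W` are
#' scale-normalized to unit Euclidean norm with compensating row scaling of
#' `C`.
#'
#' @param V Non-negative numeric matrix, muscles x samples.
#' @param order_n Number of synergies, `1 <= order_n <= nrow(V)`.
#' @param seed Integer master seed for the restarts.
#' @param reruns Number of random restarts (default 5).
#' @param max_iter Maximum ANLS iterations per restart (default 1000).
#' @param tol_residual,tol_change Stopping tolerances (defaults 1e-6).
#' @return An object of class `nmf_fit`: `W`, `C`, `residual` (relative
#'   Frobenius), `rerun_errors`, `order_n`, `iterations`.
#' @export
#' @examples
#' V <- outer(c(1, 2, 0.5), abs(sin(seq(0, pi, length.out = 200))))
#' fit <- nmf_anls(V, 1, seed = 1)
#' fit$residual < 1e-6
nmf_anls <- function(V, order_n, seed, reruns = 5L, max_iter = 1000L,
                     tol_residual = 1e-6, tol_change = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) {
    abort("`V` must be non-negative", class = "choosyn_domain")
  }
  order_n <- as.integer(order_n)
  if (order_n < 1L || order_n > nrow(V)) {
    abort("number of synergies must not exceed the number of muscles",
          class = "choosyn_order_exceeds_muscles")
  }
  m <- nrow(V)
  best <- NULL
  errors <- numeric(reruns)
  for (r in seq_len(reruns)) {
    W0 <- withr::with_seed(seed + r, matrix(runif(m * order_n), m, order_n))
    fit <- anls_nmf_cpp(V, W0, max_iter, tol_residual, tol_change)
    errors[r] <- fit$residual
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  # fix the scale indeterminacy: unit-norm columns of W
  nw <- sqrt(colSums(best$W^2))
  pos <- nw > 0
  best$W[, pos] <- sweep(best$W[, pos, drop = FALSE], 2, nw[pos], "/")
  best$C[pos, ] <- sweep(best$C[pos, , drop = FALSE], 1, nw[pos], "*")
  structure(list(W = best$W, C = best$C, residual = best$residual,
                 rerun_errors = errors, order_n = order_n,
                 iterations = best$iterations),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> ", nrow(x$W), " muscles x ", x$order_n,
      " synergies, relative residual ", signif(x$residual, 4), "\n", sep = "")
  invisible(x)
}

#' Average activation coefficients across the 10 cycles of a subgroup
#'
#' Reshapes an n x 10,000 coefficient matrix into ten 1000-sample windows
#' (one per cycle) and averages across windows, giving the mean activation
#' over the normalized gait cycle.
#'
#' @param C_full Coefficient matrix, n x (10 * cycle_length).
#' @param cycle_length Samples per cycle (default 1000).
#' @return An n x cycle_length matrix.
#' @export
average_coefficients <- function(C_full, cycle_length = 1000L) {
  C_full <- as.matrix(C_full)
  Tn <- ncol(C_full)
  if (Tn %% cycle_length != 0) {
    abort("coefficient length must be a multiple of the cycle length",
          class = "choosyn_shape")
  }
  k <- Tn %/% cycle_length
  out <- matrix(0, nrow(C_full), cycle_length)
  for (w in seq_len(k)) {
    out <- out + C_full[, ((w - 1L) * cycle_length + 1L):(w * cycle_length),
                        drop = FALSE]
  }
  out / k
}

#' Variance accounted for by a reconstruction
#'
#' Uncentered reconstruction quality in percent:
#' `(1 - sum((M - R)^2) / sum(M^2)) * 100`, sums over all entries.
#'
#' @param M Matrix before factorization.
#' @param R Reconstructed matrix (`W %*% C`).
#' @return A scalar (at most 100).
#' @export
#' @examples
#' vaf(matrix(c(1, 3, 2, 4), 2), matrix(c(1, 3, 1, 3), 2)) # 93.33
vaf <- function(M, R) {
  if (!all(dim(M) == dim(R))) {
    abort("`M` and `R` must have the same shape", class = "choosyn_shape")
  }
  den <- sum(M^2)
  if (den == 0) {
    abort("VAF undefined for an all-zero matrix", class = "choosyn_undefined_vaf")
  }
  (1 - sum((M - R)^2) / den) * 100
}

#' Factorize every subgroup at every candidate order
#'
#' Runs [nmf_anls()] on each 10-cycle subgroup for every order in
#' `n_range`, stores the VAF of each fit and the cycle-averaged
#' coefficients.
#'
#' @param subs A `subgroup_envelopes` object.
#' @param n_range Candidate synergy numbers (default 1:8).
#' @param seed Integer master seed; restart seeds are derived per
#'   (subgroup, order).
#' @param reruns,max_iter,tol_residual,tol_change Passed to [nmf_anls()].
#' @return An object of class `synergy_extraction`: `fits` (list indexed
#'   `[[subgroup]][[order]]` of `nmf_fit` objects, each with a `C_avg`
#'   element), `vaf` (tibble: subgroup, n, vaf), `n_range`,
#'   `n_subgroups`.
#' @export
extract_synergies <- function(subs, n_range = 1:8, seed = 1L, reruns = 5L,
                              max_iter = 1000L, tol_residual = 1e-6,
                              tol_change = 1e-6) {
  m <- nrow(subs$subgroups[[1]])
  if (max(n_range) > m) {
    abort("number of synergies must not exceed the number of muscles",
          class = "choosyn_order_exceeds_muscles")
  }
  fits <- vector("list", subs$n_subgroups)
  vaf_rows <- list()
  for (g in seq_len(subs$n_subgroups)) {
    V <- subs$subgroups[[g]]
    fits[[g]] <- vector("list", max(n_range))
    for (n in n_range) {
      fit <- nmf_anls(V, n, seed = seed + 1000L * g + 10L * n,
                      reruns = reruns, max_iter = max_iter,
                      tol_residual = tol_residual, tol_change = tol_change)
      fit$C_avg <- average_coefficients(fit$C)
      fits[[g]][[n]] <- fit
      vaf_rows[[length(vaf_rows) + 1L]] <-
        tibble(subgroup = g, n = n, vaf = vaf(V, fit$W %*% fit$C))
    }
  }
  structure(list(fits = fits, vaf = dplyr::bind_rows(vaf_rows),
                 n_range = sort(as.integer(n_range)),
                 n_subgroups = subs$n_subgroups),
            class = "synergy_extraction")
}

#' @export
print.synergy_extraction <- function(x, ...) {
  cat("<synergy_extraction> ", x$n_subgroups, " subgroups, orders ",
      min(x$n_range), "..", max(x$n_range), "\n", sep = "")
  invisible(x)
}
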