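test_that("the multi-RHS NNLS solver matches an independent active-set oracle", {
  skip_if_not_installed("pracma")
  for (seed in 1:5) {
    A <- withr::with_seed(seed, matrix(rnorm(20 * 6), 20, 6))
    B <- withr::with_seed(seed + 50, matrix(rnorm(20 * 7), 20, 7))
    X <- choosyn:::nnls_multi_cpp(A, B)
    for (j in seq_len(ncol(B))) {
      ref <- pracma::lsqnonneg(A, B[, j])$x
      expect_equal(X[, j], ref, tolerance = 1e-8)
    }
  }
})

test_that("exact rank-1 input is recovered essentially perfectly", {
  w <- c(1, 2, 0.5, 3)
  cvec <- abs(sin(seq(0, 2 * pi, length.out = 600))) + 0.1
  V <- outer(w, cvec)
  fit <- nmf_anls(V, 1, seed = 1)
  expect_gte(vaf(V, fit$W %*% fit$C), 99.99)
  expect_true(all(fit$W >= 0) && all(fit$C >= 0))
})

test_that("factors are non-negative and W columns are unit-norm", {
  V <- rand_nonneg(8, 400, seed = 3)
  fit <- nmf_anls(V, 3, seed = 2)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$C >= 0))
  expect_equal(colSums(fit$W^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(fit$residual, min(fit$rerun_errors))
  expect_length(fit$rerun_errors, 5)
})

test_that("the best-of-restarts residual does not increase with the order", {
  for (seed in 1:6) {
    V <- rand_nonneg(12, 1000, seed = seed)
    res <- vapply(2:5, function(k) {
      nmf_anls(V, k, seed = 7, reruns = 3)$residual
    }, numeric(1))
    expect_true(all(diff(res) <= 1e-3))
  }
})

test_that("a zero row of V gives a zero row of W at the fixed point", {
  V <- rand_nonneg(6, 300, seed = 4)
  V[2, ] <- 0
  fit <- nmf_anls(V, 2, seed = 5)
  expect_lt(max(abs(fit$W[2, ])), 1e-8)
})

test_that("nmf_anls rejects invalid input", {
  expect_error(nmf_anls(matrix(-1, 2, 4), 1, seed = 1),
               class = "choosyn_domain")
  expect_error(nmf_anls(matrix(1, 2, 4), 3, seed = 1),
               class = "choosyn_order_exceeds_muscles")
})

test_that("coefficient averaging reduces ten windows to one mean cycle", {
  expect_equal(average_coefficients(matrix(0.5, 2, 10000)),
               matrix(0.5, 2, 1000))
  r <- sin(seq(0, pi, length.out = 1000))^2
  periodic <- matrix(rep(r, 10), 1, byrow = TRUE)
  expect_equal(average_coefficients(periodic), matrix(r, 1), tolerance = 1e-12)
  # windows k * r for k = 1..10 average to 5.5 * r
  ramped <- matrix(unlist(lapply(1:10, function(k) k * r)), 1, byrow = TRUE)
  expect_equal(average_coefficients(ramped), matrix(5.5 * r, 1),
               tolerance = 1e-12)
  expect_error(average_coefficients(matrix(1, 2, 9999)),
               class = "choosyn_shape")
})

test_that("VAF follows the uncentered worked example", {
  M <- matrix(c(1, 3, 2, 4), 2)
  R <- matrix(c(1, 3, 1, 3), 2)
  expect_equal(vaf(M, R), (1 - 2 / 30) * 100)
  expect_equal(vaf(M, M), 100)
  expect_equal(vaf(M, 0 * M), 0)
  expect_error(vaf(M, matrix(0, 3, 2)), class = "choosyn_shape")
  expect_error(vaf(0 * M, R), class = "choosyn_undefined_vaf")
})

test_that("extraction covers every subgroup/order pair deterministically", {
  subs <- true_envelope_subgroups(true_n = 3, m = 8, n_cycles = 20, seed = 6)
  extr <- extract_synergies(subs, n_range = 1:4, seed = 9, reruns = 2)
  expect_equal(nrow(extr$vaf), 2 * 4)
  extr2 <- extract_synergies(subs, n_range = 1:4, seed = 9, reruns = 2)
  expect_identical(extr$vaf, extr2$vaf)
  # rank-3 noiseless input saturates at n = 3
  v3 <- extr$vaf$vaf[extr$vaf$n == 3]
  expect_gte(mean(v3), 99.9)
  # VAF non-decreasing in n per subgroup (stochastic tolerance)
  for (g in 1:2) {
    curve <- extr$vaf$vaf[extr$vaf$subgroup == g][order(extr$vaf$n[extr$vaf$subgroup == g])]
    expect_true(all(diff(curve) >= -1e-3))
  }
})

test_that("cosine k-means recovers exact clusters and orders subgroups", {
  # same three orthogonal weight vectors, shuffled per subgroup
  base <- diag(3)
  fits <- lapply(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), function(p) {
    list(W = base[, p], C_avg = matrix(as.numeric(p), 3, 10), order_n = 3L)
  })
  sorted <- sort_synergies(fits, seed = 1)
  for (g in 2:3) {
    expect_equal(sorted$W_sorted[[g]], sorted$W_sorted[[1]])
  }
  # coefficients sorted along with their weights: synergy i carries the
  # constant row equal to its original column index
  for (i in 1:3) {
    expect_equal(length(unique(c(sapply(1:3, function(g)
      sorted$C_sorted[[g]][i, 1])))), 1)
  }
})

test_that("nearest-by-cosine pairing matches the brute-force assignment", {
  w1 <- cbind(c(1, 0), c(0, 1))
  w2 <- cbind(c(0.9, 0.1), c(0.1, 0.9))
  w2 <- sweep(w2, 2, sqrt(colSums(w2^2)), "/")
  fits <- list(list(W = w1, C_avg = matrix(1:2, 2, 5), order_n = 2L),
               list(W = w2[, 2:1], C_avg = matrix(c(9, 8), 2, 5), order_n = 2L))
  sorted <- sort_synergies(fits, seed = 3)
  # brute force over both pairings: identity pairing has higher cosine
  s1 <- cosine_similarity(sorted$W_sorted[[1]][, 1], sorted$W_sorted[[2]][, 1])
  s2 <- cosine_similarity(sorted$W_sorted[[1]][, 2], sorted$W_sorted[[2]][, 2])
  expect_gt(s1, 0.9)
  expect_gt(s2, 0.9)
})

test_that("centroids are invariant to subgroup order up to relabeling", {
  subs <- true_envelope_subgroups(true_n = 3, m = 8, n_cycles = 30, seed = 12)
  extr <- extract_synergies(subs, n_range = 3, seed = 4, reruns = 2)
  fits <- lapply(seq_len(extr$n_subgroups), function(g) extr$fits[[g]][[3]])
  a <- sort_synergies(fits, seed = 5)
  b <- sort_synergies(rev(fits), seed = 5)
  # compare centroid sets as unordered collections
  match_cost <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    sum((a$W_centroid[, i] - b$W_centroid[, j])^2)
  }))
  expect_lt(sum(apply(match_cost, 1, min)), 1e-8)
})

test_that("sorting rejects all-zero weight vectors and tiny orders", {
  fits <- list(list(W = cbind(c(1, 0), c(0, 0)), C_avg = matrix(1, 2, 5),
                    order_n = 2L))
  expect_error(sort_synergies(c(fits, fits)), class = "choosyn_zero_norm")
  fits1 <- list(list(W = matrix(1, 2, 1), C_avg = matrix(1, 1, 5),
                     order_n = 1L))
  expect_error(sort_synergies(fits1), class = "choosyn_domain")
})

test_that("per-subgroup sorted labels are a one-to-one assignment", {
  subs <- true_envelope_subgroups(true_n = 4, m = 10, n_cycles = 20, seed = 21)
  extr <- extract_synergies(subs, n_range = 1:5, seed = 2, reruns = 2)
  stack <- build_synergy_stack(extr, seed = 3)
  for (n in 2:5) {
    lvl <- stack$levels[[as.character(n)]]
    for (g in seq_along(lvl$W_sorted)) {
      expect_identical(dim(lvl$W_sorted[[g]]), c(10L, n))
      expect_identical(dim(lvl$C_sorted[[g]]), c(n, 1000L))
    }
    expect_identical(dim(lvl$W_centroid), c(10L, n))
  }
})
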