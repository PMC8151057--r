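test_that("intra-cluster variability follows the cosine worked examples", {
  # members identical to the centroid: perfectly repeatable, ICV = 0
  members <- list(cbind(c(1, 0)), cbind(c(1, 0)))
  expect_equal(intra_cluster_variability(members, cbind(c(1, 0))), 0)
  # orthogonal members around a diagonal centroid: 1 - cos(45 deg)
  members <- list(cbind(c(1, 0)), cbind(c(0, 1)))
  expect_equal(intra_cluster_variability(members, cbind(c(0.5, 0.5))),
               1 - sqrt(2) / 2, tolerance = 1e-10)
  # worst synergy wins: max over {0, 0.2929}
  members2 <- list(cbind(c(1, 0), c(1, 0)), cbind(c(0, 1), c(1, 0)))
  centroids <- cbind(c(0.5, 0.5), c(1, 0))
  expect_equal(intra_cluster_variability(members2, centroids),
               1 - sqrt(2) / 2, tolerance = 1e-10)
  expect_error(intra_cluster_variability(list(cbind(c(0, 0))), cbind(c(1, 0))),
               class = "choosyn_zero_norm")
})

test_that("weight similarity is the worst-case pairwise cosine", {
  expect_equal(weight_similarity(cbind(c(1, 0), c(1, 0))), 1)
  expect_equal(weight_similarity(cbind(c(1, 0), c(0, 1))), 0)
  expect_equal(weight_similarity(cbind(c(1, 0, 0), c(1, 1, 0) / sqrt(2))),
               sqrt(2) / 2, tolerance = 1e-10)
  # brute force over all pairs for n > 2
  W <- rand_nonneg(6, 4, seed = 8)
  brute <- max(combn(4, 2, function(p)
    cosine_similarity(W[, p[1]], W[, p[2]])))
  expect_equal(weight_similarity(W), brute)
  expect_error(weight_similarity(cbind(c(1, 0))), class = "choosyn_domain")
})

test_that("split pairs are found by clustering level n into n-1 groups", {
  expect_equal(find_split_pair(cbind(c(1, 0), c(0, 1))), c(1L, 2L))
  # a orthogonal to b, c; cos(b, c) = 0.9: the pair must be (b, c)
  theta <- acos(0.9)
  b <- c(cos(theta / 2), sin(theta / 2), 0)
  cc <- c(cos(theta / 2), -sin(theta / 2), 0)
  a <- c(0, 0, 1)
  W3 <- cbind(a, b, cc)
  W2 <- cbind(a, (b + cc) / 2)
  expect_setequal(find_split_pair(W3, W2), c(2L, 3L))
  # pigeonhole: n vectors into n-1 clusters always yields a pair
  for (seed in 1:5) {
    Wn <- rand_nonneg(8, 5, seed = seed)
    Wp <- rand_nonneg(8, 4, seed = seed + 100)
    pair <- find_split_pair(Wn, Wp)
    expect_length(pair, 2)
    expect_true(all(pair %in% 1:5))
    expect_false(pair[1] == pair[2])
  }
})

test_that("coefficient similarity is the cosine of the split pair", {
  C <- rbind(c(1, 1), c(1, 0), c(0, 1))
  expect_equal(coefficient_similarity(C, c(1, 1)), 1)
  expect_equal(coefficient_similarity(C, c(2, 3)), 0)
  expect_equal(coefficient_similarity(C, c(1, 2)), sqrt(2) / 2,
               tolerance = 1e-10)
})

test_that("candidate detection matches the worked step and minimum examples", {
  step_profile <- c(0.30, 0.32, 0.31, 0.75, 0.80, 0.85, 0.90)
  cand <- detect_candidates(step_profile)
  expect_equal(cand$n, 4L)
  expect_equal(cand$kind, "step")

  min_profile <- c(0.50, 0.48, 0.20, 0.55, 0.57, 0.58, 0.60)
  cand <- detect_candidates(min_profile)
  expect_equal(cand$n, 4L)
  expect_equal(cand$kind, "local_minimum")

  # flat profile: no candidates
  expect_equal(nrow(detect_candidates(rep(0.4, 7))), 0)
})

test_that("only the two highest candidate orders are kept", {
  # steps at 3, 5 and 7: rises from stable plateaus
  v <- c(0.10, 0.10, 0.40, 0.40, 0.70, 0.70, 1.00)
  cand <- detect_candidates(v)
  expect_equal(sort(cand$n), c(5L, 7L))
})

test_that("candidate detection equals a brute-force rule evaluator", {
  for (i in 1:2000) {
    v <- withr::with_seed(i, runif(7))
    got <- detect_candidates(v)
    ref <- brute_candidates(v)
    expect_equal(got$n, as.integer(ref$n), info = paste("profile seed", i))
    expect_equal(got$kind, as.character(ref$kind))
  }
})

make_profile <- function(w, c) {
  structure(list(profile = tibble::tibble(
    n = 2:8, icv_w = 0, icv_c = 0, ws = w, cs = c,
    choosyn_w = w, choosyn_c = c)), class = "choosyn_profile")
}

test_that("a common candidate order is selected when both sides agree", {
  v <- c(0.30, 0.32, 0.31, 0.75, 0.80, 0.85, 0.90)   # step candidate {4}
  sel <- select_n_choosyn(make_profile(v, v))
  expect_equal(sel$n, 4L)
  expect_equal(sel$rule, "common")
  expect_false(sel$fallback)
})

test_that("disjoint candidates fall back to the lowest ChoOSyn sum", {
  w <- c(0.30, 0.31, 0.32, 0.33, 0.80, 0.85, 0.90)   # step candidate {5}
  c <- c(0.30, 0.32, 0.31, 0.75, 0.80, 0.85, 0.90)   # step candidate {4}
  sel <- select_n_choosyn(make_profile(w, c))
  expect_equal(sel$candidates_w$n, 5L)
  expect_equal(sel$candidates_c$n, 4L)
  # sums: at 4 -> 0.33 + 0.75 = 1.08; at 5 -> 0.80 + 0.80 = 1.60
  expect_equal(sel$n, 4L)
  expect_equal(sel$rule, "lowest-sum")
})

test_that("a flat profile falls back to the overall minimum sum", {
  sel <- select_n_choosyn(make_profile(rep(0.5, 7), rep(0.3, 7)))
  expect_equal(sel$n, 2L)
  expect_true(sel$fallback)
  expect_equal(sel$rule, "fallback")
})

test_that("the full profile is scale-invariant and within bounds", {
  subs <- true_envelope_subgroups(true_n = 3, m = 8, n_cycles = 20, seed = 31)
  extr <- extract_synergies(subs, n_range = 1:5, seed = 3, reruns = 2)
  stack <- build_synergy_stack(extr, seed = 4)
  prof <- build_profile(stack)
  pf <- prof$profile
  expect_equal(pf$n, 2:5)
  for (col in c("icv_w", "icv_c", "ws", "cs")) {
    expect_true(all(pf[[col]] >= -1e-9 & pf[[col]] <= 1 + 1e-9))
  }
  expect_equal(pf$choosyn_w, pf$ws + pf$icv_w)
  expect_equal(pf$choosyn_c, pf$cs + pf$icv_c)
  # finite-difference oracle for the stored deltas
  expect_equal(pf$delta_w, c(pf$choosyn_w[-1] - pf$choosyn_w[-nrow(pf)], NA))
  expect_equal(pf$delta_c, c(pf$choosyn_c[-1] - pf$choosyn_c[-nrow(pf)], NA))

  # multiplying any member and centroid vectors by positive constants
  # leaves every cosine-based parameter unchanged
  scaled <- stack
  for (n in names(scaled$levels)) {
    lvl <- scaled$levels[[n]]
    lvl$W_sorted <- lapply(lvl$W_sorted, function(W) W * 7.3)
    lvl$C_sorted <- lapply(lvl$C_sorted, function(C) C * 0.21)
    lvl$W_centroid <- lvl$W_centroid * 7.3
    lvl$C_centroid <- lvl$C_centroid * 0.21
    scaled$levels[[n]] <- lvl
  }
  prof2 <- build_profile(scaled)
  expect_equal(prof2$profile, pf, tolerance = 1e-10)
})

test_that("an incomplete stack is rejected", {
  subs <- true_envelope_subgroups(true_n = 3, m = 8, n_cycles = 20, seed = 31)
  extr <- extract_synergies(subs, n_range = 3:5, seed = 3, reruns = 2)
  stack <- build_synergy_stack(extr, seed = 4)
  expect_error(build_profile(stack), class = "choosyn_incomplete_stack")
})
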