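test_that("ground-truth sets have the contracted shape, sign and determinism", {
  gt <- generate_ground_truth(true_n = 4, m = 12, n_cycles = 1, seed = 7)
  expect_identical(dim(gt$weights), c(12L, 4L))
  expect_identical(dim(gt$coefficients), c(4L, 1000L))
  expect_true(all(gt$weights >= 0))
  expect_true(all(gt$coefficients >= 0))
  expect_true(all(colSums(gt$weights > 0) >= 1))
  expect_identical(gt, generate_ground_truth(4, 12, 1, seed = 7))
  expect_false(identical(gt, generate_ground_truth(4, 12, 1, seed = 8)))
})

test_that("weight columns respect the distinctness cap", {
  gt <- generate_ground_truth(true_n = 5, m = 12, n_cycles = 150, seed = 1)
  Wn <- apply(gt$weights, 2, function(w) w / sqrt(sum(w^2)))
  cosines <- combn(5, 2, function(p) sum(Wn[, p[1]] * Wn[, p[2]]))
  expect_lte(max(cosines), 0.6)
  expect_equal(ncol(gt$coefficients), 150 * 1000)
})

test_that("generator rejects impossible orders", {
  expect_error(generate_ground_truth(6, 4, 1, seed = 1),
               class = "choosyn_order_exceeds_muscles")
  expect_error(generate_ground_truth(1, 12, 1, seed = 1),
               class = "choosyn_domain")
})

test_that("augmentation crosses weights with coefficients in order", {
  subjects <- lapply(1:3, function(s)
    generate_ground_truth(3, 8, 1, seed = 100 + s))
  sets <- augment_sets(subjects)
  expect_length(sets, 9)
  # third set pairs subject 1's weights with subject 3's coefficients
  expect_identical(sets[[3]]$weights, subjects[[1]]$weights)
  expect_identical(sets[[3]]$coefficients, subjects[[3]]$coefficients)
  # brute-force double loop over (i, j)
  for (i in 1:3) for (j in 1:3) {
    s <- sets[[(i - 1) * 3 + j]]
    expect_identical(s$weights, subjects[[i]]$weights)
    expect_identical(s$coefficients, subjects[[j]]$coefficients)
  }
  expect_length(augment_sets(subjects[1]), 1)

  other <- generate_ground_truth(4, 8, 1, seed = 9)
  expect_error(augment_sets(list(subjects[[1]], other)),
               class = "choosyn_incompatible_sets")
  expect_error(augment_sets(list()), class = "choosyn_empty_input")
})

test_that("reconstructed envelopes equal the weight-row / coefficient product", {
  C <- rbind(sin(seq(0, pi, length.out = 2000))^2,
             cos(seq(0, pi, length.out = 2000))^2)
  truth <- manual_truth(matrix(c(0, 0, 1, 0, 0.5, 0.5), 3, 2, byrow = TRUE), C)
  expect_equal(reconstruct_envelope(truth, 1), rep(0, 2000))
  expect_equal(reconstruct_envelope(truth, 2), as.numeric(C[1, ]))
  # independent elementwise oracle
  oracle <- vapply(seq_len(2000),
                   function(t) 0.5 * C[1, t] + 0.5 * C[2, t], numeric(1))
  expect_equal(reconstruct_envelope(truth, 3), oracle)
  expect_error(reconstruct_envelope(truth, 4), class = "choosyn_domain")
})

test_that("the carrier model multiplies the envelope by unit-variance noise", {
  truth <- manual_truth(matrix(c(0.8, 0.3), 2, 1),
                        matrix(0.5, 1, 3000))
  rec <- synthesize_emg(truth, snr_db = NA, carrier_seed = 5, noise_seed = 6)
  carrier <- withr::with_seed(5, matrix(rnorm(3000 * 2), 3000, 2))
  E <- t(truth$weights %*% truth$coefficients)
  expect_equal(unname(rec$signal), E * carrier)
  # constant envelope 0.4: sd of signal / envelope ratio close to 1
  expect_equal(sd(rec$signal[, 1] / E[, 1]), 1, tolerance = 0.05)
  expect_identical(rec$events, c(1L, 1001L, 2001L))
})

test_that("additive noise has the standard deviation 10^(-SNR/20)", {
  # all-zero envelope: the signal is pure background noise
  truth <- manual_truth(matrix(0, 2, 1), matrix(1, 1, 75000))
  rec <- synthesize_emg(truth, snr_db = 15, carrier_seed = 1, noise_seed = 2)
  sigma <- 10^(-15 / 20)
  se <- sigma / sqrt(2 * length(rec$signal))
  expect_lt(abs(sd(rec$signal) - sigma), 3 * se)
})

test_that("requested SNR is realized empirically on constant envelopes", {
  # constant envelope of amplitude 1: the SNR definition's reference level
  truth <- manual_truth(matrix(1, 1, 1), matrix(1, 1, 100000))
  for (snr in c(30, 20, 15)) {
    clean <- synthesize_emg(truth, NA, carrier_seed = 3, noise_seed = 4)
    noisy <- synthesize_emg(truth, snr, carrier_seed = 3, noise_seed = 4)
    noise <- noisy$signal - clean$signal
    measured <- 20 * log10(sd(clean$signal) / sd(noise))
    expect_lt(abs(measured - snr), 0.5)
  }
})

test_that("noiseless envelope matrices have numerical rank at most true_n", {
  for (tn in c(3, 5)) {
    gt <- generate_ground_truth(tn, 10, 12, seed = 30 + tn)
    sv <- svd(gt$weights %*% gt$coefficients)$d
    expect_lt(sv[tn + 1] / sv[1], 1e-8)
  }
})

test_that("the default dataset grid yields 375 recordings", {
  ds <- build_simulated_dataset(dataset_config(n_cycles = 2L), seed = 1)
  expect_equal(nrow(ds$manifest), 375)
  expect_equal(length(ds$truths), 75)
  expect_equal(sort(unique(ds$manifest$true_n)), c(4L, 5L, 6L))
  counts <- table(ds$manifest$condition)
  expect_true(all(counts == 75))
})

test_that("reduced grids and manifest replay behave as contracted", {
  ds <- build_simulated_dataset(
    dataset_config(true_n_levels = 4, snr_db = NA, n_cycles = 2L), seed = 3)
  expect_equal(nrow(ds$manifest), 25)
  r1 <- realize_recording(ds, ds$manifest$id[7])
  ds2 <- build_simulated_dataset(
    dataset_config(true_n_levels = 4, snr_db = NA, n_cycles = 2L), seed = 3)
  r2 <- realize_recording(ds2, ds2$manifest$id[7])
  expect_identical(r1$signal, r2$signal)
  expect_error(dataset_config(snr_db = numeric()), class = "choosyn_domain")
})

test_that("recordings round-trip through the CSV/events text format", {
  gt <- generate_ground_truth(3, 4, 3, seed = 11)
  rec <- synthesize_emg(gt, 20, carrier_seed = 1, noise_seed = 2)
  sig_f <- withr::local_tempfile(fileext = ".csv")
  ev_f <- withr::local_tempfile(fileext = ".txt")
  write_emg_csv(rec, sig_f, ev_f)
  # events file is 0-based, one index per line
  expect_identical(as.integer(readLines(ev_f)), rec$events - 1L)
  back <- read_emg_csv(sig_f, ev_f)
  expect_equal(unname(back$signal), unname(rec$signal), tolerance = 1e-12)
  expect_identical(back$events, rec$events)
})
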