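# Shared fixtures, built in code at test time.

# exact low-rank subgroup envelopes straight from a ground-truth set
# (no carrier, no filtering): m x 10,000 blocks of W %*% C
true_envelope_subgroups <- function(true_n = 4, m = 12, n_cycles = 20,
                                    seed = 1) {
  gt <- generate_ground_truth(true_n, m, n_cycles, seed = seed)
  E <- gt$weights %*% gt$coefficients
  n_sub <- ncol(E) %/% 10000L
  subs <- lapply(seq_len(n_sub), function(g) {
    E[, ((g - 1L) * 10000L + 1L):(g * 10000L)]
  })
  structure(list(subgroups = subs, n_subgroups = n_sub),
            class = "subgroup_envelopes")
}

# small non-negative random matrix
rand_nonneg <- function(m, n, seed) {
  withr::with_seed(seed, matrix(runif(m * n), m, n))
}

# a ground-truth-like object with arbitrary weights/coefficients, for
# driving synthesize_emg with hand-built envelopes
manual_truth <- function(weights, coefficients, cycle_length = 1000L) {
  stopifnot(ncol(coefficients) %% cycle_length == 0)
  structure(list(weights = weights, coefficients = coefficients,
                 true_n = ncol(weights), cycle_length = cycle_length,
                 n_cycles = ncol(coefficients) %/% cycle_length,
                 seed = NA_integer_),
            class = "ground_truth")
}

# brute-force re-implementation of the step / local-minimum candidate
# rules, kept deliberately naive and independent of the package code
brute_candidates <- function(values, n_min = 2L) {
  d <- numeric(length(values) - 1)
  for (i in seq_along(d)) d[i] <- values[i + 1] - values[i]
  theta <- mean(abs(d))
  out <- data.frame(n = integer(), kind = character())
  for (i in seq_along(d)) {
    n <- n_min + i - 1L
    is_step <- d[i] > theta && (i == 1L || abs(d[i - 1]) <= theta)
    if (is_step) out <- rbind(out, data.frame(n = n, kind = "step"))
    if (i > 1L && -d[i - 1] > theta && d[i] > theta) {
      out <- rbind(out, data.frame(n = n, kind = "local_minimum"))
    }
  }
  out <- out[order(out$n), , drop = FALSE]
  if (nrow(out) > 2L) out <- out[(nrow(out) - 1L):nrow(out), , drop = FALSE]
  out
}
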