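#' Settings for the ground-truth synergy generator
#'
#' Parameters controlling how synthetic weight vectors and activation
#' coefficients are drawn. Activations are sums of Gaussian bumps locked to
#' the gait cycle (1000 samples per cycle); weights are sparse-ish
#' non-negative loadings in which each synergy is dominated by its own
#' subset of muscles.
#'
#' @param distinctness_cap Maximum allowed pairwise cosine similarity
#'   between distinct weight columns (default 0.6). Draws violating the cap
#'   are retried.
#' @param activation_distinctness_cap Maximum allowed pairwise cosine
#'   similarity between distinct activation rows (default 0.2): synergies
#'   must drive recognizably distinct phases of the cycle. Draws violating
#'   the cap are retried.
#' @param bump_sigma_range Range for the standard deviation of the
#'   Gaussian activation bursts, as a fraction of the inter-burst interval
#'   (cycle / true_n); the default c(0.08, 0.18) gives bursts roughly
#'   30--70% of their phase wide.
#' @param jitter_sd Cycle-to-cycle jitter of bump centres, as a fraction of
#'   the cycle (default 0.02).
#' @param amp_jitter_sd Cycle-to-cycle multiplicative amplitude jitter
#'   (default 0.05).
#' @param dominant_range,background_range Ranges for the dominant and
#'   background muscle loadings of each synergy.
#' @param second_bump_prob Probability that a synergy carries a secondary,
#'   smaller activation burst (default 0.15).
#' @param max_retries Redraws allowed before the distinctness cap is
#'   declared unsatisfiable.
#' @return A list of class `gt_config`.
#' @export
gt_config <- function(distinctness_cap = 0.6,
                      activation_distinctness_cap = 0.2,
                      bump_sigma_range = c(0.08, 0.18),
                      jitter_sd = 0.02,
                      amp_jitter_sd = 0.05,
                      dominant_range = c(0.6, 1),
                      background_range = c(0.01, 0.08),
                      second_bump_prob = 0.15,
                      max_retries = 60L) {
  structure(list(distinctness_cap = distinctness_cap,
                 activation_distinctness_cap = activation_distinctness_cap,
                 bump_sigma_range = bump_sigma_range,
                 jitter_sd = jitter_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 dominant_range = dominant_range,
                 background_range = background_range,
                 second_bump_prob = second_bump_prob,
                 max_retries = as.integer(max_retries)),
            class = "gt_config")
}

# maximum pairwise cosine between columns of W
max_pairwise_cosine <- function(W) {
  Wn <- apply(W, 2, function(w) w / sqrt(sum(w^2)))
  G <- crossprod(Wn)
  max(G[upper.tri(G)])
}

draw_weights <- function(true_n, m, config) {
  owner <- sample(rep(seq_len(true_n), length.out = m))
  W <- matrix(runif(m * true_n, config$background_range[1],
                    config$background_range[2]), m, true_n)
  for (s in seq_len(true_n)) {
    mus <- which(owner == s)
    W[mus, s] <- runif(length(mus), config$dominant_range[1],
                       config$dominant_range[2])
  }
  W
}

# one synergy's activation over all cycles: 1-2 wrapped Gaussian bumps per
# cycle with small centre/amplitude jitter. Main-burst centres are
# stratified across synergies so the bursts tile the gait cycle, the way
# walking synergies sequence weight acceptance, push-off, swing, ...
draw_coefficient_row <- function(s, true_n, n_cycles, cycle_length, config) {
  t_grid <- (seq_len(cycle_length) - 0.5) / cycle_length
  n_bumps <- if (runif(1) < config$second_bump_prob) 2L else 1L
  centre <- c((s - 1 + runif(1, 0.25, 0.75)) / true_n, runif(1))[seq_len(n_bumps)]
  # burst width scales with the inter-burst interval: the more synergies
  # tile the cycle, the narrower each phase
  sigma <- runif(n_bumps, config$bump_sigma_range[1],
                 config$bump_sigma_range[2]) / true_n
  amp <- c(runif(1, 0.7, 1), runif(1, 0.2, 0.4))[seq_len(n_bumps)]
  out <- numeric(n_cycles * cycle_length)
  for (cyc in seq_len(n_cycles)) {
    v <- numeric(cycle_length)
    for (b in seq_len(n_bumps)) {
      c_b <- centre[b] + rnorm(1, 0, config$jitter_sd)
      a_b <- max(amp[b] * (1 + rnorm(1, 0, config$amp_jitter_sd)), 0)
      d <- abs(t_grid - (c_b %% 1))
      d <- pmin(d, 1 - d)                 # wrap around the cycle boundary
      v <- v + a_b * exp(-d^2 / (2 * sigma[b]^2))
    }
    out[((cyc - 1) * cycle_length + 1):(cyc * cycle_length)] <- v
  }
  out
}

#' Generate a ground-truth synergy set
#'
#' Draws a set of non-negative weight vectors `W` (muscles x synergies) and
#' cycle-locked activation coefficients `C` (synergies x samples, 1000
#' samples per gait cycle), emulating the low-rank, non-negative,
#' cycle-locked structure of muscle synergies during walking. Per-synergy
#' signal power is balanced, and the set is scaled so that the strongest
#' muscle's noiseless envelope `W %*% C` peaks at 1 (every muscle peaks
#' near 1), emulating amplitude-normalised envelopes.
#'
#' @param true_n Number of synergies, between 2 and 8.
#' @param m Number of muscles (`true_n <= m`).
#' @param n_cycles Number of gait cycles.
#' @param seed Integer seed; identical seeds give identical sets.
#' @param config A [gt_config()].
#' @return An object of class `ground_truth` with elements `weights`
#'   (m x true_n), `coefficients` (true_n x 1000*n_cycles), `true_n`,
#'   `cycle_length`, `n_cycles`, `seed`.
#' @export
#' @examples
#' gt <- generate_ground_truth(true_n = 4, m = 12, n_cycles = 2, seed = 7)
#' dim(gt$weights)
generate_ground_truth <- function(true_n, m, n_cycles, seed,
                                  config = gt_config()) {
  true_n <- as.integer(true_n)
  m <- as.integer(m)
  n_cycles <- as.integer(n_cycles)
  if (true_n < 2L || true_n > 8L) {
    abort("`true_n` must be between 2 and 8", class = "choosyn_domain")
  }
  if (true_n > m) {
    abort("number of synergies must not exceed the number of muscles",
          class = "choosyn_order_exceeds_muscles")
  }
  if (n_cycles < 1L) abort("`n_cycles` must be >= 1", class = "choosyn_domain")
  cycle_length <- 1000L

  withr::with_seed(seed, {
    ok <- FALSE
    for (try in seq_len(config$max_retries)) {
      W <- draw_weights(true_n, m, config)
      C <- t(vapply(seq_len(true_n),
                    function(s) draw_coefficient_row(s, true_n, n_cycles,
                                                     cycle_length, config),
                    numeric(n_cycles * cycle_length)))
      # balance per-synergy signal power: each rank-1 contribution
      # outer(w_s, c_s) gets the same Frobenius norm, as gait synergies
      # each drive a distinct phase of the cycle with comparable power.
      # Norms are equalized within each factor separately so the balance
      # survives crossing one subject's weights with another's
      # coefficients during augmentation; the scalings leave the
      # weight-distinctness geometry untouched.
      cn <- sqrt(rowSums(C^2))
      C <- C * (mean(cn) / cn)
      wn <- sqrt(colSums(W^2))
      W <- sweep(W, 2, mean(wn) / wn, "*")
      # one global scale: the strongest muscle envelope peaks at 1 (every
      # muscle peaks near 1, since each muscle has a dominant synergy),
      # emulating amplitude-normalised envelopes
      W <- W / max(W %*% C)
      if (max_pairwise_cosine(W) <= config$distinctness_cap &&
          max_pairwise_cosine(t(C)) <= config$activation_distinctness_cap) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not satisfy the weight distinctness cap; relax `gt_config()`",
            class = "choosyn_generation_failure")
    }
    structure(list(weights = W, coefficients = C, true_n = true_n,
                   cycle_length = cycle_length, n_cycles = n_cycles,
                   seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$weights), " muscles, ", x$true_n,
      " synergies, ", x$n_cycles, " cycles (", x$cycle_length,
      " samples/cycle)\n", sep = "")
  invisible(x)
}

#' Augment ground-truth sets by crossing weights with coefficients
#'
#' Given k sets sharing the same number of synergies and muscles, forms all
#' k^2 combinations pairing the weights of set i with the coefficients of
#' set j (i outer, j inner), the data-augmentation scheme used to multiply
#' simulated subjects.
#'
#' @param subjects A list of `ground_truth` objects with equal `true_n` and
#'   muscle count.
#' @return A list of k^2 `ground_truth` objects; element (i-1)*k + j has the
#'   weights of subject i and the coefficients of subject j.
#' @export
augment_sets <- function(subjects) {
  if (length(subjects) == 0) {
    abort("empty list of subjects", class = "choosyn_empty_input")
  }
  tn <- vapply(subjects, function(s) s$true_n, integer(1))
  mm <- vapply(subjects, function(s) nrow(s$weights), integer(1))
  if (length(unique(tn)) != 1L || length(unique(mm)) != 1L) {
    abort("all subjects must share `true_n` and the number of muscles",
          class = "choosyn_incompatible_sets")
  }
  k <- length(subjects)
  out <- vector("list", k * k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      s <- subjects[[j]]
      s$weights <- subjects[[i]]$weights
      s$n_cycles <- subjects[[j]]$n_cycles
      s$w_subject <- i
      s$c_subject <- j
      out[[(i - 1L) * k + j]] <- s
    }
  }
  out
}

#' Reconstruct one muscle's noiseless envelope
#'
#' The envelope of muscle `muscle` is the product of its weight row with the
#' coefficient matrix.
#'
#' @param truth A `ground_truth` object.
#' @param muscle Muscle index (1-based).
#' @return A non-negative numeric vector of length `ncol(truth$coefficients)`.
#' @export
reconstruct_envelope <- function(truth, muscle) {
  m <- nrow(truth$weights)
  if (muscle < 1 || muscle > m) {
    abort("muscle index out of range", class = "choosyn_domain")
  }
  as.numeric(truth$weights[muscle, , drop = FALSE] %*% truth$coefficients)
}
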