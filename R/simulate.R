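#' Synthesize a pseudo-real sEMG recording from ground truth
#'
#' Each muscle's noiseless envelope (weights row times coefficients) is
#' multiplied sample-by-sample by a zero-mean, unit-variance Gaussian
#' carrier; unless the no-additive-noise condition is requested, zero-mean
#' Gaussian background noise with standard deviation
#' `10^(-snr_db / 20)` is added. Carrier and noise streams are independent
#' and reproducible from their seeds.
#'
#' @param truth A `ground_truth` object.
#' @param snr_db Signal-to-noise ratio in dB, or `NA` for the
#'   no-additive-noise condition.
#' @param carrier_seed,noise_seed Integer seeds for the carrier and noise
#'   streams.
#' @return An object of class `simulated_recording`: `signal` (samples x
#'   muscles), `events` (1-based cycle-start sample indices, spacing =
#'   cycle length), `snr_db`, `truth`, `carrier_seed`, `noise_seed`.
#' @export
#' @examples
#' gt <- generate_ground_truth(4, 12, 2, seed = 1)
#' rec <- synthesize_emg(gt, snr_db = 20, carrier_seed = 1, noise_seed = 2)
#' dim(rec$signal)
synthesize_emg <- function(truth, snr_db = NA_real_, carrier_seed, noise_seed) {
  if (!is.na(snr_db) && !is.finite(snr_db)) {
    abort("`snr_db` must be finite, or NA for the no-additive-noise condition",
          class = "choosyn_domain")
  }
  E <- truth$weights %*% truth$coefficients     # m x T
  T_len <- ncol(E)
  m <- nrow(E)
  carrier <- withr::with_seed(carrier_seed,
                              matrix(rnorm(T_len * m), T_len, m))
  S <- t(E) * carrier
  if (!is.na(snr_db)) {
    sigma_n <- 10^(-snr_db / 20)
    S <- S + withr::with_seed(noise_seed,
                              matrix(rnorm(T_len * m, sd = sigma_n), T_len, m))
  }
  colnames(S) <- sprintf("M%02d", seq_len(m))
  events <- seq(1L, by = truth$cycle_length,
                length.out = truth$n_cycles)
  structure(list(signal = S, events = as.integer(events), snr_db = snr_db,
                 truth = truth,
                 carrier_seed = as.integer(carrier_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cond <- if (is.na(x$snr_db)) "no additive noise" else
    sprintf("SNR = %g dB", x$snr_db)
  cat("<simulated_recording> ", nrow(x$signal), " samples x ",
      ncol(x$signal), " muscles, ", length(x$events), " cycles, ",
      cond, "\n", sep = "")
  invisible(x)
}

condition_label <- function(snr_db) {
  ifelse(is.na(snr_db), "no-noise", sprintf("%g dB", snr_db))
}

#' Configuration of a simulated benchmark dataset
#'
#' The default grid mirrors the simulation study design: three true synergy
#' numbers (4, 5, 6) with 5 subjects each, augmented to 25 sets per level,
#' each synthesized under five noise conditions (no additive noise and SNR
#' 30, 25, 20, 15 dB), for 375 recordings in total.
#'
#' @param true_n_levels True synergy numbers to simulate.
#' @param subjects_per_level Ground-truth subjects per level (augmented to
#'   the square of this number of sets).
#' @param snr_db Noise conditions; `NA` is the no-additive-noise condition.
#' @param n_cycles Gait cycles simulated per recording. Note that k+1
#'   heel-strike events delimit k complete cycles, so a walk meant to
#'   provide `k` analysable cycles should simulate `k + 1`.
#' @param m Number of muscles.
#' @param gt Generator settings, a [gt_config()].
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(true_n_levels = c(4L, 5L, 6L),
                           subjects_per_level = 5L,
                           snr_db = c(NA, 30, 25, 20, 15),
                           n_cycles = 151L,
                           m = 12L,
                           gt = gt_config()) {
  if (length(snr_db) == 0) {
    abort("at least one noise condition is required", class = "choosyn_domain")
  }
  structure(list(true_n_levels = as.integer(true_n_levels),
                 subjects_per_level = as.integer(subjects_per_level),
                 snr_db = as.numeric(snr_db),
                 n_cycles = as.integer(n_cycles),
                 m = as.integer(m),
                 gt = gt),
            class = "dataset_config")
}

#' Desk-scale dataset configuration
#'
#' A reduced preset for interactive runs: 31 simulated cycles per recording
#' (30 analysable cycles, hence 3 ten-cycle subgroups). Pair it with
#' `reruns = 3` in [run_benchmark()].
#'
#' @param ... Overrides passed to [dataset_config()].
#' @export
dataset_config_desk <- function(...) {
  dataset_config(n_cycles = 31L, ...)
}

#' Build a simulated dataset (lazily)
#'
#' Generates the ground-truth subjects for every level, augments them by
#' crossing weights with coefficients, and lays out one manifest row per
#' (set, noise condition) with all derived seeds. Signals are synthesized on
#' demand by [realize_recording()] so that large grids stay cheap to build.
#'
#' @param config A [dataset_config()].
#' @param seed Master seed; the whole dataset is a pure function of
#'   (config, seed).
#' @return An object of class `synergy_dataset` with `manifest` (a tibble,
#'   one row per recording), `truths` (augmented ground-truth sets, named by
#'   set id), `config` and `seed`.
#' @export
#' @examples
#' ds <- build_simulated_dataset(dataset_config_desk(snr_db = NA), seed = 1)
#' nrow(ds$manifest) # 75
build_simulated_dataset <- function(config = dataset_config(), seed = 1L) {
  seed <- as.integer(seed)
  truths <- list()
  rows <- list()
  for (lv in seq_along(config$true_n_levels)) {
    tn <- config$true_n_levels[lv]
    k <- config$subjects_per_level
    subjects <- lapply(seq_len(k), function(s) {
      generate_ground_truth(tn, config$m, config$n_cycles,
                            seed = seed + 1000L * lv + s,
                            config = config$gt)
    })
    sets <- augment_sets(subjects)
    for (idx in seq_along(sets)) {
      set_id <- sprintf("n%d_W%dC%d", tn, sets[[idx]]$w_subject,
                        sets[[idx]]$c_subject)
      truths[[set_id]] <- sets[[idx]]
      for (cond in seq_along(config$snr_db)) {
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%s_%s", set_id,
                       gsub(" ", "", condition_label(config$snr_db[cond]))),
          set_id = set_id,
          true_n = tn,
          w_subject = sets[[idx]]$w_subject,
          c_subject = sets[[idx]]$c_subject,
          condition = condition_label(config$snr_db[cond]),
          snr_db = config$snr_db[cond],
          n_cycles = config$n_cycles,
          m = config$m,
          carrier_seed = seed + 20000L * lv + 100L * idx + 2L * cond,
          noise_seed = seed + 20000L * lv + 100L * idx + 2L * cond + 1L)
      }
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), truths = truths,
                 config = config, seed = seed),
            class = "synergy_dataset")
}

#' @export
print.synergy_dataset <- function(x, ...) {
  cat("<synergy_dataset> ", nrow(x$manifest), " recordings (",
      length(x$truths), " ground-truth sets x ",
      length(x$config$snr_db), " conditions), master seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Materialize one recording of a simulated dataset
#'
#' @param dataset A `synergy_dataset`.
#' @param id A manifest `id`, or an integer row index into the manifest.
#' @return A `simulated_recording`.
#' @export
realize_recording <- function(dataset, id) {
  man <- dataset$manifest
  row <- if (is.numeric(id)) man[id, ] else man[man$id == id, ]
  if (nrow(row) != 1L) abort("unknown recording id", class = "choosyn_domain")
  synthesize_emg(dataset$truths[[row$set_id]], snr_db = row$snr_db,
                 carrier_seed = row$carrier_seed, noise_seed = row$noise_seed)
}

#' Write / read a recording as plain text
#'
#' The signal is written as a CSV with a header of muscle names (rows =
#' samples, columns = muscles); events as one 0-based cycle-start sample
#' index per line.
#'
#' @param rec A `simulated_recording` or `emg_recording`.
#' @param signal_path,events_path Output file paths.
#' @return `write_emg_csv` returns the paths invisibly; `read_emg_csv`
#'   returns an [emg_recording()].
#' @export
write_emg_csv <- function(rec, signal_path, events_path) {
  utils::write.csv(as.data.frame(rec$signal), signal_path, row.names = FALSE)
  writeLines(as.character(rec$events - 1L), events_path)
  invisible(c(signal = signal_path, events = events_path))
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(signal_path, events_path) {
  sig <- as.matrix(utils::read.csv(signal_path, check.names = FALSE))
  ev <- as.integer(readLines(events_path)) + 1L
  emg_recording(sig, ev, muscle_names = colnames(sig))
}
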