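# End-to-end benchmark harness: simulate -> preprocess -> factorize -> sort
# -> select with every criterion, scored against the known ground truth.

#' Mean error and RMSE of selected synergy numbers
#'
#' `mean_error` is the mean of (selected - true): its sign says whether a
#' criterion errs by defect or excess. `rms_error` is the root mean square
#' of the same differences. Pairs where the selection failed (`NA`) are
#' excluded.
#'
#' @param selected Integer vector of selected orders (`NA` = failed trial).
#' @param truth Integer vector of true orders, same length.
#' @return A scalar, in synergies.
#' @export
#' @examples
#' mean_error(c(4, 4, 6), c(4, 5, 6)) # -1/3
#' rms_error(c(4, 4, 6), c(4, 5, 6))  # 0.577
mean_error <- function(selected, truth) {
  d <- selection_diffs(selected, truth)
  mean(d)
}

#' @rdname mean_error
#' @export
rms_error <- function(selected, truth) {
  d <- selection_diffs(selected, truth)
  sqrt(mean(d^2))
}

selection_diffs <- function(selected, truth) {
  if (length(selected) != length(truth) || length(selected) == 0) {
    abort("`selected` and `truth` must have equal, positive length",
          class = "choosyn_domain")
  }
  ok <- !is.na(selected)
  if (!any(ok)) {
    abort("no successful selections to score", class = "choosyn_undefined_metric")
  }
  selected[ok] - truth[ok]
}

#' Apply every selection criterion to one processed walk
#'
#' @param curve A `vaf_curve` for the walk.
#' @param profile A `choosyn_profile` (required only when "choosyn" is
#'   among the methods).
#' @param methods Criteria to apply, a subset of
#'   `c("tvaf90", "tvaf95", "evaf", "pvaf", "choosyn")`.
#' @param tvaf_thresholds Named thresholds for the T-VAF variants.
#' @param pvaf_mse P-VAF line-fit mean-square-error threshold.
#' @return A tibble with columns `method`, `selected` (NA on a failed
#'   selection) and `note`.
#' @export
select_all_methods <- function(curve, profile = NULL,
                               methods = c("tvaf90", "tvaf95", "evaf",
                                           "pvaf", "choosyn"),
                               tvaf_thresholds = c(tvaf90 = 90, tvaf95 = 95),
                               pvaf_mse = 1e-2) {
  one <- function(method) {
    res <- tryCatch({
      n <- switch(method,
        tvaf90 = select_tvaf(curve, tvaf_thresholds[["tvaf90"]]),
        tvaf95 = select_tvaf(curve, tvaf_thresholds[["tvaf95"]]),
        evaf = select_evaf(curve),
        pvaf = select_pvaf(curve, pvaf_mse),
        choosyn = select_n_choosyn(profile)$n,
        abort(paste("unknown method", method), class = "choosyn_domain"))
      list(n = n, note = NA_character_)
    }, choosyn_no_selection = function(e) list(n = NA_integer_, note = conditionMessage(e)),
       choosyn_degenerate_elbow = function(e) list(n = NA_integer_, note = conditionMessage(e)))
    tibble(method = method, selected = as.integer(res$n), note = res$note)
  }
  dplyr::bind_rows(lapply(methods, one))
}

#' Run the simulation benchmark
#'
#' For every recording of the dataset: synthesize the signal, preprocess it
#' into 10-cycle subgroup envelopes, factorize at every order, sort
#' synergies across subgroups, and select the number of synergies with each
#' requested criterion; aggregate per method and noise condition.
#'
#' A failed selection (e.g. a VAF curve never crossing the threshold)
#' counts as incorrect in the fraction correct but is excluded from ME and
#' RMSE, and reported in `n_failed`. An error in any pipeline stage flags
#' the whole set as failed for every method and the run continues.
#'
#' @param dataset A `synergy_dataset` from [build_simulated_dataset()].
#' @param methods Criteria to score (see [select_all_methods()]).
#' @param n_range Candidate orders (default 1:8).
#' @param reruns NMF restarts per fit (5 in the full protocol, 3 in the
#'   desk-scale preset).
#' @param seed Master seed for extraction and sorting.
#' @param fs Nominal sampling rate for the envelope filters.
#' @param verbose Print one line per recording.
#' @return An object of class `synergy_benchmark`: `trials` (tibble, one
#'   row per recording x method), `report` (tibble per method x
#'   condition: fraction_correct, correct, total, me, rmse, n_failed),
#'   `seed`, `methods`, `reruns`, `scaled_down` flag.
#' @export
run_benchmark <- function(dataset,
                          methods = c("tvaf90", "tvaf95", "evaf", "pvaf",
                                      "choosyn"),
                          n_range = 1:8, reruns = 5L, seed = 1L, fs = 1000,
                          verbose = FALSE) {
  man <- dataset$manifest
  need_profile <- "choosyn" %in% methods
  trial_rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    seed_i <- seed + 17L * i
    res <- tryCatch({
      rec <- realize_recording(dataset, i)
      subs <- preprocess_emg(rec, fs = fs)
      extr <- extract_synergies(subs, n_range = n_range, seed = seed_i,
                                reruns = reruns)
      curve <- vaf_curve(extr)
      # a ChoOSyn stage failure must not take the VAF methods down with it
      profile <- if (need_profile) {
        tryCatch(build_profile(build_synergy_stack(extr, seed = seed_i)),
                 error = function(e) e)
      } else NULL
      if (inherits(profile, "error")) {
        out <- select_all_methods(curve, NULL,
                                  methods = setdiff(methods, "choosyn"))
        dplyr::bind_rows(out, tibble(method = "choosyn",
                                     selected = NA_integer_,
                                     note = conditionMessage(profile)))
      } else {
        select_all_methods(curve, profile, methods = methods)
      }
    }, error = function(e) {
      tibble(method = methods, selected = NA_integer_,
             note = conditionMessage(e))
    })
    res$id <- row$id
    res$set_id <- row$set_id
    res$condition <- row$condition
    res$true_n <- row$true_n
    trial_rows[[i]] <- res
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s", i, nrow(man), row$id,
                      paste(res$method, res$selected, collapse = ", ")))
    }
  }
  trials <- dplyr::relocate(dplyr::bind_rows(trial_rows), "id", "set_id",
                            "condition", "true_n")
  report <- benchmark_report(trials)
  structure(list(trials = trials, report = report, seed = as.integer(seed),
                 methods = methods, reruns = as.integer(reruns),
                 scaled_down = dataset$config$n_cycles < 100L),
            class = "synergy_benchmark")
}

# aggregate per-trial selections into the per-method x condition report
benchmark_report <- function(trials) {
  grp <- dplyr::group_by(trials, .data$method, .data$condition)
  dplyr::summarise(grp,
    total = dplyr::n(),
    n_failed = sum(is.na(.data$selected)),
    correct = sum(!is.na(.data$selected) & .data$selected == .data$true_n),
    fraction_correct = .data$correct / .data$total,
    me = if (all(is.na(.data$selected))) NA_real_ else
      mean_error(.data$selected, .data$true_n),
    rmse = if (all(is.na(.data$selected))) NA_real_ else
      rms_error(.data$selected, .data$true_n),
    .groups = "drop")
}

#' @export
print.synergy_benchmark <- function(x, ...) {
  cat("<synergy_benchmark> ", length(unique(x$trials$id)), " recordings, ",
      "methods: ", paste(x$methods, collapse = ", "),
      if (x$scaled_down) " (desk-scale)", "\n", sep = "")
  print(x$report)
  invisible(x)
}
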