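# broom-style accessors for the package's result objects.

#' Tidy a ChoOSyn profile
#'
#' @param x A `choosyn_profile`.
#' @param ... Unused.
#' @return A tibble with one row per (order, parameter): columns `n`,
#'   `parameter`, `value`.
#' @export
tidy.choosyn_profile <- function(x, ...) {
  tidyr::pivot_longer(x$profile, -"n", names_to = "parameter",
                      values_to = "value")
}

#' @rdname tidy.choosyn_profile
#' @export
glance.choosyn_profile <- function(x, ...) {
  sel <- select_n_choosyn(x)
  glance(sel)
}

#' Tidy / glance a ChoOSyn selection
#'
#' @param x A `choosyn_selection`.
#' @param ... Unused.
#' @return `tidy()`: the candidate orders with their kind and side;
#'   `glance()`: a one-row tibble with `n`, `rule`, `fallback`.
#' @export
tidy.choosyn_selection <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$candidates_w, side = "weights"),
    dplyr::mutate(x$candidates_c, side = "coefficients"))
}

#' @rdname tidy.choosyn_selection
#' @export
glance.choosyn_selection <- function(x, ...) {
  tibble(n = x$n, rule = x$rule, fallback = x$fallback)
}

#' Tidy a VAF curve
#'
#' @param x A `vaf_curve`.
#' @param ... Unused.
#' @return The underlying tibble (`n`, `vaf`).
#' @export
tidy.vaf_curve <- function(x, ...) x$curve

#' Tidy an NMF fit
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per (muscle, synergy) with the weight;
#'   `glance()`: residual, restarts, iterations.
#' @export
tidy.nmf_fit <- function(x, ...) {
  W <- x$W
  tibble(muscle = rep(seq_len(nrow(W)), ncol(W)),
         synergy = rep(seq_len(ncol(W)), each = nrow(W)),
         weight = as.vector(W))
}

#' @rdname tidy.nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(order_n = x$order_n, residual = x$residual,
         reruns = length(x$rerun_errors), iterations = x$iterations)
}

#' Tidy / glance a benchmark
#'
#' @param x A `synergy_benchmark`.
#' @param ... Unused.
#' @return `tidy()`: the per-trial tibble; `glance()`: the aggregated
#'   per-method x condition report.
#' @export
tidy.synergy_benchmark <- function(x, ...) x$trials

#' @rdname tidy.synergy_benchmark
#' @export
glance.synergy_benchmark <- function(x, ...) x$report
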