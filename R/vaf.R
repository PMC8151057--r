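# VAF-based baseline criteria for the number of synergies: threshold,
# elbow (maximum curvature) and plateau (straight-line fit).

#' VAF curve across candidate orders
#'
#' The VAF of each (subgroup, order) fit is averaged across subgroups,
#' giving one reconstruction-quality value per candidate number of
#' synergies.
#'
#' @param extraction A `synergy_extraction` (or `synergy_stack`).
#' @return An object of class `vaf_curve` wrapping a tibble with columns
#'   `n` and `vaf` (percent).
#' @export
vaf_curve <- function(extraction) {
  tab <- dplyr::summarise(dplyr::group_by(extraction$vaf, .data$n),
                          vaf = mean(.data$vaf), .groups = "drop")
  tab <- dplyr::arrange(tab, .data$n)
  if (any(diff(tab$vaf) < -1e-3)) {
    warn("VAF curve is not non-decreasing beyond stochastic tolerance")
  }
  structure(list(curve = tab), class = "vaf_curve")
}

#' @export
print.vaf_curve <- function(x, ...) {
  cat("<vaf_curve>\n")
  print(x$curve)
  invisible(x)
}

as_vaf_tab <- function(curve) {
  if (inherits(curve, "vaf_curve")) return(curve$curve)
  if (is.data.frame(curve)) return(curve)
  tibble(n = seq_along(curve), vaf = as.numeric(curve))
}

#' Threshold-VAF selection
#'
#' The smallest order whose VAF meets or exceeds the threshold (commonly
#' 90% or 95%).
#'
#' @param curve A `vaf_curve`, a data frame with columns n/vaf, or a plain
#'   numeric vector of VAF values at n = 1, 2, ....
#' @param threshold Threshold in percent, in (0, 100).
#' @return The selected order (integer).
#' @export
select_tvaf <- function(curve, threshold = 90) {
  if (threshold <= 0 || threshold >= 100) {
    abort("`threshold` must be in (0, 100)", class = "choosyn_domain")
  }
  tab <- as_vaf_tab(curve)
  hit <- tab$n[tab$vaf >= threshold]
  if (length(hit) == 0) {
    abort("no order reaches the VAF threshold", class = "choosyn_no_selection")
  }
  as.integer(min(hit))
}

#' Elbow-VAF selection
#'
#' The interior order at maximum perpendicular distance from the chord
#' joining the first and last points of the VAF curve — the point of
#' highest curvature of the saturating curve. Ties go to the smaller
#' order; a perfectly linear curve has no elbow.
#'
#' @inheritParams select_tvaf
#' @return The selected order (integer).
#' @export
select_evaf <- function(curve) {
  tab <- as_vaf_tab(curve)
  if (nrow(tab) < 3L) abort("need at least 3 points", class = "choosyn_domain")
  x <- tab$n
  y <- tab$vaf
  k <- nrow(tab)
  dx <- x[k] - x[1]
  dy <- y[k] - y[1]
  len <- sqrt(dx^2 + dy^2)
  dist <- abs(dy * (x - x[1]) - dx * (y - y[1])) / len
  dist[c(1, k)] <- 0
  if (max(dist) <= 1e-9 * max(1, abs(diff(range(y))))) {
    abort("VAF curve is linear; elbow undefined",
          class = "choosyn_degenerate_elbow")
  }
  as.integer(x[which.max(dist)])
}

#' Plateau-VAF selection
#'
#' For each order n (leaving at least three points), an ordinary
#' least-squares line is fitted through the tail `{(k, VAF(k)) : k >= n}`
#' on the percent scale; the first n whose fit mean-square error falls
#' below `mse_threshold` (default 1e-2) marks the start of the plateau.
#'
#' @inheritParams select_tvaf
#' @param mse_threshold Mean-square-error threshold on the percent scale.
#' @return The selected order (integer).
#' @export
select_pvaf <- function(curve, mse_threshold = 1e-2) {
  tab <- as_vaf_tab(curve)
  if (nrow(tab) < 3L) abort("need at least 3 points", class = "choosyn_domain")
  k <- nrow(tab)
  for (i in seq_len(k - 2L)) {
    xs <- tab$n[i:k]
    ys <- tab$vaf[i:k]
    fit <- lm(ys ~ xs)
    mse <- mean(resid(fit)^2)
    if (mse < mse_threshold) return(as.integer(tab$n[i]))
  }
  abort("VAF curve never reaches a plateau at this threshold",
        class = "choosyn_no_selection")
}
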