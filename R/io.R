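# JSON / CSV reports.

#' Write a per-walk selection report as JSON
#'
#' Emits the VAF curve, the ChoOSyn per-order parameter table with its
#' candidate sets and chosen order, and each requested criterion's
#' selection.
#'
#' @param selections A tibble from [select_all_methods()].
#' @param path Output path.
#' @param curve Optional `vaf_curve` to embed.
#' @param profile Optional `choosyn_profile` to embed (with its selection
#'   diagnostics).
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selections, path, curve = NULL,
                                   profile = NULL) {
  out <- list(selections = selections)
  if (!is.null(curve)) out$vaf_curve <- curve$curve
  if (!is.null(profile)) {
    sel <- select_n_choosyn(profile)
    out$choosyn <- list(profile = profile$profile,
                        candidates = tidy(sel),
                        n = sel$n, rule = sel$rule, fallback = sel$fallback)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a benchmark report
#'
#' The aggregate report goes to JSON (with provenance: master seed,
#' restarts, methods, scale flag); the per-trial table to CSV.
#'
#' @param bench A `synergy_benchmark`.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
write_benchmark_report <- function(bench, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(report = bench$report,
           provenance = list(seed = bench$seed, reruns = bench$reruns,
                             methods = bench$methods,
                             scaled_down = bench$scaled_down)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(bench$trials, csv_path, row.names = FALSE)
  }
  invisible(c(json = json_path, csv = csv_path))
}

#' Render a benchmark report as a plain-text table
#'
#' One block per metric (fraction correct, ME, RMSE), conditions as rows
#' and methods as columns.
#'
#' @param bench A `synergy_benchmark`.
#' @return A character vector of lines, invisibly; printed as a side
#'   effect.
#' @export
format_benchmark_table <- function(bench) {
  rp <- bench$report
  blocks <- list(
    `Fraction correct` = sprintf("%d/%d", rp$correct, rp$total),
    ME = sprintf("%.2f", rp$me),
    RMSE = sprintf("%.2f", rp$rmse))
  lines <- character()
  for (b in names(blocks)) {
    rp$val <- blocks[[b]]
    wide <- tidyr::pivot_wider(rp[, c("condition", "method", "val")],
                               names_from = "method", values_from = "val")
    lines <- c(lines, b, utils::capture.output(print(as.data.frame(wide),
                                                     row.names = FALSE)), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
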