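#' Curated reference tables from a published systematic review
#'
#' Machine-readable transcriptions of the summary tables of a published
#' systematic review of rare-disease severity scales, shipped with the package
#' for benchmarking and regression tests:
#'
#' * `scales_single` — the ten rare diseases with exactly one disease-specific
#'   severity scale, with the scale name and indicator count.
#' * `scales_multi` — the twelve diseases with more than one scale: first scale
#'   (year, size) and composite bookkeeping `[total indicators, duplicates
#'   excluded]`.
#' * `neutrality_single` — per disease, the number of studies and the most and
#'   least Neutral study as `N (Se, Sp)` at 2 decimals.
#' * `neutrality_multi` — per disease, mean `N (Se, Sp)` of the studies scored
#'   against the first scale and against the composite, at 3 decimals.
#' * `acceptability_single` — per disease, how many studies exceeded the 1.50
#'   acceptability threshold.
#'
#' Values are transcribed verbatim, including internally inconsistent rows;
#' those carry a non-empty `flag` column describing the inconsistency (e.g. a
#' composite total smaller than the first scale, or printed mean components
#' that do not add up to the printed mean). Flagged rows should be excluded
#' from identity checks.
#'
#' @param table One of `"scales_single"`, `"scales_multi"`,
#'   `"neutrality_single"`, `"neutrality_multi"`, `"acceptability_single"`, or
#'   `"all"` (default) for a named list of all five tibbles.
#' @return A tibble, or a named list of tibbles when `table = "all"`.
#' @export
reference_tables <- function(table = c("all", "scales_single", "scales_multi",
                                       "neutrality_single", "neutrality_multi",
                                       "acceptability_single")) {
  table <- match.arg(table)
  files <- c(
    scales_single = "single_dss_scales.csv",
    scales_multi = "multi_dss_scales.csv",
    neutrality_single = "single_dss_neutrality.csv",
    neutrality_multi = "multi_dss_neutrality.csv",
    acceptability_single = "single_dss_acceptability.csv"
  )
  read_one <- function(f) {
    path <- system.file("extdata", f, package = "neutrality", mustWork = TRUE)
    out <- readr::read_csv(path, show_col_types = FALSE,
                           progress = FALSE)
    if ("flag" %in% names(out)) {
      out$flag <- ifelse(is.na(out$flag), "", out$flag)
    }
    out
  }
  if (table == "all") return(lapply(files, read_one))
  read_one(files[[table]])
}
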