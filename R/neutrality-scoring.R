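#' Score a classification table
#'
#' Sensitivity is the proportion of overlapping indicators among the reference
#' scale items, `a / (a + c)`; specificity is the proportion of irrelevant
#' indicators among the items outside the scale, `d / (b + d)`. The Neutrality
#' score is their sum: 2 is perfect (100% sensitivity and 100% specificity) and
#' a score strictly greater than 1.50 is considered an acceptable match between
#' the study endpoints and the disease phenotype surrogate.
#'
#' `a + c = 0` (an empty reference) and `b + d = 0` (no observed information
#' outside the scale) are refused rather than given a conventional value:
#' specificity computed from no outside information would be fabricated.
#'
#' @param table A [classification_table()].
#' @param threshold Acceptability cut-off on the Neutrality score; the strict
#'   inequality `neutrality > threshold` is used. Default 1.5.
#' @return An object of class `neutrality_result` with fields `sensitivity`,
#'   `specificity`, `neutrality`, `acceptable` and the input `table`. Values are
#'   carried at full precision; round only for presentation.
#' @examples
#' neutrality_score(classification_table(a = 4, b = 0, c = 0, d = 6))
#' @export
neutrality_score <- function(table, threshold = 1.5) {
  stopifnot(inherits(table, "classification_table"))
  if (table$a + table$c == 0L) {
    abort2("Cannot score: reference scale is empty (a + c = 0).",
           "neutrality_empty_reference")
  }
  if (table$b + table$d == 0L) {
    abort2(paste0("Cannot score: no observed information outside the reference ",
                  "scale (b + d = 0)."),
           "neutrality_empty_complement")
  }
  se <- table$a / (table$a + table$c)
  sp <- table$d / (table$b + table$d)
  structure(
    list(sensitivity = se, specificity = sp, neutrality = se + sp,
         acceptable = (se + sp) > threshold, threshold = threshold,
         table = table),
    class = "neutrality_result"
  )
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("<neutrality_result> N = %.2f (Se %.2f, Sp %.2f)%s\n",
              x$neutrality, x$sensitivity, x$specificity,
              if (x$acceptable) " [acceptable]" else ""))
  invisible(x)
}

#' Build a composite scale from several severity scales
#'
#' The composite pools the indicators of the given scales (typically all scales
#' published after the first one for a disease), deduplicating by normalized
#' label. The number of duplicates excluded is recorded:
#' `length(indicators) = sum of member sizes - duplicates_excluded`.
#'
#' @param scales List of [severity_scale()] objects of one disease (member
#'   order follows publication year).
#' @param name Optional composite name.
#' @return An object of class `composite_scale` with fields `disease`, `name`,
#'   `member_scales`, `indicators`, `duplicates_excluded`.
#' @export
build_composite <- function(scales, name = NULL) {
  if (inherits(scales, "severity_scale")) scales <- list(scales)
  if (length(scales) == 0L) {
    abort2("A composite needs at least one member scale.",
           "neutrality_empty_composite")
  }
  stopifnot(all(vapply(scales, inherits, logical(1), "severity_scale")))
  diseases <- unique(vapply(scales, `[[`, character(1), "disease"))
  if (length(diseases) != 1L) {
    abort2(paste0("Composite members must share one disease; got: ",
                  paste(diseases, collapse = ", ")),
           "neutrality_cross_disease")
  }
  ord <- order(vapply(scales, `[[`, integer(1), "year"),
               vapply(scales, `[[`, character(1), "name"))
  scales <- scales[ord]
  sizes <- vapply(scales, function(s) length(s$indicators), integer(1))
  ind <- unique(unlist(lapply(scales, `[[`, "indicators"), use.names = FALSE))
  structure(
    list(disease = diseases,
         name = name %||% paste0("composite of ", length(scales), " scale(s)"),
         member_scales = vapply(scales, `[[`, character(1), "name"),
         indicators = ind,
         duplicates_excluded = sum(sizes) - length(ind)),
    class = "composite_scale"
  )
}

#' @export
print.composite_scale <- function(x, ...) {
  cat(sprintf("<composite_scale> %s - %s: [%d, %d] (indicators, duplicates excluded)\n",
              x$name, x$disease, length(x$indicators), x$duplicates_excluded))
  invisible(x)
}

#' Score one study against a reference scale
#'
#' Builds the observation universe for the disease (folding in the composite's
#' indicators via `fold_in` when scoring against the first scale, so that the
#' composite counts as observed information), classifies the study's endpoints
#' and computes the Neutrality score. Deterministic.
#'
#' @param study A [study_endpoints()] of the dataset's disease.
#' @param reference A [severity_scale()] or [build_composite()] result.
#' @param dataset The [disease_dataset()] supplying the other studies.
#' @param fold_in Optional scale/composite (or list) folded into the universe.
#' @param threshold Acceptability cut-off, see [neutrality_score()].
#' @return A `neutrality_result`.
#' @export
score_study <- function(study, reference, dataset, fold_in = NULL,
                        threshold = 1.5) {
  stopifnot(inherits(study, "study_endpoints"))
  if (!identical(study$disease, dataset$disease)) {
    abort2(sprintf("Study '%s' is for '%s' but the dataset is for '%s'.",
                   study$study_id, study$disease, dataset$disease),
           "neutrality_cross_disease")
  }
  universe <- observation_universe(dataset, reference, extra_scales = fold_in)
  neutrality_score(classify_endpoints(study, reference, universe),
                   threshold = threshold)
}

#' Score every study of a disease against a reference scale
#'
#' The tidy workhorse behind the per-disease tables: one row per study with the
#' classification cells, sensitivity, specificity, Neutrality and the
#' acceptability flag.
#'
#' @inheritParams score_study
#' @param dataset A [disease_dataset()] with at least one study.
#' @param reference Reference scale or composite; defaults to the first
#'   (earliest) scale of the dataset.
#' @param reference_label Label written into the `reference` column.
#' @return A tibble with columns `disease`, `study_id`, `reference`, `a`, `b`,
#'   `c`, `d`, `sensitivity`, `specificity`, `neutrality`, `acceptable`,
#'   `sample_size`.
#' @export
score_studies <- function(dataset, reference = NULL, fold_in = NULL,
                          threshold = 1.5, reference_label = NULL) {
  stopifnot(inherits(dataset, "disease_dataset"))
  if (length(dataset$studies) == 0L) {
    abort2("The dataset contains no studies to score.", "neutrality_no_studies")
  }
  reference <- reference %||% dataset$scales[[1L]]
  reference_label <- reference_label %||% reference$name
  purrr::map_dfr(dataset$studies, function(st) {
    res <- score_study(st, reference, dataset, fold_in = fold_in,
                       threshold = threshold)
    tibble::tibble(
      disease = dataset$disease, study_id = st$study_id,
      reference = reference_label,
      a = res$table$a, b = res$table$b, c = res$table$c, d = res$table$d,
      sensitivity = res$sensitivity, specificity = res$specificity,
      neutrality = res$neutrality, acceptable = res$acceptable,
      sample_size = st$sample_size
    )
  })
}
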