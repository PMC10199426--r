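#' Normalize an indicator label to its canonical key
#'
#' Indicator labels arriving from scale definitions and study endpoint lists
#' are free text. Matching between a study and a scale is exact matching on a
#' normalized key: the label is trimmed, case-folded, punctuation is replaced
#' by spaces, internal whitespace is collapsed, and finally an optional synonym
#' map is applied. Normalization is idempotent, so re-ingesting an already
#' normalized dataset changes nothing. No fuzzy matching is performed: a silent
#' fuzzy merge would corrupt the classification counts irreversibly.
#'
#' @param x Character vector of raw labels.
#' @param synonyms Optional synonym map created by [synonym_map()] (or a named
#'   character vector `c(variant = "canonical")`; names and values are
#'   themselves normalized and chains are resolved).
#' @return Character vector of canonical keys, same length as `x`.
#' @examples
#' normalize_label("  Dysphagia ")
#' normalize_label("Quality-of-Life", synonym_map(c("quality of life" = "qol")))
#' @export
normalize_label <- function(x, synonyms = NULL) {
  if (!is.character(x)) {
    abort2("`x` must be a character vector of labels.", "neutrality_invalid_label")
  }
  if (length(x) == 0L) return(character(0))
  if (anyNA(x) || any(!nzchar(trimws(x)))) {
    abort2("Indicator labels must be non-empty, non-missing text.",
           "neutrality_invalid_label")
  }
  out <- tolower(trimws(x))
  out <- gsub("[[:punct:]]", " ", out)
  out <- gsub("[[:space:]]+", " ", out)
  out <- trimws(out)
  if (any(!nzchar(out))) {
    abort2("Indicator labels must contain at least one letter or digit.",
           "neutrality_invalid_label")
  }
  if (!is.null(synonyms)) {
    syn <- synonym_map(synonyms)
    hit <- out %in% names(syn)
    out[hit] <- unname(syn[out[hit]])
  }
  out
}

#' Build a resolved synonym map
#'
#' Keys (variants) and values (canonical labels) are normalized with the base
#' rules, and chains such as `a -> b`, `b -> c` are resolved to `a -> c` so that
#' [normalize_label()] stays idempotent. Cycles are an error.
#'
#' @param x Named character vector `c(variant = "canonical")`, or an existing
#'   synonym map (returned unchanged).
#' @return A named character vector of class `synonym_map`.
#' @export
synonym_map <- function(x) {
  if (inherits(x, "synonym_map")) return(x)
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort2("A synonym map is a named character vector: c(variant = 'canonical').",
           "neutrality_invalid_synonyms")
  }
  keys <- normalize_label(names(x))
  vals <- normalize_label(unname(x))
  if (anyDuplicated(keys)) {
    abort2("Duplicate variants in synonym map after normalization.",
           "neutrality_invalid_synonyms")
  }
  map <- stats::setNames(vals, keys)
  # resolve each variant to the end of its chain, detecting cycles
  resolved <- vapply(names(map), function(k) {
    seen <- k
    cur <- map[[k]]
    while (cur %in% names(map) && map[[cur]] != cur) {
      if (cur %in% seen) {
        abort2("Synonym map contains a cycle.", "neutrality_invalid_synonyms")
      }
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    cur
  }, character(1))
  map <- stats::setNames(resolved, names(map))
  structure(map, class = c("synonym_map", "character"))
}

#' Construct a disease-severity scale
#'
#' A scale is the indicator set of one validated disease-specific
#' disease-severity instrument, used as the surrogate disease phenotype.
#'
#' @param disease Disease key (free text; normalized internally).
#' @param name Scale name.
#' @param year Integer publication year (orders scales; the earliest is the
#'   "first" scale of a disease).
#' @param indicators Character vector of indicator labels; must be non-empty.
#'   Duplicates after normalization collapse to one indicator.
#' @param synonyms Optional synonym map applied during normalization.
#' @return An object of class `severity_scale`.
#' @export
severity_scale <- function(disease, name, year, indicators, synonyms = NULL) {
  stopifnot(is.character(disease), length(disease) == 1L,
            is.character(name), length(name) == 1L,
            is.numeric(year), length(year) == 1L, year == trunc(year))
  ind <- unique(normalize_label(indicators, synonyms))
  if (length(ind) == 0L) {
    abort2("A severity scale must contain at least one indicator.",
           "neutrality_empty_scale")
  }
  structure(
    list(disease = normalize_label(disease), name = name,
         year = as.integer(year), indicators = ind),
    class = "severity_scale"
  )
}

#' Construct a study endpoint set
#'
#' One clinical study's endpoints plus its reported sample size. An empty
#' endpoint set is allowed (a study can share nothing with any list); a missing
#' sample size is allowed and downstream simulation falls back to the default
#' cohort size of 30 subjects.
#'
#' @param disease Disease key.
#' @param study_id Study identifier, unique within the disease.
#' @param endpoints Character vector of endpoint labels (may be empty).
#' @param sample_size Reported number of subjects (`NA` when unreported).
#' @param synonyms Optional synonym map.
#' @return An object of class `study_endpoints`.
#' @export
study_endpoints <- function(disease, study_id, endpoints = character(),
                            sample_size = NA_integer_, synonyms = NULL) {
  stopifnot(is.character(disease), length(disease) == 1L,
            is.character(study_id), length(study_id) == 1L)
  if (!is.na(sample_size) && (!is.numeric(sample_size) || sample_size < 1 ||
                              sample_size != trunc(sample_size))) {
    abort2("`sample_size` must be a positive integer or NA.",
           "neutrality_invalid_sample_size")
  }
  ep <- if (length(endpoints) == 0L) character(0) else {
    unique(normalize_label(endpoints, synonyms))
  }
  structure(
    list(disease = normalize_label(disease), study_id = study_id,
         endpoints = ep,
         sample_size = if (is.na(sample_size)) NA_integer_ else as.integer(sample_size)),
    class = "study_endpoints"
  )
}

#' Bundle the scales and studies of one disease
#'
#' Scales are sorted ascending by publication year (ties broken by name), so
#' `scales[[1]]` is always the first disease-specific scale. All members must
#' share the disease key.
#'
#' @param scales List of [severity_scale()] objects (at least one).
#' @param studies List of [study_endpoints()] objects.
#' @return An object of class `disease_dataset`.
#' @export
disease_dataset <- function(scales, studies = list()) {
  if (length(scales) == 0L) {
    abort2("A disease dataset needs at least one severity scale.",
           "neutrality_empty_dataset")
  }
  stopifnot(all(vapply(scales, inherits, logical(1), "severity_scale")),
            all(vapply(studies, inherits, logical(1), "study_endpoints")))
  diseases <- unique(c(vapply(scales, `[[`, character(1), "disease"),
                       vapply(studies, `[[`, character(1), "disease")))
  if (length(diseases) != 1L) {
    abort2(paste0("All scales and studies must share one disease; got: ",
                  paste(diseases, collapse = ", ")),
           "neutrality_cross_disease")
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    abort2("Study identifiers must be unique within a disease.",
           "neutrality_duplicate_study")
  }
  ord <- order(vapply(scales, `[[`, integer(1), "year"),
               vapply(scales, `[[`, character(1), "name"))
  structure(
    list(disease = diseases, scales = scales[ord], studies = studies),
    class = "disease_dataset"
  )
}

#' @export
print.severity_scale <- function(x, ...) {
  cat(sprintf("<severity_scale> %s (%d) - %s: %d indicators\n",
              x$name, x$year, x$disease, length(x$indicators)))
  invisible(x)
}

#' @export
print.study_endpoints <- function(x, ...) {
  cat(sprintf("<study_endpoints> %s - %s: %d endpoints, n = %s\n",
              x$study_id, x$disease, length(x$endpoints),
              ifelse(is.na(x$sample_size), "unreported", x$sample_size)))
  invisible(x)
}

#' @export
print.disease_dataset <- function(x, ...) {
  cat(sprintf("<disease_dataset> %s: %d scale(s), %d study(ies)\n",
              x$disease, length(x$scales), length(x$studies)))
  invisible(x)
}

# indicator set of a severity_scale / composite_scale / character vector
indicator_set <- function(x) {
  if (inherits(x, c("severity_scale", "composite_scale"))) return(x$indicators)
  if (is.character(x)) return(unique(x))
  abort2("Expected a severity scale, composite scale, or character vector.",
         "neutrality_invalid_reference")
}

#' Build the observation universe for scoring one reference scale
#'
#' The universe is the total information observed for the disease: the union of
#' every study's endpoints across the disease, the reference scale's
#' indicators, and the indicators of any extra scales folded in (used to count
#' a composite's indicators as observed information when scoring against the
#' first scale). The irrelevant cell `d` of the classification is counted from
#' this universe.
#'
#' @param dataset A [disease_dataset()].
#' @param reference A [severity_scale()] or [composite_scale] belonging to the
#'   same disease.
#' @param extra_scales Optional list of scales/composites whose indicators are
#'   folded into the universe.
#' @return Character vector of normalized indicator keys.
#' @export
observation_universe <- function(dataset, reference, extra_scales = NULL) {
  stopifnot(inherits(dataset, "disease_dataset"))
  ref_disease <- if (inherits(reference, c("severity_scale", "composite_scale"))) {
    reference$disease
  } else {
    dataset$disease
  }
  if (!identical(ref_disease, dataset$disease)) {
    abort2(sprintf("Reference belongs to '%s' but the dataset is for '%s'.",
                   ref_disease, dataset$disease),
           "neutrality_cross_disease")
  }
  extras <- if (is.null(extra_scales)) character(0) else {
    if (inherits(extra_scales, c("severity_scale", "composite_scale"))) {
      extra_scales <- list(extra_scales)
    }
    unlist(lapply(extra_scales, indicator_set), use.names = FALSE)
  }
  unique(c(
    unlist(lapply(dataset$studies, `[[`, "endpoints"), use.names = FALSE),
    indicator_set(reference),
    extras
  ))
}

#' Construct a classification table
#'
#' The four cells of the endpoint classification: `a` overlapping (in study and
#' scale), `b` redundant (study only), `c` missing (scale only), `d` irrelevant
#' (in neither, but observed in some study of the disease). By construction
#' `a + c` is the reference scale size and `b + d` the size of the universe
#' outside the scale.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `classification_table`.
#' @export
classification_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    abort2("Classification cells must be non-negative integers.",
           "neutrality_invalid_cells")
  }
  structure(as.list(as.integer(cells)), names = c("a", "b", "c", "d"),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf(
    "<classification_table> overlap a=%d, redundant b=%d, missing c=%d, irrelevant d=%d (universe %d)\n",
    x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Classify a study's endpoints against a reference indicator set
#'
#' Partitions the observation universe into the four classification cells.
#' Both the study endpoints and the reference must lie inside the universe:
#' the universe is built from all studies of the disease, so an endpoint
#' outside it signals a construction error upstream, not a scoring case.
#'
#' @param study A [study_endpoints()] object or character vector of endpoints.
#' @param reference A scale, composite, or character vector of indicators.
#' @param universe Character vector from [observation_universe()].
#' @return A [classification_table()] with `a + b + c + d = length(universe)`.
#' @export
classify_endpoints <- function(study, reference, universe) {
  ep <- if (inherits(study, "study_endpoints")) study$endpoints else unique(study)
  ref <- indicator_set(reference)
  universe <- unique(universe)
  if (!all(ref %in% universe)) {
    abort2("Reference indicators must be a subset of the observation universe.",
           "neutrality_universe_incomplete")
  }
  if (!all(ep %in% universe)) {
    abort2(paste0("Study endpoints outside the observation universe: ",
                  paste(setdiff(ep, universe), collapse = ", ")),
           "neutrality_universe_incomplete")
  }
  a <- length(intersect(ep, ref))
  b <- length(setdiff(ep, ref))
  c <- length(setdiff(ref, ep))
  d <- length(universe) - a - b - c
  classification_table(a, b, c, d)
}
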