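#' Specification for a synthetic disease dataset
#'
#' Describes a disease with `n_scales` severity scales and `n_studies` studies
#' whose classification against the reference (first) scale hits per-study
#' target sensitivities and specificities. Indicator labels are opaque,
#' disease-prefixed tokens, keeping label normalization out of the generator's
#' correctness path.
#'
#' Overlap structure: scale 1 is all-fresh; each later scale `i` shares
#' `shared_with_previous[i - 1]` indicators with the union of the earlier
#' scales and adds fresh ones, so a composite over all scales excludes exactly
#' `sum(shared_with_previous)` duplicates.
#'
#' Targets are realized on the integer lattice: `a = round(se * |reference|)`
#' and the redundant count `b = round((1 - sp) * universe_extra_count)`, so a
#' target that is not integer-feasible is snapped to the nearest feasible value
#' and the realized value is recorded in the manifest (`strict = TRUE` errors
#' instead). The pool of `universe_extra_count` out-of-scale indicators is
#' carried by an auxiliary "endpoint registry" study (flagged `is_registry` in
#' the manifest) so the whole pool is part of the observation universe, which
#' is built only from studies and the reference; this emulates the situation
#' where every irrelevant indicator has been used as an endpoint by some other
#' study of the disease.
#'
#' @param disease Disease key.
#' @param scale_sizes Integer vector of indicator counts, one per scale.
#' @param shared_with_previous For each scale after the first, how many of its
#'   indicators are drawn from the union of earlier scales.
#' @param target_sensitivity,target_specificity Per-study target proportions
#'   (recycled to `n_studies`).
#' @param n_studies Number of studies (defaults to the target length).
#' @param universe_extra_count Size of the out-of-scale indicator pool; must be
#'   at least 1 so that specificity is defined.
#' @param sample_sizes Reported subjects per study (recycled); `NA` allowed.
#'   Default 30.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param strict If `TRUE`, non-integer-feasible targets are an error.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(disease = "synthetic disease",
                           scale_sizes = 10L,
                           shared_with_previous = integer(0),
                           target_sensitivity = 0.5,
                           target_specificity = 0.8,
                           n_studies = NULL,
                           universe_extra_count = 10L,
                           sample_sizes = 30L,
                           seed = 1L,
                           strict = FALSE) {
  stopifnot(is.numeric(scale_sizes), length(scale_sizes) >= 1L,
            all(vapply(as.list(scale_sizes), is_count, logical(1))),
            all(scale_sizes >= 1))
  if (length(shared_with_previous) != length(scale_sizes) - 1L) {
    abort2("`shared_with_previous` needs one entry per scale after the first.",
           "neutrality_infeasible_spec")
  }
  n_studies <- n_studies %||% max(length(target_sensitivity),
                                  length(target_specificity))
  stopifnot(is_count(n_studies), n_studies >= 1,
            is_count(universe_extra_count))
  if (universe_extra_count < 1) {
    abort2(paste0("`universe_extra_count` must be >= 1: with an empty ",
                  "out-of-scale pool the universe complement is empty and ",
                  "specificity is undefined."),
           "neutrality_infeasible_spec")
  }
  se <- rep_len(target_sensitivity, n_studies)
  sp <- rep_len(target_specificity, n_studies)
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    abort2("Target sensitivities/specificities must lie in [0, 1].",
           "neutrality_infeasible_spec")
  }
  if (length(shared_with_previous) > 0) {
    cum_union <- cumsum(c(scale_sizes[1L],
                          scale_sizes[-1L] - shared_with_previous))
    prev_union <- cum_union[-length(cum_union)] # union size before each later scale
    ok <- shared_with_previous <= pmin(scale_sizes[-1L], prev_union)
    if (any(!ok)) {
      abort2("`shared_with_previous` exceeds an earlier-union or scale size.",
             "neutrality_infeasible_spec")
    }
  }
  structure(
    list(disease = normalize_label(disease),
         scale_sizes = as.integer(scale_sizes),
         shared_with_previous = as.integer(shared_with_previous),
         target_sensitivity = se, target_specificity = sp,
         n_studies = as.integer(n_studies),
         universe_extra_count = as.integer(universe_extra_count),
         sample_sizes = rep_len(sample_sizes, n_studies),
         seed = as.integer(seed), strict = isTRUE(strict)),
    class = "synthetic_spec"
  )
}

# opaque indicator tokens: "<disease> i0001", "<disease> i0002", ...
synth_tokens <- function(disease, from, n) {
  if (n == 0L) return(character(0))
  sprintf("%s i%04d", disease, seq.int(from, length.out = n))
}

#' Generate a disease dataset with controlled overlap structure
#'
#' Realizes a [synthetic_spec()]: builds the scales with the requested shared
#' indicator counts, then builds each study so that re-scoring it against the
#' first scale returns the realized targets exactly (integers by
#' construction). The manifest records, per study, the planned cells and the
#' realized sensitivity/specificity actually achievable on the integer
#' lattice.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `dataset` (a [disease_dataset()]) and
#'   `manifest` (tibble: `study_id`, `is_registry`, `target_*`, `realized_*`,
#'   `a`, `b`, `c`, `d`, `sample_size`, plus the seed as an attribute).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    disease <- spec$disease
    n_scales <- length(spec$scale_sizes)
    counter <- 0L
    scales <- vector("list", n_scales)
    for (i in seq_len(n_scales)) {
      shared <- if (i == 1L) character(0) else {
        prev <- unique(unlist(lapply(scales[seq_len(i - 1L)], `[[`, "indicators")))
        sample(prev, spec$shared_with_previous[i - 1L])
      }
      n_fresh <- spec$scale_sizes[i] - length(shared)
      fresh <- synth_tokens(disease, counter + 1L, n_fresh)
      counter <- counter + n_fresh
      scales[[i]] <- severity_scale(disease, sprintf("synthetic scale %d", i),
                                    year = 2000L + 5L * (i - 1L),
                                    indicators = c(shared, fresh))
    }
    reference <- scales[[1L]]
    ref_ind <- reference$indicators
    R <- length(ref_ind)
    extras <- synth_tokens(disease, counter + 1L, spec$universe_extra_count)
    E <- length(extras)

    a <- as.integer(round(spec$target_sensitivity * R))
    b <- as.integer(round((1 - spec$target_specificity) * E))
    realized_se <- a / R
    realized_sp <- (E - b) / E
    if (spec$strict &&
        (any(abs(realized_se - spec$target_sensitivity) > 1e-12) ||
         any(abs(realized_sp - spec$target_specificity) > 1e-12))) {
      abort2("Targets are not integer-feasible under `strict = TRUE`.",
             "neutrality_infeasible_spec")
    }
    studies <- purrr::map(seq_len(spec$n_studies), function(j) {
      overlap <- if (a[j] > 0) sample(ref_ind, a[j]) else character(0)
      redundant <- if (b[j] > 0) sample(extras, b[j]) else character(0)
      study_endpoints(disease, sprintf("study %02d", j),
                      endpoints = c(overlap, redundant),
                      sample_size = spec$sample_sizes[j])
    })
    # registry study: carries the whole extra pool into the universe
    registry <- study_endpoints(disease, "endpoint registry",
                                endpoints = extras, sample_size = NA)
    cell_c <- c(R - a, R)
    cell_d <- c(E - b, 0L)
    manifest <- tibble::tibble(
      study_id = c(vapply(studies, `[[`, character(1), "study_id"),
                   registry$study_id),
      is_registry = c(rep(FALSE, spec$n_studies), TRUE),
      target_sensitivity = c(spec$target_sensitivity, NA),
      target_specificity = c(spec$target_specificity, NA),
      realized_sensitivity = c(realized_se, 0),
      realized_specificity = c(realized_sp, 0),
      a = c(a, 0L), b = c(b, E), c = cell_c, d = cell_d,
      sample_size = c(as.integer(spec$sample_sizes), NA_integer_)
    )
    attr(manifest, "seed") <- spec$seed
    list(dataset = disease_dataset(scales, c(studies, list(registry))),
         manifest = manifest)
  })
}
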