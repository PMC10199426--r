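#' Summarize the per-study Neutrality results of one disease
#'
#' Unweighted arithmetic means of sensitivity, specificity and Neutrality over
#' studies (so mean Neutrality = mean sensitivity + mean specificity exactly),
#' plus the most and least Neutral study and the acceptability count (strict
#' `neutrality > threshold`). Ties on Neutrality are broken by higher
#' specificity, then lexically by `study_id`.
#'
#' @param results Tibble as returned by [score_studies()] (one disease).
#' @param threshold Acceptability cut-off; default 1.5.
#' @return One-row tibble: `disease`, `n_studies`, `mean_sensitivity`,
#'   `mean_specificity`, `mean_neutrality`, `most_*` and `least_*` columns
#'   (`study_id`, `neutrality`, `sensitivity`, `specificity`), `n_acceptable`,
#'   `proportion_acceptable`.
#' @export
summarize_cohort <- function(results, threshold = 1.5) {
  required <- c("disease", "study_id", "sensitivity", "specificity", "neutrality")
  if (!is.data.frame(results) || nrow(results) == 0L ||
      !all(required %in% names(results))) {
    abort2("`results` must be a non-empty per-study results table.",
           "neutrality_empty_cohort")
  }
  if (length(unique(results$disease)) != 1L) {
    abort2("A cohort summary covers exactly one disease.",
           "neutrality_cross_disease")
  }
  # ties on neutrality: higher specificity wins, then lexically smaller id
  least <- results[order(results$neutrality, -results$specificity,
                         xtfrm(results$study_id))[1L], ]
  most <- results[order(-results$neutrality, -results$specificity,
                        xtfrm(results$study_id))[1L], ]
  n_acc <- sum(results$neutrality > threshold)
  tibble::tibble(
    disease = results$disease[[1L]],
    n_studies = nrow(results),
    mean_sensitivity = mean(results$sensitivity),
    mean_specificity = mean(results$specificity),
    mean_neutrality = mean(results$sensitivity) + mean(results$specificity),
    most_study_id = most$study_id, most_neutrality = most$neutrality,
    most_sensitivity = most$sensitivity, most_specificity = most$specificity,
    least_study_id = least$study_id, least_neutrality = least$neutrality,
    least_sensitivity = least$sensitivity, least_specificity = least$specificity,
    n_acceptable = n_acc,
    proportion_acceptable = n_acc / nrow(results)
  )
}

#' Compare study Neutrality against the first scale versus a composite
#'
#' Takes the per-study results of the same study set scored against the first
#' disease-specific scale and against the composite of later scales, and
#' reports both cohort means with signed differences (composite minus first).
#' A positive `delta_neutrality` means the study endpoints match the composite
#' better than the first scale.
#'
#' @param first_results,composite_results Per-study tibbles from
#'   [score_studies()] over the same studies (matched by `study_id`).
#' @param threshold Acceptability cut-off passed to [summarize_cohort()].
#' @return One-row tibble: `disease`, `n_studies`, `first_*` and `composite_*`
#'   mean columns, `delta_neutrality`, `delta_sensitivity`,
#'   `delta_specificity`.
#' @export
compare_scales <- function(first_results, composite_results, threshold = 1.5) {
  f <- first_results[order(first_results$study_id), ]
  g <- composite_results[order(composite_results$study_id), ]
  if (nrow(f) != nrow(g) || !identical(f$study_id, g$study_id) ||
      !identical(unique(f$disease), unique(g$disease))) {
    abort2("First and composite results must cover the same studies of one disease.",
           "neutrality_pairing_error")
  }
  sf <- summarize_cohort(f, threshold)
  sg <- summarize_cohort(g, threshold)
  tibble::tibble(
    disease = sf$disease,
    n_studies = sf$n_studies,
    first_neutrality = sf$mean_neutrality,
    first_sensitivity = sf$mean_sensitivity,
    first_specificity = sf$mean_specificity,
    composite_neutrality = sg$mean_neutrality,
    composite_sensitivity = sg$mean_sensitivity,
    composite_specificity = sg$mean_specificity,
    delta_neutrality = sg$mean_neutrality - sf$mean_neutrality,
    delta_sensitivity = sg$mean_sensitivity - sf$mean_sensitivity,
    delta_specificity = sg$mean_specificity - sf$mean_specificity
  )
}

#' Misclassification report for the most and least Neutral studies
#'
#' For each extreme study of a cohort and each prevalence, attaches the
#' analytic predictive values (and optionally a Monte Carlo summary using the
#' study's reported sample size, falling back to `default_sample_size`).
#' RNG substreams are derived per (study, prevalence) from the master seed, so
#' adding a prevalence or study never perturbs the other draws.
#'
#' @param results Per-study tibble from [score_studies()] (one disease).
#' @param prevalence Prevalence grid, each strictly in `(0, 1)`; default
#'   `c(0.2, 0.5, 0.8)`.
#' @param simulate If `TRUE`, adds simulated medians and 5th/95th percentiles.
#' @param replicates Replicates per simulation; default 1000.
#' @param default_sample_size Cohort size used when a study reports none;
#'   default 30.
#' @param seed Master seed for the simulations.
#' @param threshold Acceptability cut-off used to pick extremes.
#' @return Tibble with one row per extreme x prevalence: `disease`, `which`
#'   (`"most"`/`"least"`), `study_id`, `sensitivity`, `specificity`,
#'   `neutrality`, `prevalence`, `ppv`, `npv`, `fp_rate`, `fn_rate`, and when
#'   `simulate = TRUE` also `sim_fp_p5/p50/p95`, `sim_fn_p5/p50/p95`,
#'   `sim_dropped_fp`, `sim_dropped_fn`, `sample_size`.
#' @export
extremes_report <- function(results, prevalence = c(0.2, 0.5, 0.8),
                            simulate = FALSE, replicates = 1000,
                            default_sample_size = 30, seed = NULL,
                            threshold = 1.5) {
  summ <- summarize_cohort(results, threshold)
  extremes <- tibble::tibble(
    which = c("most", "least"),
    study_id = c(summ$most_study_id, summ$least_study_id)
  )
  purrr::pmap_dfr(extremes, function(which, study_id) {
    row <- results[results$study_id == study_id, ][1L, ]
    pv <- predictive_values(row$sensitivity, row$specificity, prevalence)
    out <- dplyr::bind_cols(
      tibble::tibble(disease = row$disease, which = which,
                     study_id = study_id, neutrality = row$neutrality),
      pv
    )
    if (!simulate) return(out)
    n <- row$sample_size
    if (is.null(n) || is.na(n)) n <- default_sample_size
    sims <- purrr::map_dfr(prevalence, function(p) {
      sim <- simulate_misclassification(
        row$sensitivity, row$specificity, p,
        sample_size = n, replicates = replicates,
        seed = if (is.null(seed)) NULL else derive_seed(seed, study_id, p)
      )
      ss <- summarize_simulation(sim)
      tibble::tibble(
        prevalence = p, sample_size = as.integer(n),
        sim_fp_p5 = ss$p5[ss$metric == "fp"], sim_fp_p50 = ss$p50[ss$metric == "fp"],
        sim_fp_p95 = ss$p95[ss$metric == "fp"],
        sim_fn_p5 = ss$p5[ss$metric == "fn"], sim_fn_p50 = ss$p50[ss$metric == "fn"],
        sim_fn_p95 = ss$p95[ss$metric == "fn"],
        sim_dropped_fp = ss$dropped[ss$metric == "fp"],
        sim_dropped_fn = ss$dropped[ss$metric == "fn"]
      )
    })
    dplyr::left_join(out, sims, by = "prevalence")
  })
}
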