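#' Predictive values and misclassification rates at given prevalences
#'
#' Propagates a study's sensitivity and specificity into positive and negative
#' predictive values at each prevalence of severe disease, treating sensitivity
#' and specificity as statistically independent of prevalence:
#' \deqn{PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)}, \qquad
#'       NPV = \frac{Sp(1-p)}{Sp(1-p) + (1-Se)p}.}
#' The false-positive rate is `1 - PPV` (the probability that a positive
#' severity classification is wrong) and the false-negative rate is `1 - NPV`.
#' When a denominator is zero (e.g. a perfect test that never classifies anyone
#' positive at the given prevalence composition) the value is `NA`, marked
#' undefined rather than given a convention.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]` (recycled against
#'   `prevalence`).
#' @param prevalence Prevalences of severe disease, each strictly inside
#'   `(0, 1)`. Default grid `c(0.2, 0.5, 0.8)`.
#' @return A tibble with columns `sensitivity`, `specificity`, `prevalence`,
#'   `ppv`, `npv`, `fp_rate`, `fn_rate`.
#' @examples
#' predictive_values(0.8, 0.9, 0.5)
#' @export
predictive_values <- function(sensitivity, specificity,
                              prevalence = c(0.2, 0.5, 0.8)) {
  if (!is.numeric(prevalence) || length(prevalence) == 0L ||
      anyNA(prevalence) || any(prevalence <= 0 | prevalence >= 1)) {
    abort2("`prevalence` values must lie strictly inside (0, 1).",
           "neutrality_invalid_prevalence")
  }
  if (anyNA(sensitivity) || anyNA(specificity) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    abort2("`sensitivity` and `specificity` must lie in [0, 1].",
           "neutrality_invalid_proportion")
  }
  grid <- tibble::tibble(sensitivity = sensitivity,
                         specificity = specificity) |>
    tidyr::crossing(prevalence = prevalence)
  se <- grid$sensitivity; sp <- grid$specificity; p <- grid$prevalence
  pos <- se * p + (1 - sp) * (1 - p)
  neg <- sp * (1 - p) + (1 - se) * p
  ppv <- ifelse(pos > 0, se * p / pos, NA_real_)
  npv <- ifelse(neg > 0, sp * (1 - p) / neg, NA_real_)
  grid$ppv <- ppv
  grid$npv <- npv
  grid$fp_rate <- 1 - ppv
  grid$fn_rate <- 1 - npv
  grid
}

#' Monte Carlo simulation of misclassification in a trial-sized cohort
#'
#' Per replicate, `sample_size` subjects are drawn: each is truly severe with
#' probability `prevalence`; severe subjects classify positive with probability
#' `sensitivity` and non-severe subjects with probability `1 - specificity`.
#' The replicate's false-positive proportion is `FP / (FP + TP)` among
#' test-positives (the empirical `1 - PPV`) and the false-negative proportion
#' is `FN / (FN + TN)` among test-negatives (the empirical `1 - NPV`).
#' Replicates with no positives (resp. negatives) are dropped from the
#' respective list and counted, never imputed — imputing 0 or 1 would bias the
#' medians at extreme prevalences.
#'
#' Fully seed-deterministic: the same seed reproduces the result bit for bit,
#' and the caller's RNG state is left untouched.
#'
#' @inheritParams predictive_values
#' @param prevalence A single prevalence strictly inside `(0, 1)`.
#' @param sample_size Subjects per replicate; default 30, the fallback cohort
#'   size used when a study reports none.
#' @param replicates Number of simulated cohorts; default 1000.
#' @param seed Integer seed (optional but recommended).
#' @return An object of class `misclassification_sim`: list with `params`,
#'   `fp_proportions`, `fn_proportions`, `dropped_fp_replicates`,
#'   `dropped_fn_replicates`.
#' @export
simulate_misclassification <- function(sensitivity, specificity, prevalence,
                                       sample_size = 30, replicates = 1000,
                                       seed = NULL) {
  if (!is_scalar_prob(sensitivity) || !is_scalar_prob(specificity)) {
    abort2("`sensitivity` and `specificity` must be single values in [0, 1].",
           "neutrality_invalid_proportion")
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort2("`prevalence` must be a single value strictly inside (0, 1).",
           "neutrality_invalid_prevalence")
  }
  stopifnot(is_count(sample_size), sample_size >= 1,
            is_count(replicates), replicates >= 1)
  counts <- local_seed(seed, {
    n_severe <- stats::rbinom(replicates, sample_size, prevalence)
    tp <- stats::rbinom(replicates, n_severe, sensitivity)
    fp <- stats::rbinom(replicates, sample_size - n_severe, 1 - specificity)
    list(tp = tp, fp = fp, fn = n_severe - tp,
         tn = sample_size - n_severe - fp)
  })
  n_pos <- counts$tp + counts$fp
  n_neg <- counts$tn + counts$fn
  structure(
    list(
      params = list(sensitivity = sensitivity, specificity = specificity,
                    prevalence = prevalence, sample_size = as.integer(sample_size),
                    replicates = as.integer(replicates), seed = seed),
      fp_proportions = counts$fp[n_pos > 0] / n_pos[n_pos > 0],
      fn_proportions = counts$fn[n_neg > 0] / n_neg[n_neg > 0],
      dropped_fp_replicates = sum(n_pos == 0),
      dropped_fn_replicates = sum(n_neg == 0)
    ),
    class = "misclassification_sim"
  )
}

#' @export
print.misclassification_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<misclassification_sim> Se %.2f, Sp %.2f, p %.2f, n %d, %d replicates (dropped fp %d, fn %d)\n",
    p$sensitivity, p$specificity, p$prevalence, p$sample_size, p$replicates,
    x$dropped_fp_replicates, x$dropped_fn_replicates))
  invisible(x)
}

#' Summarize a misclassification simulation
#'
#' Median with 5th and 95th percentiles of the per-replicate false-positive and
#' false-negative proportions, using the linear-interpolation percentile
#' (`stats::quantile()` type 7) so summaries are reproducible bit for bit at a
#' fixed seed. An empty list (every replicate dropped) yields `NA` summaries
#' with the dropped count reported.
#'
#' @param sim A [simulate_misclassification()] result.
#' @param probs Percentile levels; default `c(0.05, 0.5, 0.95)`.
#' @return A tibble with one row per metric (`fp`, `fn`): `n_replicates`,
#'   `dropped`, then one percentile column per element of `probs` (`p5`, `p50`,
#'   `p95` at the defaults).
#' @export
summarize_simulation <- function(sim, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(sim, "misclassification_sim"),
            is.numeric(probs), all(probs >= 0 & probs <= 1))
  one <- function(metric, x, dropped) {
    qs <- if (length(x) == 0L) rep(NA_real_, length(probs)) else {
      unname(stats::quantile(x, probs = probs, type = 7))
    }
    out <- tibble::tibble(metric = metric, n_replicates = length(x),
                          dropped = dropped)
    out[paste0("p", format(probs * 100, trim = TRUE))] <-
      as.list(qs)
    out
  }
  dplyr::bind_rows(
    one("fp", sim$fp_proportions, sim$dropped_fp_replicates),
    one("fn", sim$fn_proportions, sim$dropped_fn_replicates)
  )
}
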