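#' Read a synonym map from CSV or JSON
#'
#' CSV needs columns `variant,canonical`; JSON is a flat object
#' `{"variant": "canonical"}`.
#'
#' @param path File path.
#' @return A [synonym_map()].
#' @export
read_synonyms <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(synonym_map(unlist(obj)))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("variant", "canonical") %in% names(df))) {
    abort2("Synonym CSV needs columns `variant` and `canonical`.",
           "neutrality_schema_error")
  }
  synonym_map(stats::setNames(df$canonical, df$variant))
}

read_table_any <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort2(sprintf("%s is missing column(s): %s", what,
                   paste(missing, collapse = ", ")),
           "neutrality_schema_error")
  }
}

#' Load scales and studies files into per-disease datasets
#'
#' The scales file has one row per scale indicator with columns
#' `disease,scale_name,year,indicator`; the studies file has one row per study
#' endpoint with columns `disease,study_id,sample_size,indicator` (an empty
#' `sample_size` is allowed and repeated values per study must agree).
#' Equivalent flat JSON arrays are accepted. Labels are normalized and
#' deduplicated on ingest; a load report (rows read, duplicates collapsed) is
#' attached as the `"report"` attribute.
#'
#' @param scales_path Path to the scales CSV/JSON.
#' @param studies_path Optional path to the studies CSV/JSON.
#' @param synonyms_path Optional synonym CSV/JSON (or a [synonym_map()]).
#' @return Named list of [disease_dataset()] objects, one per disease.
#' @export
load_datasets <- function(scales_path, studies_path = NULL,
                          synonyms_path = NULL) {
  syn <- if (is.null(synonyms_path)) NULL else if (is.character(synonyms_path)) {
    read_synonyms(synonyms_path)
  } else {
    synonym_map(synonyms_path)
  }
  sc <- read_table_any(scales_path)
  check_columns(sc, c("disease", "scale_name", "year", "indicator"),
                "Scales file")
  if (nrow(sc) == 0L) {
    abort2("Scales file contains no rows.", "neutrality_schema_error")
  }
  sc$disease_key <- normalize_label(sc$disease)

  st <- NULL
  if (!is.null(studies_path)) {
    st <- read_table_any(studies_path)
    check_columns(st, c("disease", "study_id", "sample_size", "indicator"),
                  "Studies file")
    st$disease_key <- if (nrow(st) > 0) normalize_label(st$disease) else character(0)
    unknown <- setdiff(unique(st$disease_key), unique(sc$disease_key))
    if (length(unknown) > 0L) {
      abort2(paste0("Studies reference disease(s) absent from the scales file: ",
                    paste(unknown, collapse = ", ")),
             "neutrality_unknown_disease")
    }
  }

  report <- list(scale_rows = nrow(sc),
                 study_rows = if (is.null(st)) 0L else nrow(st),
                 duplicates_collapsed = 0L)
  out <- lapply(unique(sc$disease_key), function(dk) {
    scd <- sc[sc$disease_key == dk, ]
    scales <- lapply(split(scd, paste(scd$scale_name, scd$year)), function(g) {
      s <- severity_scale(dk, g$scale_name[[1L]], g$year[[1L]], g$indicator,
                          synonyms = syn)
      report$duplicates_collapsed <<- report$duplicates_collapsed +
        (nrow(g) - length(s$indicators))
      s
    })
    studies <- list()
    if (!is.null(st)) {
      std <- st[st$disease_key == dk, , drop = FALSE]
      studies <- lapply(split(std, std$study_id), function(g) {
        n <- unique(g$sample_size[!is.na(g$sample_size)])
        if (length(n) > 1L) {
          abort2(sprintf("Study '%s' reports conflicting sample sizes.",
                         g$study_id[[1L]]),
                 "neutrality_schema_error")
        }
        s <- study_endpoints(dk, g$study_id[[1L]], g$indicator,
                             sample_size = if (length(n) == 1L) n else NA,
                             synonyms = syn)
        report$duplicates_collapsed <<- report$duplicates_collapsed +
          (nrow(g) - length(s$endpoints))
        s
      })
    }
    disease_dataset(unname(scales), unname(studies))
  })
  names(out) <- unique(sc$disease_key)
  attr(out, "report") <- report
  out
}

#' Pipeline configuration
#'
#' Defaults mirror the study conditions of the underlying method: prevalence
#' grid 20%/50%/80%, fallback cohort size 30 subjects, 1000 Monte Carlo
#' replicates, acceptability threshold 1.50.
#'
#' @param scales,studies,synonyms Input file paths (synonyms optional).
#' @param reference_policy `"single"` scores every study against the first
#'   (earliest) scale of its disease; `"first-vs-composite"` additionally
#'   scores against the composite of all later scales and reports deltas.
#' @param include_first_in_composite Fold the first scale into the composite
#'   (off by default: the composite is built from the later scales only).
#' @param prevalence Prevalence grid for misclassification outputs.
#' @param default_sample_size Cohort size when a study reports none.
#' @param replicates Monte Carlo replicates.
#' @param threshold Acceptability cut-off.
#' @param simulate Run Monte Carlo simulations for the extreme studies.
#' @param seed Master seed; all randomness flows from it.
#' @param out_dir Optional output directory; when given, CSV/JSON artifacts and
#'   a manifest are written.
#' @return A `run_config` list.
#' @export
run_config <- function(scales, studies = NULL, synonyms = NULL,
                       reference_policy = c("single", "first-vs-composite"),
                       include_first_in_composite = FALSE,
                       prevalence = c(0.2, 0.5, 0.8),
                       default_sample_size = 30, replicates = 1000,
                       threshold = 1.5, simulate = FALSE, seed = 1L,
                       out_dir = NULL) {
  structure(
    list(scales = scales, studies = studies, synonyms = synonyms,
         reference_policy = match.arg(reference_policy),
         include_first_in_composite = isTRUE(include_first_in_composite),
         prevalence = prevalence,
         default_sample_size = default_sample_size,
         replicates = replicates, threshold = threshold,
         simulate = isTRUE(simulate), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full scoring pipeline
#'
#' Loads the inputs, scores every study of every disease, aggregates cohort
#' summaries (and first-vs-composite comparisons under that policy), attaches
#' misclassification reports for the extreme studies, and optionally writes
#' the whole bundle as CSV plus a JSON manifest. Re-running with the same
#' config and seed reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `scores`, `summaries`, `comparisons` (or
#'   `NULL`), `misclassification`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  datasets <- load_datasets(config$scales, config$studies, config$synonyms)
  datasets <- Filter(function(d) length(d$studies) > 0L, datasets)
  if (length(datasets) == 0L) {
    abort2("No disease has any studies to score.", "neutrality_no_studies")
  }

  scores <- list(); summaries <- list(); comparisons <- list(); misc <- list()
  for (ds in datasets) {
    first <- ds$scales[[1L]]
    if (config$reference_policy == "single") {
      res <- score_studies(ds, first, threshold = config$threshold)
      scores[[ds$disease]] <- res
      summaries[[ds$disease]] <- summarize_cohort(res, config$threshold)
      misc[[ds$disease]] <- extremes_report(
        res, config$prevalence, simulate = config$simulate,
        replicates = config$replicates,
        default_sample_size = config$default_sample_size,
        seed = derive_seed(config$seed, ds$disease),
        threshold = config$threshold)
    } else {
      if (length(ds$scales) < 2L) {
        abort2(sprintf("Disease '%s' has a single scale; the first-vs-composite policy needs at least two.",
                       ds$disease),
               "neutrality_infeasible_spec")
      }
      members <- if (config$include_first_in_composite) ds$scales else ds$scales[-1L]
      comp <- build_composite(members)
      res_first <- score_studies(ds, first, fold_in = comp,
                                 threshold = config$threshold,
                                 reference_label = first$name)
      res_comp <- score_studies(ds, comp, threshold = config$threshold,
                                reference_label = comp$name)
      scores[[ds$disease]] <- dplyr::bind_rows(res_first, res_comp)
      summaries[[ds$disease]] <- dplyr::bind_rows(
        summarize_cohort(res_first, config$threshold),
        summarize_cohort(res_comp, config$threshold))
      comparisons[[ds$disease]] <- compare_scales(res_first, res_comp,
                                                  config$threshold)
      misc[[ds$disease]] <- extremes_report(
        res_first, config$prevalence, simulate = config$simulate,
        replicates = config$replicates,
        default_sample_size = config$default_sample_size,
        seed = derive_seed(config$seed, ds$disease),
        threshold = config$threshold)
    }
  }
  bundle <- list(
    scores = dplyr::bind_rows(scores),
    summaries = dplyr::bind_rows(summaries),
    comparisons = if (length(comparisons)) dplyr::bind_rows(comparisons) else NULL,
    misclassification = dplyr::bind_rows(misc),
    manifest = list(
      reference_policy = config$reference_policy,
      prevalence = config$prevalence,
      default_sample_size = config$default_sample_size,
      replicates = config$replicates, threshold = config$threshold,
      simulate = config$simulate, seed = config$seed,
      n_diseases = length(datasets),
      package_version = as.character(utils::packageVersion("neutrality"))
    )
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

#' Write a pipeline bundle to disk
#'
#' CSV is the canonical interchange; the manifest is JSON. Byte-identical for
#' identical inputs and seed.
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return()
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  emit(bundle$scores, "study_scores")
  emit(bundle$summaries, "cohort_summaries")
  emit(bundle$comparisons, "scale_comparisons")
  emit(bundle$misclassification, "misclassification")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
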