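# independent brute-force oracles and tiny builders used across the suite

# pairwise-dedup union: compares every candidate against everything kept so far
brute_union <- function(sets) {
  out <- character(0)
  for (s in sets) {
    for (x in s) {
      seen <- FALSE
      for (y in out) if (identical(x, y)) seen <- TRUE
      if (!seen) out <- c(out, x)
    }
  }
  out
}

# double-loop membership classification of a universe into the four cells
brute_cells <- function(study, reference, universe) {
  a <- b <- c <- d <- 0L
  for (u in universe) {
    in_study <- any(vapply(study, identical, logical(1), u))
    in_ref <- any(vapply(reference, identical, logical(1), u))
    if (in_study && in_ref) a <- a + 1L
    else if (in_study) b <- b + 1L
    else if (in_ref) c <- c + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c, d = d)
}

# sort-and-index linear-interpolation percentile, written independently of
# stats::quantile: h = (n - 1) p + 1, interpolate between order statistics
brute_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# exhaustive enumeration of the four joint (disease, classification) outcomes
enum_predictive <- function(se, sp, p) {
  pr <- c(tp = p * se, fn = p * (1 - se),
          fp = (1 - p) * (1 - sp), tn = (1 - p) * sp)
  list(ppv = pr[["tp"]] / (pr[["tp"]] + pr[["fp"]]),
       npv = pr[["tn"]] / (pr[["tn"]] + pr[["fn"]]))
}

# label factory: distinct indicator tokens
toks <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

make_scale <- function(indicators, disease = "d", name = "scale",
                       year = 2000L) {
  severity_scale(disease, name, year, indicators)
}

make_study <- function(endpoints, id = "s1", disease = "d",
                       sample_size = NA) {
  study_endpoints(disease, id, endpoints, sample_size = sample_size)
}

# random printable label that survives normalization (>= 1 alnum character)
random_label <- function() {
  pool <- c(letters, LETTERS, 0:9, " ", "-", "_", ".", ",", "(", ")", "/")
  repeat {
    s <- paste(sample(pool, sample(1:20, 1), replace = TRUE), collapse = "")
    if (grepl("[[:alnum:]]", s)) return(s)
  }
}

# a random feasible synthetic spec: targets chosen on the integer lattice
random_feasible_spec <- function(seed) {
  set.seed(seed)
  n_scales <- sample(1:3, 1)
  sizes <- sample(3:12, n_scales, replace = TRUE)
  shared <- if (n_scales > 1) {
    vapply(seq_len(n_scales - 1), function(i) {
      sample(0:min(sizes[i + 1] - 1, sizes[1]), 1)
    }, integer(1))
  } else integer(0)
  R <- sizes[1]
  E <- sample(1:15, 1)
  n_studies <- sample(1:6, 1)
  a <- sample(0:R, n_studies, replace = TRUE)
  b <- sample(0:E, n_studies, replace = TRUE)
  synthetic_spec(
    disease = sprintf("disease %d", seed),
    scale_sizes = sizes, shared_with_previous = shared,
    target_sensitivity = a / R, target_specificity = (E - b) / E,
    n_studies = n_studies, universe_extra_count = E,
    sample_sizes = sample(c(NA, 10:80), n_studies, replace = TRUE),
    seed = seed, strict = TRUE
  )
}
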