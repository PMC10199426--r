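# internal helpers shared across modules

abort2 <- function(msg, class) {
  rlang::abort(msg, class = c(class, "neutrality_error"))
}

# run `expr` under `seed` without disturbing the caller's RNG state
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# deterministic substream seed: polynomial string hash folded with the master
# seed, kept inside the 32-bit integer range so set.seed() accepts it.
# adding a study/prevalence never perturbs another substream's draws.
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 + h) %% 2147483629)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_scalar_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
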