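#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of a simulation draw their random numbers from a
#' seed derived deterministically from the run's master seed and a stage
#' name, so that changing the configuration of one stage never perturbs the
#' draws of another.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"layout"`, `"counts"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.numeric(master) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Largest-remainder apportionment of n items to named proportions.
# Deterministic; ties broken by descending remainder then name order.
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1", call. = FALSE)
  raw <- n * proportions
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-rem, names(proportions))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

# Round half up to the nearest integer (used when fold-scaling counts).
round_half_up <- function(x) floor(x + 0.5)

# Fold-scale counts, preserving integer storage when the input had it.
fold_scale <- function(x, fold, as_int) {
  out <- round_half_up(x * fold)
  if (as_int) {
    o <- as.integer(out)
    attributes(o) <- attributes(out)
    o
  } else out
}

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
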