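# Internal helpers shared across modules.

#' Run code under a temporary RNG state
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG
#' state, so seeded package functions never perturb the user's stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as_seed(seed, "seed")
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
  set.seed(seed)
  expr
}

# Deterministic per-stage sub-seed derived from one global seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  seed <- as_seed(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

as_seed <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x)) {
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  }
  as.integer(x %% 2147483647)
}

# Fail with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
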