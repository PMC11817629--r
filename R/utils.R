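# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded operations do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministically derive `n` child seeds from one master seed.
# Seeds stay below 2^31 so they are representable as R integers.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      x != as.integer(x) || x < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_fraction <- function(x, field, open_left = FALSE, open_right = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop_field(field, "must be a single number")
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop_field(field, sprintf("must lie in %s0, 1%s",
                              if (open_left) "(" else "[",
                              if (open_right) ")" else "]"))
  }
  as.numeric(x)
}
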