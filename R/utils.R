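#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' then restores the previous RNG state so callers' random streams are
#' unaffected. All stochastic entry points in the package route their
#' seeding through this helper, which is what makes same-seed runs
#' byte-identical.
#'
#' @param seed Integer seed, or `NULL` to run without touching the RNG.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-block child seed from a base seed; kept well below 2^31.
child_seed <- function(seed, index) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(index)
}
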