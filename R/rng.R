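# Seed handling: every stochastic function takes an explicit seed and runs
# under a locally scoped RNG state, so nothing in the package perturbs (or
# depends on) the caller's global stream.

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `code`, and restores the previous state on exit. With `seed = NULL` the
#' code runs on the ambient stream.
#'
#' @param seed integer seed, or `NULL` for no local seeding.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed from a parent seed and a stage tag, so the
# stages of one study draw from distinct but reproducible streams.
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483647
  }
  s <- ((as.double(seed) %% 2147483647) * 48271 + h) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}
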