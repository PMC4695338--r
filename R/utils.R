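#' Derive a reproducible sub-seed for a named stage
#'
#' Expands one global seed into independent per-stage seeds so that, for
#' example, the MIC reference and a new-MAC sample drawn under the same run
#' seed use different random streams, while each stream stays reproducible
#' when other parts of a configuration change.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"wgs_MIC"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

# run `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_param <- function(...) stop(..., call. = FALSE)

# scalar checks used across constructors
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param(name, " must be a single value in [0, 1]")
  x
}
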