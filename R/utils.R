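#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic mixing of a master seed with a small stage offset, kept
#' below 2^31 so the result is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param stage Small integer identifying the pipeline stage.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage = 0L) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(stage) * 16807 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
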