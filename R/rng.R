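#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline (genome generation, modification
#' placement, digestion, read emission) draws its own RNG stream from a
#' single integer master seed combined with the stage name.  Stages are
#' therefore reorderable and independently reproducible: re-running one
#' stage never perturbs another's draws.
#'
#' The derivation is a small multiplicative hash over the stage name,
#' folded with the master seed modulo 2^31 - 1, so results are identical
#' across platforms and fit in a 32-bit integer as required by
#' [set.seed()].
#'
#' @param master Integer master seed (any finite number; used modulo
#'   2^31 - 1).
#' @param stage Character scalar naming the stage, e.g. `"genome"`,
#'   `"modify"`, `"digest"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "digest")
#' derive_seed(42, "genome") != derive_seed(42, "digest")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% m
  # doubles are exact below 2^53; (m-1) * 48271 ~ 1e14 stays well inside
  as.integer(((abs(master) %% m) * 48271 + h) %% m)
}

# Run an expression under a stage-derived seed without disturbing the
# caller's RNG state.
with_stage_seed <- function(master, stage, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(derive_seed(master, stage))
  expr
}
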