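# RNG plumbing shared by every stochastic stage.
#
# All user-facing functions take an explicit `seed`; the global RNG state is
# saved and restored so package calls never perturb a user's stream. A master
# seed fans out to per-stage sub-seeds through a fixed affine map so that a
# whole run is reproducible from one integer.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Fixed affine derivation modulo a prime below 2^31, so per-stage seeds
#' (per-phase SOMs, second-stage SOM, CV repeats, ...) are decorrelated but
#' fully determined by the master seed.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483629 * 48271 + offset) %% 2147483629)
}
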