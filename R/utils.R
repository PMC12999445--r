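#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded generator calls never perturb an enclosing
#' simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  expr
}

# deterministic sub-seed derivation, kept well below 2^31
derive_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000000L) * 1009L + (as.integer(salt) %% 1009L)
}

clamp01 <- function(x) {
  # keeps dims (pmin/pmax with a scalar first argument would drop them)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Per-pixel luminance of an RGB array
#' @param pixels H x W x 3 array in \[0,1\].
#' @return H x W matrix.
#' @keywords internal
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

stop_domain <- function(...) stop(..., call. = FALSE)
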