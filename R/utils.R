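#' @useDynLib idrbind, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
NULL

# Boltzmann constant in kJ/mol/K and Coulomb constant in kJ mol^-1 nm e^-2
.kB <- 0.0083144626
.kCoulomb <- 138.935458
.NAvogadro <- 6.02214076e23

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators are pure
#' functions of their arguments and do not disturb the caller's stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index, kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + 97 * as.double(stream)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
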