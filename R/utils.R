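`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the current RNG state, seeds, evaluates `code`, restores the state.
#' Used so that generators and bootstrap routines are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed, or NULL to run without touching the RNG.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Fisher z-transform of a correlation coefficient
#'
#' @param r correlation in (-1, 1).
#' @return atanh(r).
#' @export
fisher_z <- function(r) atanh(r)

#' Inverse Fisher z-transform
#' @param z Fisher-transformed correlation.
#' @return tanh(z).
#' @export
fisher_z_inv <- function(z) tanh(z)

# Legendre polynomials P1, P2 on u in [-1, 1]; used for scanner drift.
legendre_basis <- function(n) {
  u <- seq(-1, 1, length.out = n)
  cbind(p1 = u, p2 = 0.5 * (3 * u^2 - 1))
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Frame time stamps: frame i (1-based) is stamped at (i-1) * tr.
frame_times <- function(n_frames, tr) (seq_len(n_frames) - 1) * tr
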