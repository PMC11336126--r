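# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their `seed` argument and never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

stop_invalid <- function(...) stop("invalid-argument: ", ..., call. = FALSE)
stop_quality <- function(...) stop("data-quality: ", ..., call. = FALSE)

# Remove the channel mean (average reference) from a map vector or from each
# row of a maps matrix.
demean_map <- function(m) {
  if (is.matrix(m)) m - rowMeans(m) else m - mean(m)
}

# Unit-normalize rows of a matrix (or a single vector); zero-norm rows error.
unit_norm <- function(m) {
  if (is.matrix(m)) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm < 1e-12)) stop_invalid("cannot normalize zero-norm map")
    m / nrm
  } else {
    nrm <- sqrt(sum(m^2))
    if (nrm < 1e-12) stop_invalid("cannot normalize zero-norm map")
    m / nrm
  }
}

# First principal axis of a set of maps (rows), i.e. the unit vector t
# maximizing sum_i (m_i . t)^2.  Polarity-proof centroid estimator: sign
# flips of member maps leave the scatter matrix unchanged.
principal_axis <- function(scatter) {
  v <- eigen(scatter, symmetric = TRUE)$vectors[, 1L]
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop_invalid("degenerate principal axis")
  v / nrm
}
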