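# Internal helpers shared across modules.

.ordcfa_env <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes on [0, 1], cached
#' @noRd
gl_nodes <- function(n = 64L) {
  key <- paste0("gl", n)
  if (is.null(.ordcfa_env[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .ordcfa_env[[key]] <- list(x = gl$x, w = gl$w)
  }
  .ordcfa_env[[key]]
}

#' Deterministic child seed derivation
#'
#' Derives a reproducible 31-bit child seed from a master seed and one or more
#' integer indices, so that every cell/replication of a study can be re-run in
#' isolation and results do not depend on scheduling order.
#'
#' @param master master seed (integer)
#' @param ... integer indices (cell index, replication index, ...)
#' @return a single integer in [1, 2^31 - 2]
#' @export
child_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    # multiplicative-congruential style mixing, kept in double-safe range
    h <- (h * 48271 + as.double(k) * 12345 + 1) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Lower-triangle (column-major) index pairs for a p x p matrix:
# (2,1),(3,1),...,(p,1),(3,2),...,(p,p-1). This is the single vectorization
# order used everywhere in the package (it matches m[lower.tri(m)]).
lower_tri_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# Assemble a symmetric correlation matrix from its lower-triangle vector.
vec_to_corr <- function(r, p) {
  m <- diag(p)
  m[lower.tri(m)] <- r
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
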