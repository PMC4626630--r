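# Shared fixtures and oracles, all built in code.

# Exact polychoric result from a known truth (identity ACM): feeding the
# implied correlations back through the fit must recover the parameters.
perfect_polychoric <- function(loadings, xi, n = 1000L) {
  r <- implied_rho(loadings, xi)
  structure(list(r = r, R = implied_sigma(loadings, xi), acm = diag(45),
                 acm_pd = TRUE, all_converged = TRUE, boundary = FALSE,
                 n = n),
            class = "polychoric_result")
}

# Brute-force grid-search maximizer of the pairwise contingency-table
# likelihood (independent oracle for polychoric_pair).
grid_polychoric <- function(counts, tau1, tau2, step = 1e-4) {
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(rho) {
    a <- c(-Inf, tau1, Inf); b <- c(-Inf, tau2, Inf)
    k1 <- length(tau1) + 1L; k2 <- length(tau2) + 1L
    P <- matrix(pbinorm(rep(a, k2 + 1L), rep(b, each = k1 + 1L), rho),
                k1 + 1L, k2 + 1L)
    pi <- P[-1, -1] - P[-(k1 + 1L), -1] - P[-1, -(k2 + 1L)] +
      P[-(k1 + 1L), -(k2 + 1L)]
    sum(counts[counts > 0] * log(pmax(pi[counts > 0], 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# Minimal records table for the metrics module.
make_records <- function(est, lower, upper, se = NA_real_,
                         converged = TRUE, admissible = TRUE,
                         method = "RULS", dist = "normal",
                         xi_true = 0.5, n = 100L) {
  k <- length(est)
  data.frame(dist = dist, xi_true = xi_true, n = n, method = method,
             rep = seq_len(k), est = est, se = rep_len(se, k),
             lower = lower, upper = upper,
             converged = rep_len(converged, k),
             admissible = rep_len(admissible, k))
}

# Deterministic empty dataset (prior-only sampling).
empty_dataset <- function() {
  structure(list(responses = matrix(integer(0), 0, 10,
                                    dimnames = list(NULL, paste0("item", 1:10))),
                 n = 0L, spec = NULL, seed = NULL),
            class = "ordinal_dataset")
}

# Cache for expensive acceptance-scale simulation runs shared across
# test blocks (computed once per test session).
.acc_cache <- new.env(parent = emptyenv())

acc_cell_run <- function(key, xi, n, methods, R, master = 42L, cell = 1L,
                         dist = "normal") {
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  des <- study_design(distributions = dist, xi_values = xi,
                      sample_sizes = n, methods = methods,
                      replications = R, master_seed = master)
  .acc_cache[[key]] <- run_cell(des, dist, xi, n, cell_index = cell)
  .acc_cache[[key]]
}
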