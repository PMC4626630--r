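# Two-step polychoric estimation (Joreskog-style): thresholds from marginal
# frequencies, then each pairwise correlation by maximizing the bivariate
# normal contingency-table likelihood with thresholds held fixed. The
# asymptotic covariance matrix (ACM) of the 45 polychoric correlations is
# estimated from the stacked estimating functions of the two-step procedure
# (outer-product "meat", sandwiched through the block-triangular Jacobian),
# so threshold estimation error propagates into the ACM.

#' Estimate item thresholds from marginal frequencies
#'
#' \code{tau_k} is the standard normal quantile of the cumulative proportion
#' through category k. Empty categories are collapsed (leading/trailing ones
#' dropped, interior ones merged with the category below) so the returned
#' thresholds are strictly increasing over the observed categories; the
#' returned map records the recoding.
#'
#' @param column integer vector of categories in 1..n_categories
#' @param n_categories number of nominal categories
#' @return list with \code{tau} (increasing vector of length k-1 over the k
#'   observed categories), \code{map} (recode of nominal to effective
#'   category), \code{k} (number of effective categories), and
#'   \code{collapsed} (flag)
#' @export
estimate_thresholds <- function(column, n_categories = 4L) {
  counts <- tabulate(column, nbins = n_categories)
  nonzero <- counts > 0L
  if (sum(nonzero) < 2L)
    stop("degenerate column: fewer than two observed categories")
  # map nominal category -> effective category (empty cats merge downward;
  # a leading run of empties merges upward into the first observed one)
  map <- cumsum(nonzero)
  map[map == 0L] <- 1L
  k <- max(map)
  eff_counts <- as.vector(tapply(counts, map, sum))
  cum <- cumsum(eff_counts) / sum(eff_counts)
  tau <- stats::qnorm(cum[seq_len(k - 1L)])
  list(tau = tau, map = map, k = k, collapsed = any(!nonzero))
}

# Rectangle cell probabilities for a k1 x k2 table given thresholds and rho.
# Returns list(pi = cell probabilities, dpi = d pi / d rho).
cell_probs <- function(tau1, tau2, rho, want_deriv = TRUE) {
  a <- c(-Inf, tau1, Inf)
  b <- c(-Inf, tau2, Inf)
  k1 <- length(tau1) + 1L
  k2 <- length(tau2) + 1L
  gh <- rep(a, times = k2 + 1L)
  gk <- rep(b, each = k1 + 1L)
  P <- matrix(pbinorm(gh, gk, rho), k1 + 1L, k2 + 1L)
  pi <- P[-1, -1] - P[-(k1 + 1L), -1] - P[-1, -(k2 + 1L)] +
    P[-(k1 + 1L), -(k2 + 1L)]
  out <- list(pi = pi)
  if (want_deriv) {
    D <- matrix(dbinorm(gh, gk, rho), k1 + 1L, k2 + 1L)
    out$dpi <- D[-1, -1] - D[-(k1 + 1L), -1] - D[-1, -(k2 + 1L)] +
      D[-(k1 + 1L), -(k2 + 1L)]
  }
  out
}

# Contingency-table log-likelihood in rho (thresholds fixed).
table_loglik <- function(rho, tau1, tau2, counts) {
  pi <- cell_probs(tau1, tau2, rho, want_deriv = FALSE)$pi
  sum(counts[counts > 0] * log(pmax(pi[counts > 0], 1e-300)))
}

#' Pairwise polychoric correlation with fixed thresholds
#'
#' Maximizes the bivariate-normal cell-probability likelihood of the
#' two-way contingency table over rho alone (second step of the two-step
#' procedure). The estimate is constrained to [-0.999, 0.999]; hits of that
#' bound are flagged.
#'
#' @param x,y integer category vectors of equal length (already recoded to
#'   effective categories)
#' @param tau_x,tau_y fixed thresholds from \code{\link{estimate_thresholds}}
#' @param bound box constraint for |rho|
#' @return list with \code{rho}, \code{boundary} flag, \code{converged} flag,
#'   and the contingency \code{table}
#' @export
polychoric_pair <- function(x, y, tau_x, tau_y, bound = 0.999) {
  stopifnot(length(x) == length(y))
  k1 <- length(tau_x) + 1L
  k2 <- length(tau_y) + 1L
  counts <- table(factor(x, levels = seq_len(k1)),
                  factor(y, levels = seq_len(k2)))
  counts <- matrix(as.numeric(counts), k1, k2)
  if (sum(counts) == 0) stop("empty contingency table")
  opt <- tryCatch(
    stats::optimize(table_loglik, c(-bound, bound), tau1 = tau_x,
                    tau2 = tau_y, counts = counts, maximum = TRUE,
                    tol = 1e-8),
    error = function(e) NULL)
  if (is.null(opt))
    return(list(rho = NA_real_, boundary = FALSE, converged = FALSE,
                table = counts))
  rho <- opt$maximum
  # optimize() never returns the exact interval ends; snap near-bound optima
  if (bound - abs(rho) < 1e-4) {
    if (table_loglik(sign(rho) * bound, tau_x, tau_y, counts) >= opt$objective)
      rho <- sign(rho) * bound
  }
  list(rho = rho, boundary = (bound - abs(rho)) < 1e-6, converged = TRUE,
       table = counts)
}

# Score matrix s_ab = (d pi_ab / d rho) / pi_ab for one pair.
score_matrix <- function(tau1, tau2, rho) {
  cp <- cell_probs(tau1, tau2, rho)
  cp$dpi / pmax(cp$pi, 1e-300)
}

#' Polychoric correlations and ACM for an ordinal dataset
#'
#' Runs the full two-step estimation over all 45 item pairs and (optionally)
#' estimates the asymptotic covariance matrix Gamma of the polychoric
#' correlation vector. Gamma is on the scale of \code{sqrt(n) * (r - rho)}
#' (i.e. it estimates \code{n * Cov(r)}); consumers divide by \code{n}.
#'
#' @param dataset an \code{\link{ordinal_dataset}}
#' @param acm compute the ACM? (needed for WLS/DWLS weighting and all
#'   robust standard errors)
#' @param acm_method \code{"score"} (default): outer product of the
#'   per-observation pairwise-likelihood scores with thresholds held fixed,
#'   matching the two-step convention in which correlations are estimated
#'   "holding the thresholds constant". \code{"score-adjusted"}: full
#'   two-step sandwich additionally propagating threshold-estimation error
#'   through the block-triangular Jacobian. \code{"jackknife"}: delete-one
#'   re-estimation (slow; cross-checking only).
#' @return object of class \code{polychoric_result} with fields
#'   \code{thresholds} (per-item list), \code{r} (45-vector, column-major
#'   lower triangle), \code{R} (10 x 10 matrix), \code{acm}, \code{acm_pd},
#'   \code{boundary} (any pair at the rho bound), \code{all_converged},
#'   \code{n}
#' @export
polychoric <- function(dataset, acm = TRUE,
                       acm_method = c("score", "score-adjusted", "jackknife")) {
  acm_method <- match.arg(acm_method)
  Y <- dataset$responses
  n <- nrow(Y)
  p <- ncol(Y)
  marg <- lapply(seq_len(p), function(j) estimate_thresholds(Y[, j]))
  # recode to effective categories
  Z <- Y
  for (j in seq_len(p)) Z[, j] <- marg[[j]]$map[Y[, j]]
  pairs <- lower_tri_pairs(p)
  np <- nrow(pairs)
  r <- numeric(np)
  boundary <- logical(np)
  conv <- logical(np)
  tabs <- vector("list", np)
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    pr <- polychoric_pair(Z[, i], Z[, j], marg[[i]]$tau, marg[[j]]$tau)
    r[q] <- pr$rho; boundary[q] <- pr$boundary; conv[q] <- pr$converged
    tabs[[q]] <- pr$table
  }
  res <- structure(
    list(thresholds = lapply(marg, `[[`, "tau"),
         margins = marg, r = r, R = vec_to_corr(r, p),
         acm = NULL, acm_pd = NA, boundary = any(boundary),
         boundary_pairs = boundary, all_converged = all(conv),
         pair_converged = conv, n = n, pairs = pairs),
    class = "polychoric_result")
  if (acm && all(conv)) {
    res$acm <- switch(acm_method,
                      "score" = acm_score(Z, marg, r, pairs, tabs,
                                          adjust = FALSE),
                      "score-adjusted" = acm_score(Z, marg, r, pairs, tabs,
                                                   adjust = TRUE),
                      "jackknife" = acm_jackknife(dataset))
    res$acm_pd <- is_pd(res$acm)
  }
  res
}

#' @export
print.polychoric_result <- function(x, ...) {
  cat(sprintf("Polychoric estimates: %d items, n = %d\n", ncol(x$R), x$n))
  cat(sprintf("  correlations in [%.3f, %.3f]%s\n", min(x$r), max(x$r),
              if (x$boundary) " (boundary hit)" else ""))
  if (!is.null(x$acm))
    cat("  ACM:", nrow(x$acm), "x", ncol(x$acm),
        if (isTRUE(x$acm_pd)) "(positive definite)" else "(NOT positive definite)", "\n")
  invisible(x)
}

is_pd <- function(m) {
  if (is.null(m) || anyNA(m) || any(!is.finite(m))) return(FALSE)
  !inherits(tryCatch(chol(m), error = function(e) e), "error")
}

#' Score-based ACM of the two-step polychoric estimates
#'
#' Builds per-observation estimating-function contributions and forms the
#' sandwich \code{A^\{-1\} B A^\{-T\}} with \code{B} the empirical outer
#' product and \code{A} the mean Jacobian; the returned 45 x 45 block is the
#' ACM of \code{sqrt(n) (r - rho)}. With \code{adjust = FALSE} the
#' estimating functions are the pairwise-likelihood scores in rho with
#' thresholds treated as fixed (A is then diagonal); with
#' \code{adjust = TRUE} the threshold equations
#' \code{1\{y_i <= k\} - Phi(tau_ik)} are stacked as well and A is block
#' lower-triangular, propagating first-step estimation error.
#'
#' @note With fewer observations than estimating functions (e.g. n = 42 <
#'   45 correlations) \code{B} is rank-deficient and the ACM cannot be
#'   positive definite, which is what makes full-weight WLS infeasible at
#'   the smallest sample size.
#' @noRd
acm_score <- function(Z, marg, r, pairs, tabs, adjust = FALSE) {
  n <- nrow(Z)
  p <- ncol(Z)
  np <- nrow(pairs)
  h <- 1e-5
  ntau <- vapply(marg, function(m) m$k - 1L, integer(1))
  tau_off <- c(0L, cumsum(ntau))      # offsets into the threshold block
  qtau <- if (adjust) sum(ntau) else 0L
  G <- matrix(0, n, qtau + np)
  dtau <- numeric(qtau)
  if (adjust) {
    for (j in seq_len(p)) {
      tau <- marg[[j]]$tau
      for (k in seq_along(tau)) {
        G[, tau_off[j] + k] <- (Z[, j] <= k) - stats::pnorm(tau[k])
        dtau[tau_off[j] + k] <- -stats::dnorm(tau[k])
      }
    }
  }
  drho <- numeric(np)
  C <- if (adjust) matrix(0, np, qtau)  # d mean rho-score / d tau
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    ti <- marg[[i]]$tau; tj <- marg[[j]]$tau
    S <- score_matrix(ti, tj, r[q])
    G[, qtau + q] <- S[cbind(Z[, i], Z[, j])]
    w <- tabs[[q]] / n                # empirical cell proportions
    drho[q] <- sum(w * (score_matrix(ti, tj, r[q] + h) -
                          score_matrix(ti, tj, r[q] - h))) / (2 * h)
    if (adjust) {
      for (k in seq_along(ti)) {
        tp <- ti; tp[k] <- tp[k] + h
        tm <- ti; tm[k] <- tm[k] - h
        C[q, tau_off[i] + k] <-
          sum(w * (score_matrix(tp, tj, r[q]) - score_matrix(tm, tj, r[q]))) / (2 * h)
      }
      for (k in seq_along(tj)) {
        tp <- tj; tp[k] <- tp[k] + h
        tm <- tj; tm[k] <- tm[k] - h
        C[q, tau_off[j] + k] <-
          sum(w * (score_matrix(ti, tp, r[q]) - score_matrix(ti, tm, r[q]))) / (2 * h)
      }
    }
  }
  B <- crossprod(G) / n
  # A^{-1} rows for the rho block; A is diagonal (fixed thresholds) or block
  # lower-triangular: [ -Drho^{-1} C Dtau^{-1} , Drho^{-1} ]
  M <- if (adjust)
    cbind(-sweep(C, 2, dtau, "/") / drho, diag(1 / drho, np))
  else
    diag(1 / drho, np)
  Gam <- M %*% B %*% t(M)
  (Gam + t(Gam)) / 2
}

#' Estimate the ACM for an existing polychoric result
#'
#' Standalone entry to the ACM stage: given a dataset and its polychoric
#' estimates (computed if not supplied), returns the result augmented with
#' the asymptotic covariance matrix and its positive-definiteness flag.
#' Non-positive-definiteness is a recorded state, not an error -- it is
#' what makes full-weight WLS infeasible downstream.
#'
#' @param dataset an \code{\link{ordinal_dataset}}
#' @param result a \code{polychoric_result} for \code{dataset} (without
#'   ACM); estimated afresh when omitted
#' @param acm_method see \code{\link{polychoric}}
#' @return the \code{polychoric_result} with \code{acm} and \code{acm_pd}
#' @export
estimate_acm <- function(dataset, result = NULL,
                         acm_method = c("score", "score-adjusted",
                                        "jackknife")) {
  acm_method <- match.arg(acm_method)
  full <- polychoric(dataset, acm = TRUE, acm_method = acm_method)
  if (is.null(result)) return(full)
  result$acm <- full$acm
  result$acm_pd <- full$acm_pd
  result
}

#' Jackknife ACM (delete-one re-estimation of all pairs)
#' @noRd
acm_jackknife <- function(dataset) {
  Y <- dataset$responses
  n <- nrow(Y)
  est_r <- function(Y) {
    d <- ordinal_dataset(Y)
    polychoric(d, acm = FALSE)$r
  }
  R <- t(vapply(seq_len(n), function(t) est_r(Y[-t, , drop = FALSE]),
                numeric(45)))
  Rbar <- colMeans(R)
  Rc <- sweep(R, 2, Rbar, "-")
  # jackknife Cov(r) = (n-1)/n * sum of squared deviations; scale by n
  n * ((n - 1) / n) * crossprod(Rc)
}

#' Serialize a polychoric result to JSON
#'
#' @param result a \code{polychoric_result}
#' @param path output path
#' @export
write_polychoric <- function(result, path) {
  jsonlite::write_json(
    list(thresholds = result$thresholds, r = result$r,
         acm = result$acm, acm_pd = result$acm_pd,
         boundary = result$boundary, all_converged = result$all_converged,
         n = result$n),
    path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}
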