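# Least-squares and ML fitting of the two-factor CFA to the polychoric
# correlations, with ACM-based sandwich standard errors and Fisher-z
# confidence intervals for the factor correlation.
#
# Methods (weight V in F = [r - rho(theta)]' V [r - rho(theta)]):
#   WLS   full inverse ACM (requires a positive definite ACM)
#   RDWLS diagonal of the inverse ACM for point estimation, full ACM for SEs
#   RULS  identity weight, full ACM for SEs
#   RML   ML discrepancy on the polychoric matrix, ACM sandwich SEs

PAR_BOUND <- 0.999

#' Jacobian of the implied correlation vector
#'
#' Analytic 45 x 11 matrix of derivatives of \code{\link{implied_rho}} with
#' respect to (lambda_1..lambda_10, xi).
#'
#' @inheritParams implied_sigma
#' @return 45 x 11 matrix
#' @export
rho_jacobian <- function(loadings, xi) {
  pairs <- lower_tri_pairs(10)
  f <- rep(1:2, each = 5)
  D <- matrix(0, nrow(pairs), 11)
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    cf <- if (f[i] == f[j]) 1 else xi
    D[q, i] <- loadings[j] * cf
    D[q, j] <- loadings[i] * cf
    if (f[i] != f[j]) D[q, 11] <- loadings[i] * loadings[j]
  }
  D
}

#' Least-squares discrepancy
#'
#' The quadratic form \code{[r - rho(theta)]' V [r - rho(theta)]}.
#'
#' @param r 45-vector of sample polychoric correlations
#' @param loadings,xi structural parameters
#' @param V 45 x 45 positive (semi-)definite weight matrix
#' @return nonnegative scalar
#' @export
cfa_discrepancy <- function(r, loadings, xi, V) {
  if (length(r) != nrow(V) || length(r) != ncol(V))
    stop("dimension mismatch between r and V")
  e <- r - implied_rho(loadings, xi)
  drop(crossprod(e, V %*% e))
}

# ML discrepancy on the correlation matrix R: log det Sigma - log det R +
# tr(R Sigma^-1) - p; gradient via chain rule through the off-diagonals.
ml_discrepancy <- function(R, logdetR, loadings, xi) {
  S <- implied_sigma(loadings, xi)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(list(value = Inf, grad = NULL))
  Si <- chol2inv(ch)
  val <- 2 * sum(log(diag(ch))) - logdetR + sum(Si * R) - nrow(R)
  W <- Si - Si %*% R %*% Si          # dF/dSigma (full-matrix convention)
  g_rho <- 2 * W[lower.tri(W)]       # symmetric off-diagonal perturbations
  list(value = val, grad = g_rho)
}

#' Sandwich covariance of the structural parameters
#'
#' \code{(D'VD)^-1 D'V Gamma V D (D'VD)^-1 / n}, with \code{Gamma} on the
#' \code{sqrt(n)} scale produced by \code{\link{polychoric}}. When
#' \code{V = Gamma^-1} this collapses to \code{(D' Gamma^-1 D)^-1 / n}.
#'
#' @param delta 45 x k Jacobian of the implied correlations
#' @param V weight matrix used for estimation
#' @param gamma ACM of \code{sqrt(n) (r - rho)}
#' @param n sample size
#' @return k x k covariance matrix
#' @export
sandwich_cov <- function(delta, V, gamma, n) {
  bread <- solve(crossprod(delta, V %*% delta))
  meat <- crossprod(delta, V %*% gamma %*% V %*% delta)
  (bread %*% meat %*% bread) / n
}

#' Sandwich standard errors of the structural parameters
#'
#' Square roots of the diagonal of \code{\link{sandwich_cov}}; a singular
#' bread matrix is an error (callers record the fit as non-converged).
#'
#' @inheritParams sandwich_cov
#' @return vector of per-parameter standard errors
#' @export
sandwich_se <- function(delta, V, gamma, n) {
  covm <- tryCatch(sandwich_cov(delta, V, gamma, n),
                   error = function(e) stop("singular bread matrix"))
  sqrt(pmax(diag(covm), 0))
}

#' Fisher-z confidence interval for a correlation
#'
#' \code{z = atanh(xi)}, \code{se_z = se / (1 - xi^2)}, endpoints mapped back
#' through \code{tanh} so they always lie inside (-1, 1).
#'
#' @param xi point estimate, |xi| < 1
#' @param se standard error of xi
#' @param level confidence level
#' @return named vector \code{c(lower, upper)}
#' @export
fisher_z_interval <- function(xi, se, level = 0.95) {
  if (abs(xi) >= 1) stop("Fisher-z interval undefined for |xi| >= 1")
  if (se < 0) stop("negative standard error")
  z <- atanh(xi)
  se_z <- se / (1 - xi^2)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se_z), upper = tanh(z + q * se_z))
}

#' Fit the two-factor ordinal CFA to polychoric correlations
#'
#' Minimizes the selected discrepancy over the 10 loadings and the factor
#' correlation (box-constrained quasi-Newton), computes ACM sandwich
#' standard errors, the Fisher-z interval for the factor correlation, and
#' classifies convergence and admissibility. Parameters pinned at the box
#' bound (|.| = 0.999) indicate a Heywood-type solution and are classified
#' inadmissible.
#'
#' The confidence interval for the factor correlation uses Fisher's z
#' transformation. By default (\code{se = "fisherz"}) the z-scale standard
#' error is the classical \code{1 / sqrt(n - 3)}, i.e.
#' \code{se_xi = (1 - xi_hat^2) / sqrt(n - 3)} on the correlation scale --
#' the convention behind standard SEM software output for correlation
#' intervals, which ignores the uncertainty of the loading estimates and is
#' therefore anti-conservative. \code{se = "sandwich"} instead propagates the
#' ACM through the fit (robust sandwich); both SEs are always stored.
#'
#' @param pc a \code{\link{polychoric_result}} with ACM
#' @param n sample size of the underlying data
#' @param method one of \code{"WLS"}, \code{"RDWLS"}, \code{"RULS"},
#'   \code{"RML"}
#' @param level confidence level of the Fisher-z interval
#' @param se which standard error feeds the interval (see Details)
#' @param start optional starting values (length 11)
#' @param maxit iteration cap
#' @return object of class \code{cfa_fit}
#' @export
cfa_fit <- function(pc, n = pc$n, method = c("WLS", "RDWLS", "RULS", "RML"),
                    level = 0.95, se = c("fisherz", "sandwich"),
                    start = NULL, maxit = 500L) {
  method <- match.arg(method)
  se <- match.arg(se)
  failed <- function(reason) {
    structure(list(method = method, loadings = rep(NA_real_, 10),
                   xi = NA_real_, se_xi = NA_real_,
                   se_xi_sandwich = NA_real_,
                   ci = c(lower = NA_real_, upper = NA_real_),
                   converged = FALSE, admissible = FALSE, reason = reason,
                   discrepancy = NA_real_, iterations = 0L, n = n,
                   level = level),
              class = "cfa_fit")
  }
  if (!pc$all_converged) return(failed("polychoric-failure"))
  gamma <- pc$acm
  if (is.null(gamma)) stop("polychoric result has no ACM; rerun with acm = TRUE")
  if (method == "WLS" && !isTRUE(pc$acm_pd)) return(failed("acm-not-pd"))
  r <- pc$r
  R <- pc$R
  if (method == "RML") {
    chR <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(chR)) return(failed("pcm-not-pd"))
    logdetR <- 2 * sum(log(diag(chR)))
  }
  V <- switch(method,
              WLS = tryCatch(chol2inv(chol(gamma)), error = function(e) NULL),
              RDWLS = diag(1 / diag(gamma)),
              RULS = diag(45),
              RML = NULL)
  if (method == "WLS" && is.null(V)) return(failed("acm-not-pd"))

  if (is.null(start)) {
    # scale-aware deterministic starts: mean within-block correlation gives a
    # crude common loading, the cross-block mean then implies xi
    pairs <- lower_tri_pairs(10)
    f <- rep(1:2, each = 5)
    same <- f[pairs[, 1]] == f[pairs[, 2]]
    lam_bar <- sqrt(max(mean(r[same]), 0.01))
    xi0 <- mean(r[!same]) / lam_bar^2
    start <- c(rep(0.5, 10), max(min(xi0, 0.9), -0.9))
  }

  if (method == "RML") {
    objfn <- function(par) {
      ml_discrepancy(R, logdetR, par[1:10], par[11])$value
    }
    grfn <- function(par) {
      md <- ml_discrepancy(R, logdetR, par[1:10], par[11])
      if (is.null(md$grad)) return(rep(0, 11))
      drop(crossprod(rho_jacobian(par[1:10], par[11]), md$grad))
    }
  } else {
    objfn <- function(par) cfa_discrepancy(r, par[1:10], par[11], V)
    grfn <- function(par) {
      e <- r - implied_rho(par[1:10], par[11])
      drop(-2 * crossprod(rho_jacobian(par[1:10], par[11]), V %*% e))
    }
  }
  opt <- tryCatch(
    stats::optim(start, objfn, grfn, method = "L-BFGS-B",
                 lower = rep(-PAR_BOUND, 11), upper = rep(PAR_BOUND, 11),
                 control = list(maxit = maxit, factr = 1e2)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value))
    return(failed("optimizer-failure"))
  par <- opt$par
  g <- grfn(par)
  # projected gradient: at an active bound only the inward direction counts
  at_lo <- par <= -PAR_BOUND + 1e-12
  at_hi <- par >= PAR_BOUND - 1e-12
  g_proj <- g
  g_proj[at_lo & g > 0] <- 0
  g_proj[at_hi & g < 0] <- 0
  converged <- opt$convergence == 0 &&
    max(abs(g_proj)) < 1e-5 * (1 + abs(opt$value))
  lam_hat <- par[1:10]
  xi_hat <- par[11]

  fit <- structure(
    list(method = method, loadings = lam_hat, xi = xi_hat,
         se_xi = NA_real_, se_xi_sandwich = NA_real_,
         ci = c(lower = NA_real_, upper = NA_real_),
         converged = converged, admissible = FALSE, reason = NULL,
         discrepancy = opt$value,
         iterations = unname(opt$counts["function"]), n = n, level = level),
    class = "cfa_fit")
  fit <- classify_fit(fit, pc)
  if (!fit$converged || !fit$admissible) return(fit)

  delta <- rho_jacobian(lam_hat, xi_hat)
  Vse <- if (method == "RML") ml_weight(implied_sigma(lam_hat, xi_hat)) else V
  covm <- tryCatch(sandwich_cov(delta, Vse, gamma, n), error = function(e) NULL)
  if (!is.null(covm) && is.finite(covm[11, 11]) && covm[11, 11] > 0)
    fit$se_xi_sandwich <- sqrt(covm[11, 11])
  se_fisher <- (1 - xi_hat^2) / sqrt(n - 3)
  fit$se_xi <- if (se == "fisherz") se_fisher else fit$se_xi_sandwich
  if (is.na(fit$se_xi)) {
    fit$converged <- FALSE
    fit$admissible <- FALSE
    fit$reason <- "singular-bread"
    return(fit)
  }
  fit$ci <- fisher_z_interval(xi_hat, fit$se_xi, level)
  fit
}

#' Expected ML weight matrix on the correlation scale
#'
#' Half the Hessian of the ML discrepancy with respect to the 45 lower-tri
#' elements of Sigma at a perfect fit:
#' \code{V[ab, cd] = Si_ac Si_bd + Si_ad Si_bc} with \code{Si = Sigma^-1}.
#'
#' @param sigma model-implied correlation matrix at the optimum
#' @return 45 x 45 weight matrix
#' @export
ml_weight <- function(sigma) {
  Si <- solve(sigma)
  pairs <- lower_tri_pairs(nrow(sigma))
  a <- pairs[, 1]; b <- pairs[, 2]
  Si[a, a] * Si[b, b] + Si[a, b] * Si[b, a]
}

#' Classify convergence and admissibility of a fit
#'
#' A fit is admissible iff it converged, no parameter sits at the Heywood
#' bound (|lambda| or |xi| pinned at 0.999, i.e. implied error variance
#' non-positive or correlation out of range), and no boundary-clipped
#' polychoric correlation fed the fit. Non-converged fits are never
#' classified inadmissible (the two states are counted separately).
#'
#' @param fit a \code{cfa_fit}
#' @param pc the \code{polychoric_result} used (for boundary flags); omit to
#'   classify on parameter values alone
#' @return the fit with updated \code{admissible} / \code{reason}
#' @export
classify_fit <- function(fit, pc = NULL) {
  if (!fit$converged) {
    fit$admissible <- FALSE
    fit$reason <- fit$reason %||% "non-converged"
    return(fit)
  }
  bad_par <- max(abs(fit$loadings)) >= PAR_BOUND - 1e-6 ||
    abs(fit$xi) >= PAR_BOUND - 1e-6 ||
    abs(fit$xi) >= 1 || max(abs(fit$loadings)) >= 1
  bad_poly <- !is.null(pc) && isTRUE(pc$boundary)
  fit$admissible <- !bad_par && !bad_poly
  fit$reason <- if (bad_par) "heywood" else if (bad_poly) "polychoric-boundary"
  fit
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): ", x$method, x$n))
  if (!x$converged) {
    cat("NOT CONVERGED", if (!is.null(x$reason)) paste0("(", x$reason, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("xi = %.4f (se %.4f), %d%% CI [%.4f, %.4f]%s\n",
              x$xi, x$se_xi, round(100 * x$level), x$ci[1], x$ci[2],
              if (!x$admissible) "  [INADMISSIBLE]" else ""))
  invisible(x)
}
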