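# Gibbs sampler with data augmentation for the two-factor ordinal CFA.
#
# Parameters: positive loadings a_j with error variances tied by the
# unit-variance identification theta_j = 1 - a_j^2, ordered item thresholds,
# factor means mu, factor scores omega, and the factor correlation xi with a
# uniform prior on (-1, 1) ("relatively less informative") or (0, 1)
# ("informative"). The latent responses underlying each ordinal observation
# are augmented so all updates are (truncated-) normal draws; the loading
# update and the xi update use Metropolis corrections (the theta(a) coupling
# and the non-conjugate correlation make those two conditionals
# non-standard).

#' Prior specification for the Bayesian ordinal CFA
#'
#' Loadings are standard normal truncated to positive; thresholds standard
#' normal with enforced ordering; factor means standard normal. Only the
#' factor-correlation prior varies: \code{"lessinf"} is Uniform(-1, 1),
#' \code{"inf"} is Uniform(0, 1).
#'
#' @param xi_prior \code{"lessinf"} or \code{"inf"}
#' @return object of class \code{prior_spec} with the xi support
#' @export
prior_spec <- function(xi_prior = c("lessinf", "inf")) {
  xi_prior <- match.arg(xi_prior)
  structure(list(xi_prior = xi_prior,
                 xi_support = if (xi_prior == "inf") c(0, 1) else c(-1, 1)),
            class = "prior_spec")
}

# Initialize a chain state. xi_start allows over-dispersed starts.
init_state <- function(Y, prior, xi_start = NULL) {
  n <- nrow(Y)
  sup <- prior$xi_support
  state <- list(
    Y = Y, n = n, prior = prior,
    a = rep(0.5, 10),
    mu = c(0, 0),
    tau = matrix(rep(stats::qnorm(c(0.25, 0.5, 0.75)), each = 10), 10, 3),
    omega = matrix(0, n, 2),
    xi = if (is.null(xi_start)) mean(sup) else xi_start,
    prop_scale = 0.3,
    f = rep(1:2, each = 5))
  # start y* at the conditional medians of their bins under N(0, 1)
  state$ystar <- matrix(0, n, 10)
  if (n > 0) {
    for (j in 1:10) {
      cuts <- c(-Inf, state$tau[j, ], Inf)
      lo <- cuts[Y[, j]]
      hi <- cuts[Y[, j] + 1L]
      state$ystar[, j] <- stats::qnorm((stats::pnorm(lo) + stats::pnorm(hi)) / 2)
    }
  }
  state
}

#' Gibbs step (a): item thresholds
#'
#' Each interior threshold is drawn from its standard-normal prior truncated
#' to the interval allowed by the current latent responses (above every
#' latent response in its lower category, below every one in its upper
#' category) intersected with the ordering constraint; a final sort guards
#' the ordering.
#'
#' @param state chain state (internal structure; see \code{\link{run_chain}})
#' @return updated state
#' @export
step_thresholds <- function(state) {
  Y <- state$Y
  for (j in 1:10) {
    ys <- state$ystar[, j]
    tau <- state$tau[j, ]
    for (k in 1:3) {
      in_k <- Y[, j] == k
      in_k1 <- Y[, j] == (k + 1L)
      lo <- if (any(in_k)) max(ys[in_k]) else -Inf
      hi <- if (any(in_k1)) min(ys[in_k1]) else Inf
      if (k > 1) lo <- max(lo, tau[k - 1])
      if (k < 3) hi <- min(hi, tau[k + 1])
      if (lo >= hi) stop("empty threshold support (corrupted state)")
      tau[k] <- truncnorm::rtruncnorm(1, a = lo, b = hi, mean = 0, sd = 1)
    }
    state$tau[j, ] <- sort(tau)
  }
  state
}

#' Gibbs step (b): latent responses
#'
#' Each latent response is drawn from a normal with mean (loading x factor
#' score) and variance \code{1 - a_j^2}, truncated to the threshold bin of
#' its observed category.
#'
#' @inheritParams step_thresholds
#' @return updated state
#' @export
step_latent <- function(state) {
  if (state$n == 0) return(state)
  for (j in 1:10) {
    cuts <- c(-Inf, state$tau[j, ], Inf)
    lo <- cuts[state$Y[, j]]
    hi <- cuts[state$Y[, j] + 1L]
    m <- state$a[j] * state$omega[, state$f[j]]
    s <- sqrt(1 - state$a[j]^2)
    state$ystar[, j] <- truncnorm::rtruncnorm(state$n, a = lo, b = hi,
                                              mean = m, sd = s)
  }
  state
}

#' Gibbs step (c): structural parameters
#'
#' Updates, in order: each loading by an independence Metropolis-Hastings
#' step (conditional-normal proposal at the current error variance, with an
#' acceptance correction for the theta(a) = 1 - a^2 coupling and the
#' truncated-normal prior); the factor means from their bivariate normal
#' full conditional; the factor scores from their (common-covariance)
#' bivariate normal full conditionals; and the factor correlation by a
#' random-walk Metropolis step on its full conditional under the uniform
#' prior, with proposals reflected at the support bounds.
#'
#' @inheritParams step_thresholds
#' @param adapt adapt the xi proposal scale (burn-in only)
#' @return updated state
#' @export
step_structural <- function(state, adapt = FALSE) {
  n <- state$n
  sup <- state$prior$xi_support

  # --- loadings (random-walk MH on the collapsed conditionals) ----------
  # As with xi below, the conditional of a loading given the factor scores
  # is far narrower than its marginal posterior (the scores adapt to the
  # loadings), so the sampler updates each loading against the marginal
  # likelihood y*_t ~ N(Lambda mu, Lambda Sigma(xi) Lambda' + Theta(a))
  # with the scores integrated out; theta_j = 1 - a_j^2 throughout.
  Sxi0 <- matrix(c(1, state$xi, state$xi, 1), 2)
  if (n > 0) {
    YtY <- crossprod(state$ystar)
    ysum <- colSums(state$ystar)
    marg_loglik <- function(a) {
      Lc <- matrix(0, 10, 2)
      Lc[cbind(1:10, state$f)] <- a
      m <- drop(Lc %*% state$mu)
      Om <- Lc %*% Sxi0 %*% t(Lc) + diag(1 - a^2)
      ch <- tryCatch(chol(Om), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      Scp <- YtY - outer(m, ysum) - outer(ysum, m) + n * outer(m, m)
      -n * sum(log(diag(ch))) - sum(chol2inv(ch) * Scp) / 2
    }
  } else {
    marg_loglik <- function(a) 0
  }
  if (is.null(state$a_scale)) state$a_scale <- rep(0.1, 10)
  cur_ll <- marg_loglik(state$a)
  for (j in 1:10) {
    aj1 <- state$a[j] + state$a_scale[j] * stats::rnorm(1)
    for (rep_try in 1:50) {
      if (aj1 < 0) aj1 <- -aj1
      else if (aj1 > 0.999) aj1 <- 2 * 0.999 - aj1
      else break
    }
    aj1 <- min(max(aj1, 1e-9), 0.999 - 1e-9)
    cand <- state$a; cand[j] <- aj1
    cand_ll <- marg_loglik(cand)
    logacc <- (cand_ll - aj1^2 / 2) - (cur_ll - state$a[j]^2 / 2)
    acc_a <- is.finite(logacc) && log(stats::runif(1)) < logacc
    if (acc_a) {
      state$a <- cand
      cur_ll <- cand_ll
    }
    if (adapt) {
      state$a_scale[j] <- exp(log(state$a_scale[j]) + (acc_a - 0.44) * 0.05)
      state$a_scale[j] <- min(max(state$a_scale[j], 1e-3), 0.5)
    }
  }

  # --- factor means (collapsed over the factor scores) ------------------
  # mu and omega form a weakly identified location ridge; drawing mu from
  # p(mu | Y*, a, xi) with omega integrated out, then omega | mu, avoids the
  # slow mu <-> omega random walk of the uncollapsed scheme.
  Sxi <- matrix(c(1, state$xi, state$xi, 1), 2)
  Sxi_inv <- solve(Sxi)
  th <- 1 - state$a^2
  L <- matrix(0, 10, 2)
  L[cbind(1:10, state$f)] <- state$a
  if (n > 0) {
    Om <- L %*% Sxi %*% t(L) + diag(th)      # marginal Cov(y* | mu)
    Oi_L <- solve(Om, L)                     # Om^-1 Lambda (10 x 2)
    Pmu <- diag(2) + n * crossprod(L, Oi_L)
    Vmu <- solve(Pmu)
    mmu <- Vmu %*% crossprod(Oi_L, colSums(state$ystar))
  } else {
    Vmu <- diag(2)
    mmu <- c(0, 0)
  }
  state$mu <- drop(mmu + t(chol(Vmu)) %*% stats::rnorm(2))

  # --- factor correlation (random-walk MH on the collapsed conditional) -
  # Conditioning on the factor scores would leave xi a conditional much
  # narrower than its marginal posterior (the scores pin it down), giving
  # single-digit effective sample sizes. Integrating omega out, the
  # likelihood is y*_t ~ N(Lambda mu, Lambda Sigma(xi) Lambda' + Theta),
  # evaluated from 10 x 10 factors; the scores are redrawn afterwards.
  if (n > 0) {
    cen <- sweep(state$ystar, 2, drop(L %*% state$mu), "-")
    Scp <- crossprod(cen)
    xi_loglik <- function(xi) {
      if (xi <= sup[1] || xi >= sup[2]) return(-Inf)
      Om <- L %*% matrix(c(1, xi, xi, 1), 2) %*% t(L) + diag(th)
      ch <- chol(Om)
      -n * sum(log(diag(ch))) - sum(chol2inv(ch) * Scp) / 2
    }
  } else {
    xi_loglik <- function(xi) {
      if (xi <= sup[1] || xi >= sup[2]) return(-Inf)
      0
    }
  }
  prop <- state$xi + state$prop_scale * stats::rnorm(1)
  # reflect into the open support
  span <- sup[2] - sup[1]
  for (rep_try in 1:50) {
    if (prop < sup[1]) prop <- 2 * sup[1] - prop
    else if (prop > sup[2]) prop <- 2 * sup[2] - prop
    else break
  }
  prop <- min(max(prop, sup[1] + 1e-9), sup[2] - 1e-9)
  logacc <- xi_loglik(prop) - xi_loglik(state$xi)
  acc <- is.finite(logacc) && log(stats::runif(1)) < logacc
  if (acc) state$xi <- prop
  if (adapt) {
    # drift the proposal scale toward a mid-range acceptance rate
    state$prop_scale <- exp(log(state$prop_scale) + (acc - 0.44) * 0.05)
    state$prop_scale <- min(max(state$prop_scale, 1e-3), span)
  }

  # --- factor scores (refresh given the new mu and xi) ------------------
  if (n > 0) {
    Sxi <- matrix(c(1, state$xi, state$xi, 1), 2)
    Sxi_inv <- solve(Sxi)
    Bmat <- matrix(0, 2, 10)
    Bmat[cbind(state$f, 1:10)] <- state$a / th
    prec <- Sxi_inv
    prec[1, 1] <- prec[1, 1] + sum((state$a^2 / th)[state$f == 1])
    prec[2, 2] <- prec[2, 2] + sum((state$a^2 / th)[state$f == 2])
    Vo <- solve(prec)
    base <- drop(Sxi_inv %*% state$mu)
    M <- (state$ystar %*% t(Bmat) +
            matrix(base, n, 2, byrow = TRUE)) %*% Vo
    state$omega <- M + matrix(stats::rnorm(2 * n), n, 2) %*% chol(Vo)
  }
  state
}

#' Run one Gibbs chain
#'
#' Executes the three-step sampler (thresholds, latent responses,
#' structural parameters), discards \code{n_burn} iterations and retains
#' \code{n_keep}. The defaults mirror the study configuration of 2,000
#' retained updates after 10,000 burn-in iterations.
#'
#' @param dataset an \code{\link{ordinal_dataset}} (n = 0 rows is allowed:
#'   the chain then samples the priors)
#' @param prior a \code{\link{prior_spec}}
#' @param n_burn,n_keep burn-in / retained iterations
#' @param seed optional seed
#' @param xi_start optional over-dispersed start for xi
#' @return matrix of retained draws (n_keep x 13): xi, a1..a10, mu1, mu2
#' @export
run_chain <- function(dataset, prior = prior_spec(), n_burn = 10000L,
                      n_keep = 2000L, seed = NULL, xi_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- dataset$responses
  state <- init_state(Y, prior, xi_start = xi_start)
  draws <- matrix(NA_real_, n_keep, 13)
  colnames(draws) <- c("xi", paste0("a", 1:10), "mu1", "mu2")
  total <- n_burn + n_keep
  for (it in seq_len(total)) {
    state <- step_thresholds(state)
    state <- step_latent(state)
    state <- step_structural(state, adapt = it <= n_burn)
    if (it > n_burn)
      draws[it - n_burn, ] <- c(state$xi, state$a, state$mu)
  }
  draws
}

#' Multivariate potential scale reduction factor (Brooks-Gelman)
#'
#' \code{sqrt((n-1)/n + ((m+1)/m) lambda_1)}, with \code{lambda_1} the
#' largest eigenvalue of \code{W^-1 B/n} computed from the within- and
#' between-chain covariance matrices of \code{m} chains of length \code{n}.
#' Reported on the square-root (scale-reduction) scale on which the
#' conventional "below 1.2" convergence rule is stated. Approaches 1 from
#' above at convergence; identical chains return the finite-sample floor
#' \code{sqrt((n-1)/n)}.
#'
#' @param chains list of >= 2 draw matrices with identical dimensions
#' @return scalar MPSRF
#' @export
mpsrf <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("MPSRF needs at least 2 chains")
  dims <- vapply(chains, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("chains must have equal length and dimension")
  n <- dims[1, 1]
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  means <- t(vapply(chains, colMeans, numeric(dims[2, 1])))
  Bn <- stats::cov(means)              # B/n in Brooks-Gelman notation
  lam1 <- tryCatch(
    max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
    error = function(e) {
      # singular W: regularize minimally
      max(Re(eigen(solve(W + diag(1e-12, nrow(W)), Bn),
                   only.values = TRUE)$values))
    })
  sqrt((n - 1) / n + (m + 1) / m * max(lam1, 0))
}

#' Heidelberger-Welch stationarity and half-width diagnostic
#'
#' Classical implementation: the spectral density at frequency zero is
#' estimated once from the second half of the chain (AR fit), the
#' Cramer-von-Mises statistic of the standardized Brownian bridge is
#' compared with its asymptotic critical value, and the test is repeated
#' with the first 10\%, 20\%, ..., 50\% discarded until it passes. The
#' half-width test checks that the asymptotic 95\% half-width of the mean
#' over the usable portion is below \code{eps} times the mean's magnitude.
#' A numerically constant chain is reported as passing with zero
#' half-width.
#'
#' @param chain numeric vector of draws (length >= 100)
#' @param alpha stationarity test level (0.1, 0.05, 0.025 or 0.01)
#' @param eps half-width tolerance
#' @return list with \code{pass}, \code{usable_frac}, \code{halfwidth_pass}
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  n <- length(chain)
  if (n < 100) stop("chain too short for Heidelberger-Welch")
  if (stats::sd(chain) < 1e-12)
    return(list(pass = TRUE, usable_frac = 1, halfwidth_pass = TRUE))
  # asymptotic critical values of the Cramer-von-Mises omega^2 statistic
  crit_tab <- c("0.1" = 0.34730, "0.05" = 0.46136,
                "0.025" = 0.58061, "0.01" = 0.74346)
  key <- as.character(alpha)
  if (!key %in% names(crit_tab))
    stop("alpha must be one of 0.1, 0.05, 0.025, 0.01")
  crit <- crit_tab[[key]]
  spec0 <- function(x) {
    # spectral density at zero via an AR fit (variance of the mean * n)
    fit <- tryCatch(stats::ar(x, aic = TRUE,
                              order.max = min(30, length(x) %/% 10)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(stats::var(x))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  s0 <- spec0(chain[(n %/% 2 + 1):n])
  if (!is.finite(s0) || s0 <= 0) s0 <- stats::var(chain)
  pass <- FALSE
  usable_start <- n + 1L
  for (frac in seq(0, 0.5, by = 0.1)) {
    start <- floor(frac * n) + 1L
    w <- chain[start:n]
    nw <- length(w)
    S <- cumsum(w) - seq_len(nw) * mean(w)
    cvm <- sum(S^2) / (nw^2 * s0)
    if (cvm < crit) {
      pass <- TRUE
      usable_start <- start
      break
    }
  }
  if (!pass)
    return(list(pass = FALSE, usable_frac = 0, halfwidth_pass = FALSE))
  use <- chain[usable_start:n]
  hw <- stats::qnorm(0.975) * sqrt(spec0(use) / length(use))
  list(pass = TRUE, usable_frac = length(use) / n,
       halfwidth_pass = is.finite(hw) && hw <= eps * abs(mean(use)))
}

#' Fit the Bayesian ordinal CFA
#'
#' Runs \code{n_chains} Gibbs chains with over-dispersed starting values for
#' the factor correlation (prior quantiles 0.1 / 0.5 / 0.9 ...), pools the
#' retained draws, and summarizes the factor correlation: EAP (posterior
#' mean), posterior SD, equal-tailed 95\% credibility interval, MPSRF over
#' (xi, loadings), and the Heidelberger-Welch result for the pooled xi
#' chain.
#'
#' @inheritParams run_chain
#' @param n_chains number of chains (>= 2 for MPSRF)
#' @param level credibility level
#' @return object of class \code{bayes_fit}
#' @export
bayes_fit <- function(dataset, prior = prior_spec(), n_chains = 3L,
                      n_burn = 10000L, n_keep = 2000L, seed = NULL,
                      level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  sup <- prior$xi_support
  qs <- seq(0.1, 0.9, length.out = max(n_chains, 2L))
  starts <- sup[1] + qs * (sup[2] - sup[1])
  chains <- lapply(seq_len(n_chains), function(c)
    run_chain(dataset, prior, n_burn = n_burn, n_keep = n_keep,
              xi_start = starts[c]))
  summarize_chains(chains, prior, n_burn = n_burn, level = level)
}

#' Summarize retained chains into a posterior result
#'
#' @param chains list of draw matrices from \code{\link{run_chain}}
#' @param prior the \code{\link{prior_spec}} used
#' @param n_burn burn-in recorded for provenance
#' @param level credibility level
#' @return object of class \code{bayes_fit}
#' @export
summarize_chains <- function(chains, prior = prior_spec(), n_burn = NA_integer_,
                             level = 0.95) {
  xi_all <- unlist(lapply(chains, function(d) d[, "xi"]))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(xi_all, c(alpha, 1 - alpha), names = FALSE)
  mp <- if (length(chains) >= 2)
    mpsrf(lapply(chains, function(d) d[, c("xi", paste0("a", 1:10))]))
  else NA_real_
  hw <- if (length(xi_all) >= 100) heidelberger_welch(xi_all)
  else list(pass = NA, usable_frac = NA, halfwidth_pass = NA)
  structure(
    list(eap = mean(xi_all), post_sd = stats::sd(xi_all),
         ci = c(lower = ci[1], upper = ci[2]),
         mpsrf = mp, hw_pass = hw$pass,
         xi_draws = xi_all, chains = chains, prior = prior,
         n_chains = length(chains), n_burn = n_burn,
         n_keep = if (length(chains)) nrow(chains[[1]]) else 0L,
         level = level),
    class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("Bayesian ordinal CFA (%s prior, %d chains x %d kept)\n",
              x$prior$xi_prior, x$n_chains, x$n_keep))
  cat(sprintf("  xi: EAP = %.4f, posterior SD = %.4f, %d%% CI [%.4f, %.4f]\n",
              x$eap, x$post_sd, round(100 * x$level), x$ci[1], x$ci[2]))
  if (!is.na(x$mpsrf)) cat(sprintf("  MPSRF = %.4f\n", x$mpsrf))
  invisible(x)
}
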