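# Monte-Carlo diagnostics over per-replication interval records: coverage,
# width, directional interval bias, RMSE, bias, SE calibration, solution
# tallies, and eta-squared effect sizes from factorial ANOVAs.
#
# A "records" data frame has one row per (replication x method) with columns
# dist, xi_true, n, method, rep, est, se, lower, upper, converged,
# admissible. Interval and point diagnostics use only converging AND
# admissible replications (the usable set); tallies use all replications.

usable <- function(records) {
  records[records$converged & records$admissible &
            !is.na(records$lower) & !is.na(records$upper), , drop = FALSE]
}

#' Coverage of interval estimates
#'
#' Fraction of usable (converged, admissible) intervals containing the
#' generating value.
#'
#' @param records records data frame (see package overview)
#' @param xi_true generating factor correlation
#' @return proportion in [0, 1]
#' @export
coverage <- function(records, xi_true) {
  u <- usable(records)
  if (nrow(u) == 0) stop("no usable replications")
  mean(u$lower <= xi_true & xi_true <= u$upper)
}

#' Directional interval bias
#'
#' Positive interval bias is the percentage of usable intervals lying
#' entirely above the generating value (lower bound above it); negative
#' bias the percentage entirely below. Together with coverage these
#' partition the usable replications:
#' \code{100 * coverage + positive + negative = 100}.
#'
#' @inheritParams coverage
#' @return named vector \code{c(positive, negative)} in percent
#' @export
interval_bias <- function(records, xi_true) {
  u <- usable(records)
  if (nrow(u) == 0) stop("no usable replications")
  c(positive = 100 * mean(u$lower > xi_true),
    negative = 100 * mean(u$upper < xi_true))
}

#' Mean interval width
#'
#' @inheritParams coverage
#' @return mean of (upper - lower) over usable replications
#' @export
mean_width <- function(records) {
  u <- usable(records)
  if (nrow(u) == 0) stop("no usable replications")
  mean(u$upper - u$lower)
}

#' Root mean squared error of point estimates
#'
#' \code{sqrt(mean((est - xi_true)^2))} over the R usable replications.
#'
#' @param estimates numeric vector of point estimates
#' @param xi_true generating value
#' @return nonnegative scalar
#' @export
rmse <- function(estimates, xi_true) {
  if (length(estimates) == 0) stop("no estimates")
  sqrt(mean((estimates - xi_true)^2))
}

#' Mean bias of point estimates
#'
#' \code{mean(est - xi_true)} over the usable replications.
#'
#' @inheritParams rmse
#' @return scalar
#' @export
bias <- function(estimates, xi_true) {
  if (length(estimates) == 0) stop("no estimates")
  mean(estimates - xi_true)
}

#' Standard-error calibration
#'
#' Compares the mean reported standard error (mu.se) with the empirical
#' standard error (sigma.mu, the SD of the point estimates). A ratio
#' sigma.mu / mu.se above 1 indicates the reported standard errors
#' underestimate the true sampling variability.
#'
#' @inheritParams coverage
#' @return list with \code{mu_se}, \code{sigma_mu}, \code{ratio},
#'   \code{underestimated}
#' @export
se_calibration <- function(records) {
  u <- usable(records)
  if (nrow(u) < 2) stop("need at least 2 usable replications")
  mu_se <- mean(u$se, na.rm = TRUE)
  sigma_mu <- stats::sd(u$est)
  list(mu_se = mu_se, sigma_mu = sigma_mu, ratio = sigma_mu / mu_se,
       underestimated = sigma_mu > mu_se)
}

#' Solution accounting per method
#'
#' Percentages of non-converged and inadmissible replications out of the
#' total, with the precedence rule: a non-converged replication is counted
#' only as non-converged; admissibility is assessed only on converged fits.
#'
#' @param records records data frame including failed replications
#' @return data frame with method, pct_nonconverged, pct_inadmissible,
#'   n_total, n_used
#' @export
tally_solutions <- function(records) {
  out <- lapply(split(records, records$method), function(r) {
    data.frame(method = r$method[1],
               pct_nonconverged = 100 * mean(!r$converged),
               pct_inadmissible = 100 * mean(r$converged & !r$admissible),
               n_total = nrow(r),
               n_used = sum(r$converged & r$admissible))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize one design cell for one method
#'
#' Aggregates the full set of interval and point diagnostics for a single
#' (distribution, xi_true, n, method) cell.
#'
#' @param records records of one cell and method (failures included)
#' @param xi_true generating factor correlation
#' @return one-row data frame (class \code{cell_summary})
#' @export
cell_summary <- function(records, xi_true) {
  stopifnot(length(unique(records$method)) == 1)
  tal <- tally_solutions(records)
  u <- usable(records)
  base <- data.frame(
    dist = records$dist[1], xi_true = xi_true, n = records$n[1],
    method = records$method[1],
    R_total = tal$n_total, R_used = tal$n_used,
    pct_nonconverged = tal$pct_nonconverged,
    pct_inadmissible = tal$pct_inadmissible)
  if (nrow(u) >= 2) {
    ib <- interval_bias(records, xi_true)
    sc <- se_calibration(records)
    base <- cbind(base, data.frame(
      coverage = coverage(records, xi_true),
      mean_width = mean_width(records),
      pos_bias_pct = ib[["positive"]], neg_bias_pct = ib[["negative"]],
      rmse = rmse(u$est, xi_true), bias = bias(u$est, xi_true),
      mu_se = sc$mu_se, sigma_mu = sc$sigma_mu))
  } else {
    base <- cbind(base, data.frame(
      coverage = NA_real_, mean_width = NA_real_,
      pos_bias_pct = NA_real_, neg_bias_pct = NA_real_,
      rmse = NA_real_, bias = NA_real_,
      mu_se = NA_real_, sigma_mu = NA_real_))
  }
  class(base) <- c("cell_summary", "data.frame")
  base
}

#' Eta-squared effect sizes from a factorial ANOVA
#'
#' Fixed-effects ANOVA of a cell-level outcome on the design factors
#' (method, sample size, distribution, factor correlation) with all main
#' effects and two-way interactions; higher-order interactions are pooled
#' into the residual. Effect sizes are \code{100 * SS_effect / SS_total};
#' together with the residual they sum to 100.
#'
#' @param cell_table data frame with one row per design cell, containing
#'   factor columns \code{method}, \code{n}, \code{dist}, \code{xi_true}
#'   and the outcome column
#' @param outcome name of the outcome column
#' @return data frame with effect and eta_sq_pct (residual last)
#' @export
eta_squared <- function(cell_table, outcome) {
  d <- cell_table[!is.na(cell_table[[outcome]]), , drop = FALSE]
  if (nrow(d) < 4) stop("too few cells for an ANOVA")
  d$.y <- d[[outcome]]
  for (v in c("method", "n", "dist", "xi_true"))
    if (v %in% names(d)) d[[v]] <- factor(d[[v]])
  terms <- c("method", "n", "dist", "xi_true")
  terms <- terms[vapply(terms, function(v) nlevels(d[[v]]) > 1, logical(1))]
  if (length(terms) == 0) stop("no varying design factors")
  form <- stats::as.formula(paste(".y ~ (", paste(terms, collapse = " + "), ")^2"))
  fit <- stats::aov(form, data = d)
  ss <- summary(fit)[[1]][, "Sum Sq"]
  labs <- trimws(rownames(summary(fit)[[1]]))
  tot <- sum(ss)
  data.frame(effect = labs, eta_sq_pct = 100 * ss / tot)
}
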