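# Generating truth for the two-factor ordinal CFA.
#
# The measurement model is y* = Lambda omega + eps with Var(y*_i) = 1, so the
# error variances are tied to the loadings, theta_i = 1 - lambda_i^2, and the
# model-implied correlation matrix is
#   Sigma(Lambda, Phi) = Lambda Phi Lambda' + I - diag(Lambda Phi Lambda').
# Observed items are 4-category discretizations of y* at strictly increasing
# thresholds.

#' Specify the generating model
#'
#' Builds the generating truth for a two-factor ordinal CFA with five items
#' per factor (items 1-5 on factor 1, items 6-10 on factor 2), four response
#' categories per item, and either multivariate normal or mildly skewed
#' (Vale-Maurelli) factor scores.
#'
#' @param loadings numeric vector of length 10, each in (0, 1)
#' @param factor_correlation correlation between the two factors, in [-1, 1]
#' @param thresholds either a length-3 increasing vector used for every item,
#'   or a 10 x 3 matrix of per-item thresholds. Defaults to the standard
#'   normal quartile cut-points, which yield balanced categories.
#' @param dist_shape \code{"normal"} or \code{"mild_skew"}
#' @param skewness,excess_kurtosis target moments of each factor-score margin
#'   when \code{dist_shape = "mild_skew"}
#' @return an object of class \code{model_spec}
#' @export
model_spec <- function(loadings,
                       factor_correlation,
                       thresholds = stats::qnorm(c(0.25, 0.5, 0.75)),
                       dist_shape = c("normal", "mild_skew"),
                       skewness = 1.5,
                       excess_kurtosis = 1.5) {
  dist_shape <- match.arg(dist_shape)
  loadings <- as.numeric(loadings)
  if (length(loadings) != 10L)
    stop("'loadings' must have length 10 (five items per factor)")
  if (any(loadings <= 0 | loadings >= 1))
    stop("each loading must lie in (0, 1) so that theta_i = 1 - lambda_i^2 > 0")
  if (abs(factor_correlation) > 1)
    stop("'factor_correlation' must lie in [-1, 1]")
  if (is.matrix(thresholds)) {
    if (!all(dim(thresholds) == c(10L, 3L)))
      stop("threshold matrix must be 10 x 3")
  } else {
    if (length(thresholds) != 3L) stop("'thresholds' must have 3 cut-points")
    thresholds <- matrix(thresholds, nrow = 10L, ncol = 3L, byrow = TRUE)
  }
  if (any(apply(thresholds, 1, function(t) any(diff(t) <= 0))))
    stop("thresholds must be strictly increasing for every item")
  structure(
    list(loadings = loadings,
         factor_correlation = factor_correlation,
         thresholds = thresholds,
         dist_shape = dist_shape,
         skewness = if (dist_shape == "mild_skew") skewness else 0,
         excess_kurtosis = if (dist_shape == "mild_skew") excess_kurtosis else 0,
         n_categories = 4L,
         factor_of_item = rep(1:2, each = 5L)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Two-factor ordinal CFA generating model\n")
  cat("  loadings:          ", paste(sprintf("%.3f", x$loadings), collapse = " "), "\n")
  cat("  factor correlation:", x$factor_correlation, "\n")
  cat("  factor scores:     ", x$dist_shape,
      if (x$dist_shape == "mild_skew")
        sprintf("(skew %.2f, excess kurtosis %.2f)", x$skewness, x$excess_kurtosis),
      "\n")
  invisible(x)
}

#' Model-implied correlation matrix
#'
#' \code{Sigma = Lambda Phi Lambda' + I - diag(Lambda Phi Lambda')}, the
#' correlation matrix of the latent responses under the generating model.
#'
#' @param loadings length-10 loading vector (simple structure)
#' @param xi factor correlation
#' @return 10 x 10 correlation matrix
#' @export
implied_sigma <- function(loadings, xi) {
  lam <- matrix(0, 10, 2)
  lam[cbind(1:10, rep(1:2, each = 5))] <- loadings
  phi <- matrix(c(1, xi, xi, 1), 2)
  m <- lam %*% phi %*% t(lam)
  diag(m) <- 1
  m
}

#' Model-implied polychoric correlation vector
#'
#' Below-diagonal elements of \code{Lambda Phi Lambda'} in the package's
#' vectorization order (column-major lower triangle). Within-factor element
#' (i, j) equals \code{lambda_i lambda_j}; cross-factor elements pick up the
#' factor correlation: \code{lambda_i lambda_j xi}.
#'
#' @inheritParams implied_sigma
#' @return numeric vector of length 45
#' @export
implied_rho <- function(loadings, xi) {
  implied_sigma(loadings, xi)[lower.tri(diag(10))]
}
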