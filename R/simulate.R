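# Synthetic ordinal CFA data: factor scores (normal or Vale-Maurelli skewed),
# latent responses, and threshold discretization.

#' Draw factor loadings for a replication
#'
#' The study design draws each of the \code{p} loadings independently from
#' Uniform(0.4, 0.8).
#'
#' @param p number of items
#' @param lower,upper range of the uniform distribution
#' @return numeric vector of length \code{p}
#' @export
draw_loadings <- function(p = 10L, lower = 0.4, upper = 0.8) {
  stopifnot(p %% 2 == 0)
  stats::runif(p, lower, upper)
}

#' Draw factor scores
#'
#' For \code{dist_shape = "normal"}, rows are bivariate standard normal with
#' correlation \code{xi}, generated via the Cholesky factor of the 2 x 2
#' correlation matrix. For \code{"mild_skew"}, each margin is a Fleishman
#' cubic transform of normals generated at the Vale-Maurelli intermediate
#' correlation, then re-standardized to sample mean 0 / sd 1 (the design
#' fixes the factor-score sd at 1).
#'
#' @param n number of rows
#' @param spec a \code{\link{model_spec}}
#' @return n x 2 matrix of factor scores
#' @export
draw_factor_scores <- function(n, spec) {
  stopifnot(n >= 1)
  xi <- spec$factor_correlation
  if (spec$dist_shape == "normal") {
    z <- matrix(stats::rnorm(2 * n), n, 2)
    cm <- matrix(c(1, xi, xi, 1), 2)
    return(z %*% chol(cm))
  }
  key <- paste0("flcoef_", spec$skewness, "_", spec$excess_kurtosis)
  coef <- .ordcfa_env[[key]]
  if (is.null(coef)) {
    coef <- fleishman_coefficients(spec$skewness, spec$excess_kurtosis,
                                   on_infeasible = "nearest")
    .ordcfa_env[[key]] <- coef
  }
  rho_z <- vm_intermediate_cor(xi, coef)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  z <- z %*% chol(matrix(c(1, rho_z, rho_z, 1), 2))
  x <- coef$a + coef$b * z + coef$c * z^2 + coef$d * z^3
  if (n >= 2L) {
    x <- sweep(x, 2, colMeans(x), "-")
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, sds, "/")
  }
  x
}

#' Discretize latent responses
#'
#' Maps each latent response to its ordinal category by the threshold rule:
#' category k iff \code{tau_{k-1} <= y* < tau_k}, with \code{tau_0 = -Inf}
#' and \code{tau_c = Inf} (a value equal to a threshold goes to the upper
#' category).
#'
#' @param ystar n x p matrix of latent responses
#' @param spec a \code{\link{model_spec}} (its thresholds are used)
#' @return an \code{ordinal_dataset}
#' @export
discretize <- function(ystar, spec) {
  p <- ncol(ystar)
  stopifnot(p == nrow(spec$thresholds))
  resp <- matrix(0L, nrow(ystar), p)
  for (j in seq_len(p)) {
    tau <- spec$thresholds[j, ]
    if (any(diff(tau) <= 0)) stop("non-monotone thresholds for item ", j)
    # findInterval with left-closed bins: tau_{k-1} <= y < tau_k
    resp[, j] <- findInterval(ystar[, j], tau, left.open = FALSE) + 1L
  }
  ordinal_dataset(resp, spec = spec)
}

#' Construct an ordinal dataset
#'
#' @param responses n x 10 integer matrix with entries in 1..4
#' @param spec generating \code{\link{model_spec}}, if known
#' @param seed seed used to generate the data, if known
#' @return object of class \code{ordinal_dataset}
#' @export
ordinal_dataset <- function(responses, spec = NULL, seed = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (ncol(responses) != 10L) stop("exactly 10 items are expected")
  if (nrow(responses) < 1L) stop("n must be positive")
  if (anyNA(responses) || any(responses < 1L) || any(responses > 4L))
    stop("entries must be integer categories in 1..4")
  colnames(responses) <- paste0("item", 1:10)
  structure(list(responses = responses, n = nrow(responses),
                 spec = spec, seed = seed),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("Ordinal dataset: n = %d, p = %d, categories 1..4\n",
              x$n, ncol(x$responses)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Generate an ordinal dataset from the model
#'
#' Builds latent responses \code{y* = Lambda omega + eps} with independent
#' normal errors of variance \code{1 - lambda_i^2} (so each latent response
#' has unit variance), then discretizes at the spec's thresholds.
#'
#' @param spec a \code{\link{model_spec}}
#' @param n sample size
#' @param seed optional seed set before generation (for reproducibility)
#' @return an \code{ordinal_dataset}
#' @export
generate_dataset <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  omega <- draw_factor_scores(n, spec)
  lam <- spec$loadings
  f <- spec$factor_of_item
  mu <- omega[, f, drop = FALSE] * matrix(lam, n, 10, byrow = TRUE)
  theta <- 1 - lam^2
  eps <- matrix(stats::rnorm(n * 10), n, 10) *
    matrix(sqrt(theta), n, 10, byrow = TRUE)
  out <- discretize(mu + eps, spec)
  out$seed <- seed
  out
}

#' Write / read an ordinal dataset as delimited text
#'
#' The dataset is written as a tab-delimited file with a header row of item
#' names; a JSON sidecar (same path + \code{.json}) records the generating
#' model, sample size and seed.
#'
#' @param dataset an \code{ordinal_dataset}
#' @param path file path
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset$responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(n = dataset$n, seed = dataset$seed)
  if (!is.null(dataset$spec)) {
    s <- dataset$spec
    meta$spec <- list(loadings = s$loadings,
                      factor_correlation = s$factor_correlation,
                      thresholds = s$thresholds[1, ],
                      dist_shape = s$dist_shape,
                      skewness = s$skewness,
                      excess_kurtosis = s$excess_kurtosis)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  resp <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  spec <- NULL; seed <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- meta$seed
    if (!is.null(meta$spec))
      spec <- model_spec(meta$spec$loadings, meta$spec$factor_correlation,
                         thresholds = meta$spec$thresholds,
                         dist_shape = meta$spec$dist_shape,
                         skewness = meta$spec$skewness %||% 1.5,
                         excess_kurtosis = meta$spec$excess_kurtosis %||% 1.5)
  }
  ordinal_dataset(resp, spec = spec, seed = seed)
}
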