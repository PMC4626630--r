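# Fleishman power-method coefficients and the Vale-Maurelli intermediate
# correlation, used to generate non-normal factor scores with target
# skewness/kurtosis and target correlation.

#' Solve for Fleishman power-method coefficients
#'
#' Finds (a, b, c, d) of the cubic transform \code{X = a + bZ + cZ^2 + dZ^3}
#' of a standard normal Z such that X has mean 0, variance 1, and the
#' requested skewness and excess kurtosis. \code{a = -c} enforces the zero
#' mean; (b, c, d) solve the three Fleishman moment equations.
#'
#' Not every (skewness, kurtosis) pair is attainable by a cubic transform of
#' a normal: the power-method feasible region requires, roughly, excess
#' kurtosis above \code{-1.13 + 1.59 * skewness^2}. For infeasible targets
#' the default is an error; \code{on_infeasible = "nearest"} instead returns
#' the coefficients of the closest attainable (skewness, kurtosis) pair with
#' the unit-variance constraint held exactly, recording the achieved moments
#' in the result. (Mainstream non-normal data generators silently do the
#' latter.)
#'
#' @param skewness target skewness
#' @param excess_kurtosis target excess kurtosis
#' @param tol residual tolerance for the moment equations
#' @param on_infeasible \code{"error"} or \code{"nearest"}
#' @return object of class \code{fleishman_coef} with fields a, b, c, d and
#'   the achieved \code{skewness} / \code{excess_kurtosis}
#' @export
fleishman_coefficients <- function(skewness, excess_kurtosis, tol = 1e-10,
                                   on_infeasible = c("error", "nearest")) {
  on_infeasible <- match.arg(on_infeasible)
  g1 <- skewness; g2 <- excess_kurtosis
  if (g1 == 0 && g2 == 0) {
    return(structure(list(a = 0, b = 1, c = 0, d = 0,
                          skewness = 0, excess_kurtosis = 0, exact = TRUE),
                     class = "fleishman_coef"))
  }
  moments <- function(x) {
    b <- x[1]; c <- x[2]; d <- x[3]
    c(v = b^2 + 6 * b * d + 2 * c^2 + 15 * d^2,
      s = 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2),
      k = 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
                  d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)))
  }
  eqs <- function(x) moments(x) - c(1, g1, g2)
  sol <- NULL
  for (start in list(c(0.9, 0.1 * g1, 0.03 * g2),
                     c(1, 0.15 * g1, 0.05),
                     c(0.8, 0.2, 0.1))) {
    s <- tryCatch(
      suppressWarnings(pracma::fsolve(eqs, start, tol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(s) && max(abs(eqs(s$x))) < tol) { sol <- s$x; break }
  }
  if (!is.null(sol)) {
    return(structure(list(a = -sol[2], b = sol[1], c = sol[2], d = sol[3],
                          skewness = g1, excess_kurtosis = g2, exact = TRUE),
                     class = "fleishman_coef"))
  }
  if (on_infeasible == "error")
    stop("infeasible moments: no Fleishman coefficients for skewness = ",
         g1, ", excess kurtosis = ", g2)
  # nearest attainable (skew, kurtosis), variance pinned at 1: penalized
  # search, then the variance equation re-solved exactly for b given (c, d)
  obj <- function(x) {
    m <- moments(x)
    (m["s"] - g1)^2 + (m["k"] - g2)^2 + 1e8 * (m["v"] - 1)^2
  }
  best <- NULL
  for (start in list(c(1, 0.3, -0.05), c(0.9, 0.2, 0.05), c(1.1, 0.4, -0.1))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  x <- best$par
  disc <- 9 * x[3]^2 - (2 * x[2]^2 + 15 * x[3]^2 - 1)
  if (disc < 0) stop("infeasible moments: skewness = ", g1,
                     ", excess kurtosis = ", g2)
  x[1] <- -3 * x[3] + sqrt(disc)          # variance exactly 1
  m <- moments(x)
  structure(list(a = -x[2], b = x[1], c = x[2], d = x[3],
                 skewness = unname(m["s"]),
                 excess_kurtosis = unname(m["k"]), exact = FALSE),
            class = "fleishman_coef")
}

#' @export
print.fleishman_coef <- function(x, ...) {
  cat(sprintf("Fleishman coefficients (skew %.3g, excess kurtosis %.3g):\n",
              x$skewness, x$excess_kurtosis))
  cat(sprintf("  a = %.8f  b = %.8f  c = %.8f  d = %.8f\n", x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Vale-Maurelli intermediate correlation
#'
#' Given Fleishman coefficients for two margins, finds the correlation
#' \code{rho_z} of the underlying normals such that the correlation of the
#' transformed variables equals \code{target}. The post-transform correlation
#' is the cubic
#' \code{rho_z (b1 b2 + 3 b1 d2 + 3 d1 b2 + 9 d1 d2) + 2 rho_z^2 c1 c2 + 6 rho_z^3 d1 d2}.
#'
#' @param target desired post-transform correlation, in [-1, 1]
#' @param coef1,coef2 \code{fleishman_coef} objects for the two margins
#' @param tol root tolerance
#' @return the intermediate (pre-transform) correlation
#' @export
vm_intermediate_cor <- function(target, coef1, coef2 = coef1, tol = 1e-12) {
  stopifnot(abs(target) <= 1)
  if (target == 0) return(0)
  f <- function(r) {
    r * (coef1$b * coef2$b + 3 * coef1$b * coef2$d + 3 * coef1$d * coef2$b +
           9 * coef1$d * coef2$d) +
      r^2 * (2 * coef1$c * coef2$c) + r^3 * (6 * coef1$d * coef2$d) - target
  }
  if (f(-1) > 0 || f(1) < 0)
    stop("no intermediate correlation in [-1, 1] attains target ", target)
  stats::uniroot(f, c(-1, 1), tol = tol)$root
}
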