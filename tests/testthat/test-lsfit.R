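test_that("implied correlations follow the factor algebra", {
  r0 <- implied_rho(rep(0.5, 10), 0)
  pairs <- lower_tri_pairs(10)
  same <- rep(1:2, each = 5)[pairs[, 1]] == rep(1:2, each = 5)[pairs[, 2]]
  expect_true(all(r0[same] == 0.25))
  expect_true(all(r0[!same] == 0))
  # single-factor degeneracy at xi = 1
  expect_true(all(abs(implied_rho(rep(0.6, 10), 1) - 0.36) < 1e-12))
  # general case against a direct matrix product
  lam <- seq(0.4, 0.8, length.out = 10)
  L <- matrix(0, 10, 2); L[cbind(1:10, rep(1:2, each = 5))] <- lam
  M <- L %*% matrix(c(1, 0.5, 0.5, 1), 2) %*% t(L)
  expect_equal(implied_rho(lam, 0.5), M[lower.tri(M)])
})

test_that("the discrepancy is the stated quadratic form", {
  set.seed(51)
  lam <- runif(10, 0.4, 0.8); xi <- 0.3
  r <- implied_rho(lam, xi)
  expect_equal(cfa_discrepancy(r, lam, xi, diag(45)), 0)
  r2 <- r + rnorm(45, sd = 0.05)
  expect_equal(cfa_discrepancy(r2, lam, xi, diag(45)),
               sum((r2 - r)^2))
  A <- crossprod(matrix(rnorm(45 * 45), 45))
  e <- r2 - r
  expect_equal(cfa_discrepancy(r2, lam, xi, A),
               drop(t(e) %*% A %*% e), tolerance = 1e-12)
  expect_error(cfa_discrepancy(r2[1:10], lam, xi, A), "dimension")
})

test_that("the analytic Jacobian matches finite differences", {
  lam <- seq(0.45, 0.75, length.out = 10); xi <- 0.6
  D <- rho_jacobian(lam, xi)
  eps <- 1e-6
  for (j in 1:11) {
    par <- c(lam, xi)
    up <- par; up[j] <- up[j] + eps
    dn <- par; dn[j] <- dn[j] - eps
    num <- (implied_rho(up[1:10], up[11]) - implied_rho(dn[1:10], dn[11])) /
      (2 * eps)
    expect_equal(D[, j], num, tolerance = 1e-7)
  }
})

test_that("all four methods recover a zero-residual truth exactly", {
  lam <- seq(0.4, 0.8, length.out = 10); xi <- 0.5
  pc <- perfect_polychoric(lam, xi)
  for (m in c("WLS", "RDWLS", "RULS", "RML")) {
    ft <- cfa_fit(pc, 1000, m)
    expect_true(ft$converged)
    expect_true(ft$admissible)
    expect_lt(abs(ft$xi - xi), 1e-6)
    expect_lt(max(abs(ft$loadings - lam)), 1e-5)
    expect_lt(ft$discrepancy, 1e-10)
  }
})

test_that("methods agree with each other at large n", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.8), 1e5, seed = 52)
  pc <- polychoric(d)
  est <- vapply(c("WLS", "RDWLS", "RULS", "RML"),
                function(m) cfa_fit(pc, 1e5, m)$xi, numeric(1))
  expect_lt(max(est) - min(est), 0.01)
  expect_lt(max(abs(est - 0.8)), 0.02)
})

test_that("sandwich covariance collapses when V is the inverse ACM", {
  set.seed(53)
  delta <- rho_jacobian(runif(10, 0.4, 0.8), 0.5)
  G <- crossprod(matrix(rnorm(60 * 45), 60)) / 60 + diag(0.05, 45)
  n <- 200
  Vi <- solve(G)
  collapsed <- solve(t(delta) %*% Vi %*% delta) / n
  expect_equal(sandwich_cov(delta, Vi, G, n), collapsed, tolerance = 1e-8)
  # identity everything: (D'D)^-1 / n
  expect_equal(sandwich_cov(delta, diag(45), diag(45), n),
               solve(crossprod(delta)) / n, tolerance = 1e-10)
  # diagonal weighting against the direct matrix expression
  V <- diag(1 / diag(G))
  bread <- solve(t(delta) %*% V %*% delta)
  direct <- bread %*% t(delta) %*% V %*% G %*% V %*% delta %*% bread / n
  expect_equal(sandwich_cov(delta, V, G, n), direct, tolerance = 1e-10)
  expect_equal(sandwich_se(delta, V, G, n), sqrt(diag(direct)),
               tolerance = 1e-10)
})

test_that("the ML weight is half the Hessian of the ML discrepancy", {
  lam <- seq(0.45, 0.75, length.out = 10)
  S <- implied_sigma(lam, 0.5)
  Vml <- ml_weight(S)
  # numeric Hessian of logdet(Sig) + tr(S Sig^-1) in a few off-diagonal
  # coordinates, at the perfect-fit point Sig = S
  f <- function(rvec) {
    Sig <- vec_to_corr(rvec, 10)
    as.numeric(determinant(Sig)$modulus) + sum(solve(Sig) * S)
  }
  r0 <- S[lower.tri(S)]
  eps <- 1e-4
  for (q in c(1, 7, 23, 45)) {
    for (s in c(3, 19, 40)) {
      up <- r0; up[q] <- up[q] + eps
      num <- if (q == s) {
        dn <- r0; dn[q] <- dn[q] - eps
        (f(up) - 2 * f(r0) + f(dn)) / eps^2
      } else {
        uu <- up; uu[s] <- uu[s] + eps
        ud <- up; ud[s] <- ud[s] - eps
        du <- r0; du[q] <- du[q] - eps; du[s] <- du[s] + eps
        dd <- r0; dd[q] <- dd[q] - eps; dd[s] <- dd[s] - eps
        (f(uu) - f(ud) - f(du) + f(dd)) / (4 * eps^2)
      }
      expect_equal(Vml[q, s], num / 2, tolerance = 1e-3)
    }
  }
})

test_that("Fisher-z intervals match the transcendental construction", {
  ci <- fisher_z_interval(0.5, 0.1, 0.95)
  q <- qnorm(0.975)
  expect_equal(unname(ci["lower"]), tanh(atanh(0.5) - q * 0.1 / 0.75),
               tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), tanh(atanh(0.5) + q * 0.1 / 0.75),
               tolerance = 1e-10)
  # symmetry at zero
  ci0 <- fisher_z_interval(0, 0.1)
  expect_equal(unname(ci0["lower"]), -unname(ci0["upper"]))
  # collapses onto the point as se -> 0
  ciz <- fisher_z_interval(0.3, 1e-12)
  expect_lt(ciz["upper"] - ciz["lower"], 1e-10)
  # endpoints never leave [-1, 1] even when the z-interval saturates tanh
  expect_true(all(abs(c(fisher_z_interval(0.99, 0.5))) <= 1))
  expect_true(all(abs(c(fisher_z_interval(0.9, 0.05))) < 1))
  expect_error(fisher_z_interval(1, 0.1), "undefined")
})

test_that("convergence and admissibility are classified separately", {
  lam <- seq(0.4, 0.8, length.out = 10)
  base <- cfa_fit(perfect_polychoric(lam, 0.5), 500, "RULS")
  expect_true(base$converged && base$admissible)
  # a loading at the Heywood bound -> inadmissible (negative implied
  # error variance), but still converged
  hey <- base; hey$loadings[3] <- 0.999
  hey <- classify_fit(hey)
  expect_true(hey$converged)
  expect_false(hey$admissible)
  expect_equal(hey$reason, "heywood")
  # an out-of-range factor correlation -> inadmissible
  oob <- base; oob$xi <- 1.05
  expect_false(classify_fit(oob)$admissible)
  # non-converged fits are never also counted inadmissible
  nc <- base; nc$converged <- FALSE; nc$reason <- NULL
  nc <- classify_fit(nc)
  expect_false(nc$admissible)
  expect_equal(nc$reason, "non-converged")
  # boundary-clipped polychoric input poisons admissibility
  pcb <- perfect_polychoric(lam, 0.5); pcb$boundary <- TRUE
  expect_false(classify_fit(base, pcb)$admissible)
})

test_that("WLS refuses a non-positive-definite ACM", {
  lam <- seq(0.4, 0.8, length.out = 10)
  pc <- perfect_polychoric(lam, 0.5)
  pc$acm_pd <- FALSE
  ft <- cfa_fit(pc, 100, "WLS")
  expect_false(ft$converged)
  expect_equal(ft$reason, "acm-not-pd")
  # other methods do not need a PD ACM for point estimation
  expect_true(cfa_fit(pc, 100, "RULS")$converged)
})

test_that("both stored standard errors are available and used as asked", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 400, seed = 55)
  pc <- polychoric(d)
  f1 <- cfa_fit(pc, 400, "RULS", se = "fisherz")
  f2 <- cfa_fit(pc, 400, "RULS", se = "sandwich")
  expect_equal(f1$xi, f2$xi)
  expect_equal(f1$se_xi, (1 - f1$xi^2) / sqrt(400 - 3), tolerance = 1e-12)
  expect_equal(f2$se_xi, f2$se_xi_sandwich)
  expect_equal(f1$se_xi_sandwich, f2$se_xi_sandwich)
  # the naive Fisher-z SE ignores loading-estimation noise, so it is
  # smaller than the ACM-propagated one
  expect_lt(f1$se_xi, f2$se_xi_sandwich)
})
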