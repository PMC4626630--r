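test_that("thresholds are normal quantiles of cumulative margins", {
  col <- rep(1:4, times = c(25, 25, 25, 25))
  th <- estimate_thresholds(col)
  expect_equal(th$tau, qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(th$k, 4L)
  # two observed categories -> median split at 0
  th2 <- estimate_thresholds(rep(1:2, each = 50), n_categories = 2L)
  expect_equal(th2$tau, 0)
  # empty categories collapse; a single observed category is degenerate
  th3 <- estimate_thresholds(rep(c(1L, 4L), c(30, 70)))
  expect_equal(th3$k, 2L)
  expect_true(th3$collapsed)
  expect_equal(th3$tau, qnorm(0.3))
  expect_error(estimate_thresholds(rep(1L, 100)), "degenerate")
})

test_that("pairwise estimates agree with the brute-force grid oracle", {
  set.seed(21)
  for (case in 1:6) {
    n <- sample(40:200, 1)
    rho <- runif(1, -0.9, 0.9)
    z <- matrix(rnorm(2 * n), n, 2) %*%
      chol(matrix(c(1, rho, rho, 1), 2))
    cats <- sample(2:4, 2, replace = TRUE)
    cuts1 <- sort(rnorm(cats[1] - 1, sd = 0.8))
    cuts2 <- sort(rnorm(cats[2] - 1, sd = 0.8))
    x <- findInterval(z[, 1], cuts1) + 1L
    y <- findInterval(z[, 2], cuts2) + 1L
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    tx <- estimate_thresholds(x, max(x))
    ty <- estimate_thresholds(y, max(y))
    pr <- polychoric_pair(tx$map[x], ty$map[y], tx$tau, ty$tau)
    counts <- matrix(as.numeric(table(factor(tx$map[x], levels = seq_len(tx$k)),
                                      factor(ty$map[y], levels = seq_len(ty$k)))),
                     tx$k)
    oracle <- grid_polychoric(counts, tx$tau, ty$tau)
    # agreement to the grid resolution, or an exact likelihood tie (the
    # profile can be flat to machine precision near the boundary)
    ll_opt <- ordcfa:::table_loglik(pr$rho, tx$tau, ty$tau, counts)
    ll_grid <- ordcfa:::table_loglik(oracle, tx$tau, ty$tau, counts)
    expect_true(abs(pr$rho - oracle) < 1e-4 + 1e-12 || ll_opt >= ll_grid)
    expect_gte(ll_opt, ll_grid - 1e-7)
  }
})

test_that("independence, consistency and boundary cases behave", {
  # table proportional to independence
  x <- rep(rep(1:4, each = 4), times = 25)
  y <- rep(rep(1:4, times = 4), times = 25)
  tau <- qnorm(c(0.25, 0.5, 0.75))
  pr <- polychoric_pair(x, y, tau, tau)
  expect_lt(abs(pr$rho), 1e-6)
  # large-sample consistency at rho = 0.5, quartile thresholds
  set.seed(22)
  n <- 2e5
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
  x <- findInterval(z[, 1], tau) + 1L
  y <- findInterval(z[, 2], tau) + 1L
  pr2 <- polychoric_pair(x, y, tau, tau)
  expect_lt(abs(pr2$rho - 0.5), 0.01)
  # perfect association on a 2x2 diagonal table hits the positive bound
  x3 <- rep(1:2, each = 30); y3 <- x3
  pr3 <- polychoric_pair(x3, y3, 0, 0)
  expect_true(pr3$boundary)
  expect_equal(pr3$rho, 0.999)
})

test_that("estimator bias shrinks with sample size", {
  spec <- model_spec(rep(0.7, 10), 0.5)
  tau <- qnorm(c(0.25, 0.5, 0.75))
  truth <- 0.49  # lambda_i lambda_j at 0.7, within factor 1
  err <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    reps <- vapply(1:20, function(i) {
      d <- generate_dataset(spec, n)
      Z <- d$responses
      polychoric_pair(Z[, 1], Z[, 2], tau, tau)$rho
    }, numeric(1))
    abs(mean(reps) - truth)
  }, numeric(1))
  expect_lt(err[3], err[1] + 0.01)
  expect_lt(err[3], 0.01)
})

test_that("full-matrix estimation is symmetric with the fixed pair order", {
  d <- generate_dataset(model_spec(draw_loadings(), 0.5), 300, seed = 23)
  pc <- polychoric(d, acm = FALSE)
  expect_identical(pc$R, t(pc$R))
  expect_equal(diag(pc$R), rep(1, 10))
  expect_equal(pc$R[lower.tri(pc$R)], pc$r)
  expect_equal(pc$pairs[1, ], c(row = 2L, col = 1L))
  expect_equal(pc$pairs[45, ], c(row = 10L, col = 9L))
  # off-block entries vanish when factors are uncorrelated
  d0 <- generate_dataset(model_spec(rep(0.7, 10), 0), 2e4, seed = 24)
  pc0 <- polychoric(d0, acm = FALSE)
  cross <- pc0$R[6:10, 1:5]
  expect_lt(max(abs(cross)), 0.03)
})

test_that("the ACM is symmetric, scale-consistent, and rank-limited at n = 42", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 400, seed = 25)
  pc <- polychoric(d)
  expect_identical(pc$acm, t(pc$acm))
  expect_true(pc$acm_pd)
  # n = 42: fewer observations than correlations, never positive definite
  for (s in 1:5) {
    d42 <- generate_dataset(model_spec(draw_loadings(), 0.5), 42, seed = 30 + s)
    expect_false(polychoric(d42)$acm_pd)
  }
})

test_that("ACM diagonals calibrate against Monte-Carlo variance of r", {
  # sqrt(n) scale convention: diag(acm)/n estimates Var(r_q)
  spec <- model_spec(rep(0.6, 10), 0.5)
  n <- 1500
  d <- generate_dataset(spec, n, seed = 40)
  g_fix <- diag(polychoric(d)$acm) / n
  g_adj <- diag(polychoric(d, acm_method = "score-adjusted")$acm) / n
  reps <- t(vapply(1:250, function(i)
    polychoric(generate_dataset(spec, n, seed = 4000 + i), acm = FALSE)$r,
    numeric(45)))
  mc <- apply(reps, 2, var)
  for (g in list(g_fix, g_adj)) {
    ratio <- g / mc
    expect_gt(mean(ratio >= 0.8 & ratio <= 1.25), 0.85)
    expect_true(all(ratio > 0.6 & ratio < 1.6))
  }
})

test_that("the standalone ACM stage augments an ACM-free result", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 200, seed = 44)
  bare <- polychoric(d, acm = FALSE)
  expect_null(bare$acm)
  aug <- estimate_acm(d, bare)
  ref <- polychoric(d)
  expect_equal(aug$acm, ref$acm)
  expect_equal(aug$acm_pd, ref$acm_pd)
  expect_equal(aug$r, bare$r)
})

test_that("jackknife ACM agrees with the threshold-adjusted score ACM", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 120, seed = 41)
  gs <- polychoric(d, acm_method = "score-adjusted")$acm
  gj <- polychoric(d, acm_method = "jackknife")$acm
  expect_identical(gj, t(gj))
  expect_gt(cor(diag(gs), diag(gj)), 0.8)
  expect_true(all(diag(gj) / diag(gs) > 0.5 & diag(gj) / diag(gs) < 2))
})

test_that("polychoric results serialize to JSON", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 150, seed = 42)
  pc <- polychoric(d)
  path <- file.path(tempdir(), "pc.json")
  write_polychoric(pc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$r, pc$r, tolerance = 1e-12)
  expect_equal(back$acm_pd, pc$acm_pd)
  unlink(path)
})
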