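test_that("sampler states respect supports, bins and ordering", {
  d <- generate_dataset(model_spec(draw_loadings(), 0.5), 150, seed = 61)
  set.seed(62)
  state <- ordcfa:::init_state(d$responses, prior_spec("lessinf"))
  for (it in 1:60) {
    state <- step_thresholds(state)
    state <- step_latent(state)
    state <- step_structural(state, adapt = TRUE)
    expect_true(all(diff(t(state$tau)) > 0))     # ordered per item
    expect_true(all(state$a > 0))
    expect_true(abs(state$xi) < 1)
    # every latent response sits in the bin of its observed category
    for (j in c(1, 6)) {
      cuts <- c(-Inf, state$tau[j, ], Inf)
      lo <- cuts[d$responses[, j]]
      hi <- cuts[d$responses[, j] + 1L]
      expect_true(all(state$ystar[, j] >= lo & state$ystar[, j] <= hi))
    }
  }
})

test_that("latent draws have the truncated-normal cell mean", {
  d <- generate_dataset(model_spec(rep(0.6, 10), 0.5), 50, seed = 63)
  set.seed(64)
  state <- ordcfa:::init_state(d$responses, prior_spec("lessinf"))
  state$a <- rep(0.6, 10)
  draws <- replicate(600, {
    s <- step_latent(state)
    s$ystar[1, 1]
  })
  cuts <- c(-Inf, state$tau[1, ], Inf)
  ccat <- d$responses[1, 1]
  m <- state$a[1] * state$omega[1, 1]
  s <- sqrt(1 - state$a[1]^2)
  expected <- truncnorm::etruncnorm(a = cuts[ccat], b = cuts[ccat + 1],
                                    mean = m, sd = s)
  se_mc <- sqrt(truncnorm::vtruncnorm(a = cuts[ccat], b = cuts[ccat + 1],
                                      mean = m, sd = s) / 600)
  expect_lt(abs(mean(draws) - expected), 4 * se_mc)
})

test_that("chains are reproducible and respect the informative support", {
  d <- generate_dataset(model_spec(rep(0.7, 10), 0.5), 80, seed = 65)
  c1 <- run_chain(d, prior_spec("inf"), n_burn = 100, n_keep = 150, seed = 66)
  c2 <- run_chain(d, prior_spec("inf"), n_burn = 100, n_keep = 150, seed = 66)
  expect_identical(c1, c2)
  expect_true(all(c1[, "xi"] > 0 & c1[, "xi"] < 1))
  expect_true(all(c1[, paste0("a", 1:10)] > 0))
  # n_keep = 0 retains nothing
  c0 <- run_chain(d, prior_spec("inf"), n_burn = 10, n_keep = 0, seed = 66)
  expect_equal(nrow(c0), 0)
})

test_that("with no data the posterior for xi is its uniform prior", {
  ch <- run_chain(empty_dataset(), prior_spec("lessinf"),
                  n_burn = 300, n_keep = 2000, seed = 67)
  ks <- suppressWarnings(ks.test(ch[, "xi"], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  chi <- run_chain(empty_dataset(), prior_spec("inf"),
                   n_burn = 300, n_keep = 2000, seed = 68)
  ksi <- suppressWarnings(ks.test(chi[, "xi"], "punif", 0, 1))
  expect_gt(ksi$p.value, 0.01)
})

test_that("the posterior recovers the generating correlation", {
  d <- generate_dataset(model_spec(rep(0.7, 10), 0.8), 2000, seed = 69)
  bf <- bayes_fit(d, prior_spec("inf"), n_chains = 2, n_burn = 400,
                  n_keep = 400, seed = 70)
  expect_lt(abs(bf$eap - 0.8), 0.05)
  expect_true(bf$ci["lower"] < bf$eap & bf$eap < bf$ci["upper"])
  expect_true(all(bf$xi_draws > 0 & bf$xi_draws < 1))
  # split-half stationarity, with the Monte-Carlo error taken from the
  # autocorrelation-adjusted effective sample size
  xs <- bf$chains[[1]][, "xi"]
  half <- length(xs) %/% 2
  ess <- coda::effectiveSize(coda::mcmc(xs))
  se <- sd(xs) / sqrt(ess / 2)
  expect_lt(abs(mean(xs[1:half]) - mean(xs[-(1:half)])), 4 * se)
})

test_that("MPSRF has its floor, null behavior, and detects separation", {
  set.seed(71)
  base <- matrix(rnorm(5000 * 3), 5000, 3)
  expect_equal(mpsrf(list(base, base)), sqrt((5000 - 1) / 5000),
               tolerance = 1e-12)
  iid <- lapply(1:3, function(i) matrix(rnorm(10000 * 3), 10000, 3))
  expect_lt(mpsrf(iid), 1.05)
  expect_gte(mpsrf(iid), sqrt((10000 - 1) / 10000) - 1e-9)
  apart <- list(matrix(rnorm(500 * 2, -0.5), 500, 2),
                matrix(rnorm(500 * 2, 0.5), 500, 2))
  expect_gt(mpsrf(apart), 1.2)
  expect_error(mpsrf(list(base)), "at least 2")
  # agrees with the reference implementation up to its chain-count factor
  ch <- lapply(1:3, function(i) matrix(rnorm(2000 * 4), 2000, 4) + 0.02 * i)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                           autoburnin = FALSE)$mpsrf
  m <- 3; nv <- 4; n <- 2000
  lam1 <- (mpsrf(ch)^2 - (n - 1) / n) / ((m + 1) / m)
  ref_mine <- sqrt((n - 1) / n + (1 + 1 / nv) * lam1)
  expect_equal(ref_mine, ref, tolerance = 1e-6)
})

test_that("Heidelberger-Welch flags engineered non-stationarity", {
  set.seed(72)
  good <- rnorm(5000, mean = 2)
  hw_good <- heidelberger_welch(good)
  expect_true(hw_good$pass)
  expect_equal(hw_good$usable_frac, 1)
  expect_true(hw_good$halfwidth_pass)
  # an early level shift is trimmed away, not ignored
  early <- c(rnorm(1000, 6), rnorm(4000))
  hw_early <- heidelberger_welch(early)
  expect_true(hw_early$pass)
  expect_lt(hw_early$usable_frac, 1)
  # a drift spanning the whole chain fails every trimmed window
  trend <- seq(0, 4, length.out = 5000) + rnorm(5000)
  expect_false(heidelberger_welch(trend)$pass)
  # with progressive trimming the null pass rate sits near 1 and nearly
  # the whole chain is usable
  res <- vapply(1:120, function(i) {
    h <- heidelberger_welch(rnorm(1500))
    c(h$pass, h$usable_frac)
  }, numeric(2))
  expect_gt(mean(res[1, ]), 0.95)
  expect_gt(mean(res[2, ]), 0.9)
  const <- rep(1.234, 500)
  hw <- heidelberger_welch(const)
  expect_true(hw$pass)
  expect_true(hw$halfwidth_pass)
  expect_error(heidelberger_welch(rnorm(50)), "too short")
  expect_error(heidelberger_welch(rnorm(500), alpha = 0.2), "alpha")
})

test_that("posterior summaries pool chains with quantile intervals", {
  ch <- matrix(0, 2000, 13,
               dimnames = list(NULL, c("xi", paste0("a", 1:10), "mu1", "mu2")))
  ch[, "xi"] <- rep(c(0.1, 0.3), each = 1000)
  ch[, paste0("a", 1:10)] <- 0.5
  s <- summarize_chains(list(ch))
  expect_equal(s$eap, 0.2)
  expect_equal(unname(s$ci),
               unname(quantile(ch[, "xi"], c(0.025, 0.975))))
  # all-equal draws give a zero-width interval at the value
  ch2 <- ch; ch2[, "xi"] <- 0.4
  s2 <- summarize_chains(list(ch2))
  expect_equal(unname(s2$ci), c(0.4, 0.4))
  expect_equal(s2$post_sd, 0)
})
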