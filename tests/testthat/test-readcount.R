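test_that("unit efficiency reduces the read-count model to exact Poisson", {
  tab <- test_density_table()
  expect_equal(umi_read_pmf(0, 1, 2, tab), exp(-2), tolerance = 1e-6)
  expect_lt(max(abs(umi_read_pmf(0:20, 1, 4, tab) - dpois(0:20, 4))), 1e-3)
  expect_equal(umi_read_moments(1, 7), list(mean = 7, variance = 7))

  # zero-truncated Poisson closed forms at T = 1
  cm <- umi_censored_moments(1, 2, 1, tab)
  ztp_mean <- 2 / (1 - exp(-2))
  ztp_var <- ztp_mean * (1 + 2 - ztp_mean)
  expect_equal(cm$mean, ztp_mean, tolerance = 1e-3)
  expect_equal(cm$variance, ztp_var, tolerance = 1e-3)
  expect_equal(umi_loss(1, 2, 1, tab), exp(-2), tolerance = 1e-3)
})

test_that("pmf agrees with the Monte-Carlo mixture oracle", {
  tab <- test_density_table()
  n <- 1e5
  f <- simulate_normalized_family(n, 0.5, seed = 31)
  # P(C=0) = E[exp(-F D)] at D = 1
  oracle <- exp(-f)
  expect_lt(
    abs(umi_read_pmf(0, 0.5, 1, tab) - mean(oracle)),
    3 * sd(oracle) / sqrt(n)
  )
})

test_that("closed-form moments match the numeric pmf series", {
  tab <- test_density_table()
  mom <- umi_read_moments(0.5, 4)
  expect_equal(mom$mean, 4)
  expect_equal(mom$variance, 4 + 16 / 3)

  k <- 0:300
  p <- umi_read_pmf(k, 0.6, 4, tab)
  expect_lt(sum(p[k > 4 + 10 * sqrt(umi_read_moments(0.6, 4)$variance)]), 1e-8)
  series <- umi_read_moments(0.6, 4)
  expect_equal(sum(k * p), series$mean, tolerance = 5e-3)
  expect_equal(sum(k^2 * p) - sum(k * p)^2, series$variance, tolerance = 5e-3)
})

test_that("pmf normalizes across the parameter space", {
  tab <- test_density_table()
  for (e in c(0.05, 0.3, 0.7, 1)) {
    for (d in c(0.25, 4, 300)) {
      v <- umi_read_moments(e, d)$variance
      k <- 0:ceiling(d + 12 * sqrt(v))
      expect_equal(sum(umi_read_pmf(k, e, d, tab)), 1, tolerance = 0.01)
    }
  }
})

test_that("censoring at T = 0 is the identity and raises the mean otherwise", {
  tab <- test_density_table()
  cm0 <- umi_censored_moments(0.6, 4, 0, tab)
  expect_identical(
    cm0[c("mean", "variance")],
    umi_read_moments(0.6, 4)
  )
  for (t in c(1, 3, 5)) {
    expect_gte(umi_censored_moments(0.6, 4, t, tab)$mean, 4)
  }
})

test_that("censored moments and loss match end-to-end Monte-Carlo simulation", {
  tab <- test_density_table()
  n <- 1e6
  withr::with_seed(55, {
    f <- simulate_normalized_family(n, 0.5)
    counts <- rpois(n, f * 4)
  })
  below <- counts < 5
  expect_lt(
    abs(umi_loss(0.5, 4, 5, tab) - mean(below)),
    3 * sd(below) / sqrt(n)
  )
  surv <- counts[!below]
  cm <- umi_censored_moments(0.5, 4, 5, tab)
  expect_lt(abs(cm$mean - mean(surv)), 3 * sd(surv) / sqrt(length(surv)))
  expect_lt(abs(cm$variance - var(surv)), 3 * var_se(surv))
})

test_that("random (E, D, T) triples agree with direct simulation", {
  tab <- test_density_table()
  withr::with_seed(550, {
    cases <- data.frame(
      e = round(runif(10, 0.2, 1), 2),
      d = round(runif(10, 1, 20), 1),
      t = sample(0:6, 10, replace = TRUE)
    )
  })
  n <- 2e5
  for (i in seq_len(nrow(cases))) {
    e <- cases$e[i]
    d <- cases$d[i]
    t <- cases$t[i]
    withr::with_seed(1000 + i, {
      counts <- rpois(n, simulate_normalized_family(n, e) * d)
    })
    below <- counts < t
    expect_lt(
      abs(umi_loss(e, d, t, tab) - mean(below)),
      3 * sd(below) / sqrt(n) + 1e-9
    )
    surv <- counts[!below]
    cm <- umi_censored_moments(e, d, t, tab)
    expect_lt(abs(cm$mean - mean(surv)), 3 * sd(surv) / sqrt(length(surv)))
  }
})

test_that("loss is monotone in depth, efficiency and threshold", {
  tab <- test_density_table()
  loss_d <- sapply(c(1, 2, 4, 8, 16), function(d) umi_loss(0.5, d, 3, tab))
  expect_true(all(diff(loss_d) < 0))
  loss_e <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(e) umi_loss(e, 4, 3, tab))
  expect_true(all(diff(loss_e) < 0))
  loss_t <- sapply(0:6, function(t) umi_loss(0.5, 4, t, tab))
  expect_true(all(diff(loss_t) > 0))
  expect_equal(loss_t[1], 0)
})

test_that("the truncated-Poisson baseline under-estimates the loss for E < 1", {
  tab <- test_density_table()
  expect_equal(poisson_loss_baseline(2 / (1 - exp(-2)), 1), exp(-2), tolerance = 1e-9)
  expect_equal(poisson_loss_baseline(3.7, 0), 0)
  expect_error(poisson_loss_baseline(0.9, 2), "must exceed")

  for (e in c(0.3, 0.5, 0.8)) {
    for (t in c(2, 5)) {
      cm <- umi_censored_moments(e, 6, t, tab)
      baseline <- poisson_loss_baseline(cm$mean, t)
      expect_lte(baseline, umi_loss(e, 6, t, tab))
    }
  }
})
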