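test_that("sample moments follow the textbook definitions", {
  expect_equal(
    umi_sample_moments(c(4, 4, 4, 4)),
    list(n_obs = 4L, mean = 4, variance = 0)
  )
  expect_equal(
    umi_sample_moments(integer(0), 5),
    list(n_obs = 0L, mean = NA_real_, variance = NA_real_)
  )
  expect_equal(
    umi_sample_moments(c(2, 4, 6), 2),
    list(n_obs = 3L, mean = 4, variance = 4)
  )
  expect_error(umi_sample_moments(c(1, 5), 3), "below the threshold")
})

test_that("the uncensored closed-form fit inverts the model moments", {
  fit <- fit_readcount_model(4, 4)
  expect_equal(fit$efficiency, 1)
  expect_equal(fit$depth, 4)
  expect_false(fit$at_boundary)

  # variance 28/3 at mean 4 is exactly the model at (E = 0.5, D = 4)
  fit <- fit_readcount_model(4, 28 / 3)
  expect_equal(fit$efficiency, 0.5)
  expect_equal(fit$depth, 4)

  # under-dispersed data clamp at E = 1
  fit <- fit_readcount_model(4, 2)
  expect_equal(fit$efficiency, 1)
  expect_equal(fit$depth, 4)
  expect_true(fit$at_boundary)

  # v' > 1 clamps at E = 0
  fit <- fit_readcount_model(2, 2 + 4 + 1)
  expect_equal(fit$efficiency, 0)
  expect_true(fit$at_boundary)

  expect_error(fit_readcount_model(0, 1), "positive")
})

test_that("censored fitting inverts the censored moments across the parameter grid", {
  tab <- test_density_table()
  for (e in seq(0.2, 1, by = 0.1)) {
    for (d in c(1, 2, 4, 10, 100)) {
      for (t in c(1, 2, 5, 10)) {
        cm <- umi_censored_moments(e, d, t, tab)
        fit <- fit_readcount_model(cm$mean, cm$variance, t, tab)
        expect_lt(abs(fit$efficiency - e), 1e-3)
        expect_lt(abs(fit$depth - d) / max(1, d), 1e-3)
      }
    }
  }
})

test_that("zero-truncated Poisson data recover the E = 1 boundary", {
  tab <- test_density_table()
  cm <- umi_censored_moments(1, 2, 1, tab)
  fit <- fit_readcount_model(cm$mean, cm$variance, 1, tab)
  expect_equal(fit$efficiency, 1)
  expect_lt(abs(fit$depth - 2), 1e-3)
  expect_true(fit$at_boundary)
})

test_that("threshold zero delegates to the closed form", {
  tab <- test_density_table()
  expect_identical(
    fit_readcount_model(4, 28 / 3, 0, tab),
    fit_readcount_model(4, 28 / 3)
  )
})

test_that("parameters and loss are recovered from simulated UMIs", {
  tab <- test_density_table()
  n <- 1e5
  true_loss5 <- umi_loss(0.6, 4, 5, tab)
  for (s in 1:5) {
    counts <- simulate_gene_counts(n, 0.6, 4, table = tab, seed = 9000 + s)
    # T = 0: all counts observable (zeros included)
    sm <- umi_sample_moments(counts)
    fit0 <- fit_readcount_model(sm$mean, sm$variance)
    expect_lt(abs(fit0$efficiency - 0.6), 0.02)
    expect_lt(abs(fit0$depth - 4), 0.05)

    surv <- counts[counts >= 5]
    sm5 <- umi_sample_moments(surv, 5)
    fit5 <- fit_readcount_model(sm5$mean, sm5$variance, 5, tab)
    # censoring leaves ~40% of the draws; per-seed bounds are ~3.5 sigma
    expect_lt(abs(fit5$efficiency - 0.6), 0.06)
    expect_lt(abs(fit5$depth - 4), 0.25)
    expect_lt(abs(estimate_loss(fit5, 5, tab) - true_loss5), 0.03)
  }
})

test_that("the loss correction is unbiased over repeated simulations", {
  tab <- test_density_table()
  n_true <- 1000
  ratios <- vapply(1:400, function(s) {
    counts <- simulate_gene_counts(n_true, 0.5, 4, table = tab, seed = 3000 + s)
    surv <- counts[counts >= 5]
    sm <- umi_sample_moments(surv, 5)
    fit <- fit_readcount_model(sm$mean, sm$variance, 5, tab)
    correct_count(sm$n_obs, estimate_loss(fit, 5, tab)) / n_true
  }, numeric(1))
  expect_gt(mean(ratios), 0.99)
  expect_lt(mean(ratios), 1.01)
})

test_that("fits never step outside the parameter domain", {
  tab <- test_density_table()
  withr::with_seed(808, {
    for (i in 1:20) {
      m <- runif(1, 5.2, 30)
      v <- runif(1, 0.2, 30)^2
      fit <- fit_readcount_model(m, v, 5, tab)
      expect_gte(fit$efficiency, min(tab$e))
      expect_lte(fit$efficiency, 1)
      expect_gt(fit$depth, 0)
    }
  })
})

test_that("count correction follows n_obs / (1 - loss)", {
  expect_equal(correct_count(91, 0.09), 100)
  expect_equal(correct_count(77, 0), 77)
  expect_equal(correct_count(50, 0.5), 100)
  expect_error(correct_count(10, 1), "\\[0, 1\\)")
  expect_error(correct_count(10, -0.1), "\\[0, 1\\)")
})
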